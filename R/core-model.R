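#' Sagittal-plane inverse rope model
#'
#' Computes the longitudinal position and vertical displacement of the
#' loaded point of an ideal rope from the normalized pitch angles `alpha`
#' (back segment) and `beta` (front segment). Both angles are positive when
#' the tape is displaced downward; the ingest layer is responsible for
#' flipping the physical front-pitch sign (see [normalize_pitch_signs()]).
#'
#' Two mathematically equivalent closed forms are provided. The ray form
#' intersects the two anchor rays:
#' \deqn{t = \cos\alpha + \sin\alpha \cos\beta / \sin\beta,\quad
#'       Z = -\sin(\alpha) L / t,\quad X_Z = \cos(\alpha) L / t}
#' where `X_Z` is the distance from the back anchor. The trigonometric form
#' uses \eqn{Z = -L / (1/\tan\alpha + 1/\tan\beta)}, \eqn{X_Z = |Z|/\tan\alpha}.
#' Both are evaluated in the device frame (origin mid-span), so the
#' returned `x_mm` is `X_Z - L/2`.
#'
#' Guard and degenerate cases, applied per frame:
#' \itemize{
#'   \item Small-angle guard: if `min(|alpha|, |beta|)` is strictly below
#'     `params$small_angle_deg`, the result defaults to `(0, 0)` (no
#'     displacement, X at mid-span) and `low_load` is flagged.
#'   \item Opposite signs with both magnitudes at or above the guard: the
#'     two rays do not intersect below the tape (unloaded / oscillating
#'     state). By default the frame is flagged `no_intersection` and the
#'     numeric outputs are `NA`; with `allow_negative = TRUE` the raw
#'     closed form is evaluated anyway (numerically unstable by design --
#'     used to study the effect of IMU drift before correction).
#' }
#'
#' @param alpha,beta Normalized back/front pitch angles, degrees. Vectors
#'   of equal length (or length 1, recycled).
#' @param geom A [device_geometry()].
#' @param params A [model_params()].
#' @param method `"ray"` (default) or `"trig"`; both agree to machine
#'   precision and are exposed separately so the agreement can be asserted.
#' @param allow_negative Evaluate the closed form for sign-discordant or
#'   negative angle pairs instead of flagging them (default `FALSE`).
#'
#' @return A data.frame with columns `x_mm` (device-frame longitudinal
#'   position), `z_mm` (vertical displacement, <= 0 under load), and
#'   logical flags `low_load`, `no_intersection`.
#' @export
#' @examples
#' g <- luna_geometry(); p <- model_params()
#' estimate_sagittal(10, 10, g, p)           # symmetric load at mid-span
#' estimate_sagittal(0.05, 0.05, g, p)       # below guard -> zeros
estimate_sagittal <- function(alpha, beta, geom, params,
                              method = c("ray", "trig"),
                              allow_negative = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(geom, "tape_geometry"), inherits(params, "tape_params"))
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(as.numeric(alpha), n)
  beta <- rep_len(as.numeric(beta), n)
  if (any(!is.finite(alpha)) || any(!is.finite(beta))) {
    stop("pitch angles must be finite")
  }
  if (any(abs(alpha) >= 90) || any(abs(beta) >= 90)) {
    stop("pitch angles must satisfy |angle| < 90 degrees")
  }
  planar_intersection(alpha, beta, geom, params, method, allow_negative,
                      vertical = TRUE)
}

#' Transversal-plane inverse rope model
#'
#' The same closed-form ray-intersection model as [estimate_sagittal()]
#' applied in the horizontal plane: the yaw angles of the back and front
#' anchor segments determine the lateral displacement `y_mm` and a second,
#' independent longitudinal position estimate `x_mm`. Yaw angles are
#' normalized so that both share the sign of the lateral displacement
#' (positive = displaced toward +Y). No flat-segment correction is applied
#' in this plane. Lateral displacements may take either sign; the guard and
#' sign-discordance rules act on the magnitudes.
#'
#' @inheritParams estimate_sagittal
#' @param yaw_back,yaw_front Normalized yaw angles, degrees.
#' @return A data.frame with columns `x_mm`, `y_mm`, `low_load`,
#'   `no_intersection`.
#' @export
estimate_transversal <- function(yaw_back, yaw_front, geom, params,
                                 method = c("ray", "trig"),
                                 allow_negative = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(geom, "tape_geometry"), inherits(params, "tape_params"))
  n <- max(length(yaw_back), length(yaw_front))
  yaw_back <- rep_len(as.numeric(yaw_back), n)
  yaw_front <- rep_len(as.numeric(yaw_front), n)
  if (any(!is.finite(yaw_back)) || any(!is.finite(yaw_front))) {
    stop("yaw angles must be finite")
  }
  if (any(abs(yaw_back) >= 90) || any(abs(yaw_front) >= 90)) {
    stop("yaw angles must satisfy |angle| < 90 degrees")
  }
  out <- planar_intersection(yaw_back, yaw_front, geom, params, method,
                             allow_negative, vertical = FALSE)
  names(out)[names(out) == "z_mm"] <- "y_mm"
  out[, c("x_mm", "y_mm", "low_load", "no_intersection")]
}

# Shared planar ray-intersection core. In the vertical plane the
# displacement is reported as z <= 0 for positive (downward-normalized)
# angles; in the horizontal plane the common sign of the two yaw angles is
# the sign of the lateral displacement.
planar_intersection <- function(a_back, a_front, geom, params, method,
                                allow_negative, vertical) {
  L <- geom$span_l_mm
  thr <- params$small_angle_deg
  n <- length(a_back)

  low_load <- pmin(abs(a_back), abs(a_front)) < thr
  discordant <- !low_load & (sign(a_back) * sign(a_front) < 0)
  if (vertical) {
    # both-negative pairs put the intersection above the rest line, which a
    # tension-only tape cannot reach
    discordant <- discordant | (!low_load & a_back < 0 & a_front < 0)
  }

  x <- numeric(n)
  disp <- numeric(n)
  compute <- !low_load & (allow_negative | !discordant)

  if (any(compute)) {
    if (allow_negative) {
      aa <- deg2rad(a_back[compute])
      bb <- deg2rad(a_front[compute])
      s <- 1
    } else {
      aa <- deg2rad(abs(a_back[compute]))
      bb <- deg2rad(abs(a_front[compute]))
      # magnitudes are used; the common input sign carries the lateral
      # direction in the horizontal plane (vertical is always downward)
      s <- sign(a_back[compute])
    }
    if (method == "ray") {
      t <- cos(aa) + sin(aa) * cos(bb) / sin(bb)
      d <- sin(aa) * L / t        # displacement magnitude
      xz <- cos(aa) * L / t       # distance from back anchor
    } else {
      d <- L / (1 / tan(aa) + 1 / tan(bb))
      xz <- abs(d) / tan(aa)
    }
    x[compute] <- xz - L / 2
    disp[compute] <- if (vertical) -d else s * d
  }

  flag_na <- discordant & !allow_negative
  x[flag_na] <- NA_real_
  disp[flag_na] <- NA_real_

  data.frame(x_mm = x, z_mm = disp,
             low_load = low_load, no_intersection = discordant)
}

#' Flat-foot segment correction of the vertical displacement
#'
#' Rescales the point-mass model depth `dM` toward the true flat-segment
#' depth `dR` using the calibrated `segment_ratio` (dR/dM). Only the
#' vertical displacement is corrected; the longitudinal position is not
#' affected by this parameterization.
#'
#' @param z_mm Vertical displacement(s) from [estimate_sagittal()], mm.
#' @param params A [model_params()]; uses `segment_ratio`.
#' @return Corrected displacement(s), mm.
#' @export
#' @examples
#' apply_segment_correction(-100, model_params(segment_ratio = 0.85))  # -85
apply_segment_correction <- function(z_mm, params) {
  stopifnot(inherits(params, "tape_params"))
  params$segment_ratio * z_mm
}

#' Roll-angle prediction at the loaded tape segment
#'
#' Extrapolates the roll angles measured at the two anchor-adjacent sensor
#' sections to the foot position. Four variants are provided:
#' \describe{
#'   \item{RM}{Linear twist: the twist rate is constant from each anchor to
#'     the foot. The measured section roll is attributed to the inner
#'     boundary of the sensor section (at distance `s =
#'     sensor_section_end_mm` from its anchor), so each per-anchor estimate
#'     is `roll * d / s` with `d` the anchor-to-foot distance; RM is the
#'     mean of the two estimates.}
#'   \item{RS}{Spring-corrected: the spring segment twists at
#'     `spring_coeff` times the tape's rate, and the sensor section is
#'     taken to lie within the spring segment, so each per-anchor estimate
#'     is `roll * (k * Ls + (d - Ls)) / (k * Ls)` with `Ls` the spring
#'     length. RS is the mean of the two estimates; `k = 1` reduces RS to
#'     RM when `s = Ls`.}
#'   \item{RWS}{The RS per-anchor estimates combined with position-
#'     dependent linear weights so the sensor nearer the foot dominates:
#'     `w_back = (L - d_back)/L`, `w_front = 1 - w_back`.}
#'   \item{RA}{The plain sum `roll_front + roll_back`, ignoring the tape
#'     geometry altogether.}
#' }
#'
#' @param roll_back,roll_front Measured section roll angles, degrees.
#' @param x_mm Device-frame longitudinal foot position (typically the
#'   pitch-based estimate), mm. Unused by RA. `NA` positions yield `NA`
#'   predictions for RM/RS/RWS.
#' @param geom A [device_geometry()].
#' @param params A [model_params()]; `spring_coeff` feeds RS/RWS.
#' @param variant One of `"RM"`, `"RS"`, `"RWS"`, `"RA"`.
#' @return Predicted foot-segment roll, degrees.
#' @export
predict_roll <- function(roll_back, roll_front, x_mm, geom, params,
                         variant = c("RWS", "RM", "RS", "RA")) {
  variant <- match.arg(variant)
  stopifnot(inherits(geom, "tape_geometry"), inherits(params, "tape_params"))
  n <- max(length(roll_back), length(roll_front), length(x_mm))
  roll_back <- rep_len(as.numeric(roll_back), n)
  roll_front <- rep_len(as.numeric(roll_front), n)
  if (variant == "RA") {
    return(roll_back + roll_front)
  }
  x_mm <- rep_len(as.numeric(x_mm), n)
  L <- geom$span_l_mm
  bad <- !is.na(x_mm) & (x_mm < -L / 2 | x_mm > L / 2)
  if (any(bad)) stop("x_mm outside the anchor span")
  d_back <- x_mm + L / 2
  d_front <- L / 2 - x_mm

  if (variant == "RM") {
    s <- geom$sensor_section_end_mm
    est_b <- roll_back * d_back / s
    est_f <- roll_front * d_front / s
  } else {
    k <- params$spring_coeff
    Ls <- geom$spring_length_mm
    est_b <- roll_back * (k * Ls + pmax(d_back - Ls, 0)) / (k * Ls)
    est_f <- roll_front * (k * Ls + pmax(d_front - Ls, 0)) / (k * Ls)
  }
  if (variant == "RWS") {
    w_back <- (L - d_back) / L
    w_back * est_b + (1 - w_back) * est_f
  } else {
    (est_b + est_f) / 2
  }
}

#' Full per-frame tape state estimate
#'
#' Convenience driver running the sagittal and transversal models, the
#' flat-foot correction, and all four roll variants over a stream of
#' normalized anchor angles. Frames flagged `no_intersection` keep the
#' model's zero-default numeric outputs (no displacement, X at mid-span) so
#' that downstream statistics remain computable; the flags record which
#' frames those were.
#'
#' @param angles A data.frame with columns `time_s`, `pitch_back_deg`,
#'   `pitch_front_deg`, `yaw_back_deg`, `yaw_front_deg`, `roll_back_deg`,
#'   `roll_front_deg` (the schema written by [simulate_trial()]).
#' @param geom A [device_geometry()].
#' @param params A [model_params()].
#' @param allow_negative Passed to the planar estimators; see
#'   [estimate_sagittal()].
#' @return A data.frame with columns `time_s`, `xz_mm`, `z_mm`, `zr_mm`,
#'   `xy_mm`, `y_mm`, `roll_rm_deg`, `roll_rs_deg`, `roll_rws_deg`,
#'   `roll_ra_deg`, `low_load`, `no_intersection`.
#' @export
estimate_tape <- function(angles, geom, params, allow_negative = FALSE) {
  need <- c("pitch_back_deg", "pitch_front_deg", "yaw_back_deg",
            "yaw_front_deg", "roll_back_deg", "roll_front_deg")
  if (!all(need %in% names(angles))) {
    stop("angles is missing columns: ",
         paste(setdiff(need, names(angles)), collapse = ", "))
  }
  sag <- estimate_sagittal(angles$pitch_back_deg, angles$pitch_front_deg,
                           geom, params, allow_negative = allow_negative)
  tra <- estimate_transversal(angles$yaw_back_deg, angles$yaw_front_deg,
                              geom, params, allow_negative = allow_negative)
  # zero-default for non-intersecting frames at the stream level
  xz <- ifelse(is.na(sag$x_mm), 0, sag$x_mm)
  z <- ifelse(is.na(sag$z_mm), 0, sag$z_mm)
  xy <- ifelse(is.na(tra$x_mm), 0, tra$x_mm)
  y <- ifelse(is.na(tra$y_mm), 0, tra$y_mm)
  roll_x <- ifelse(sag$low_load | sag$no_intersection, 0, xz)
  out <- data.frame(
    time_s = if ("time_s" %in% names(angles)) angles$time_s else
      seq_len(nrow(angles)),
    xz_mm = xz,
    z_mm = z,
    zr_mm = apply_segment_correction(z, params),
    xy_mm = xy,
    y_mm = y,
    roll_rm_deg = predict_roll(angles$roll_back_deg, angles$roll_front_deg,
                               roll_x, geom, params, "RM"),
    roll_rs_deg = predict_roll(angles$roll_back_deg, angles$roll_front_deg,
                               roll_x, geom, params, "RS"),
    roll_rws_deg = predict_roll(angles$roll_back_deg, angles$roll_front_deg,
                                roll_x, geom, params, "RWS"),
    roll_ra_deg = predict_roll(angles$roll_back_deg, angles$roll_front_deg,
                               roll_x, geom, params, "RA"),
    low_load = sag$low_load & tra$low_load,
    no_intersection = sag$no_intersection | tra$no_intersection
  )
  out
}

#' Per-frame quality flags
#'
#' Heuristic reliability indicators for a stream of tape estimates:
#' \describe{
#'   \item{LOW_LOAD}{the small-angle guard fired in both planes;}
#'   \item{XZ_XY_DISCREPANCY}{the two independent longitudinal estimates
#'     disagree by more than `xz_xy_bound_mm` while both planes are
#'     loaded;}
#'   \item{TEMPORAL_JUMP}{the pitch-based X estimate jumps by more than a
#'     foot length between consecutive loaded frames without an
#'     intervening low-load (foot lift-off) phase.}
#' }
#'
#' @param est A data.frame from [estimate_tape()].
#' @param geom A [device_geometry()].
#' @param xz_xy_bound_mm Discrepancy bound, mm (default 300).
#' @param foot_length_mm Foot length used for the temporal-jump rule, mm
#'   (default 300).
#' @return A character vector (one `;`-separated flag string per frame,
#'   `""` when clean).
#' @export
quality_flags <- function(est, geom, xz_xy_bound_mm = 300,
                          foot_length_mm = 300) {
  n <- nrow(est)
  flags <- vector("list", n)
  loaded <- !(est$low_load | est$no_intersection)
  disc <- loaded & abs(est$xz_mm - est$xy_mm) > xz_xy_bound_mm
  jump <- rep(FALSE, n)
  if (n > 1) {
    dx <- abs(diff(est$xz_mm))
    both_loaded <- loaded[-1] & loaded[-n]
    jump[-1] <- both_loaded & dx > foot_length_mm
  }
  vapply(seq_len(n), function(i) {
    f <- character(0)
    if (est$low_load[i]) f <- c(f, "LOW_LOAD")
    if (disc[i]) f <- c(f, "XZ_XY_DISCREPANCY")
    if (jump[i]) f <- c(f, "TEMPORAL_JUMP")
    paste(f, collapse = ";")
  }, character(1))
}

#' Calibrate model parameters from single-mode recordings
#'
#' Least-squares estimation of the flat-foot `segment_ratio` or the spring
#' twist-rate multiple `spring_coeff` from calibration frames in which the
#' tape was manipulated to isolate one mode: vertical displacement without
#' roll for `segment_ratio`, roll without vertical or lateral displacement
#' for `spring_coeff`.
#'
#' For `segment_ratio` the point-mass depth `dM` is computed from the pitch
#' angles of each frame and regressed through the origin against the
#' reference depth `dR`. For `spring_coeff` the RS model prediction is
#' linear in `1/k` once the measured rolls and foot positions are fixed, so
#' `1/k` is likewise obtained by a through-origin regression.
#'
#' @param angles Data.frame of normalized anchor angles (schema of
#'   [estimate_tape()]).
#' @param truth Data.frame with reference columns `x_mm`, `z_mm`,
#'   `roll_deg` aligned frame-by-frame with `angles` (ground-truth tape
#'   state, e.g. from [simulate_trial()] or marker-based references).
#' @param target `"segment_ratio"` or `"spring_coeff"`.
#' @param geom A [device_geometry()].
#' @param params Starting [model_params()]; the non-targeted entries are
#'   carried through unchanged.
#' @return An updated `tape_params` object with attribute `"residual_rms"`.
#' @export
calibrate_params <- function(angles, truth,
                             target = c("segment_ratio", "spring_coeff"),
                             geom, params = model_params()) {
  target <- match.arg(target)
  stopifnot(nrow(angles) == nrow(truth))
  if (nrow(angles) < 10) stop("calibration needs at least 10 frames")

  if (target == "segment_ratio") {
    sag <- estimate_sagittal(angles$pitch_back_deg, angles$pitch_front_deg,
                             geom, params)
    ok <- !sag$low_load & !sag$no_intersection
    dm <- -sag$z_mm[ok]
    dr <- -truth$z_mm[ok]
    if (length(dm) < 10 || sum(dm^2) < 1e-8) {
      stop("degenerate calibration frames: no vertical excitation")
    }
    ratio <- sum(dm * dr) / sum(dm^2)
    res <- sqrt(mean((dr - ratio * dm)^2))
    out <- model_params(segment_ratio = ratio,
                        spring_coeff = params$spring_coeff,
                        small_angle_deg = params$small_angle_deg)
  } else {
    # RS per-anchor estimate: roll * (1 + (d - Ls)/(k*Ls)); mean of the two
    # anchors => truth_roll - mean(roll) = (1/k) * c with
    # c = mean(roll * (d - Ls)/Ls)
    L <- geom$span_l_mm
    Ls <- geom$spring_length_mm
    d_back <- truth$x_mm + L / 2
    d_front <- L / 2 - truth$x_mm
    rb <- angles$roll_back_deg
    rf <- angles$roll_front_deg
    excited <- abs(truth$roll_deg) > 10 * .Machine$double.eps
    cvec <- (rb * pmax(d_back - Ls, 0) + rf * pmax(d_front - Ls, 0)) /
      (2 * Ls)
    resid0 <- truth$roll_deg - (rb + rf) / 2
    use <- excited & abs(cvec) > 0
    if (sum(use) < 10 || sum(cvec[use]^2) < 1e-12) {
      stop("degenerate calibration frames: no roll excitation")
    }
    inv_k <- sum(cvec[use] * resid0[use]) / sum(cvec[use]^2)
    if (inv_k <= 0) stop("calibration produced a non-positive spring_coeff")
    k <- 1 / inv_k
    res <- sqrt(mean((resid0[use] - inv_k * cvec[use])^2))
    out <- model_params(segment_ratio = params$segment_ratio,
                        spring_coeff = k,
                        small_angle_deg = params$small_angle_deg)
  }
  attr(out, "residual_rms") <- res
  out
}

#' Normalize physical pitch signs to the model convention
#'
#' The model expects both pitch angles to be positive when the tape is
#' displaced downward; in the physical device frame the front pitch has the
#' opposite sign. This helper flips the front pitch column of a raw angle
#' stream.
#'
#' @param angles Data.frame with a `pitch_front_deg` column.
#' @return The data.frame with `pitch_front_deg` negated.
#' @export
normalize_pitch_signs <- function(angles) {
  stopifnot("pitch_front_deg" %in% names(angles))
  angles$pitch_front_deg <- -angles$pitch_front_deg
  angles
}
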