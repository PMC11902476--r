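#' Foot load description for the forward simulator
#'
#' @param x_mm Device-frame longitudinal center of the foot contact, mm.
#' @param depth_mm True lowest-point vertical displacement (dR), mm, >= 0.
#' @param flat_mm Length of the flat foot-contact segment (LF), mm; 0 is a
#'   point load.
#' @param y_mm Lateral displacement of the contact, mm.
#' @param roll_deg Roll angle of the foot-contact segment, degrees.
#' @param airborne Logical; `TRUE` forces an unloaded tape (all
#'   displacements zero).
#' @return A list of class `foot_load`.
#' @export
foot_load <- function(x_mm = 0, depth_mm = 0, flat_mm = 0, y_mm = 0,
                      roll_deg = 0, airborne = FALSE) {
  if (airborne) {
    depth_mm <- 0; y_mm <- 0; roll_deg <- 0
  }
  stopifnot(depth_mm >= 0, flat_mm >= 0)
  structure(list(x_mm = x_mm, depth_mm = depth_mm, flat_mm = flat_mm,
                 y_mm = y_mm, roll_deg = roll_deg, airborne = airborne),
            class = "foot_load")
}

#' IMU degradation specification
#'
#' Parameters of the simulated orientation-sensor error model: additive
#' white noise on every channel, a deterministic one-sided (negative-going)
#' pitch ramp, an unbiased random walk on yaw, and an optional roll ramp
#' (zero by default, matching the observation that sensor-fusion roll does
#' not drift appreciably).
#'
#' @param pitch_drift_rate_dps Pitch ramp rate, degrees/second (negative =
#'   drift toward negative normalized pitch).
#' @param yaw_walk_sd Standard deviation of the yaw random-walk increment
#'   per sqrt(second), degrees.
#' @param roll_drift_rate_dps Roll ramp rate, degrees/second (default 0).
#' @param noise_sigma_deg White-noise standard deviation, degrees.
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return A list of class `drift_spec`.
#' @export
drift_spec <- function(pitch_drift_rate_dps = -0.05, yaw_walk_sd = 0.02,
                       roll_drift_rate_dps = 0, noise_sigma_deg = 0.1,
                       seed = NULL) {
  stopifnot(noise_sigma_deg >= 0, yaw_walk_sd >= 0)
  structure(list(pitch_drift_rate_dps = pitch_drift_rate_dps,
                 yaw_walk_sd = yaw_walk_sd,
                 roll_drift_rate_dps = roll_drift_rate_dps,
                 noise_sigma_deg = noise_sigma_deg,
                 seed = seed),
            class = "drift_spec")
}

# Piecewise-linear twist profile on one side of the foot: rate is
# `mult` times larger within the first `ls` mm from the anchor; the
# accumulated rotation at the contact point (distance `d`) equals `total`.
# Returns the rotation at distance `u` from the anchor.
twist_at <- function(u, d, ls, mult, total) {
  if (total == 0 || d <= 0) return(rep(0, length(u)))
  ls_eff <- min(ls, d)
  rate <- total / (mult * ls_eff + max(d - ls_eff, 0))
  ifelse(u <= ls_eff, mult * rate * u,
         mult * rate * ls_eff + rate * (pmin(u, d) - ls_eff))
}

# Orthonormal frame of a straight tape piece: e1 along the piece, e2 the
# cross-tape direction (projection of device Y), e3 = e1 x e2.
piece_frame <- function(p0, p1) {
  v <- p1 - p0
  e1 <- v / sqrt(sum(v^2))
  ey <- c(0, 1, 0)
  e2 <- ey - sum(ey * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' Forward geometric simulation of a statically loaded tape
#'
#' Constructs the exact ideal-rope geometry for one foot load: the tape is
#' a polyline of straight pieces from the anchors to the contact (point
#' load) or to the endpoints of a horizontal flat foot segment, with an
#' additional lateral kink at the spring boundary when `yaw_multiplier`
#' differs from 1. Torsion is piecewise linear with the twist rate
#' multiplied by `spring_coeff` inside the spring segments.
#'
#' Anchor angles are emitted with the model's sign normalization (pitch
#' positive at both ends for downward displacement, yaw sharing the sign
#' of the lateral displacement) as the plane-projection angles of the
#' anchor-adjacent piece -- exactly the quantities the inverse model
#' inverts. Section angles are the Tait-Bryan XYZ-intrinsic angles of each
#' section's rigid frame. Markers are generated by mapping each rest
#' marker rigidly onto its piece (with the along-piece stretch the rope
#' geometry implies), so sections lying wholly on one straight piece with
#' constant twist deform exactly rigidly and Kabsch reconstruction
#' recovers their angles to machine precision; sections straddling the
#' contact (or carrying a twist gradient) are only approximately rigid,
#' as on the physical device.
#'
#' @param load A [foot_load()].
#' @param geom A [device_geometry()].
#' @param spring_coeff Twist-rate multiple of the spring segment (roll).
#' @param yaw_multiplier Lateral-slope multiple of the spring segment
#'   (default 1 = homogeneous lateral geometry).
#' @param markers Emit marker positions for the default [luna_layout()]
#'   (default `TRUE`).
#' @param jitter_sd_mm Isotropic Gaussian marker jitter, mm (default 0;
#'   ~0.5 mm emulates motion-capture marker jitter).
#' @return A list with elements `angles` (one-row data.frame of normalized
#'   anchor angles), `shape` (list: `polyline`, `sections`, `markers`,
#'   `contact`, `true_foot_roll_deg`), and the echoed `load`.
#' @export
#' @examples
#' sim <- simulate_static(foot_load(x_mm = 0, depth_mm = 150), luna_geometry())
#' sim$angles$pitch_back_deg  # atan(150/863) ~ 9.86 deg
simulate_static <- function(load, geom, spring_coeff = 1,
                            yaw_multiplier = 1, markers = TRUE,
                            jitter_sd_mm = 0) {
  stopifnot(inherits(load, "foot_load"), inherits(geom, "tape_geometry"))
  L <- geom$span_l_mm
  half <- L / 2
  xb <- load$x_mm - load$flat_mm / 2
  xf <- load$x_mm + load$flat_mm / 2
  if (xb <= -half || xf >= half) stop("foot load outside the anchor span")

  depth <- load$depth_mm
  yoff <- load$y_mm
  th <- load$roll_deg
  unloaded <- load$airborne || (depth == 0 && yoff == 0 && th == 0)

  run_b <- xb + half
  run_f <- half - xf
  ls <- geom$spring_length_mm
  s_end <- geom$sensor_section_end_mm
  k <- spring_coeff
  m <- yaw_multiplier

  # lateral kink slopes per side (spring slope = m * tape slope)
  lat_rate_b <- if (unloaded) 0 else
    yoff / (m * min(ls, run_b) + max(run_b - ls, 0))
  lat_rate_f <- if (unloaded) 0 else
    yoff / (m * min(ls, run_f) + max(run_f - ls, 0))

  if (unloaded) {
    ang <- data.frame(pitch_back_deg = 0, pitch_front_deg = 0,
                      yaw_back_deg = 0, yaw_front_deg = 0,
                      roll_back_deg = 0, roll_front_deg = 0)
  } else {
    ang <- data.frame(
      pitch_back_deg = rad2deg(atan2(depth, run_b)),
      pitch_front_deg = rad2deg(atan2(depth, run_f)),
      yaw_back_deg = rad2deg(atan(m * lat_rate_b)),
      yaw_front_deg = rad2deg(atan(m * lat_rate_f)),
      roll_back_deg = twist_at(s_end, run_b, ls, k, th),
      roll_front_deg = twist_at(s_end, run_f, ls, k, th)
    )
  }

  # polyline nodes with their rest-x coordinates; lateral spring kinks
  # only appear when the multiplier is not 1
  y_at <- function(x) {
    db <- x + half
    df <- half - x
    if (unloaded) return(rep(0, length(x)))
    ifelse(x <= xb,
           ifelse(db <= ls, m * lat_rate_b * db,
                  m * lat_rate_b * ls + lat_rate_b * (db - ls)),
           ifelse(x >= xf,
                  ifelse(df <= ls, m * lat_rate_f * df,
                         m * lat_rate_f * ls + lat_rate_f * (df - ls)),
                  yoff))
  }
  z_at <- function(x) {
    if (unloaded) return(rep(0, length(x)))
    ifelse(x <= xb, -depth * (x + half) / run_b,
           ifelse(x >= xf, -depth * (half - x) / run_f, -depth))
  }
  roll_at <- function(x) {
    if (unloaded) return(rep(0, length(x)))
    ifelse(x <= xb, twist_at(x + half, run_b, ls, k, th),
           ifelse(x >= xf, twist_at(half - x, run_f, ls, k, th), th))
  }

  node_x <- c(-half)
  if (!unloaded && m != 1 && run_b > ls) node_x <- c(node_x, -half + ls)
  node_x <- c(node_x, if (unloaded) numeric(0) else unique(c(xb, xf)))
  if (!unloaded && m != 1 && run_f > ls) node_x <- c(node_x, half - ls)
  node_x <- sort(unique(c(node_x, half)))
  nodes <- cbind(x_mm = node_x, y_mm = y_at(node_x), z_mm = z_at(node_x))

  # rigid mapping of a rest point (x, y_edge, 0) onto its piece
  piece_of <- function(x) findInterval(x, node_x, rightmost.closed = TRUE)
  frames_cache <- lapply(seq_len(nrow(nodes) - 1), function(i) {
    fr <- piece_frame(nodes[i, ], nodes[i + 1, ])
    fr$stretch <- sqrt(sum((nodes[i + 1, ] - nodes[i, ])^2)) /
      (node_x[i + 1] - node_x[i])
    fr
  })
  deform <- function(x, y_edge) {
    i <- piece_of(x)
    fr <- frames_cache[[i]]
    phi <- deg2rad(roll_at(x))
    nodes[i, ] + (x - node_x[i]) * fr$stretch * fr$e1 +
      y_edge * (cos(phi) * fr$e2 + sin(phi) * fr$e3)
  }

  layout <- luna_layout(geom)
  bounds <- layout$boundaries
  ns <- length(bounds) - 1

  sections <- data.frame(section = seq_len(ns), x_center_mm = NA_real_,
                         y_center_mm = NA_real_, z_center_mm = NA_real_,
                         roll_deg = NA_real_, pitch_deg = NA_real_,
                         yaw_deg = NA_real_)
  for (sct in seq_len(ns)) {
    bl <- bounds[sct]; br <- bounds[sct + 1]
    pl <- deform(bl, 0); pr <- deform(br, 0)
    phi <- (roll_at(bl) + roll_at(br)) / 2
    fr <- if (piece_of(bl) == piece_of(br)) frames_cache[[piece_of(bl)]]
          else piece_frame(pl, pr)
    phr <- deg2rad(phi)
    R <- cbind(fr$e1,
               cos(phr) * fr$e2 + sin(phr) * fr$e3,
               -sin(phr) * fr$e2 + cos(phr) * fr$e3)
    tb <- taitbryan_xyz(R)
    ctr <- (pl + pr) / 2
    sections$x_center_mm[sct] <- ctr[1]
    sections$y_center_mm[sct] <- ctr[2]
    sections$z_center_mm[sct] <- ctr[3]
    sections$roll_deg[sct] <- tb[["roll_deg"]]
    sections$pitch_deg[sct] <- tb[["pitch_deg"]]
    sections$yaw_deg[sct] <- tb[["yaw_deg"]]
  }

  mk <- NULL
  if (markers) {
    mk <- layout$markers
    pos <- t(vapply(seq_len(nrow(mk)),
                    function(i) deform(mk$x_mm[i], mk$edge_offset_mm[i]),
                    numeric(3)))
    mk <- data.frame(label = mk$label, x_mm = pos[, 1], y_mm = pos[, 2],
                     z_mm = pos[, 3], stringsAsFactors = FALSE)
    if (jitter_sd_mm > 0) {
      nmk <- nrow(mk)
      mk$x_mm <- mk$x_mm + stats::rnorm(nmk, 0, jitter_sd_mm)
      mk$y_mm <- mk$y_mm + stats::rnorm(nmk, 0, jitter_sd_mm)
      mk$z_mm <- mk$z_mm + stats::rnorm(nmk, 0, jitter_sd_mm)
    }
  }

  list(angles = ang,
       shape = list(polyline = nodes, sections = sections, markers = mk,
                    contact = c(x_back = xb, x_front = xf,
                                depth_mm = depth, y_mm = yoff),
                    true_foot_roll_deg = th),
       load = load)
}

# Monotone-cubic interpolation of a keyframe channel onto a time grid;
# falls back to constant for a single keyframe.
interp_channel <- function(t_key, v_key, t_out) {
  if (length(unique(v_key)) == 1L) return(rep(v_key[1], length(t_out)))
  f <- stats::splinefun(t_key, v_key, method = "monoH.FC")
  f(pmin(pmax(t_out, min(t_key)), max(t_key)))
}

# Vectorized anchor-angle computation over frame vectors (the per-frame
# closed forms of simulate_static, without shapes/markers).
static_angles_vec <- function(x, depth, flat, y, roll, air, geom,
                              spring_coeff, yaw_multiplier) {
  L <- geom$span_l_mm; half <- L / 2
  ls <- geom$spring_length_mm; s_end <- geom$sensor_section_end_mm
  k <- spring_coeff; m <- yaw_multiplier
  xb <- x - flat / 2; xf <- x + flat / 2
  if (any(xb <= -half | xf >= half)) stop("foot load outside the anchor span")
  run_b <- xb + half; run_f <- half - xf
  loaded <- !air & (depth > 0 | y != 0 | roll != 0)
  lat_b <- ifelse(loaded, y / (m * pmin(ls, run_b) + pmax(run_b - ls, 0)), 0)
  lat_f <- ifelse(loaded, y / (m * pmin(ls, run_f) + pmax(run_f - ls, 0)), 0)
  tw <- function(d, total) {
    ls_eff <- pmin(ls, d)
    rate <- ifelse(loaded & total != 0,
                   total / (k * ls_eff + pmax(d - ls_eff, 0)), 0)
    u <- pmin(s_end, d)
    ifelse(u <= ls_eff, k * rate * u,
           k * rate * ls_eff + rate * (u - ls_eff))
  }
  data.frame(
    pitch_back_deg = ifelse(loaded, rad2deg(atan2(depth, run_b)), 0),
    pitch_front_deg = ifelse(loaded, rad2deg(atan2(depth, run_f)), 0),
    yaw_back_deg = rad2deg(atan(m * lat_b)),
    yaw_front_deg = rad2deg(atan(m * lat_f)),
    roll_back_deg = tw(run_b, roll),
    roll_front_deg = tw(run_f, roll)
  )
}

#' Simulate a timed trial from foot-load keyframes
#'
#' Interpolates a script of timed foot-load keyframes onto a regular time
#' grid (monotone cubic for the numeric channels, so depths never
#' overshoot below zero; piecewise-constant for the airborne flag, which
#' forces a step change to the unloaded state), evaluates the static
#' geometry for every frame, and emits a clean "motion-capture"
#' anchor-angle stream, a degraded "IMU" stream (white noise plus drift
#' per [add_imu_drift()]), and the ground-truth state. Deterministic under
#' a fixed seed.
#'
#' @param script Data.frame of keyframes with columns `time_s`, `x_mm`,
#'   `depth_mm`, and optionally `flat_mm`, `y_mm`, `roll_deg`, `airborne`.
#' @param rate_hz Output sampling rate, Hz.
#' @param geom A [device_geometry()].
#' @param spring_coeff,yaw_multiplier Passed to the static geometry.
#' @param noise A [drift_spec()] for the IMU stream, or `NULL` for an
#'   identical copy of the clean stream.
#' @param markers Emit per-frame marker positions (slow; default `FALSE`).
#' @param jitter_sd_mm Marker jitter passed to [simulate_static()].
#' @return A list of class `trial_bundle` with data.frames
#'   `angles_mocap`, `angles_imu`, `truth` (columns `time_s`, `x_mm`,
#'   `y_mm`, `z_mm`, `roll_deg`, `airborne`), optional `markers`, and
#'   metadata `rate_hz`, `spring_coeff`, `yaw_multiplier`, `seed`.
#' @export
simulate_trial <- function(script, rate_hz, geom, spring_coeff = 1,
                           yaw_multiplier = 1, noise = drift_spec(),
                           markers = FALSE, jitter_sd_mm = 0) {
  stopifnot(is.data.frame(script), nrow(script) > 0, rate_hz > 0)
  if (is.unsorted(script$time_s, strictly = TRUE)) {
    stop("keyframes must be strictly time-ordered")
  }
  for (col in c("flat_mm", "y_mm", "roll_deg")) {
    if (is.null(script[[col]])) script[[col]] <- 0
  }
  if (is.null(script$airborne)) script$airborne <- FALSE

  t0 <- min(script$time_s); t1 <- max(script$time_s)
  tt <- seq(t0, t1, by = 1 / rate_hz)
  n <- length(tt)

  air <- if (nrow(script) == 1L) rep(script$airborne, n) else
    as.logical(stats::approx(script$time_s, as.numeric(script$airborne),
                             tt, method = "constant", rule = 2)$y)
  x <- interp_channel(script$time_s, script$x_mm, tt)
  depth <- pmax(interp_channel(script$time_s, script$depth_mm, tt), 0)
  flat <- pmax(interp_channel(script$time_s, script$flat_mm, tt), 0)
  y <- interp_channel(script$time_s, script$y_mm, tt)
  roll <- interp_channel(script$time_s, script$roll_deg, tt)
  depth[air] <- 0; y[air] <- 0; roll[air] <- 0

  clean <- static_angles_vec(x, depth, flat, y, roll, air, geom,
                             spring_coeff, yaw_multiplier)
  clean <- cbind(time_s = tt, clean)

  mk <- NULL
  if (markers) {
    mk_frames <- vector("list", n)
    for (i in seq_len(n)) {
      sim <- simulate_static(
        foot_load(x[i], depth[i], flat[i], y[i], roll[i], air[i]),
        geom, spring_coeff, yaw_multiplier,
        markers = TRUE, jitter_sd_mm = jitter_sd_mm
      )
      mf <- sim$shape$markers
      mf$frame <- i
      mf$time_s <- tt[i]
      mk_frames[[i]] <- mf
    }
    mk <- do.call(rbind, mk_frames)
  }

  imu <- if (is.null(noise)) clean else add_imu_drift(clean, noise)

  structure(
    list(angles_mocap = clean, angles_imu = imu,
         truth = data.frame(time_s = tt, x_mm = x, y_mm = y, z_mm = -depth,
                            roll_deg = roll, airborne = air),
         markers = mk,
         rate_hz = rate_hz, spring_coeff = spring_coeff,
         yaw_multiplier = yaw_multiplier,
         seed = if (!is.null(noise)) noise$seed else NULL),
    class = "trial_bundle"
  )
}

#' Degrade an anchor-angle stream with IMU-like noise and drift
#'
#' Adds, per channel: white Gaussian noise (all channels), a deterministic
#' one-sided pitch ramp (negative-going for a negative rate, emulating the
#' observed one-sided pitch drift of sensor-fusion output), an unbiased
#' random walk on yaw (independent per end), and an optional roll ramp.
#' Reproducible when `spec$seed` is set; the caller's RNG state is left
#' untouched in that case.
#'
#' @param angles Data.frame with `time_s` and the six angle columns of
#'   [simulate_trial()].
#' @param spec A [drift_spec()].
#' @return The degraded data.frame (same shape).
#' @export
add_imu_drift <- function(angles, spec) {
  stopifnot(inherits(spec, "drift_spec"))
  tt <- angles$time_s
  if (is.unsorted(tt)) stop("angle series must be time-ordered")
  n <- length(tt)
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
  }
  el <- tt - tt[1]
  dt <- diff(tt)
  walk <- function(sd) {
    if (sd == 0 || n < 2) return(rep(0, n))
    c(0, cumsum(stats::rnorm(n - 1, 0, sd * sqrt(dt))))
  }
  wn <- function() {
    if (spec$noise_sigma_deg == 0) rep(0, n)
    else stats::rnorm(n, 0, spec$noise_sigma_deg)
  }
  out <- angles
  out$pitch_back_deg <- angles$pitch_back_deg +
    spec$pitch_drift_rate_dps * el + wn()
  out$pitch_front_deg <- angles$pitch_front_deg +
    spec$pitch_drift_rate_dps * el + wn()
  out$yaw_back_deg <- angles$yaw_back_deg + walk(spec$yaw_walk_sd) + wn()
  out$yaw_front_deg <- angles$yaw_front_deg + walk(spec$yaw_walk_sd) + wn()
  out$roll_back_deg <- angles$roll_back_deg +
    spec$roll_drift_rate_dps * el + wn()
  out$roll_front_deg <- angles$roll_front_deg +
    spec$roll_drift_rate_dps * el + wn()
  out
}
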