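#' Butterworth filter design in second-order sections
#'
#' Designs a digital Butterworth low- or high-pass filter via the analog
#' prototype, frequency pre-warping, and the bilinear transform, returned
#' as a cascade of second-order sections (one first-order section for odd
#' orders). Second-order sections keep the 0.001 Hz detrending filters
#' numerically sound where a single polynomial form would not be.
#'
#' @param order Filter order (>= 1).
#' @param cutoff_hz -3 dB cutoff frequency, Hz.
#' @param fs_hz Sampling rate, Hz; `cutoff_hz` must lie strictly inside
#'   (0, fs_hz/2).
#' @param type `"low"` or `"high"`.
#' @return A numeric matrix with one row per section and columns
#'   `b0 b1 b2 a0 a1 a2` (`a0` always 1); overall gain is folded into the
#'   first section.
#' @export
butter_sos <- function(order, cutoff_hz, fs_hz, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, order == round(order), fs_hz > 0)
  wn <- cutoff_hz / (fs_hz / 2)
  if (wn <= 0 || wn >= 1) stop("cutoff must lie strictly inside (0, Nyquist)")
  n <- as.integer(order)

  # analog prototype: n left-half-plane poles on the unit circle
  kk <- seq_len(n)
  p <- exp(1i * pi * (2 * kk + n - 1) / (2 * n))
  warped <- 4 * tan(pi * wn / 2)     # bilinear pre-warp with fs2 = 2

  if (type == "low") {
    pa <- warped * p
    za <- complex(0)
    ka <- warped^n
  } else {
    pa <- warped / p
    za <- rep(0 + 0i, n)
    ka <- 1
  }

  # bilinear transform z = (4 + s) / (4 - s)
  pd <- (4 + pa) / (4 - pa)
  zd <- if (length(za)) (4 + za) / (4 - za) else complex(0)
  kd <- ka * Re(prod(4 - za) / prod(4 - pa))
  zd <- c(zd, rep(-1 + 0i, n - length(zd)))   # zeros at infinity -> z = -1

  # pair conjugate poles into biquads; real poles become first-order
  # sections; all zeros are real (+1 or -1) for Butterworth LP/HP
  cplx <- pd[Im(pd) > 1e-12]
  real_p <- Re(pd[abs(Im(pd)) <= 1e-12])
  zreal <- Re(zd[1])
  sections <- list()
  for (pp in cplx) {
    sections[[length(sections) + 1]] <- list(
      b = c(1, -2 * zreal, zreal^2),
      a = c(1, -2 * Re(pp), Mod(pp)^2)
    )
  }
  for (pp in real_p) {
    sections[[length(sections) + 1]] <- list(
      b = c(1, -zreal, 0),
      a = c(1, -pp, 0)
    )
  }
  sos <- t(vapply(sections, function(s) c(s$b, s$a), numeric(6)))
  sos[1, 1:3] <- sos[1, 1:3] * kd
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

# One direct-form-II-transposed biquad pass with initial state zi (len 2).
biquad_filter <- function(b, a, x, zi = c(0, 0)) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * yi + z2
    z2 <- b[3] * x[i] - a[3] * yi
    y[i] <- yi
  }
  y
}

# Steady-state (step-response) initial conditions for one section, unit
# input. Mirrors the classic lfilter_zi construction.
biquad_zi <- function(b, a) {
  g <- sum(b) / sum(a)
  z2 <- b[3] - a[3] * g
  z1 <- b[2] - a[2] * g + z2
  c(z1, z2)
}

sos_filter <- function(sos, x, x0 = 0) {
  scale <- x0
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    zi <- biquad_zi(b, a) * scale
    x <- biquad_filter(b, a, x, zi)
    scale <- scale * sum(b) / sum(a)
  }
  x
}

#' Zero-phase filtering with a second-order-section cascade
#'
#' Forward--backward application of the cascade with odd-symmetric edge
#' extension and steady-state initial conditions, giving zero phase
#' distortion and squared magnitude response (effective order doubles).
#'
#' @param sos Section matrix from [butter_sos()].
#' @param x Numeric series.
#' @return Filtered series, same length.
#' @export
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  padlen <- min(3 * (2 * nrow(sos) + 1), n - 1)
  if (padlen < 1) stop("series too short to filter")
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- sos_filter(sos, ext, x0 = ext[1])
  y <- rev(sos_filter(sos, rev(y), x0 = y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Offline conditioning step applied to angle or marker series before
#' resampling: a third-order 100 Hz low-pass by default, run forward and
#' backward ([sos_filtfilt()]) so recordings are not phase-shifted.
#'
#' @param x Numeric series, uniformly sampled.
#' @param fs_hz Sampling rate, Hz (must exceed twice the cutoff).
#' @param cutoff_hz Cutoff, Hz (default 100).
#' @param order Filter order (default 3).
#' @return Filtered series.
#' @export
lowpass <- function(x, fs_hz, cutoff_hz = 100, order = 3) {
  if (cutoff_hz >= fs_hz / 2) stop("cutoff must be below the Nyquist rate")
  sos_filtfilt(butter_sos(order, cutoff_hz, fs_hz, "low"), x)
}

#' Zero-phase high-pass detrending of drifting channels
#'
#' Removes slow drift from IMU channels with a third-order high-pass
#' Butterworth filter: 0.001 Hz for pitch, 0.01 Hz for roll (channel
#' presets), applied forward--backward. The mean of a long stationary
#' signal goes to approximately zero; genuine long-term shifts in movement
#' patterns are attenuated too, which is the documented trade-off of
#' detrending.
#'
#' @param x Numeric series, uniformly sampled.
#' @param fs_hz Sampling rate, Hz.
#' @param channel `"pitch"` or `"roll"`, selecting the preset cutoff; or
#'   use `cutoff_hz` directly.
#' @param cutoff_hz Explicit cutoff override, Hz.
#' @param order Filter order (default 3).
#' @return Detrended series.
#' @export
detrend_highpass <- function(x, fs_hz, channel = c("pitch", "roll"),
                             cutoff_hz = NULL, order = 3) {
  if (is.null(cutoff_hz)) {
    channel <- match.arg(channel)
    cutoff_hz <- if (channel == "pitch") 0.001 else 0.01
  }
  sos_filtfilt(butter_sos(order, cutoff_hz, fs_hz, "high"), x)
}

#' Resample two streams onto one shared time grid
#'
#' Linearly interpolates every numeric column of both streams onto a
#' regular grid at `target_hz` spanning the overlap of their time ranges,
#' so that e.g. 500 Hz motion-capture and ~400 Hz IMU recordings share the
#' same timestamps. Linear interpolation is used deliberately: it cannot
#' overshoot near airborne discontinuities.
#'
#' @param a,b Data.frames with a `time_s` column and numeric channels.
#' @param target_hz Target rate, Hz (default 200).
#' @return A list with elements `a` and `b`, both on the identical grid.
#' @export
resample_align <- function(a, b, target_hz = 200) {
  stopifnot("time_s" %in% names(a), "time_s" %in% names(b), target_hz > 0)
  t0 <- max(min(a$time_s), min(b$time_s))
  t1 <- min(max(a$time_s), max(b$time_s))
  if (t1 <= t0) stop("streams have no overlapping time range")
  grid <- seq(t0, t1, by = 1 / target_hz)
  interp_df <- function(df) {
    out <- data.frame(time_s = grid)
    for (col in setdiff(names(df), "time_s")) {
      if (is.numeric(df[[col]])) {
        out[[col]] <- stats::approx(df$time_s, df[[col]], grid,
                                    method = "linear")$y
      } else {
        out[[col]] <- stats::approx(df$time_s, as.numeric(df[[col]]), grid,
                                    method = "constant", rule = 2)$y > 0.5
      }
    }
    out
  }
  list(a = interp_df(a), b = interp_df(b))
}

#' Frame exclusion mask from foot height
#'
#' Excludes frames where the foot-segment center is at least
#' `threshold_mm` above the tape-segment center (the foot is almost or
#' entirely off the tape), and optionally frames where both feet are on
#' the same tape. The comparison is inclusive (`>=`): a 70.0 mm difference
#' is excluded at the default threshold, 69.9 mm is kept.
#'
#' @param foot_center_z Numeric series of foot-center heights, mm.
#' @param tape_center_z Matching tape-center heights, mm.
#' @param threshold_mm Exclusion threshold, mm (default 70).
#' @param both_feet_same_tape Optional logical series flagging frames with
#'   two feet mapped to one tape.
#' @return Data.frame with logical `excluded` and `reason` in
#'   `{"FOOT_OFF", "BOTH_FEET_SAME_TAPE", "NONE"}`.
#' @export
exclude_frames <- function(foot_center_z, tape_center_z, threshold_mm = 70,
                           both_feet_same_tape = NULL) {
  stopifnot(length(foot_center_z) == length(tape_center_z))
  off <- (foot_center_z - tape_center_z) >= threshold_mm
  reason <- ifelse(off, "FOOT_OFF", "NONE")
  if (!is.null(both_feet_same_tape)) {
    reason[!off & both_feet_same_tape] <- "BOTH_FEET_SAME_TAPE"
    off <- off | both_feet_same_tape
  }
  data.frame(excluded = off, reason = reason, stringsAsFactors = FALSE)
}

#' Drift adjustment of normalized pitch series
#'
#' Two adjustments for the one-sided negative drift of IMU pitch, both
#' exploiting that the tape cannot rise above its rest height (normalized
#' pitch cannot truly be negative): `"clamp"` sets negative samples to
#' zero and preserves positive samples exactly; `"shift"` raises the whole
#' series so its minimum is zero (identity when the series is already
#' non-negative).
#'
#' @param x Normalized pitch series, degrees.
#' @param mode `"clamp"` (default) or `"shift"`.
#' @return Adjusted series.
#' @export
clamp_pitch <- function(x, mode = c("clamp", "shift")) {
  mode <- match.arg(mode)
  if (mode == "clamp") {
    pmax(x, 0)
  } else {
    m <- min(x)
    if (m < 0) x - m else x
  }
}
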