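# shared fixtures: default Luna geometry/params and small builders

luna <- luna_geometry()
pars <- model_params()

# vectorized forward-angle oracle (the simulator's vector path)
fwd_angles <- function(x, depth, flat = 0, y = 0, roll = 0, geom = luna,
                       k = 1, m = 1) {
  n <- max(length(x), length(depth), length(flat), length(y), length(roll))
  tapekin:::static_angles_vec(rep_len(x, n), rep_len(depth, n),
                              rep_len(flat, n), rep_len(y, n),
                              rep_len(roll, n), rep(FALSE, n), geom, k, m)
}

# clamp the pitch channels of an IMU stream (default drift correction)
clamp_imu <- function(ang) {
  ang$pitch_back_deg <- clamp_pitch(ang$pitch_back_deg)
  ang$pitch_front_deg <- clamp_pitch(ang$pitch_front_deg)
  ang
}

# random proper rotation matrices from unit quaternions, n x 9 (row-major)
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

rot_from_row <- function(r) matrix(r, 3, 3, byrow = TRUE)

# frozen scipy.signal.butter(3, ...) second-order sections (b0 b1 b2 a0 a1 a2)
scipy_lp_100_500 <- rbind(
  c(0.09853116092392705, 0.1970623218478541, 0.09853116092392705,
    1, -0.15838444032453627, 0),
  c(1, 1, 0, 1, -0.4188560844817663, 0.3554467621723904))
scipy_hp_001_200 <- rbind(
  c(0.999968584566938, -0.999968584566938, 0,
    1, -0.9999685845669339, 0),
  c(1, -2, 1, 1, -1.999968583579997, 0.9999685845669419))

sos_response <- function(sos, w) {
  z <- exp(1i * w)
  h <- rep(1 + 0i, length(w))
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    h <- h * (b[1] + b[2] / z + b[3] / z^2) / (a[1] + a[2] / z + a[3] / z^2)
  }
  h
}
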