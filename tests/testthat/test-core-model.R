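test_that("sagittal model reproduces the closed-form examples", {
  # symmetric load: x at mid-span, z = -L tan(a)/2
  r <- estimate_sagittal(10, 10, luna, pars)
  expect_equal(r$x_mm, 0, tolerance = 1e-12)
  expect_equal(r$z_mm, -1726 * tan(pi / 18) / 2, tolerance = 1e-9)

  # asymmetric load, both formulations, distance from the back anchor
  for (m in c("ray", "trig")) {
    r2 <- estimate_sagittal(20, 10, luna, pars, method = m)
    expect_equal(r2$z_mm, -205.01833476713, tolerance = 1e-9)
    expect_equal(r2$x_mm + 863, 563.2832453468782, tolerance = 1e-9)
  }
})

test_that("small-angle guard defaults to zero predictions below 0.1 deg", {
  r <- estimate_sagittal(c(0.05, 0.0999, 0.1), c(0.05, 5, 0.1), luna, pars)
  expect_equal(r$x_mm, c(0, 0, 0))
  expect_equal(r$z_mm[1:2], c(0, 0))
  expect_true(all(r$low_load[1:2]))
  # exactly at threshold: strict "<" does not fire the guard
  expect_false(r$low_load[3])
  expect_lt(r$z_mm[3], 0)
})

test_that("sign-discordant angles are flagged without numeric output", {
  r <- estimate_sagittal(5, -3, luna, pars)
  expect_true(r$no_intersection)
  expect_true(is.na(r$x_mm) && is.na(r$z_mm))
  # allow_negative evaluates the raw (unstable) form instead
  r2 <- estimate_sagittal(5, -3, luna, pars, allow_negative = TRUE)
  expect_false(is.na(r2$z_mm))
})

test_that("inputs outside the domain are rejected", {
  expect_error(estimate_sagittal(95, 10, luna, pars), "90")
  expect_error(estimate_sagittal(NaN, 10, luna, pars), "finite")
})

test_that("ray and trig formulations agree over a (0.1, 80) deg sweep", {
  set.seed(1)
  a <- runif(1e4, 0.1, 80)
  b <- runif(1e4, 0.1, 80)
  r1 <- estimate_sagittal(a, b, luna, pars, method = "ray")
  r2 <- estimate_sagittal(a, b, luna, pars, method = "trig")
  expect_lt(max(abs(r1$z_mm - r2$z_mm)), 1e-9 * luna$span_l_mm)
  expect_lt(max(abs(r1$x_mm - r2$x_mm)), 1e-9 * luna$span_l_mm)
})

test_that("sagittal model is symmetric and monotone", {
  set.seed(2)
  a <- runif(200, 0.2, 75); b <- runif(200, 0.2, 75)
  r <- estimate_sagittal(a, b, luna, pars)
  rs <- estimate_sagittal(b, a, luna, pars)
  expect_equal(r$z_mm, rs$z_mm, tolerance = 1e-12)
  expect_equal(r$x_mm, -rs$x_mm, tolerance = 1e-9)
  # |z| strictly increases in alpha at fixed beta
  aa <- seq(0.2, 79, length.out = 400)
  z <- estimate_sagittal(aa, 15, luna, pars)$z_mm
  expect_true(all(diff(-z) > 0))
  z2 <- estimate_sagittal(15, aa, luna, pars)$z_mm
  expect_true(all(diff(-z2) > 0))
})

test_that("transversal model mirrors the sagittal mathematics", {
  r <- estimate_transversal(2, 2, luna, pars)
  expect_equal(r$x_mm, 0, tolerance = 1e-12)
  expect_equal(r$y_mm, 1726 * tan(2 * pi / 180) / 2, tolerance = 1e-9)
  # guard
  expect_true(estimate_transversal(0.05, 0.05, luna, pars)$low_load)
  # mirrored inputs: x mirrors, y unchanged
  r1 <- estimate_transversal(3, 1.5, luna, pars)
  r2 <- estimate_transversal(1.5, 3, luna, pars)
  expect_equal(r1$y_mm, r2$y_mm, tolerance = 1e-12)
  expect_equal(r1$x_mm, -r2$x_mm, tolerance = 1e-9)
  # negative lateral displacement keeps the common sign
  rn <- estimate_transversal(-2, -2, luna, pars)
  expect_equal(rn$y_mm, -r$y_mm, tolerance = 1e-12)
})

test_that("segment correction scales z only", {
  expect_equal(apply_segment_correction(-100, model_params(0.85)), -85)
  expect_equal(apply_segment_correction(0, model_params(0.6)), 0)
  # geometric ratio for LF = 260 on L = 1726 rounds to 0.85
  expect_equal(round(segment_ratio_flatfoot(260, luna), 2), 0.85)
})

test_that("roll variants behave as defined", {
  p2 <- model_params(spring_coeff = 2)
  # RA is the plain sum and needs no position
  expect_equal(predict_roll(2, 3, NA, luna, pars, "RA"), 5)
  # all variants vanish on zero rolls
  for (v in c("RM", "RS", "RWS", "RA")) {
    expect_equal(predict_roll(0, 0, 100, luna, p2, v), 0)
  }
  # RS inverts the torsion simulator exactly at the true spring coefficient
  for (x in c(-500, -100, 260)) {
    ang <- fwd_angles(x, 120, roll = 9, k = 2)
    xs <- estimate_sagittal(ang$pitch_back_deg, ang$pitch_front_deg,
                            luna, p2)$x_mm
    expect_equal(predict_roll(ang$roll_back_deg, ang$roll_front_deg, xs,
                              luna, p2, "RS"), 9, tolerance = 1e-6)
    expect_equal(predict_roll(ang$roll_back_deg, ang$roll_front_deg, xs,
                              luna, p2, "RWS"), 9, tolerance = 1e-6)
  }
  # k = 1 reduces RS to RM (default geometry: sensor section = spring)
  ang <- fwd_angles(200, 100, roll = 8, k = 1)
  xs <- estimate_sagittal(ang$pitch_back_deg, ang$pitch_front_deg,
                          luna, pars)$x_mm
  expect_equal(
    predict_roll(ang$roll_back_deg, ang$roll_front_deg, xs, luna, pars, "RM"),
    predict_roll(ang$roll_back_deg, ang$roll_front_deg, xs, luna, pars, "RS"),
    tolerance = 1e-12)
  # NA position propagates for position-dependent variants
  expect_true(is.na(predict_roll(1, 1, NA, luna, pars, "RM")))
})

test_that("quality flags fire on their defining conditions", {
  est <- data.frame(
    xz_mm = c(0, 0, 500, 0), xy_mm = c(0, 400, 500, 0),
    z_mm = c(0, -50, -50, -50), y_mm = 0,
    low_load = c(TRUE, FALSE, FALSE, FALSE),
    no_intersection = FALSE
  )
  fl <- quality_flags(est, luna, xz_xy_bound_mm = 300, foot_length_mm = 300)
  expect_match(fl[1], "LOW_LOAD")
  expect_match(fl[2], "XZ_XY_DISCREPANCY")
  expect_match(fl[3], "TEMPORAL_JUMP")   # 0 -> 500 mm between loaded frames
  expect_match(fl[4], "TEMPORAL_JUMP")
  # a lift-off phase in between suppresses the jump flag
  est$low_load[3] <- TRUE
  fl2 <- quality_flags(est, luna, 300, 300)
  expect_false(grepl("TEMPORAL_JUMP", fl2[3]))
  expect_false(grepl("TEMPORAL_JUMP", fl2[4]))
})

test_that("calibration recovers simulator-truth parameters", {
  ratio_true <- segment_ratio_flatfoot(260, luna)
  ratios <- numeric(20); ks <- numeric(20)
  for (s in seq_len(20)) {
    set.seed(s)
    n <- 200
    # Z-only flat-foot frames
    x <- runif(n, -400, 400); dr <- runif(n, 30, 250)
    ang <- fwd_angles(x, dr, flat = 260)
    ang$pitch_back_deg <- ang$pitch_back_deg + rnorm(n, 0, 0.1)
    ang$pitch_front_deg <- ang$pitch_front_deg + rnorm(n, 0, 0.1)
    ratios[s] <- calibrate_params(ang, data.frame(x_mm = x, z_mm = -dr,
                                                  roll_deg = 0),
                                  "segment_ratio", luna)$segment_ratio
    # roll-only frames, k_true = 2
    x2 <- runif(n, -500, 500); th <- runif(n, -25, 25)
    ang2 <- fwd_angles(x2, 0, roll = th, k = 2)
    ang2$roll_back_deg <- ang2$roll_back_deg + rnorm(n, 0, 0.1)
    ang2$roll_front_deg <- ang2$roll_front_deg + rnorm(n, 0, 0.1)
    ks[s] <- calibrate_params(ang2, data.frame(x_mm = x2, z_mm = 0,
                                               roll_deg = th),
                              "spring_coeff", luna)$spring_coeff
  }
  expect_true(all(abs(ratios - ratio_true) < 0.01))
  expect_true(all(abs(ks - 2) / 2 < 0.05))
})

test_that("calibration rejects degenerate input", {
  n <- 20
  ang <- fwd_angles(rep(0, n), 0)   # no excitation at all
  tr <- data.frame(x_mm = 0, z_mm = 0, roll_deg = 0)[rep(1, n), ]
  expect_error(calibrate_params(ang, tr, "segment_ratio", luna), "degenerate")
  expect_error(calibrate_params(ang, tr, "spring_coeff", luna), "degenerate")
  expect_error(calibrate_params(ang[1:5, ], tr[1:5, ], "segment_ratio", luna),
               "10 frames")
})

test_that("noise-free calibration has near-zero residual", {
  set.seed(3)
  n <- 50
  x <- runif(n, -300, 300); dr <- runif(n, 50, 200)
  ang <- fwd_angles(x, dr, flat = 260)
  p <- calibrate_params(ang, data.frame(x_mm = x, z_mm = -dr, roll_deg = 0),
                        "segment_ratio", luna)
  expect_lt(attr(p, "residual_rms"), 1e-9)
  expect_equal(p$segment_ratio, segment_ratio_flatfoot(260, luna),
               tolerance = 1e-9)
})
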