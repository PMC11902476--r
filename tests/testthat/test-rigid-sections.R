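test_that("Kabsch recovers exact transforms and stays proper", {
  set.seed(9)
  ref <- matrix(rnorm(12, sd = 100), 4, 3)
  # identity
  kt <- kabsch_transform(ref, ref)
  expect_equal(kt$rotation, diag(3), tolerance = 1e-12)
  expect_equal(kt$rmsd, 0, tolerance = 1e-9)
  # known rotation + translation
  R0 <- rot_from_row(random_rotations(1))
  tr <- c(10, -40, 7)
  obs <- sweep(ref %*% t(R0), 2, -tr)
  kt2 <- kabsch_transform(ref, obs)
  expect_lt(max(abs(kt2$rotation - R0)), 1e-9)
  expect_lt(max(abs(kt2$translation - tr)), 1e-9)
  expect_lt(kt2$rmsd, 1e-9)
  # reflected observation still yields a proper rotation with rmsd > 0
  refl <- ref %*% diag(c(1, 1, -1))
  kt3 <- kabsch_transform(ref, refl)
  expect_equal(det(kt3$rotation), 1, tolerance = 1e-9)
  expect_gt(kt3$rmsd, 1)
  # collinear points are rejected
  line <- cbind(1:4, 2 * (1:4), 0)
  expect_error(kabsch_transform(line, line), "degenerate")
})

test_that("Kabsch beats a random-rotation grid on random instances", {
  set.seed(10)
  rots <- random_rotations(1e4)
  for (i in 1:20) {
    ref <- matrix(rnorm(12, sd = 50), 4, 3)
    obs <- matrix(rnorm(12, sd = 50), 4, 3)
    p <- sweep(ref, 2, colMeans(ref))
    q <- sweep(obs, 2, colMeans(obs))
    kt <- kabsch_transform(ref, obs)
    # rmsd of every random rotation, vectorized: q - p R^T
    pr <- p %*% matrix(t(rots), nrow = 3)    # 4 x (3 * 1e4)
    e <- (pr - as.vector(q))^2
    dim(e) <- c(12, 1e4)
    best <- min(sqrt(colSums(e) / 4))
    expect_lte(kt$rmsd, best + 1e-12)
  }
})

test_that("Tait-Bryan decomposition round-trips", {
  expect_equal(unclass(taitbryan_xyz(diag(3)))[1:3],
               c(roll_deg = 0, pitch_deg = 0, yaw_deg = 0))
  r10 <- taitbryan_xyz(taitbryan_matrix(10, 0, 0))
  expect_equal(r10[["roll_deg"]], 10, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    R0 <- rot_from_row(random_rotations(1))
    tb <- taitbryan_xyz(R0)
    if (attr(tb, "gimbal")) next
    R1 <- taitbryan_matrix(tb[["roll_deg"]], tb[["pitch_deg"]],
                           tb[["yaw_deg"]])
    expect_lt(max(abs(R1 - R0)), 1e-9)
  }
  expect_error(taitbryan_xyz(matrix(2 * diag(3), 3)), "proper")
})

test_that("angles stay close to axis-angle magnitude in the working range", {
  # within the device's restricted rotation range the Tait-Bryan angle of
  # a single-axis rotation matches the axis-angle magnitude within 5%
  set.seed(12)
  for (i in 1:100) {
    ang <- runif(3, -15, 15)
    R0 <- taitbryan_matrix(ang[1], ang[2], ang[3])
    aa <- acos((sum(diag(R0)) - 1) / 2) * 180 / pi
    expect_lt(abs(sqrt(sum(ang^2)) - aa) / aa, 0.05)
  }
})

test_that("sections on a single straight piece reconstruct exactly", {
  lay <- luna_layout(luna)
  st <- lay$boundaries
  # contact at the section-3/4 boundary, combined sagittal + lateral load
  sc <- simulate_static(foot_load(st[4], 180, y_mm = 25), luna)
  rec <- section_angles(sc$shape$markers, lay)
  tru <- sc$shape$sections
  # sections 1-2 and 6-7 lie wholly on one straight piece (their marker
  # sets do not span the contact); these must be exact
  pure <- c(1, 2, 6, 7)
  for (col in c("roll_deg", "pitch_deg", "yaw_deg")) {
    expect_lt(max(abs(rec[[col]][pure] - tru[[col]][pure])), 1e-6)
  }
  # along-span stretch makes the fit rmsd nonzero (scaling, not rotation);
  # it stays small and does not perturb the recovered angles
  expect_lt(max(rec$rmsd_mm[pure]), 10)
  # near-contact sections are approximately rigid only
  expect_lt(max(abs(rec$pitch_deg - tru$pitch_deg), na.rm = TRUE), 10)
})

test_that("rest pose gives zero angles everywhere", {
  lay <- luna_layout(luna)
  sc <- simulate_static(foot_load(0, 0, airborne = TRUE), luna)
  rec <- section_angles(sc$shape$markers, lay)
  expect_lt(max(abs(as.matrix(rec[, c("roll_deg", "pitch_deg", "yaw_deg")]))),
            1e-9)
})

test_that("occluded markers invalidate only their own sections", {
  lay <- luna_layout(luna)
  sc <- simulate_static(foot_load(200, 150), luna)
  mk <- sc$shape$markers
  rec <- section_angles(mk[mk$label != "inC", ], lay)
  # the shared center marker belongs to sections 3, 4, and 5
  expect_true(all(is.na(rec$pitch_deg[3:5])))
  expect_true(all(!is.na(rec$pitch_deg[c(1, 2, 6, 7)])))
})

test_that("anchor angles recovered from markers feed the inverse model", {
  lay <- luna_layout(luna)
  st <- lay$boundaries
  sc <- simulate_static(foot_load(st[4], 160, y_mm = 15), luna)
  aa <- anchor_angles_from_sections(section_angles(sc$shape$markers, lay))
  inv <- estimate_sagittal(aa$pitch_back_deg, aa$pitch_front_deg, luna, pars)
  # Tait-Bryan section pitch differs from the plane-projection angle only
  # at second order in the small lateral angle
  expect_equal(inv$z_mm, -160, tolerance = 0.1)
  expect_equal(inv$x_mm, st[4], tolerance = 1)
})

test_that("marker layout matches the instrumented-tape description", {
  lay <- luna_layout(luna)
  expect_equal(nrow(lay$markers), 11)
  expect_equal(sum(lay$markers$edge == "outer"), 6)
  expect_equal(sum(lay$markers$edge == "inner"), 5)
  expect_length(lay$section_members, 7)
  sizes <- lengths(lay$section_members)
  expect_equal(sizes[4], 3)                    # middle section: 3 markers
  expect_true(all(sizes[-4] >= 3))
  # the shared center marker belongs to more than one section
  expect_equal(sum(vapply(lay$section_members,
                          function(m) "inC" %in% m, logical(1))), 3)
})
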