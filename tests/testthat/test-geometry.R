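test_that("Kabsch superposition recovers constructed transforms", {
  set.seed(42)
  X <- matrix(rnorm(60), ncol = 3)
  s <- kabsch_superpose(X, X)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)

  R37 <- tcrm:::rotation_about(c(0, 0, 1), tcrm:::deg2rad(37))
  Y <- X %*% t(R37)
  Y <- sweep(Y, 2, c(3, -2, 7), "+")
  s2 <- kabsch_superpose(X, Y)
  expect_lt(max(abs(s2$rotation %*% R37 - diag(3))), 1e-9)
  expect_lt(s2$rmsd, 1e-9)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-8)
  moved <- sweep(Y %*% t(s2$rotation), 2, s2$translation, "+")
  expect_lt(max(abs(moved - X)), 1e-8)
})

test_that("Kabsch rejects degenerate or mismatched inputs", {
  line <- cbind(1:5, 2 * (1:5), -1:3 * 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "size")
})

test_that("rmsd matches the brute-force formula and Kabsch never exceeds raw", {
  set.seed(7)
  for (k in 1:5) {
    a <- matrix(rnorm(150), ncol = 3)
    b <- a + matrix(rnorm(150, sd = 0.5), ncol = 3)
    brute <- sqrt(mean(rowSums((a - b)^2)))
    expect_equal(rmsd(a, b), brute, tolerance = 1e-12)
    expect_lte(rmsd(a, b, superpose = TRUE), rmsd(a, b) + 1e-12)
  }
  two <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  shift1A <- matrix(c(1, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  expect_equal(rmsd(two, two + shift1A), 1.0)
})

test_that("Kabsch agrees with the bio3d reference on random point sets", {
  set.seed(11)
  a <- matrix(rnorm(90), ncol = 3)
  b <- a %*% t(tcrm:::rotation_about(c(1, 2, 3), 0.8)) +
    matrix(rnorm(90, sd = 0.3), ncol = 3)
  ours <- kabsch_superpose(a, b)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("crossing angle is recovered on constructed complexes", {
  for (th in c(15, 45, 62, 90, 120)) {
    toy <- toy_fixture(seed = 3, crossing_angle_target = th,
                       incident_angle_target = 0)
    g <- docking_geometry(partition_complex(toy$model, "auto")[[1]])
    expect_lt(abs(g$crossing_angle - th), 0.5)
    expect_lt(g$incident_angle, 0.5)  # axis parallel to the groove plane
  }
})

test_that("incident angle reflects the constructed TCR tilt", {
  toy <- toy_fixture(seed = 1)  # built at 62 / 8 degrees
  g <- docking_geometry(toy_partition(seed = 1))
  expect_lt(abs(g$crossing_angle - 62), 0.5)
  expect_lt(abs(g$incident_angle - 8), 0.5)
  expect_equal(tcrm:::vnorm(g$tcr_axis), 1, tolerance = 1e-9)
  expect_equal(tcrm:::vnorm(g$peptide_axis), 1, tolerance = 1e-9)
})

test_that("geometry outputs are invariant under rigid motion", {
  part <- toy_partition(seed = 1)
  g1 <- docking_geometry(part)
  R <- tcrm:::rotation_about(c(1, -1, 2), 1.1)
  part2 <- part
  part2$model <- transform_model(part$model, R, c(13, -40, 5))
  g2 <- docking_geometry(part2)
  expect_equal(g2$crossing_angle, g1$crossing_angle, tolerance = 1e-6)
  expect_equal(g2$incident_angle, g1$incident_angle, tolerance = 1e-6)
  # translation alone leaves the groove normal unchanged
  part3 <- part
  part3$model <- transform_model(part$model, diag(3), c(100, 0, -7))
  expect_equal(groove_plane(part3)$normal, groove_plane(part)$normal,
               tolerance = 1e-9)
})
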