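test_that("SASA matches the analytic sphere and isolated-pair values", {
  one <- tiny_model("CB", "ALA", "A", 1, matrix(c(0, 0, 0), 1))
  one$atoms$radius <- 1.7
  s <- shrake_rupley(one)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 1e-9)
  two <- tiny_model(c("CB", "CB"), c("ALA", "ALA"), c("A", "B"), c(1, 1),
                    matrix(c(0, 0, 0, 10, 0, 0), 2, byrow = TRUE))
  two$atoms$radius <- 1.7
  s2 <- shrake_rupley(two)
  expect_equal(s2$per_atom, rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)
  expect_equal(s2$total, sum(s2$per_atom), tolerance = 1e-6)
})

test_that("SASA agrees with a dense Monte-Carlo oracle within 2%", {
  set.seed(5)
  xyz <- matrix(rnorm(30, sd = 2.2), ncol = 3)
  m <- tiny_model(rep("CB", 10), rep("ALA", 10), "A", seq(1, 19, 2), xyz)
  ours <- shrake_rupley(m, n_points = 960)
  oracle <- mc_sasa_oracle(m)
  expect_lt(abs(ours$total - oracle$total) / oracle$total, 0.02)
})

test_that("SASA is monotone in environment and converged in lattice density", {
  set.seed(6)
  xyz <- matrix(rnorm(30, sd = 2.2), ncol = 3)
  m10 <- tiny_model(rep("CB", 10), rep("ALA", 10), "A", seq(1, 19, 2), xyz)
  s10 <- shrake_rupley(m10)
  xyz15 <- rbind(xyz, matrix(rnorm(15, sd = 2.2), ncol = 3))
  m15 <- tiny_model(rep("CB", 15), rep("ALA", 15), "A", seq(1, 29, 2), xyz15)
  s15 <- shrake_rupley(m15)
  expect_true(all(s15$per_atom[1:10] <= s10$per_atom + 1e-9))
  # doubling the lattice changes the toy total by < 1%
  part <- toy_partition(seed = 1)
  t1 <- shrake_rupley(part$model, n_points = 480)$total
  t2 <- shrake_rupley(part$model, n_points = 960)$total
  expect_lt(abs(t2 - t1) / t1, 0.01)
})

test_that("buried surface area follows the additive convention", {
  part <- toy_partition(seed = 1)
  ba <- buried_surface_area(part, n_points = 480)
  st <- tcrm:::tcr_sel(part); sp <- tcrm:::pmhc_sel(part)
  direct <- shrake_rupley(part$model, st, n_points = 480)$total +
    shrake_rupley(part$model, sp, n_points = 480)$total -
    shrake_rupley(part$model, st | sp, n_points = 480)$total
  expect_equal(ba$bsa_total, direct, tolerance = 1e-9)
  expect_gte(ba$bsa_total, 0)
  expect_gt(ba$peptide_burial, 0)
  # translation invariance is exact (the lattice moves with each atom);
  # rotation re-clips the finite lattice, so agreement is to lattice
  # resolution only
  part2 <- part
  part2$model <- transform_model(part$model, diag(3), c(50, -20, 5))
  ba2 <- buried_surface_area(part2, n_points = 480)
  expect_equal(ba2$bsa_total, ba$bsa_total, tolerance = 1e-9)
  part3 <- part
  part3$model <- transform_model(part$model,
                                 tcrm:::rotation_about(c(1, 1, 0), 0.7),
                                 c(5, 5, 5))
  ba3 <- buried_surface_area(part3, n_points = 480)
  expect_equal(ba3$bsa_total, ba$bsa_total, tolerance = 0.05)
})

test_that("separated partners bury no surface", {
  part <- separated_partition(toy_partition(seed = 1))
  ba <- buried_surface_area(part, n_points = 480)
  expect_equal(ba$bsa_total, 0, tolerance = 1e-9)
})

test_that("a constructed Lys-Asp pair yields salt-bridge and vdW contacts", {
  fx <- saltbridge_fixture()
  ct <- find_contacts(fx$partition)
  hit <- ct[ct$chain_a == "E" & ct$resno_a == 7 &
              ct$chain_b == "C" & ct$resno_b == 4, ]
  expect_true("saltbridge" %in% hit$type)
  expect_true("vdw" %in% hit$type)
  sb <- hit[hit$type == "saltbridge" & hit$atom_a == "NZ" &
              hit$atom_b == "OD1", ]
  expect_equal(sb$distance, 3.0, tolerance = 1e-6)
  # stored distances recompute from coordinates
  a <- fx$model$atoms
  for (k in seq_len(nrow(ct))) {
    pa <- as.numeric(a[a$chain == ct$chain_a[k] & a$resno == ct$resno_a[k] &
                         a$elety == ct$atom_a[k], c("x", "y", "z")])
    pb <- as.numeric(a[a$chain == ct$chain_b[k] & a$resno == ct$resno_b[k] &
                         a$elety == ct$atom_b[k], c("x", "y", "z")])
    expect_equal(tcrm:::vnorm(pa - pb), ct$distance[k], tolerance = 1e-6)
  }
})

test_that("distant partners give an empty contact set", {
  part <- separated_partition(toy_partition(seed = 1))
  expect_equal(nrow(find_contacts(part)), 0L)
})

test_that("design-position selection honours the distance cutoff", {
  part <- toy_partition(seed = 1)
  expect_equal(nrow(select_design_positions(part, 0.1)), 0L)
  pos <- select_design_positions(part, 8)
  expect_gt(nrow(pos), 0)
  expect_true(all(pos$min_dist <= 8))
  expect_true(all(pos$role %in% c("tcr_alpha", "tcr_beta")))
  # deterministic (chain, resno) order
  expect_identical(order(pos$chain, pos$resno), seq_len(nrow(pos)))
  # widening to the whole pMHC can only add positions
  pos2 <- select_design_positions(part, 8, reference = "pmhc")
  expect_gte(nrow(pos2), nrow(pos))
  expect_error(select_design_positions(part, -1), "positive")
  # cross-module arithmetic: candidates = positions x 19
  expect_equal(nrow(enumerate_substitutions(pos)), nrow(pos) * 19L)
})
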