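em_default <- energy_model()

test_that("two neutral atoms at the LJ minimum score -epsilon attraction", {
  # two alanine C-beta atoms: rmin pair = 4.0 A, epsilon = 0.09
  m <- tiny_model(c("CB", "CB"), c("ALA", "ALA"), c("A", "B"), c(1, 1),
                  matrix(c(0, 0, 0, 4.0, 0, 0), 2, byrow = TRUE))
  e <- score_pose(m, em_default)
  expect_equal(e$lj_attr, -0.09, tolerance = 1e-12)
  expect_equal(e$lj_rep, 0, tolerance = 1e-12)
  expect_equal(e$coulomb, 0, tolerance = 1e-12)
  expect_equal(e$total,
               sum(unlist(e[c("lj_attr", "lj_rep", "coulomb", "solvation",
                              "hbond")]) *
                     em_default$weights), tolerance = 1e-9)
})

test_that("pairs beyond the cutoff contribute nothing", {
  m <- tiny_model(c("CB", "NZ"), c("ALA", "LYS"), c("A", "B"), c(1, 1),
                  matrix(c(0, 0, 0, 6.5, 0, 0), 2, byrow = TRUE))
  e <- score_pose(m, em_default)
  for (t in c("lj_attr", "lj_rep", "coulomb", "solvation", "hbond", "total"))
    expect_identical(e[[t]], 0)
})

test_that("vectorized scoring equals the naive double-loop oracle", {
  set.seed(12)
  ety <- c("CB", "OD1", "NZ", "SG", "OG", "CG", "OE1", "NE2", "CD1", "OH")
  rsd <- c("ALA", "ASP", "LYS", "CYS", "SER", "LEU", "GLU", "GLN", "ILE",
           "TYR")
  n <- 30
  pick <- sample(10, n, replace = TRUE)
  xyz <- matrix(runif(3 * n, 0, 9), ncol = 3)
  m <- tiny_model(ety[pick], rsd[pick], "A", seq(1, by = 2, length.out = n),
                  xyz)
  ours <- score_pose(m, em_default)
  oracle <- naive_score_oracle(m, em_default)
  for (t in names(oracle))
    expect_equal(ours[[t]], unname(oracle[t]), tolerance = 1e-9)
})

test_that("energy is continuous across rmin, the knee and the switch window", {
  probe <- function(r) {
    m <- tiny_model(c("CB", "CB"), c("ALA", "ALA"), c("A", "B"), c(1, 1),
                    matrix(c(0, 0, 0, r, 0, 0), 2, byrow = TRUE))
    score_pose(m, em_default)$total
  }
  h <- 1e-9
  for (r0 in c(4.0, 2.4, 5.5, 6.0)) {  # rmin, 0.6*rmin, switch-on, cutoff
    expect_lt(abs(probe(r0 + h) - probe(r0 - h)), 1e-6)
  }
})

test_that("pose score is invariant under rigid motion", {
  part <- toy_partition(seed = 1)
  e1 <- score_pose(part$model, em_default)
  m2 <- transform_model(part$model, tcrm:::rotation_about(c(2, 1, 1), 0.9),
                        c(-30, 12, 4))
  e2 <- score_pose(m2, em_default)
  for (t in c("lj_attr", "lj_rep", "coulomb", "solvation", "hbond", "total"))
    expect_equal(e2[[t]], e1[[t]], tolerance = 1e-6)
})

test_that("binding score equals the cross-partner pair sum and vanishes on separation", {
  part <- toy_partition(seed = 1)
  b <- binding_score(part, em_default)
  expect_equal(b$binding$total,
               b$complex$total - b$tcr_alone$total - b$pmhc_alone$total,
               tolerance = 1e-9)
  oracle <- naive_cross_oracle(part, em_default)
  for (t in names(oracle))
    expect_equal(b$binding[[t]], unname(oracle[t]), tolerance = 1e-9)
  sep <- separated_partition(part)
  bsep <- binding_score(sep, em_default)
  expect_equal(bsep$binding$total, 0, tolerance = 1e-9)
})

test_that("a favorable cross-interface Lys-Asp pair gives negative coulomb", {
  fx <- saltbridge_fixture()
  b <- binding_score(fx$partition, em_default)
  expect_lt(b$binding$coulomb, 0)
})

test_that("atoms without parameters are reported by name", {
  m <- tiny_model(c("CB", "XX"), c("ALA", "ALA"), c("A", "B"), c(1, 1),
                  matrix(c(0, 0, 0, 4, 0, 0), 2, byrow = TRUE))
  m$atoms$elem[2] <- "Q"  # unknown element class falls back to X defaults
  e <- score_pose(m, em_default)
  expect_true(is.finite(e$total))
})
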