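test_that("Langmuir closed form has the right limits and matches an ODE oracle", {
  ka <- 1e4; kd <- 0.308; Rmax <- 100
  long <- simulate_sensorgram(ka, kd, Rmax, 3.12e-6, t_assoc = 4000,
                              t_dissoc = 4100, dt = 1, noise_sd = 0)
  plateau <- max(long$response_RU)
  expect_equal(plateau, Rmax * 3.12e-6 / (3.12e-6 + kd / ka),
               tolerance = 1e-6)
  # near-zero kd: dissociation phase stays flat
  slow <- simulate_sensorgram(ka, 1e-12, Rmax, 3.12e-6, noise_sd = 0)
  dis <- slow$response_RU[slow$phase == "dissociation"]
  expect_lt(max(dis) - min(dis), 1e-6)
  # ODE oracle: dR/dt = ka*C*(Rmax - R) - kd*R, C -> 0 after t_assoc
  C <- 6.25e-6
  sim <- simulate_sensorgram(ka, kd, Rmax, C, t_assoc = 60, t_dissoc = 120,
                             dt = 0.5, noise_sd = 0)
  rhs <- function(t, y, p) {
    conc <- if (t <= 60) C else 0
    list(ka * conc * (Rmax - y) - kd * y)
  }
  ode <- deSolve::ode(c(R = 0), sim$time_s, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(ode[, "R"] - sim$response_RU)), 1e-6)
})

test_that("noise-free kinetic fits recover the generating parameters", {
  d <- simulate_sensorgram(1e4, 0.308, 100, spr_series_wt, noise_sd = 0)
  f <- fit_1to1(d)
  expect_equal(f$ka, 1e4, tolerance = 1e-6)
  expect_equal(f$kd, 0.308, tolerance = 1e-6)
  expect_equal(f$Rmax, 100, tolerance = 1e-6)
  expect_identical(f$KD, f$kd / f$ka)
  expect_lt(f$residual_sse, 1e-10)
  expect_warning(fit_1to1(d[d$conc_M == d$conc_M[1], ]), "degenerate")
})

test_that("equilibrium fits invert the binding isotherm", {
  KD <- 30.8e-6; Rmax <- 80
  conc <- spr_series_wt
  pl <- data.frame(conc_M = conc, Req = Rmax * conc / (conc + KD))
  f <- fit_equilibrium(pl)
  expect_equal(f$KD, KD, tolerance = 1e-6)
  expect_equal(f$Rmax, Rmax, tolerance = 1e-6)
  # half-saturation at C = KD
  expect_equal(Rmax * KD / (KD + KD), Rmax / 2)
  expect_error(fit_equilibrium(data.frame(conc_M = conc, Req = rep(5, 7))),
               "degenerate")
  # noisy plateaus: median recovery within 15% over 20 seeds
  kds <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- pl
    noisy$Req <- noisy$Req * (1 + rnorm(nrow(pl), 0, 0.05))
    fit_equilibrium(noisy)$KD
  }, 1)
  expect_lt(abs(median(kds) - KD) / KD, 0.15)
})

test_that("fold changes reproduce reference arithmetic and reciprocity", {
  expect_identical(fold_change(30.8, 11.3), 2.73)
  expect_identical(fold_change(30.8, 6.68), 4.61)
  expect_identical(fold_change(30.8, 1.95), 15.8)
  expect_equal(fold_change(12, 12), 1)
  expect_equal(fold_change(3, 7) * fold_change(7, 3), 1, tolerance = 1e-2)
  expect_error(fold_change(0, 5), "positive")
  tab <- affinity_table(c("wild-type", "mutA"), c(30.8, 11.3))
  expect_equal(tab$fold_change, c(1, 2.73))
})

test_that("percent-positive has exact fixed points and affine invariance", {
  expect_equal(percent_positive(1.0, 0.2, 1.0)$percent, 100)
  expect_equal(percent_positive(0.2, 0.2, 1.0)$percent, 0)
  expect_equal(percent_positive(0.6, 0.2, 1.0)$percent, 50)
  shift <- percent_positive(0.6 + 3, 0.2 + 3, 1.0 + 3)
  expect_equal(shift$percent, 50, tolerance = 1e-9)
  # out-of-range values are not clamped
  expect_gt(percent_positive(1.4, 0.2, 1.0)$percent, 100)
  expect_lt(percent_positive(0.1, 0.2, 1.0)$percent, 0)
  expect_error(percent_positive(0.5, 0.3, 0.3), "equal")
  reps <- percent_positive(c(0.58, 0.62, 0.61), 0.2, 1.0)
  expect_equal(reps$n, 3L)
  expect_gt(reps$sem, 0)
})

test_that("binder classification applies the stability thresholds", {
  cls <- classify_binders(c(strong_pep = 72.60, mid1 = 13.60, mid2 = 16.18,
                            weak_pep = 5))
  expect_identical(cls$category,
                   c("strong", "intermediate", "intermediate", "weak"))
})

test_that("sensorgram and plate CSV round trips preserve the tables", {
  d <- simulate_sensorgram(1e4, 0.308, 100, spr_series_mh, noise_sd = 1,
                           seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensorgrams(d, f)
  d2 <- read_sensorgrams(f)
  expect_equal(d2$response_RU, d$response_RU, tolerance = 1e-9)
  expect_equal(attr(d2, "t_assoc"), attr(d, "t_assoc"))

  g <- generate_elisa_plate(c(pepA = 72.6, pepB = 10), replicate_sd = 0.02,
                            seed = 3, path = withr::local_tempfile(
                              fileext = ".csv"))
  plate <- read_elisa_plate(g$path)
  q <- quantify_plate(plate)
  expect_setequal(q$peptide, c("pepA", "pepB"))
  expect_true(all(q$sem > 0))
  truth <- jsonlite::read_json(paste0(g$path, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_percentages$pepA, 72.6)
})

test_that("zero-noise plate generation inverts exactly and single fits warn", {
  g <- generate_elisa_plate(c(pep = 72.60), replicate_sd = 0,
                            n_replicates = 1, seed = 1)
  q <- quantify_plate(g$plate)
  expect_equal(q$percent, 72.60, tolerance = 1e-9)
})
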