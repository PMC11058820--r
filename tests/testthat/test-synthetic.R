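test_that("generators are pure functions of their seed", {
  t1 <- build_toy_complex(toy_complex_spec(seed = 8))
  t2 <- build_toy_complex(toy_complex_spec(seed = 8))
  expect_identical(t1$model$atoms, t2$model$atoms)
  t3 <- build_toy_complex(toy_complex_spec(seed = 9))
  expect_false(isTRUE(all.equal(coords(t1$model), coords(t3$model))))
  # different coordinates, same recovered geometry
  g1 <- docking_geometry(partition_complex(t1$model, "auto")[[1]])
  g3 <- docking_geometry(partition_complex(t3$model, "auto")[[1]])
  expect_equal(g1$crossing_angle, g3$crossing_angle, tolerance = 0.5)

  p1 <- plant_clash_case(seed = 6)
  p2 <- plant_clash_case(seed = 6)
  expect_identical(p1$model$atoms, p2$model$atoms)

  s1 <- generate_spr_dataset(1e4, 0.308, seed = 4)
  s2 <- generate_spr_dataset(1e4, 0.308, seed = 4)
  expect_identical(s1$data, s2$data)

  e1 <- generate_elisa_plate(c(p = 50), seed = 4)
  e2 <- generate_elisa_plate(c(p = 50), seed = 4)
  expect_identical(e1$plate, e2$plate)
})

test_that("generated complexes satisfy the structural invariants they promise", {
  toy <- toy_fixture(seed = 1)
  a <- toy$model$atoms
  expect_setequal(unique(a$chain), c("A", "B", "C", "D", "E"))
  expect_equal(length(unique(a$resno[a$chain == "C"])), 9L)
  part <- partition_complex(toy$model, "auto")[[1]]
  for (d in part$v_disulfides) {
    expect_lt(d$dist, 2.5)
    expect_gt(d$dist, 1.8)
  }
  g <- docking_geometry(part)
  expect_lt(abs(g$crossing_angle - toy$truth$crossing_angle), 0.5)
  expect_lt(abs(g$incident_angle - toy$truth$incident_angle), 0.5)
  expect_gt(nrow(toy$truth$interface_residues), 0)
})

test_that("the planted clash is a verified strong repulsion", {
  pc <- plant_clash_case(seed = 5)
  expect_gte(pc$lj_rep_wt, 5)
  em <- energy_model()
  pm <- place_mutation(pc$model, pc$clash_position$chain,
                       pc$clash_position$resno, pc$expected_best, em = em,
                       score_total = FALSE)
  p2 <- pc$partition; p2$model <- pm$model
  rep_mut <- binding_score(p2, em)$binding$lj_rep
  expect_gt(pc$lj_rep_wt - rep_mut, 1)   # relief of >= 1 kcal/mol
})

test_that("SPR dataset sidecar truth round-trips and refits cleanly", {
  f <- withr::local_tempfile(fileext = ".csv")
  g <- generate_spr_dataset(1e4, 0.308, 100, spr_series_wt, noise_sd = 0,
                            seed = 1, path = f)
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$KD, 30.8e-6, tolerance = 1e-9)
  refit <- fit_1to1(read_sensorgrams(f))
  expect_lt(refit$residual_sse, 1e-8)
  expect_equal(refit$KD, truth$KD, tolerance = 1e-6)
})
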