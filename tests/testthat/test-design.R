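test_that("substitution enumeration counts follow |positions| x (20 - excluded)", {
  pos52 <- data.frame(chain = "D", resno = 1:52, insert = "",
                      resid = rep("ALA", 52), role = "tcr_alpha")
  expect_equal(nrow(enumerate_substitutions(pos52)), 988L)
  pos1 <- pos52[1, ]
  expect_equal(nrow(enumerate_substitutions(pos1)), 19L)
  expect_equal(nrow(enumerate_substitutions(pos1,
                                            exclude = c("CYS", "GLY", "PRO"))),
               17L)
  cands <- enumerate_substitutions(pos1)
  expect_true("ALA" %in% cands$mut_aa)   # self-substitution included
  expect_false("CYS" %in% cands$mut_aa)
  expect_match(cands$label[cands$mut_aa == "MET"], "^αA1M$")
  bad <- pos1; bad$resid <- "XXX"
  expect_error(enumerate_substitutions(bad), "non-standard")
})

test_that("rotamer library covers all residues with staggered chi grids", {
  lib <- rotamer_library()
  for (aa in setdiff(tcrm:::AA3, c("GLY", "ALA")))
    expect_gte(nrow(lib[[aa]]), 1)
  expect_equal(nrow(lib$LYS), 81)   # 3^4
  expect_true(all(lib$LYS > -180 & lib$LYS <= 180))
  ex <- rotamer_library(ex = TRUE)
  expect_gt(nrow(ex$LEU), nrow(lib$LEU))
})

test_that("mutation placement keeps backbone and other residues bit-identical", {
  m <- toy_fixture(seed = 4)$model
  pm <- place_mutation(m, "E", 7, "TRP", score_total = FALSE)
  a0 <- m$atoms; a1 <- pm$model$atoms
  other0 <- a0[!(a0$chain == "E" & a0$resno == 7), c("elety", "x", "y", "z")]
  other1 <- a1[!(a1$chain == "E" & a1$resno == 7), c("elety", "x", "y", "z")]
  expect_identical(other0$elety, other1$elety)
  expect_identical(unname(as.matrix(other0[, c("x", "y", "z")])),
                   unname(as.matrix(other1[, c("x", "y", "z")])))
  bb0 <- a0[a0$chain == "E" & a0$resno == 7 &
              a0$elety %in% c("N", "CA", "C", "O", "CB"), c("x", "y", "z")]
  bb1 <- a1[a1$chain == "E" & a1$resno == 7 &
              a1$elety %in% c("N", "CA", "C", "O", "CB"), c("x", "y", "z")]
  expect_identical(unname(as.matrix(bb0)), unname(as.matrix(bb1)))
  expect_setequal(a1$elety[a1$chain == "E" & a1$resno == 7],
                  c("N", "CA", "C", "O",
                    tcrm:::sidechain_atom_names("TRP")))
})

test_that("mutation to glycine strips the side chain entirely", {
  m <- toy_fixture(seed = 4)$model
  pm <- place_mutation(m, "E", 7, "GLY", score_total = FALSE)
  a1 <- pm$model$atoms
  expect_setequal(a1$elety[a1$chain == "E" & a1$resno == 7],
                  c("N", "CA", "C", "O"))
})

test_that("rotamer optimality: repacked wild type never scores above the input pose", {
  pc <- plant_clash_case(seed = 2)
  em <- energy_model()
  e_wt <- score_pose(pc$model, em)$total
  pm <- place_mutation(pc$model, pc$clash_position$chain,
                       pc$clash_position$resno, "ARG", em = em)
  expect_lte(pm$energy$total, e_wt + 1e-6)
})

test_that("removing a planted clashing arginine reduces repulsion", {
  pc <- plant_clash_case(seed = 2)
  em <- energy_model()
  b_wt <- binding_score(pc$partition, em)
  pm <- place_mutation(pc$model, pc$clash_position$chain,
                       pc$clash_position$resno, "ALA", em = em,
                       score_total = FALSE)
  p2 <- pc$partition; p2$model <- pm$model
  b_ala <- binding_score(p2, em)
  expect_lt(b_ala$binding$lj_rep, b_wt$binding$lj_rep)
})

test_that("scans are complete, self-neutral and deterministic", {
  part <- toy_partition(seed = 1)
  pos <- select_design_positions(part, 8)
  selfs <- data.frame(chain = pos$chain, role = pos$role, resno = pos$resno,
                      insert = pos$insert, wt_aa = pos$resid,
                      mut_aa = pos$resid,
                      label = tcrm:::mutation_label(pos$role, pos$resid,
                                                    pos$resno, pos$resid))
  sc <- scan_mutations(part, selfs, seed = 5)
  expect_equal(nrow(sc$rows), nrow(selfs))
  expect_true(all(abs(sc$rows$delta_binding) < 1e-6))
  sc2 <- scan_mutations(part, selfs, seed = 5)
  expect_identical(sc$rows, sc2$rows)
  expect_identical(sc$fingerprint, sc2$fingerprint)
})

test_that("the planted clash-relieving substitution tops a full scan", {
  pc <- plant_clash_case(seed = 3)
  pos <- select_design_positions(pc$partition, 8)
  cands <- enumerate_substitutions(pos)
  sc <- scan_mutations(pc$partition, cands, seed = 3)
  top <- sc$ranking[1, ]
  expect_equal(top$resno, pc$clash_position$resno)
  expect_equal(top$mut_aa, pc$expected_best)
  expect_equal(nrow(sc$rows), nrow(cands))
})

test_that("combining mutations: rejection, additivity, and stacked relief", {
  pc <- plant_clash_case(seed = 2)
  em <- energy_model()
  part <- pc$partition
  pos <- select_design_positions(part, 8)
  mk <- function(chain, resno, wt, mut, role)
    data.frame(chain = chain, role = role, resno = resno, insert = "",
               wt_aa = wt, mut_aa = mut,
               label = tcrm:::mutation_label(role, wt, resno, mut))
  same <- rbind(mk("E", pc$clash_position$resno, "ARG", "GLY", "tcr_beta"),
                mk("E", pc$clash_position$resno, "ARG", "ALA", "tcr_beta"))
  expect_error(combine_mutations(part, same, em = em), "distinct")

  # far-apart pair (alpha tip + beta clash site): deltas add
  apos <- pos[pos$role == "tcr_alpha", ][1, ]
  singles <- rbind(mk(apos$chain, apos$resno, apos$resid, "LEU", apos$role),
                   mk("E", pc$clash_position$resno, "ARG", "GLY", "tcr_beta"))
  s1 <- scan_mutations(part, singles[1, ], em = em)$rows$delta_binding
  s2 <- scan_mutations(part, singles[2, ], em = em)$rows$delta_binding
  pair <- combine_mutations(part, singles, em = em)
  expect_equal(pair$rows$delta_binding[1], s1 + s2, tolerance = 1e-6)
  # stacked relief: the pair outperforms either single
  expect_lt(pair$rows$delta_binding[1], min(s1, s2))
})
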