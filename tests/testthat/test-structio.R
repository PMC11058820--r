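test_that("PDB and mmCIF round trips preserve coordinates to dialect precision", {
  m <- toy_fixture(seed = 2)$model
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f1, "pdb")
  m2 <- read_structure(f1)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_lt(max(abs(coords(m) - coords(m2))), 0.001 + 1e-12)
  expect_identical(m2$atoms$elety, m$atoms$elety)

  f2 <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, f2, "cif")
  m3 <- suppressWarnings(read_structure(f2))
  expect_identical(unname(coords(m3)), unname(coords(m)))
  expect_identical(m3$atoms$resid, m$atoms$resid)
})

test_that("oversized coordinates are refused in the fixed-width PDB dialect", {
  m <- toy_fixture(seed = 2)$model
  m$atoms$x[1] <- 1e5
  expect_error(write_structure(m, tempfile(fileext = ".pdb"), "pdb"),
               "mmCIF")
})

test_that("alt-loc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s"
  lines <- c(
    sprintf(fmt, 1, "N", " ", "SER", "A", 1, 0, 0, 0, 1, 0, "N"),
    sprintf(fmt, 2, "CA", " ", "SER", "A", 1, 1.46, 0, 0, 1, 0, "C"),
    sprintf(fmt, 3, "C", " ", "SER", "A", 1, 2.0, 1.4, 0, 1, 0, "C"),
    sprintf(fmt, 4, "O", " ", "SER", "A", 1, 1.5, 2.5, 0, 1, 0, "O"),
    sprintf(fmt, 5, "CB", " ", "SER", "A", 1, 2.0, -1.2, 1.0, 1, 0, "C"),
    sprintf(fmt, 6, "OG", "A", "SER", "A", 1, 3.3, -1.0, 1.4, 0.6, 0, "O"),
    sprintf(fmt, 7, "OG", "B", "SER", "A", 1, 1.2, -2.2, 1.8, 0.4, 0, "O"),
    "END")
  writeLines(lines, f)
  m <- read_structure(f)
  og <- m$atoms[m$atoms$elety == "OG", ]
  expect_equal(nrow(og), 1L)
  expect_equal(og$x, 3.3, tolerance = 1e-6)
  expect_equal(og$o, 0.6, tolerance = 1e-6)
})

test_that("explicit and auto partitions of the toy complex agree", {
  toy <- toy_fixture(seed = 1)
  explicit <- partition_complex(
    toy$model, c(A = "mhc_heavy", B = "b2m", C = "peptide",
                 D = "tcr_alpha", E = "tcr_beta"))[[1]]
  auto <- partition_complex(toy$model, "auto")
  expect_length(auto, 1L)
  expect_identical(auto[[1]]$roles, explicit$roles)
  # role selections partition the residues: disjoint and exhaustive
  chains <- unlist(explicit$roles, use.names = FALSE)
  expect_false(anyDuplicated(chains) > 0)
  expect_setequal(chains, unique(toy$model$atoms$chain))
  # each TCR chain carries exactly one variable-domain disulfide
  for (d in explicit$v_disulfides) expect_lt(d$dist, 2.5)
})

test_that("partition errors name the unresolved role or missing chain", {
  xyz <- cbind(seq(0, 87, 3), rnorm(30), rnorm(30))
  m <- tiny_model(rep("CA", 30), rep("GLY", 30),
                  rep(c("A", "B"), each = 15), rep(1:15, 2), xyz)
  expect_error(partition_complex(m, "auto"), "peptide role unresolved")
  toy <- toy_fixture(seed = 1)
  expect_error(partition_complex(toy$model, c(A = "mhc_heavy")),
               "missing role")
  expect_error(partition_complex(toy$model, c(Z = "mhc_heavy")),
               "absent")
})

test_that("waters are excluded and unknown elements rejected on read", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s"
  writeLines(c(sprintf(fmt, 1, "CA", "GLY", "A", 1, 0, 0, 0, 1, 0, "C"),
               sprintf(fmt, 2, "O", "HOH", "W", 1, 5, 5, 5, 1, 0, "O"),
               "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1L)
})
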