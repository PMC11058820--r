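# Shared fixtures and independent oracles. Fixtures are generated in code;
# toy complexes are cached per seed so test files can share them cheaply.

.toy_cache <- new.env(parent = emptyenv())

toy_fixture <- function(seed = 1L, ...) {
  key <- paste0("toy", seed, paste(c(...), collapse = "_"))
  if (is.null(.toy_cache[[key]]))
    .toy_cache[[key]] <- build_toy_complex(toy_complex_spec(seed = seed, ...))
  .toy_cache[[key]]
}

toy_partition <- function(seed = 1L, ...) {
  key <- paste0("part", seed, paste(c(...), collapse = "_"))
  if (is.null(.toy_cache[[key]]))
    .toy_cache[[key]] <-
      partition_complex(toy_fixture(seed, ...)$model, "auto")[[1]]
  .toy_cache[[key]]
}

# minimal structure model from bare atom fields
tiny_model <- function(elety, resid, chain, resno, xyz) {
  structure_model(data.frame(elety = elety, resid = resid, chain = chain,
                             resno = resno, x = xyz[, 1], y = xyz[, 2],
                             z = xyz[, 3], stringsAsFactors = FALSE))
}

# Monte-Carlo SASA oracle: dense random sphere sampling, independent of the
# deterministic lattice implementation.
mc_sasa_oracle <- function(model, probe = 1.4, n = 20000L, seed = 99L) {
  a <- model$atoms
  X <- as.matrix(a[, c("x", "y", "z")])
  R <- a$radius + probe
  set.seed(seed)
  per_atom <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    p <- sweep(v * R[i], 2, X[i, ], "+")
    exposed <- rep(TRUE, n)
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      dj2 <- (p[, 1] - X[j, 1])^2 + (p[, 2] - X[j, 2])^2 +
        (p[, 3] - X[j, 3])^2
      exposed <- exposed & dj2 > R[j]^2
    }
    per_atom[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

# Naive scalar double-loop pose-energy oracle, written independently of the
# vectorized implementation (same physical definitions, plain arithmetic).
naive_score_oracle <- function(model, em, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  ap <- tcrm:::atom_params(structure_model(
    a[, setdiff(names(a), "ridx"), drop = FALSE]), em)
  ridx <- a$ridx
  n <- nrow(a)
  sums <- c(lj_attr = 0, lj_rep = 0, coulomb = 0, solvation = 0, hbond = 0)
  excl_pairs <- list(c("C", "N"), c("CA", "N"), c("O", "N"), c("C", "CA"))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (ridx[i] == ridx[j]) next
      if (a$chain[i] == a$chain[j] && ridx[j] - ridx[i] == 1L) {
        skip <- FALSE
        for (ep in excl_pairs)
          if (a$elety[i] == ep[1] && a$elety[j] == ep[2]) skip <- TRUE
        if (skip) next
      }
      r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      if (r >= em$cutoff) next
      s <- if (r <= em$switch_on) 1 else {
        r2 <- r^2; ron2 <- em$switch_on^2; roff2 <- em$cutoff^2
        (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
      }
      eps <- sqrt(ap$eps[i] * ap$eps[j])
      rmin <- ap$rmin2[i] + ap$rmin2[j]
      lj <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
      if (r >= rmin) {
        sums["lj_attr"] <- sums["lj_attr"] + s * lj
      } else {
        sums["lj_attr"] <- sums["lj_attr"] - s * eps
        rep_ <- if (r >= 0.6 * rmin) lj + eps else {
          rk <- 0.6 * rmin
          v0 <- eps * ((rmin / rk)^12 - 2 * (rmin / rk)^6) + eps
          s0 <- eps * (-12 * rmin^12 / rk^13 + 12 * rmin^6 / rk^7)
          v0 + s0 * (r - rk)
        }
        sums["lj_rep"] <- sums["lj_rep"] + s * rep_
      }
      sums["coulomb"] <- sums["coulomb"] +
        s * 332.064 * ap$q[i] * ap$q[j] / (em$eps0 * r^2)
      gi <- (ap$dg[i] / (2 * pi^1.5 * ap$lambda[i] * r^2)) *
        exp(-((r - ap$rvdw[i]) / ap$lambda[i])^2) * ap$vol[j]
      gj <- (ap$dg[j] / (2 * pi^1.5 * ap$lambda[j] * r^2)) *
        exp(-((r - ap$rvdw[j]) / ap$lambda[j])^2) * ap$vol[i]
      sums["solvation"] <- sums["solvation"] - s * (gi + gj)
      if ((ap$donor[i] && ap$acceptor[j]) || (ap$donor[j] && ap$acceptor[i]))
        sums["hbond"] <- sums["hbond"] - s * exp(-((r - 2.9) / 0.3)^2)
    }
  }
  sums
}

# Independent cross-partner pair sum (binding-score additivity oracle).
naive_cross_oracle <- function(partition, em) {
  m <- partition$model
  st <- which(tcrm:::tcr_sel(partition))
  sp <- which(tcrm:::pmhc_sel(partition))
  both <- tcrm:::chain_sel(m, unlist(partition$roles, use.names = FALSE))
  full <- naive_score_oracle(m, em, both)
  t_only <- naive_score_oracle(m, em,
                               seq_len(nrow(m$atoms)) %in% st)
  p_only <- naive_score_oracle(m, em,
                               seq_len(nrow(m$atoms)) %in% sp)
  full - t_only - p_only
}

# salt-bridge fixture: toy complex with a peptide ASP and a TCR LYS whose
# NZ sits 3.0 A from OD1
saltbridge_fixture <- function() {
  if (!is.null(.toy_cache[["saltbridge"]])) return(.toy_cache[["saltbridge"]])
  toy <- toy_fixture(seed = 11)
  m <- toy$model
  m <- place_mutation(m, "C", 4, "ASP", score_total = FALSE)$model
  m <- place_mutation(m, "E", 7, "LYS", score_total = FALSE)$model
  a <- m$atoms
  od1 <- as.numeric(a[a$chain == "C" & a$resno == 4 & a$elety == "OD1",
                      c("x", "y", "z")])
  nz_row <- which(a$chain == "E" & a$resno == 7 & a$elety == "NZ")
  ce_row <- which(a$chain == "E" & a$resno == 7 & a$elety == "CE")
  ce <- as.numeric(a[ce_row, c("x", "y", "z")])
  # put NZ exactly 3.0 A from OD1, roughly along the CE direction
  m$atoms[nz_row, c("x", "y", "z")] <-
    as.list(od1 + 3.0 * tcrm:::unit(ce - od1))
  part <- partition_complex(m, c(A = "mhc_heavy", B = "b2m", C = "peptide",
                                 D = "tcr_alpha", E = "tcr_beta"))[[1]]
  .toy_cache[["saltbridge"]] <- list(model = m, partition = part)
  .toy_cache[["saltbridge"]]
}

# translate the TCR chains of a partition far away from the pMHC
separated_partition <- function(part, dist = 100) {
  m <- part$model
  sel <- tcrm:::tcr_sel(part)
  m$atoms[sel, "x"] <- m$atoms[sel, "x"] + dist
  p2 <- part
  p2$model <- m
  p2
}
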