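# Decomposable pairwise pose score. This is a transparent physics-style
# analogue with the familiar decomposition roles (attractive/repulsive vdW,
# screened electrostatics, Gaussian-exclusion solvation, hydrogen bonds); it
# is designed for *ranking* fixed-backbone point mutations, not for absolute
# free energies.

COULOMB_K <- 332.064  # kcal*A/(mol*e^2)

#' Construct an energy model
#'
#' Loads the bundled versioned parameter tables (Lennard-Jones classes,
#' Lazaridis-Karplus solvation, reduced partial charges) and fixes the term
#' weights, distance-dependent dielectric and cutoff/switching window.
#'
#' The pair energy of heavy atoms i,j at distance r uses: a 12-6
#' Lennard-Jones split into an attractive part (clamped at -epsilon inside
#' Rmin) and a repulsive part (the remainder, linearly extrapolated below
#' 0.6 Rmin); screened Coulomb `332.064 q_i q_j / (eps0 r^2)` (dielectric
#' `eps(r) = eps0 * r`); Lazaridis-Karplus Gaussian-exclusion desolvation;
#' and a Gaussian hydrogen-bond well (depth 1 kcal/mol at 2.9 A) between
#' donor- and acceptor-capable heavy atoms. All terms are switched smoothly
#' to zero across `switch_on`..`cutoff`.
#'
#' @param weights named numeric: `lj_attr`, `lj_rep`, `coulomb`,
#'   `solvation`, `hbond`.
#' @param eps0 dielectric prefactor (default 10).
#' @param cutoff interaction cutoff (A, default 6).
#' @param switch_on start of the switching window (A, default 5.5).
#' @param param_dir directory holding `lj.tsv`, `solvation.tsv`,
#'   `charges.tsv` (defaults to the tables shipped with the package).
#' @return object of class `energy_model`.
#' @export
energy_model <- function(weights = c(lj_attr = 1.0, lj_rep = 0.55,
                                     coulomb = 1.0, solvation = 1.0,
                                     hbond = 1.0),
                         eps0 = 10, cutoff = 6.0, switch_on = 5.5,
                         param_dir = system.file("extdata", "params",
                                                 package = "tcrm")) {
  stopifnot(all(weights >= 0), cutoff > switch_on, switch_on > 0)
  rd <- function(f) read.delim(file.path(param_dir, f), comment.char = "#",
                               stringsAsFactors = FALSE)
  lj <- rd("lj.tsv"); solv <- rd("solvation.tsv"); chg <- rd("charges.tsv")
  obj <- list(weights = weights, eps0 = eps0, cutoff = cutoff,
              switch_on = switch_on, lj = lj, solv = solv, charges = chg,
              version = "params-1.0")
  class(obj) <- "energy_model"
  obj
}

# Per-atom parameter vectors for a model (class mapping by element).
atom_params <- function(model, em) {
  a <- model$atoms
  cls <- toupper(a$elem)
  cls[!(cls %in% em$lj$class)] <- "X"
  il <- match(cls, em$lj$class)
  is <- match(cls, em$solv$class)
  if (anyNA(il) || anyNA(is))
    stop("atoms without energy parameters: ",
         paste(unique(a$elety[is.na(il) | is.na(is)]), collapse = ", "))
  q <- numeric(nrow(a))
  for (k in seq_len(nrow(em$charges))) {
    row <- em$charges[k, ]
    hitr <- if (row$resid == "*") rep(TRUE, nrow(a)) else a$resid == row$resid
    q[hitr & a$elety == row$elety] <- row$charge
  }
  don <- mapply(is_donor, a$resid, a$elety, USE.NAMES = FALSE)
  acc <- mapply(is_acceptor, a$resid, a$elety, USE.NAMES = FALSE)
  list(rmin2 = em$lj$rmin2[il], eps = em$lj$epsilon[il],
       dg = em$solv$dgfree[is], lambda = em$solv$lambda[is],
       vol = em$solv$volume[is], q = q, donor = don, acceptor = acc,
       rvdw = a$radius)
}

# CHARMM-style C1 switching function on r in [switch_on, cutoff].
switch_fn <- function(r, ron, roff) {
  s <- rep(1, length(r))
  mid <- r > ron & r < roff
  r2 <- r[mid]^2; ron2 <- ron^2; roff2 <- roff^2
  s[mid] <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  s[r >= roff] <- 0
  s
}

# Interacting atom pairs for a selection: unique heavy-atom pairs excluding
# same-residue pairs and 1-2/1-3 neighbors across the backbone link.
pair_list <- function(model, sel = NULL) {
  a <- model$atoms
  rows <- if (is.null(sel)) seq_len(nrow(a)) else which(sel)
  a <- a[rows, , drop = FALSE]
  X <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  D2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  keep <- upper.tri(D2)
  same_res <- outer(a$ridx, a$ridx, "==")
  keep <- keep & !same_res
  # backbone-link 1-2/1-3 exclusions between consecutive residues
  adj <- outer(a$ridx, a$ridx, function(i, j) j - i == 1L) &
    outer(a$chain, a$chain, "==")
  en <- a$elety
  excl <- (outer(en == "C", en == "N", "&") |
           outer(en == "CA", en == "N", "&") |
           outer(en == "O", en == "N", "&") |
           outer(en == "C", en == "CA", "&")) & adj
  keep <- keep & !excl
  idx <- which(keep, arr.ind = TRUE)
  r <- sqrt(pmax(0, D2[keep]))
  ord <- order(idx[, 1], idx[, 2])
  list(i = rows[idx[ord, 1]], j = rows[idx[ord, 2]], r = r[ord])
}

# Per-pair term energies (unswitched) given parameter vectors at indices.
pair_terms <- function(r, pi_, pj, em) {
  eps <- sqrt(pi_$eps * pj$eps)
  rmin <- pi_$rmin2 + pj$rmin2
  x6 <- (rmin / r)^6
  lj <- eps * (x6^2 - 2 * x6)
  attr_ <- ifelse(r >= rmin, lj, -eps)
  rep_ <- ifelse(r >= rmin, 0, lj + eps)
  knee <- 0.6 * rmin
  low <- r < knee
  if (any(low)) {
    xk6 <- (rmin[low] / knee[low])^6
    v0 <- eps[low] * (xk6^2 - 2 * xk6) + eps[low]
    s0 <- eps[low] * (-12 * rmin[low]^12 / knee[low]^13 +
                        12 * rmin[low]^6 / knee[low]^7)
    rep_[low] <- v0 + s0 * (r[low] - knee[low])
  }
  coul <- COULOMB_K * pi_$q * pj$q / (em$eps0 * r^2)
  gauss <- function(p, q_) {
    d <- r - p$rvdw
    (p$dg / (2 * pi^1.5 * p$lambda * r^2)) * exp(-(d / p$lambda)^2) * q_$vol
  }
  solv <- -(gauss(pi_, pj) + gauss(pj, pi_))
  hb_pair <- (pi_$donor & pj$acceptor) | (pj$donor & pi_$acceptor)
  hb <- ifelse(hb_pair, -exp(-((r - 2.9) / 0.3)^2), 0)
  list(lj_attr = attr_, lj_rep = rep_, coulomb = coul, solvation = solv,
       hbond = hb)
}

#' Score a pose with the decomposable pairwise energy model
#'
#' Sums term energies over unique heavy-atom pairs of the selection
#' (excluding intra-residue pairs and 1-2/1-3 neighbors across the peptide
#' bond), with all terms switched to zero across the cutoff window.
#' Summation order is deterministic.
#'
#' @param model a `structure_model`.
#' @param em an [energy_model()].
#' @param sel optional row selection (atoms outside it are ignored).
#' @return list of class `energy_breakdown`: unweighted term sums `lj_attr`,
#'   `lj_rep`, `coulomb`, `solvation`, `hbond`, and `total` = weighted sum
#'   (kcal/mol).
#' @export
score_pose <- function(model, em = energy_model(), sel = NULL) {
  pl <- pair_list(model, sel)
  ap <- atom_params(model, em)
  take <- function(idx) lapply(ap, function(v) v[idx])
  if (length(pl$r) == 0L) return(energy_breakdown(rep(0, 5), em))
  within_cut <- pl$r < em$cutoff
  r <- pl$r[within_cut]
  if (length(r) == 0L) return(energy_breakdown(rep(0, 5), em))
  pi_ <- take(pl$i[within_cut]); pj <- take(pl$j[within_cut])
  terms <- pair_terms(r, pi_, pj, em)
  s <- switch_fn(r, em$switch_on, em$cutoff)
  sums <- vapply(terms, function(v) sum(v * s), 1)
  if (!all(is.finite(sums))) {
    bad <- which(!is.finite(Reduce(`+`, terms)))[1]
    stop("non-finite pair energy between atoms ", pl$i[within_cut][bad],
         " and ", pl$j[within_cut][bad])
  }
  energy_breakdown(sums, em)
}

energy_breakdown <- function(sums, em) {
  names(sums) <- c("lj_attr", "lj_rep", "coulomb", "solvation", "hbond")
  out <- as.list(sums)
  out$total <- sum(em$weights[names(sums)] * sums)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy_breakdown (kcal/mol): total %.3f\n", x$total))
  for (t in c("lj_attr", "lj_rep", "coulomb", "solvation", "hbond"))
    cat(sprintf("  %-10s %10.4f\n", t, x[[t]]))
  invisible(x)
}

breakdown_minus <- function(a, b) {
  out <- lapply(c("lj_attr", "lj_rep", "coulomb", "solvation", "hbond",
                  "total"), function(t) a[[t]] - b[[t]])
  names(out) <- c("lj_attr", "lj_rep", "coulomb", "solvation", "hbond", "total")
  class(out) <- "energy_breakdown"
  out
}

#' Interface binding score B = E(complex) - E(TCR) - E(pMHC)
#'
#' Scores the complex, then the TCR side (alpha + beta chains) and the pMHC
#' side (MHC heavy + b2m + peptide) separately on identical, unrelaxed
#' coordinates, and subtracts componentwise. With a strictly pairwise model
#' this equals the sum of cross-partner pair energies.
#'
#' @param partition a `complex_partition`.
#' @param em an [energy_model()].
#' @return list of class `binding_score` with `complex`, `tcr_alone`,
#'   `pmhc_alone` and `binding` (each an `energy_breakdown`).
#' @export
binding_score <- function(partition, em = energy_model()) {
  m <- partition$model
  st <- tcr_sel(partition); sp <- pmhc_sel(partition)
  e_cplx <- score_pose(m, em, st | sp)
  e_tcr <- score_pose(m, em, st)
  e_pmhc <- score_pose(m, em, sp)
  b <- breakdown_minus(breakdown_minus(e_cplx, e_tcr), e_pmhc)
  out <- list(complex = e_cplx, tcr_alone = e_tcr, pmhc_alone = e_pmhc,
              binding = b)
  class(out) <- "binding_score"
  out
}

#' @export
print.binding_score <- function(x, ...) {
  cat(sprintf("binding_score: B = %.3f kcal/mol (complex %.3f, TCR %.3f, pMHC %.3f)\n",
              x$binding$total, x$complex$total, x$tcr_alone$total,
              x$pmhc_alone$total))
  invisible(x)
}

# Cross-partner pair sum: direct evaluation of interactions spanning the
# TCR/pMHC boundary. Used by the scanner for speed; equals binding_score's
# subtraction by pairwise additivity (asserted in the test suite).
cross_binding <- function(partition, em) {
  m <- partition$model
  st <- which(tcr_sel(partition)); sp <- which(pmhc_sel(partition))
  a <- m$atoms
  XA <- coords(m, st); XB <- coords(m, sp)
  D2 <- outer(rowSums(XA^2), rowSums(XB^2), "+") - 2 * XA %*% t(XB)
  hit <- which(D2 < em$cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(energy_breakdown(rep(0, 5), em))
  ap <- atom_params(m, em)
  take <- function(idx) lapply(ap, function(v) v[idx])
  i <- st[hit[, 1]]; j <- sp[hit[, 2]]
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  r <- sqrt(pmax(0, D2[hit][ord]))
  terms <- pair_terms(r, take(i), take(j), em)
  s <- switch_fn(r, em$switch_on, em$cutoff)
  energy_breakdown(vapply(terms, function(v) sum(v * s), 1), em)
}
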