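# Deterministic golden-spiral (Fibonacci) unit-sphere lattice.
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the heavy-atom van der Waals surface using a
#' deterministic golden-spiral point lattice (no randomness), so repeated
#' runs are bit-identical. Per-atom area is
#' `(exposed points / n_points) * 4 * pi * (r + probe)^2`.
#'
#' @param model a `structure_model`.
#' @param sel optional row selection restricting the atom set (atoms outside
#'   the selection are ignored entirely, i.e. area of the selection alone).
#' @param probe_radius probe radius in Angstrom (default 1.4, water).
#' @param n_points lattice points per atom (default 960, minimum 92).
#' @return list with `per_atom` (A^2, one per selected atom), `per_residue`
#'   (named by chain:resno), `total`, `probe_radius`, `n_points`.
#' @export
shrake_rupley <- function(model, sel = NULL, probe_radius = 1.4,
                          n_points = 960L) {
  if (n_points < 92L) stop("n_points must be at least 92")
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  n <- nrow(a)
  if (n == 0L) stop("zero atoms selected for SASA")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$radius + probe_radius
  pts <- sphere_lattice(n_points)
  # neighbor lists via cell-free cutoff on pairwise distances
  maxR <- max(R)
  per_atom <- numeric(n)
  # squared distances between atom centers, computed blockwise for memory
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      per_atom[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > R[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- sum(exposed) / n_points * 4 * pi * R[i]^2
  }
  res_key <- paste0(a$chain, ":", a$resno, a$insert)
  per_residue <- tapply(per_atom, factor(res_key, levels = unique(res_key)),
                        sum)
  list(per_atom = per_atom, per_residue = per_residue,
       total = sum(per_atom), probe_radius = probe_radius,
       n_points = as.integer(n_points))
}

#' Buried surface area of the TCR-pMHC interface
#'
#' Total BSA follows the additive convention
#' `SASA(TCR alone) + SASA(pMHC alone) - SASA(complex)`, symmetric in the
#' partner order. Peptide burial is the area the free peptide loses on
#' binding the MHC groove (TCR absent):
#' `SASA(peptide alone) - [SASA(peptide in MHC+b2m complex)]`.
#'
#' @param partition a `complex_partition`.
#' @param probe_radius,n_points passed to [shrake_rupley()].
#' @return list with `bsa_total`, `bsa_by_side` (named, A^2 lost by each
#'   partner), `peptide_burial`.
#' @export
buried_surface_area <- function(partition, probe_radius = 1.4,
                                n_points = 960L) {
  m <- partition$model
  st <- tcr_sel(partition); sp <- pmhc_sel(partition)
  if (!any(st) || !any(sp)) stop("empty partner selection")
  sasa_t <- shrake_rupley(m, st, probe_radius, n_points)
  sasa_p <- shrake_rupley(m, sp, probe_radius, n_points)
  sasa_c <- shrake_rupley(m, st | sp, probe_radius, n_points)
  bsa_total <- sasa_t$total + sasa_p$total - sasa_c$total
  # per-side burial: each partner's own area lost in the complex
  in_complex <- which(st | sp)
  pos_t <- match(which(st), in_complex)
  pos_p <- match(which(sp), in_complex)
  by_side <- c(tcr = sasa_t$total - sum(sasa_c$per_atom[pos_t]),
               pmhc = sasa_p$total - sum(sasa_c$per_atom[pos_p]))
  spep <- role_sel(partition, "peptide")
  sgroove <- role_sel(partition, c("mhc_heavy", "b2m", "peptide"))
  sasa_pep <- shrake_rupley(m, spep, probe_radius, n_points)
  sasa_groove <- shrake_rupley(m, sgroove, probe_radius, n_points)
  pos_pep <- match(which(spep), which(sgroove))
  peptide_burial <- sasa_pep$total - sum(sasa_groove$per_atom[pos_pep])
  list(bsa_total = bsa_total, bsa_by_side = by_side,
       peptide_burial = peptide_burial,
       probe_radius = probe_radius, n_points = as.integer(n_points))
}
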