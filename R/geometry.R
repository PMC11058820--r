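#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mov`
#' onto `ref` (SVD solution with reflection correction).
#'
#' @param ref,mov n x 3 coordinate matrices, n >= 3, not all collinear.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd` (A)
#'   and `n_atoms`; apply as `mov %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!all(dim(ref) == dim(mov))) stop("point sets differ in size")
  n <- nrow(ref)
  if (n < 3) stop("need at least 3 points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  P <- sweep(mov, 2, cm); Q <- sweep(ref, 2, cr)
  if (min(svd(P)$d[2], svd(Q)$d[2]) < 1e-8)
    stop("degenerate geometry: point set is collinear")
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cr - as.numeric(R %*% cm)
  moved <- mov %*% t(R)
  moved <- sweep(moved, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((moved - ref)^2)))
  list(rotation = R, translation = t, rmsd = rmsd, n_atoms = n)
}

#' Root-mean-square deviation between two point sets
#'
#' @param a,b n x 3 coordinate matrices.
#' @param superpose minimize over rigid motions first (Kabsch); `FALSE` gives
#'   the raw coordinate RMSD.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("point sets differ in size")
  if (superpose) return(kabsch_superpose(a, b)$rmsd)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Least-squares MHC groove plane
#'
#' Fits a total-least-squares plane through the C-alpha atoms of the alpha1
#' and alpha2 helix windows of the MHC heavy chain (author numbering;
#' defaults 50-85 and 138-175). The normal is oriented toward the TCR side
#' of the complex. Because helical C-alpha atoms lie on a ~2.3 A cylinder,
#' the fit residual is of that order even for perfectly coplanar helix axes.
#'
#' @param partition a `complex_partition`.
#' @param helix_windows list of two integer ranges (author residue numbers).
#' @return list with `point`, `normal` (unit), `residual` (RMS A), `n_ca`.
#' @export
groove_plane <- function(partition,
                         helix_windows = list(50:85, 138:175)) {
  m <- partition$model
  a <- m$atoms
  heavy <- unlist(partition$roles["mhc_heavy"], use.names = FALSE)
  sel <- a$chain %in% heavy & a$elety == "CA" &
    a$resno %in% unlist(helix_windows)
  if (sum(sel) < 3)
    stop("fewer than 3 C-alpha atoms in the groove helix windows")
  X <- coords(m, sel)
  ctr <- colMeans(X)
  s <- svd(sweep(X, 2, ctr))
  normal <- s$v[, 3]
  residual <- sqrt(mean((sweep(X, 2, ctr) %*% normal)^2))
  tcr_ctr <- colMeans(coords(m, tcr_sel(partition)))
  if (sum((tcr_ctr - ctr) * normal) < 0) normal <- -normal
  list(point = ctr, normal = unit(normal), residual = residual,
       n_ca = nrow(X))
}

#' TCR-pMHC docking geometry
#'
#' The TCR axis runs from the V-alpha disulfide SG midpoint to the V-beta
#' disulfide SG midpoint (the vector drawn between the variable-domain
#' disulfides); the peptide axis runs N-terminal C-alpha to C-terminal
#' C-alpha. The crossing (docking) angle is the angle between the two axes
#' after projecting both onto the MHC groove plane, reported in [0, 180) as
#' seen looking along the peptide N-to-C direction; the incident angle is
#' the tilt of the TCR axis out of the groove plane,
#' |90 deg - angle(tcr_axis, plane normal)|.
#'
#' @param partition a `complex_partition`.
#' @param helix_windows passed to [groove_plane()].
#' @param disulfide_point `"SG"` (midpoint of the SG atoms, default) or
#'   `"CA"` (midpoint of the cysteine C-alpha atoms).
#' @return list with `crossing_angle`, `incident_angle` (degrees),
#'   `tcr_axis`, `peptide_axis`, `groove_plane_normal` (unit vectors).
#' @export
docking_geometry <- function(partition, helix_windows = list(50:85, 138:175),
                             disulfide_point = c("SG", "CA")) {
  disulfide_point <- match.arg(disulfide_point)
  m <- partition$model
  a <- m$atoms
  anchor <- function(which_chain, ss) {
    if (disulfide_point == "SG") {
      colMeans(as.matrix(a[ss$sg, c("x", "y", "z")]))
    } else {
      ca <- which(a$chain == which_chain & a$resid == "CYS" &
                    a$elety == "CA" & a$resno %in% ss$resno)
      if (length(ca) < 2) stop("C-alpha atoms of disulfide cysteines not found")
      colMeans(as.matrix(a[ca, c("x", "y", "z")]))
    }
  }
  p_alpha <- anchor(partition$roles$tcr_alpha, partition$v_disulfides$alpha)
  p_beta <- anchor(partition$roles$tcr_beta, partition$v_disulfides$beta)
  tcr_axis <- unit(p_beta - p_alpha)

  pep_chain <- partition$roles$peptide
  ca <- a[a$chain %in% pep_chain & a$elety == "CA", , drop = FALSE]
  if (nrow(ca) < 5) stop("peptide too short: ", nrow(ca), " C-alpha atoms")
  ca <- ca[order(ca$resno), , drop = FALSE]
  pep_axis <- unit(as.numeric(ca[nrow(ca), c("x", "y", "z")]) -
                   as.numeric(ca[1, c("x", "y", "z")]))

  gp <- groove_plane(partition, helix_windows)
  n <- gp$normal
  proj <- function(v) {
    w <- v - sum(v * n) * n
    if (vnorm(w) < 1e-9) stop("axis is perpendicular to the groove plane")
    unit(w)
  }
  tp <- proj(tcr_axis); pp <- proj(pep_axis)
  # signed angle in the plane, viewed along the peptide N->C direction
  ang <- rad2deg(atan2(sum(pracma_cross(pp, tp) * n), sum(pp * tp)))
  crossing <- abs(ang)
  if (crossing >= 180) crossing <- 0
  incident <- abs(90 - vec_angle(tcr_axis, n))
  list(crossing_angle = crossing, incident_angle = incident,
       tcr_axis = tcr_axis, peptide_axis = pep_axis,
       groove_plane_normal = n, groove_plane = gp)
}
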