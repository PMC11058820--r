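# Idealized side-chain internal coordinates (Z-matrix rows). Each atom is
# placed by NeRF from three previously placed atoms: angle is at the parent
# (b-c-new), dihedral a-b-c-new is a chi variable plus offset, or fixed.
# Bond lengths/angles are standard Engh-Huber-style values.
zrow <- function(name, a, b, c, dist, ang, chi = NA, offset = 0, fixed = NA) {
  list(name = name, a = a, b = b, c = c, dist = dist, ang = ang,
       chi = chi, offset = offset, fixed = fixed)
}

SIDECHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(),
  SER = list(zrow("OG", "N", "CA", "CB", 1.417, 110.8, 1)),
  CYS = list(zrow("SG", "N", "CA", "CB", 1.808, 113.8, 1)),
  THR = list(zrow("OG1", "N", "CA", "CB", 1.433, 109.6, 1),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, offset = -120)),
  VAL = list(zrow("CG1", "N", "CA", "CB", 1.527, 110.7, 1),
             zrow("CG2", "N", "CA", "CB", 1.527, 110.4, 1, offset = 120)),
  ILE = list(zrow("CG1", "N", "CA", "CB", 1.530, 110.4, 1),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, offset = -120),
             zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2)),
  LEU = list(zrow("CG", "N", "CA", "CB", 1.530, 116.3, 1),
             zrow("CD1", "CA", "CB", "CG", 1.521, 110.7, 2),
             zrow("CD2", "CA", "CB", "CG", 1.521, 110.4, 2, offset = 120)),
  MET = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
             zrow("SD", "CA", "CB", "CG", 1.803, 112.7, 2),
             zrow("CE", "CB", "CG", "SD", 1.791, 100.9, 3)),
  LYS = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
             zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 2),
             zrow("CE", "CB", "CG", "CD", 1.520, 111.3, 3),
             zrow("NZ", "CG", "CD", "CE", 1.489, 111.9, 4)),
  ARG = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
             zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 2),
             zrow("NE", "CB", "CG", "CD", 1.461, 112.0, 3),
             zrow("CZ", "CG", "CD", "NE", 1.329, 124.2, 4),
             zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, fixed = 0),
             zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, fixed = 180)),
  ASP = list(zrow("CG", "N", "CA", "CB", 1.516, 112.6, 1),
             zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, 2),
             zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 2, offset = 180)),
  ASN = list(zrow("CG", "N", "CA", "CB", 1.516, 112.6, 1),
             zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, 2),
             zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 2, offset = 180)),
  GLU = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
             zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 2),
             zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, 3),
             zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 3, offset = 180)),
  GLN = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
             zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 2),
             zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, 3),
             zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 3, offset = 180)),
  HIS = list(zrow("CG", "N", "CA", "CB", 1.497, 113.8, 1),
             zrow("ND1", "CA", "CB", "CG", 1.371, 122.7, 2),
             zrow("CD2", "CA", "CB", "CG", 1.356, 131.1, 2, offset = 180),
             zrow("CE1", "CB", "CG", "ND1", 1.319, 109.0, fixed = 180),
             zrow("NE2", "CB", "CG", "CD2", 1.374, 107.0, fixed = 180)),
  PHE = list(zrow("CG", "N", "CA", "CB", 1.502, 113.8, 1),
             zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, 2),
             zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, 2, offset = 180),
             zrow("CE1", "CB", "CG", "CD1", 1.382, 120.8, fixed = 180),
             zrow("CE2", "CB", "CG", "CD2", 1.382, 120.8, fixed = 180),
             zrow("CZ", "CG", "CD1", "CE1", 1.382, 120.0, fixed = 0)),
  TYR = list(zrow("CG", "N", "CA", "CB", 1.502, 113.8, 1),
             zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, 2),
             zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, 2, offset = 180),
             zrow("CE1", "CB", "CG", "CD1", 1.382, 120.8, fixed = 180),
             zrow("CE2", "CB", "CG", "CD2", 1.382, 120.8, fixed = 180),
             zrow("CZ", "CG", "CD1", "CE1", 1.382, 120.0, fixed = 0),
             zrow("OH", "CD1", "CE1", "CZ", 1.376, 119.9, fixed = 180)),
  TRP = list(zrow("CG", "N", "CA", "CB", 1.498, 113.6, 1),
             zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, 2),
             zrow("CD2", "CA", "CB", "CG", 1.433, 126.7, 2, offset = 180),
             zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, fixed = 180),
             zrow("CE2", "CB", "CG", "CD2", 1.409, 107.2, fixed = 180),
             zrow("CE3", "CB", "CG", "CD2", 1.398, 133.9, fixed = 0),
             zrow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, fixed = 180),
             zrow("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, fixed = 180),
             zrow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, fixed = 0)),
  PRO = list(zrow("CG", "N", "CA", "CB", 1.495, 104.5, 1),
             zrow("CD", "CA", "CB", "CG", 1.507, 106.1, 2))
)

# number of chi variables per residue type
N_CHI <- vapply(SIDECHAIN_TEMPLATES, function(tmpl) {
  ch <- vapply(tmpl, function(z) if (is.na(z$chi)) 0L else as.integer(z$chi), 1L)
  if (length(ch)) max(ch) else 0L
}, 1L)

# candidate chi values: staggered sp3 grid, sp2 terminal and ring sets
sp3_set <- c(-60, 60, 180)
sp2_terminal_set <- c(-90, 0, 90)
ring_set <- c(-90, 90)
chi_sets <- function(aa) {
  n <- N_CHI[[aa]]
  if (n == 0L) return(list())
  sets <- rep(list(sp3_set), n)
  if (aa %in% c("ASP", "ASN")) sets[[2]] <- sp2_terminal_set
  if (aa %in% c("GLU", "GLN")) sets[[3]] <- sp2_terminal_set
  if (aa %in% c("PHE", "TYR", "TRP", "HIS")) sets[[2]] <- ring_set
  if (aa == "PRO") return(NULL)  # explicit ring-compatible pairs below
  sets
}

#' Build a rotamer library
#'
#' A deterministic staggered chi grid (-60/60/180 per sp3 chi; -90/0/90 for
#' terminal sp2 chis; +-90 for aromatic ring chis; two ring-pucker pairs for
#' proline). With `ex = TRUE`, chi1 and chi2 are expanded with +-30 degree
#' half-steps around each base value, analogous to extra-rotamer flags in
#' repacking protocols.
#'
#' @param ex include half-step expansions on chi1/chi2 (default `FALSE`).
#' @return named list (one per amino acid) of matrices, one rotamer per row,
#'   chi angles in degrees in (-180, 180]; class `rotamer_library`.
#' @export
rotamer_library <- function(ex = FALSE) {
  fold <- function(x) ifelse(x <= -180, x + 360, ifelse(x > 180, x - 360, x))
  lib <- lapply(AA3, function(aa) {
    if (aa == "PRO") {
      m <- rbind(c(-25, 38), c(25, -35))
      colnames(m) <- c("chi1", "chi2")
      return(m)
    }
    sets <- chi_sets(aa)
    if (length(sets) == 0L) return(matrix(numeric(0), nrow = 1, ncol = 0))
    if (ex) {
      for (k in seq_len(min(2L, length(sets))))
        sets[[k]] <- sort(fold(unique(c(sets[[k]], sets[[k]] - 30,
                                        sets[[k]] + 30))))
    }
    g <- do.call(expand.grid, sets)
    m <- as.matrix(g)
    colnames(m) <- paste0("chi", seq_along(sets))
    m
  })
  names(lib) <- AA3
  structure(lib, class = "rotamer_library", ex = ex)
}

# Backbone CB placement (also used when mutating from GLY).
ideal_cb <- function(n, ca, c) place_atom(c, n, ca, 1.530, 110.4, -122.6)

# Cartesian side-chain coordinates for residue type `aa` at chi angles
# `chis`, given backbone N/CA/C(/CB). Returns a named list of 3-vectors for
# all side-chain atoms beyond CB (CB included only if `cb` is NULL).
build_sidechain <- function(aa, chis, n, ca, c, cb = NULL) {
  out <- list()
  if (aa == "GLY") return(out)
  if (is.null(cb)) {
    cb <- ideal_cb(n, ca, c)
    out$CB <- cb
  }
  pos <- list(N = n, CA = ca, C = c, CB = cb)
  for (z in SIDECHAIN_TEMPLATES[[aa]]) {
    dih <- if (!is.na(z$fixed)) z$fixed else chis[z$chi] + z$offset
    p <- place_atom(pos[[z$a]], pos[[z$b]], pos[[z$c]], z$dist, z$ang, dih)
    pos[[z$name]] <- p
    out[[z$name]] <- p
  }
  out
}

# Atom names of a full side chain (beyond CA) for a residue type.
sidechain_atom_names <- function(aa) {
  if (aa == "GLY") return(character(0))
  c("CB", vapply(SIDECHAIN_TEMPLATES[[aa]], function(z) z$name, ""))
}
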