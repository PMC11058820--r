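# Heavy-atom hydrogen-bond capability tables. With no hydrogens in crystal
# inputs, donors/acceptors are identified by residue + atom name, and the
# donor geometry is checked through the donor's antecedent heavy atom.
HB_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG")
HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")
# antecedent heavy atom bonded to each donor (for the angle criterion)
HB_ANTECEDENT <- c(N = "CA", NE = "CD", NH1 = "CZ", NH2 = "CZ", ND2 = "CG",
                   NE2 = "CD", ND1 = "CG", NZ = "CE", OG = "CB", OG1 = "CB",
                   NE1 = "CD1", OH = "CZ", SG = "CB")
# HIS NE2 antecedent is CD2 (ring), GLN NE2 antecedent CD; resolved per residue
antecedent_name <- function(resid, elety) {
  if (resid == "HIS" && elety == "NE2") return("CD2")
  if (resid == "HIS" && elety == "ND1") return("CG")
  unname(HB_ANTECEDENT[elety])
}

SB_POSITIVE <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                    HIS = c("NE2", "ND1"))
SB_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Contact detection criteria
#'
#' @param vdw_cutoff heavy-atom distance for van der Waals contacts (A).
#' @param hbond_da_cutoff donor-acceptor distance cutoff (A).
#' @param hbond_angle_min minimum antecedent-donor-acceptor angle (degrees).
#' @param saltbridge_cutoff distance between charged-group heavy atoms (A).
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(vdw_cutoff = 4.0, hbond_da_cutoff = 3.5,
                             hbond_angle_min = 120, saltbridge_cutoff = 4.0) {
  stopifnot(vdw_cutoff > 0, hbond_da_cutoff > 0, saltbridge_cutoff > 0)
  structure(list(vdw_cutoff = vdw_cutoff, hbond_da_cutoff = hbond_da_cutoff,
                 hbond_angle_min = hbond_angle_min,
                 saltbridge_cutoff = saltbridge_cutoff),
            class = "contact_criteria")
}

is_donor <- function(resid, elety) {
  elety %in% HB_DONORS$backbone && resid != "PRO" ||
    elety %in% (HB_DONORS[[resid]] %||% character(0))
}
is_acceptor <- function(resid, elety) {
  elety %in% HB_ACCEPTORS$backbone ||
    elety %in% (HB_ACCEPTORS[[resid]] %||% character(0))
}

#' Map interface contacts between the TCR and pMHC (and peptide vs MHC)
#'
#' Detects van der Waals contacts (any heavy-atom pair across the boundary
#' within `vdw_cutoff`), hydrogen bonds (donor-capable N/O/S vs acceptor
#' O/N/S within `hbond_da_cutoff`, antecedent-donor-acceptor angle at least
#' `hbond_angle_min`) and salt bridges (Lys/Arg/His basic nitrogens vs
#' Asp/Glu carboxylates or the C-terminal carboxylate within
#' `saltbridge_cutoff`). Output is deduplicated and deterministically
#' ordered.
#'
#' @param partition a `complex_partition`.
#' @param criteria a [contact_criteria()] object.
#' @param boundary `"tcr_pmhc"` (default) or `"peptide_mhc"`.
#' @return data.frame with columns `chain_a`, `resno_a`, `resid_a`,
#'   `atom_a`, `chain_b`, `resno_b`, `resid_b`, `atom_b`, `type`, `distance`.
#' @export
find_contacts <- function(partition, criteria = contact_criteria(),
                          boundary = c("tcr_pmhc", "peptide_mhc")) {
  boundary <- match.arg(boundary)
  m <- partition$model
  if (boundary == "tcr_pmhc") {
    sa <- tcr_sel(partition); sb <- pmhc_sel(partition)
  } else {
    sa <- role_sel(partition, "peptide")
    sb <- role_sel(partition, c("mhc_heavy", "b2m"))
  }
  A <- m$atoms[sa, , drop = FALSE]
  B <- m$atoms[sb, , drop = FALSE]
  maxcut <- max(criteria$vdw_cutoff, criteria$hbond_da_cutoff,
                criteria$saltbridge_cutoff)
  XA <- as.matrix(A[, c("x", "y", "z")]); XB <- as.matrix(B[, c("x", "y", "z")])
  D2 <- outer(rowSums(XA^2), rowSums(XB^2), "+") - 2 * XA %*% t(XB)
  idx <- which(D2 < maxcut^2, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(empty_contacts())
  rows <- list()
  cterm_ox <- function(atoms, i) {
    # C-terminal carboxylate oxygens: OXT, plus O of the residue bearing OXT
    r <- atoms[i, ]
    r$elety == "OXT"
  }
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    d <- sqrt(max(0, D2[i, j]))
    ra <- A[i, ]; rb <- B[j, ]
    if (d <= criteria$vdw_cutoff)
      rows[[length(rows) + 1L]] <- contact_row(ra, rb, "vdw", d)
    # hydrogen bond, either direction
    if (d <= criteria$hbond_da_cutoff) {
      if (hb_geometry_ok(m, ra, rb, criteria$hbond_angle_min) ||
          hb_geometry_ok(m, rb, ra, criteria$hbond_angle_min))
        rows[[length(rows) + 1L]] <- contact_row(ra, rb, "hbond", d)
    }
    if (d <= criteria$saltbridge_cutoff) {
      pos_a <- ra$elety %in% (SB_POSITIVE[[ra$resid]] %||% character(0))
      neg_a <- ra$elety %in% (SB_NEGATIVE[[ra$resid]] %||% character(0)) ||
        cterm_ox(A, i)
      pos_b <- rb$elety %in% (SB_POSITIVE[[rb$resid]] %||% character(0))
      neg_b <- rb$elety %in% (SB_NEGATIVE[[rb$resid]] %||% character(0)) ||
        cterm_ox(B, j)
      if ((pos_a && neg_b) || (neg_a && pos_b))
        rows[[length(rows) + 1L]] <- contact_row(ra, rb, "saltbridge", d)
    }
  }
  if (length(rows) == 0L) return(empty_contacts())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("chain_a", "resno_a", "atom_a", "chain_b",
                                 "resno_b", "atom_b", "type")]), , drop = FALSE]
  out <- out[order(out$chain_a, out$resno_a, out$atom_a, out$chain_b,
                   out$resno_b, out$atom_b, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_contacts <- function() {
  data.frame(chain_a = character(0), resno_a = integer(0),
             resid_a = character(0), atom_a = character(0),
             chain_b = character(0), resno_b = integer(0),
             resid_b = character(0), atom_b = character(0),
             type = character(0), distance = numeric(0),
             stringsAsFactors = FALSE)
}

contact_row <- function(ra, rb, type, d) {
  data.frame(chain_a = ra$chain, resno_a = ra$resno, resid_a = ra$resid,
             atom_a = ra$elety, chain_b = rb$chain, resno_b = rb$resno,
             resid_b = rb$resid, atom_b = rb$elety, type = type,
             distance = d, stringsAsFactors = FALSE)
}

# donor `rd` -> acceptor `racc`: capability plus antecedent angle
hb_geometry_ok <- function(model, rd, racc, angle_min) {
  if (!is_donor(rd$resid, rd$elety)) return(FALSE)
  if (!is_acceptor(racc$resid, racc$elety)) return(FALSE)
  ante <- antecedent_name(rd$resid, rd$elety)
  if (is.na(ante) || is.null(ante)) return(FALSE)
  a <- model$atoms
  ai <- which(a$chain == rd$chain & a$resno == rd$resno &
                a$insert == rd$insert & a$elety == ante)
  if (length(ai) != 1L) return(FALSE)
  v1 <- as.numeric(a[ai, c("x", "y", "z")])
  vd <- as.numeric(rd[c("x", "y", "z")])
  va <- as.numeric(racc[c("x", "y", "z")])
  vec_angle(v1 - vd, va - vd) >= angle_min
}

#' Select design positions near the peptide
#'
#' TCR residues with any heavy atom within `cutoff` of any peptide heavy
#' atom (or of any pMHC heavy atom with `reference = "pmhc"`), optionally
#' intersected with a residue restriction such as CDR ranges; ordered
#' deterministically by (chain, residue number).
#'
#' @param partition a `complex_partition`.
#' @param cutoff distance cutoff in Angstrom (default 8).
#' @param restrict_to optional data.frame with columns `chain`, `resno`.
#' @param reference `"peptide"` (default) or `"pmhc"`.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `role`, `min_dist`.
#' @export
select_design_positions <- function(partition, cutoff = 8.0,
                                    restrict_to = NULL,
                                    reference = c("peptide", "pmhc")) {
  if (cutoff <= 0) stop("cutoff must be positive")
  reference <- match.arg(reference)
  m <- partition$model
  st <- tcr_sel(partition)
  sref <- if (reference == "peptide") role_sel(partition, "peptide")
          else pmhc_sel(partition)
  A <- m$atoms[st, , drop = FALSE]
  XB <- coords(m, sref)
  XA <- as.matrix(A[, c("x", "y", "z")])
  D2 <- outer(rowSums(XA^2), rowSums(XB^2), "+") - 2 * XA %*% t(XB)
  mind <- sqrt(pmax(0, apply(D2, 1, min)))
  A$mind <- mind
  hit <- A[A$mind <= cutoff, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      role = character(0), min_dist = numeric(0)))
  agg <- stats::aggregate(mind ~ chain + resno + insert + resid, data = hit,
                          FUN = min)
  role_of <- function(ch)
    names(partition$roles)[vapply(partition$roles, function(x) ch %in% x, TRUE)][1]
  agg$role <- vapply(agg$chain, role_of, "")
  if (!is.null(restrict_to)) {
    keymask <- paste(agg$chain, agg$resno) %in%
      paste(restrict_to$chain, restrict_to$resno)
    agg <- agg[keymask, , drop = FALSE]
  }
  agg <- agg[order(agg$chain, agg$resno, agg$insert), , drop = FALSE]
  out <- data.frame(chain = agg$chain, resno = agg$resno, insert = agg$insert,
                    resid = agg$resid, role = agg$role, min_dist = agg$mind,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
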