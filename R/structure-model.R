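#' @importFrom stats median setNames rnorm runif sd
#' @importFrom utils read.csv read.delim write.csv head tail
NULL

# Three-letter <-> one-letter amino-acid codes (20 standard residues).
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- setNames(AA3, AA1)

#' Amino-acid code conversion
#'
#' @param x character vector of three-letter (`aa321`) or one-letter (`aa123`)
#'   residue codes.
#' @return character vector of converted codes; unknown codes become `NA`.
#' @export
aa321 <- function(x) unname(AA1[toupper(x)])

#' @rdname aa321
#' @export
aa123 <- function(x) unname(AA3_FROM_1[toupper(x)])

# Van der Waals radii (Angstrom), Chothia-style united-heavy-atom values.
# Element defaults with an override for carbonyl/carboxylate carbons; the
# radius set is a package constant because SASA and clash criteria depend
# on it.
VDW_ELEMENT <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, H = 1.00)
VDW_DEFAULT <- 1.80

#' Assign van der Waals radii from the bundled element/name table
#'
#' Carbonyl and carboxylate carbons (atom names `C`, `CG` of Asp/Asn, `CD` of
#' Glu/Gln, Arg `CZ`) take 1.76 A; other carbons 1.87 A; N 1.65, O 1.40,
#' S 1.85 A.
#'
#' @param elety atom-name vector.
#' @param elem element-symbol vector.
#' @param resid three-letter residue codes.
#' @return numeric vector of radii (A).
#' @export
vdw_radius <- function(elety, elem, resid) {
  r <- unname(VDW_ELEMENT[toupper(elem)])
  r[is.na(r)] <- VDW_DEFAULT
  sp2c <- toupper(elem) == "C" &
    (elety == "C" |
       (resid %in% c("ASP", "ASN") & elety == "CG") |
       (resid %in% c("GLU", "GLN") & elety == "CD") |
       (resid == "ARG" & elety == "CZ"))
  r[sp2c] <- 1.76
  r
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  e <- substr(e, 1, 1)
  toupper(e)
}

#' Construct a structure model
#'
#' The core coordinate container: an atom table (one row per heavy atom) plus
#' metadata, in the style of a `bio3d` atom data frame. Waters and hydrogens
#' are normally absent; all downstream analyses are heavy-atom based.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `elem`, `alt`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`. A `radius`
#'   column is added from [vdw_radius()] if missing.
#' @param title optional description.
#' @param id optional deposition/identifier string.
#' @param model model number (default 1).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "", id = "", model = 1L) {
  required <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(required, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0L) stop("structure model must contain at least one atom")
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(n)
  if (is.null(atoms$elem)) atoms$elem <- guess_element(atoms$elety)
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  if (is.null(atoms$radius))
    atoms$radius <- vdw_radius(atoms$elety, atoms$elem, atoms$resid)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (any(atoms$radius <= 0)) stop("non-positive van der Waals radius")
  if (any(atoms$o < 0 | atoms$o > 1)) stop("occupancy outside [0, 1]")
  atoms <- atoms[, c("eleno", "elety", "elem", "alt", "resid", "chain",
                     "resno", "insert", "x", "y", "z", "o", "b", "radius")]
  rownames(atoms) <- NULL
  # contiguous internal residue index, in file order
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  atoms$ridx <- match(key, unique(key))
  dup <- duplicated(paste(key, atoms$elety))
  if (any(dup))
    stop("duplicate atom name within a residue: ",
         paste(unique(paste(key[dup], atoms$elety[dup])), collapse = "; "))
  obj <- list(atoms = atoms,
              metadata = list(title = title, id = id, model = as.integer(model)))
  class(obj) <- "structure_model"
  obj
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain)
  cat("structure_model:", nrow(a), "atoms,", length(ch), "chains (",
      paste(ch, collapse = ", "), ")\n")
  for (c0 in ch) {
    cat(sprintf("  chain %s: %d residues\n", c0,
                length(unique(a$ridx[a$chain == c0]))))
  }
  invisible(x)
}

#' @export
as.data.frame.structure_model <- function(x, ...) x$atoms

#' Atomic coordinates of a model or selection
#'
#' @param model a `structure_model`.
#' @param sel optional logical/integer row selection on the atom table.
#' @return n x 3 numeric matrix (A).
#' @export
coords <- function(model, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

set_coords <- function(model, xyz, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(model$atoms))
  model$atoms[sel, c("x", "y", "z")] <- xyz
  model
}

# Per-residue summary table: one row per (chain, resno, insert) with resid
# and internal index.
residue_table <- function(model) {
  a <- model$atoms
  first <- !duplicated(a$ridx)
  data.frame(ridx = a$ridx[first], chain = a$chain[first],
             resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first], stringsAsFactors = FALSE)
}

# Rows of the atom table belonging to a set of chains.
chain_sel <- function(model, chains) model$atoms$chain %in% chains

# Intrachain disulfides: pairs of CYS SG atoms within `cutoff` A.
find_disulfides <- function(model, chain, cutoff = 2.5) {
  a <- model$atoms
  sg <- which(a$chain == chain & a$resid == "CYS" & a$elety == "SG")
  out <- list()
  if (length(sg) < 2) return(out)
  for (i in seq_along(sg)) {
    for (j in seq_along(sg)) {
      if (j <= i) next
      d <- vnorm(as.numeric(a[sg[i], c("x", "y", "z")]) -
                 as.numeric(a[sg[j], c("x", "y", "z")]))
      if (d <= cutoff)
        out[[length(out) + 1L]] <- list(sg = c(sg[i], sg[j]), dist = d,
                                        resno = c(a$resno[sg[i]], a$resno[sg[j]]))
    }
  }
  out
}

#' Apply a rigid transform to a structure model
#'
#' @param model a `structure_model`.
#' @param R 3x3 rotation matrix.
#' @param t translation 3-vector (A).
#' @return transformed model.
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(model) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  set_coords(model, xyz)
}
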