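#' Read a macromolecular structure
#'
#' Parses PDB or mmCIF coordinates into a [structure_model()]. Waters are
#' excluded by default, hydrogens always (all downstream analyses are
#' heavy-atom based). Where a side chain carries alternate locations, the
#' highest-occupancy conformer is retained (ties: first in file), yielding a
#' deterministic single-conformer model for scoring.
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param keep_waters retain water molecules (default `FALSE`).
#' @param keep_hetero retain non-water HETATM records (default `FALSE`).
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           keep_waters = FALSE, keep_hetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$elesy[is.na(a$elesy) | a$elesy == ""] <- guess_element(a$elety[is.na(a$elesy) | a$elesy == ""])
  keep <- rep(TRUE, nrow(a))
  if (!keep_waters) keep <- keep & !(a$resid %in% c("HOH", "WAT", "DOD"))
  if (!keep_hetero) keep <- keep & (a$type == "ATOM" | a$resid %in% AA3)
  keep <- keep & toupper(a$elesy) != "H" & toupper(a$elesy) != "D"
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("no protein atoms found in ", path)
  unknown <- !(toupper(a$elesy) %in% c(names(VDW_ELEMENT), "SE", "P"))
  if (any(unknown))
    stop("unknown element for atom(s): ",
         paste(unique(paste0(a$elesy[unknown], " (", a$resid[unknown], " ",
                             a$resno[unknown], " ", a$elety[unknown], ")")),
               collapse = ", "))
  # alt-loc resolution: per (chain, resno, insert, elety) keep the
  # highest-occupancy record; ties broken by file order.
  a$o[is.na(a$o)] <- 1
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(factor(key, levels = unique(key)), -a$o,
               seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "|")), ,
         drop = FALSE]
  # restore file order
  a <- a[order(a$eleno), , drop = FALSE]
  atoms <- data.frame(eleno = a$eleno, elety = a$elety,
                      elem = toupper(a$elesy), alt = a$alt, resid = a$resid,
                      chain = a$chain, resno = a$resno, insert = a$insert,
                      x = a$x, y = a$y, z = a$z, o = a$o,
                      b = ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
  structure_model(atoms, title = basename(path), id = basename(path))
}

#' Write a structure model
#'
#' PDB output uses fixed-width 8.3 coordinate fields (millie-Angstrom
#' precision); mmCIF output keeps full double precision, so
#' `read_structure(write_structure(m, f, "cif"), "cif")` reproduces
#' coordinates bit-exactly.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @param format `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (format == "pdb") {
    if (any(abs(a[, c("x", "y", "z")]) >= 10000))
      stop("coordinates exceed PDB fixed-width fields; write mmCIF instead")
    bio3d::write.pdb(file = path, xyz = as.numeric(t(coords(model))),
                     resno = a$resno, resid = a$resid, eleno = a$eleno,
                     elety = a$elety, chain = a$chain, insert = a$insert,
                     o = a$o, b = a$b, elesy = a$elem)
  } else {
    # canonical RCSB atom_site column order (required by common readers)
    num <- function(v) vapply(v, function(x) format(x, digits = 17L), "")
    lines <- c(
      "data_tcrm",
      paste0("_entry.id ", if (nzchar(model$metadata$id)) model$metadata$id else "model"),
      "loop_",
      "_atom_site.group_PDB",
      "_atom_site.id",
      "_atom_site.type_symbol",
      "_atom_site.label_atom_id",
      "_atom_site.label_alt_id",
      "_atom_site.label_comp_id",
      "_atom_site.label_asym_id",
      "_atom_site.label_entity_id",
      "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x",
      "_atom_site.Cartn_y",
      "_atom_site.Cartn_z",
      "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv",
      "_atom_site.pdbx_formal_charge",
      "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id",
      "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id",
      "_atom_site.pdbx_PDB_model_num",
      paste("ATOM", a$eleno, a$elem, a$elety,
            ifelse(nzchar(a$alt), a$alt, "."), a$resid, a$chain,
            "1", a$resno,
            ifelse(nzchar(a$insert), a$insert, "?"),
            num(a$x), num(a$y), num(a$z), num(a$o), num(a$b), "?",
            a$resno, a$resid, a$chain, a$elety,
            model$metadata$model))
    writeLines(lines, path)
  }
  invisible(path)
}
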