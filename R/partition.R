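ROLE_NAMES <- c("mhc_heavy", "b2m", "peptide", "tcr_alpha", "tcr_beta")

#' Partition a model into the five roles of a TCR-pMHC complex
#'
#' Assigns chains to TCR alpha, TCR beta, MHC heavy, beta-2-microglobulin and
#' peptide, either from an explicit `chain_map` or automatically. Auto mode
#' uses simple size/topology heuristics: the peptide is the shortest chain of
#' 8-11 residues; chains containing an intrachain CYS-CYS disulfide (SG
#' atoms within 2.5 A) are TCR candidates (alpha before beta in chain-id
#' order); of the remaining chains, the longer is the MHC heavy chain and the
#' shorter beta-2-microglobulin. A model holding several copies of the
#' complex yields one partition per complete copy, labelled deterministically
#' by chain-id order.
#'
#' Each TCR chain must contain a variable-domain disulfide or construction
#' fails; when a chain has both variable- and constant-domain disulfides the
#' one earliest in sequence (the variable domain) is recorded.
#'
#' @param model a `structure_model`.
#' @param chain_map named character vector mapping chain ids to roles, e.g.
#'   `c(A = "mhc_heavy", B = "b2m", C = "peptide", D = "tcr_alpha",
#'   E = "tcr_beta")`, or `"auto"`.
#' @return list of `complex_partition` objects.
#' @export
partition_complex <- function(model, chain_map = "auto") {
  rt <- residue_table(model)
  sizes <- table(rt$chain)
  if (identical(chain_map, "auto")) {
    groups <- auto_assign(model, rt, sizes)
  } else {
    if (is.null(names(chain_map))) stop("chain_map must be named by chain id")
    bad <- setdiff(names(chain_map), names(sizes))
    if (length(bad)) stop("chain_map names chains absent from model: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(chain_map, ROLE_NAMES)
    if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
    g <- lapply(ROLE_NAMES, function(r) names(chain_map)[chain_map == r])
    names(g) <- ROLE_NAMES
    miss <- ROLE_NAMES[vapply(g, length, 1L) == 0L]
    if (length(miss)) stop("missing role(s) in chain_map: ",
                           paste(miss, collapse = ", "))
    groups <- list(g)
  }
  out <- lapply(seq_along(groups), function(i) {
    new_partition(model, groups[[i]], copy_label = paste0("copy", i))
  })
  out
}

auto_assign <- function(model, rt, sizes) {
  chains <- names(sizes)
  pep <- chains[sizes >= 8 & sizes <= 11]
  if (length(pep) == 0L)
    stop("peptide role unresolved: no chain of 8-11 residues found")
  ss_chains <- chains[vapply(chains, function(ch)
    length(find_disulfides(model, ch)) >= 1L, TRUE)]
  tcr <- setdiff(ss_chains, pep)
  rest <- setdiff(chains, c(pep, tcr))
  n_copies <- length(pep)
  if (length(tcr) != 2L * n_copies)
    stop("ambiguous auto assignment: expected ", 2L * n_copies,
         " disulfide-bearing TCR chains for ", n_copies,
         " peptide(s); candidates: ", paste(tcr, collapse = ", "))
  if (length(rest) != 2L * n_copies)
    stop("ambiguous auto assignment: expected ", 2L * n_copies,
         " MHC/b2m chains; candidates: ", paste(rest, collapse = ", "))
  # group chains into copies by proximity to each peptide's centroid
  cent <- function(ch) colMeans(coords(model, chain_sel(model, ch)))
  pep <- sort(pep)
  assign_near <- function(cands, pep_id, k) {
    d <- vapply(cands, function(ch) vnorm(cent(ch) - cent(pep_id)), 1)
    cands[order(d)][seq_len(k)]
  }
  used_tcr <- character(0); used_rest <- character(0)
  lapply(pep, function(p) {
    tc <- assign_near(setdiff(tcr, used_tcr), p, 2L)
    rc <- assign_near(setdiff(rest, used_rest), p, 2L)
    used_tcr <<- c(used_tcr, tc); used_rest <<- c(used_rest, rc)
    tc <- sort(tc); rc <- rc[order(-sizes[rc])]
    list(mhc_heavy = rc[1], b2m = rc[2], peptide = p,
         tcr_alpha = tc[1], tcr_beta = tc[2])
  })
}

new_partition <- function(model, roles, copy_label = "copy1") {
  all_sel <- unlist(roles, use.names = FALSE)
  if (anyDuplicated(all_sel))
    stop("role selections are not disjoint: chain(s) ",
         paste(all_sel[duplicated(all_sel)], collapse = ", "))
  np <- length(unique(model$atoms$ridx[chain_sel(model, roles$peptide)]))
  if (np < 8 || np > 11)
    stop("peptide chain has ", np, " residues; expected 8-11")
  ss <- lapply(c(alpha = roles$tcr_alpha, beta = roles$tcr_beta),
               function(ch) {
    d <- find_disulfides(model, ch)
    if (length(d) == 0L)
      stop("no intrachain variable-domain disulfide found in TCR chain ", ch)
    # variable domain comes first in sequence: take the disulfide whose
    # first cysteine is earliest
    d[[order(vapply(d, function(x) min(x$resno), 1))[1]]]
  })
  obj <- list(model = model, roles = roles, copy_label = copy_label,
              v_disulfides = ss)
  class(obj) <- "complex_partition"
  obj
}

#' @export
print.complex_partition <- function(x, ...) {
  cat("complex_partition (", x$copy_label, "):\n", sep = "")
  for (r in ROLE_NAMES)
    cat(sprintf("  %-10s chain %s\n", r, paste(x$roles[[r]], collapse = ",")))
  invisible(x)
}

# Atom-table row selections for the two binding partners and single roles.
role_sel <- function(partition, role) {
  chain_sel(partition$model, unlist(partition$roles[role], use.names = FALSE))
}

tcr_sel <- function(partition) role_sel(partition, c("tcr_alpha", "tcr_beta"))
pmhc_sel <- function(partition) role_sel(partition, c("mhc_heavy", "b2m", "peptide"))

# Subset a structure model to a row selection, keeping class invariants.
subset_model <- function(model, sel) {
  structure_model(model$atoms[sel, setdiff(names(model$atoms), "ridx"),
                              drop = FALSE],
                  title = model$metadata$title, id = model$metadata$id,
                  model = model$metadata$model)
}

#' JSON-ready partition manifest
#'
#' @param partitions list returned by [partition_complex()].
#' @return list suitable for `jsonlite::toJSON()`.
#' @export
partition_manifest <- function(partitions) {
  lapply(partitions, function(p) {
    list(copy = p$copy_label,
         roles = p$roles,
         v_disulfides = lapply(p$v_disulfides, function(d)
           list(resno = d$resno, sg_distance = d$dist)))
  })
}
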