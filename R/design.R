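ROLE_GREEK <- c(tcr_alpha = "α", tcr_beta = "β")

mutation_label <- function(role, wt_aa, resno, mut_aa) {
  prefix <- ROLE_GREEK[role]
  prefix[is.na(prefix)] <- role[is.na(prefix)]
  paste0(prefix, aa321(wt_aa), resno, aa321(mut_aa))
}

#' Design configuration for mutation scanning and loop refinement
#'
#' @param cutoff_8A design-position selection cutoff (A, default 8).
#' @param exclude amino acids never introduced (default CYS, to avoid
#'   unpaired cysteines).
#' @param repack_shell radius for repacking neighbouring side chains after a
#'   mutation (A; default 0 = only the mutant side chain is repacked, the
#'   backbone is always fixed).
#' @param loop_refine list with `n_cycles`, `kT`, `torsion_step` (degrees)
#'   and `seed` for CCD/Monte Carlo loop refinement.
#' @return list of class `design_config`.
#' @export
design_config <- function(cutoff_8A = 8.0, exclude = "CYS",
                          repack_shell = 0,
                          loop_refine = list(n_cycles = 100, kT = 1.0,
                                             torsion_step = 10, seed = 1L)) {
  stopifnot(cutoff_8A > 0, repack_shell >= 0)
  structure(list(cutoff_8A = cutoff_8A, exclude = exclude,
                 repack_shell = repack_shell, loop_refine = loop_refine),
            class = "design_config")
}

#' Enumerate point substitutions at design positions
#'
#' Every position is paired with the 20 standard amino acids minus the
#' excluded set (default cysteine), *including* the wild-type identity, so
#' 52 positions give 52 x 19 = 988 candidates.
#'
#' @param positions data.frame from [select_design_positions()] (columns
#'   `chain`, `resno`, `insert`, `resid`, `role`).
#' @param exclude amino acids to omit (three-letter codes, default `"CYS"`).
#' @return data.frame of candidates with columns `chain`, `role`, `resno`,
#'   `insert`, `wt_aa`, `mut_aa`, `label`, in deterministic order.
#' @export
enumerate_substitutions <- function(positions, exclude = "CYS") {
  if (nrow(positions) == 0L) stop("no design positions supplied")
  bad <- !(positions$resid %in% AA3)
  if (any(bad))
    stop("non-standard residue at position(s): ",
         paste(positions$chain[bad], positions$resno[bad], collapse = ", "))
  muts <- setdiff(AA3, exclude)
  out <- do.call(rbind, lapply(seq_len(nrow(positions)), function(i) {
    p <- positions[i, ]
    data.frame(chain = p$chain, role = p$role, resno = p$resno,
               insert = p$insert, wt_aa = p$resid, mut_aa = muts,
               stringsAsFactors = FALSE)
  }))
  out$label <- mutation_label(out$role, out$wt_aa, out$resno, out$mut_aa)
  rownames(out) <- NULL
  out
}

# Energy-model parameters for newly built side-chain atoms.
params_for_new <- function(resid, elety, em) {
  elem <- guess_element(elety)
  cls <- ifelse(elem %in% em$lj$class, elem, "X")
  il <- match(cls, em$lj$class); is <- match(cls, em$solv$class)
  q <- numeric(length(elety))
  for (k in seq_len(nrow(em$charges))) {
    row <- em$charges[k, ]
    if (row$resid %in% c("*", resid)) q[elety == row$elety] <- row$charge
  }
  list(rmin2 = em$lj$rmin2[il], eps = em$lj$epsilon[il],
       dg = em$solv$dgfree[is], lambda = em$solv$lambda[is],
       vol = em$solv$volume[is], q = q,
       donor = vapply(elety, function(e) is_donor(resid, e), TRUE),
       acceptor = vapply(elety, function(e) is_acceptor(resid, e), TRUE),
       rvdw = vdw_radius(elety, elem, rep(resid, length(elety))))
}

# Interaction energy (weighted total) of a set of placed atoms against all
# model atoms outside residue `ridx_excl`.
env_interaction <- function(model, em, ap_env, env_rows, xyz_new, p_new) {
  if (length(env_rows) == 0L || nrow(xyz_new) == 0L) return(0)
  XE <- coords(model, env_rows)
  D2 <- outer(rowSums(xyz_new^2), rowSums(XE^2), "+") - 2 * xyz_new %*% t(XE)
  hit <- which(D2 < em$cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(0)
  r <- sqrt(pmax(0, D2[hit]))
  take_new <- lapply(p_new, function(v) v[hit[, 1]])
  take_env <- lapply(ap_env, function(v) v[env_rows[hit[, 2]]])
  terms <- pair_terms(r, take_new, take_env, em)
  s <- switch_fn(r, em$switch_on, em$cutoff)
  sum(vapply(names(terms), function(t)
    em$weights[[t]] * sum(terms[[t]] * s), 1))
}

backbone_names <- c("N", "CA", "C", "O", "OXT")

# locate residue rows; check backbone completeness
residue_rows <- function(model, chain, resno, insert = "") {
  rows <- which(model$atoms$chain == chain & model$atoms$resno == resno &
                  model$atoms$insert == insert)
  if (length(rows) == 0L)
    stop("residue ", chain, ":", resno, " not found")
  present <- model$atoms$elety[rows]
  if (!all(c("N", "CA", "C", "O") %in% present))
    stop("residue ", chain, ":", resno, " lacks backbone atoms (need N/CA/C/O)")
  rows
}

#' Place a point mutation with fixed-backbone rotamer repacking
#'
#' Rebuilds the side chain beyond C-beta from idealized internal coordinates
#' for every rotamer of the target amino acid and keeps the rotamer with the
#' lowest interaction energy against the rest of the structure (ties: lowest
#' rotamer index). The backbone, the existing C-beta (rebuilt only when the
#' wild type is glycine) and every other residue are untouched.
#'
#' @param model a `structure_model`.
#' @param chain,resno,insert position of the residue to mutate.
#' @param mut_aa target amino acid (three-letter code).
#' @param rotlib a [rotamer_library()].
#' @param em an [energy_model()].
#' @param score_total also compute the full pose energy of the mutated model
#'   (default `TRUE`).
#' @return list with `model` (mutated), `rotamer` (best index), `chis`,
#'   `sc_energy` (side-chain/environment interaction, kcal/mol) and
#'   `energy` (full pose `energy_breakdown`, or `NULL`).
#' @export
place_mutation <- function(model, chain, resno, mut_aa, insert = "",
                           rotlib = rotamer_library(), em = energy_model(),
                           score_total = TRUE) {
  if (!mut_aa %in% AA3) stop("unknown amino acid: ", mut_aa)
  rows <- residue_rows(model, chain, resno, insert)
  a <- model$atoms
  ridx0 <- a$ridx[rows[1]]
  get_xyz <- function(name) {
    i <- rows[a$elety[rows] == name]
    if (length(i) != 1L) return(NULL)
    as.numeric(a[i, c("x", "y", "z")])
  }
  n <- get_xyz("N"); ca <- get_xyz("CA"); cc <- get_xyz("C")
  cb <- get_xyz("CB")
  env_rows <- which(a$ridx != ridx0)
  ap_env <- atom_params(model, em)

  best <- list(idx = NA_integer_, e = Inf, atoms = NULL)
  if (mut_aa == "GLY") {
    best <- list(idx = 1L, e = 0, atoms = list())
  } else {
    rot <- rotlib[[mut_aa]]
    if (nrow(rot) == 0L && !(mut_aa %in% c("ALA", "GLY")))
      stop("empty rotamer list for ", mut_aa)
    keep_cb <- !is.null(cb)
    for (k in seq_len(max(1L, nrow(rot)))) {
      chis <- if (ncol(rot) > 0) rot[k, ] else numeric(0)
      sc <- build_sidechain(mut_aa, chis, n, ca, cc,
                            cb = if (keep_cb) cb else NULL)
      nm <- names(sc)
      beyond <- setdiff(nm, "CB")
      if (length(beyond) == 0L) {
        e <- 0
      } else {
        xyz_new <- do.call(rbind, sc[beyond])
        p_new <- params_for_new(mut_aa, beyond, em)
        e <- env_interaction(model, em, ap_env, env_rows, xyz_new, p_new)
      }
      if (e < best$e - 1e-12) best <- list(idx = k, e = e, atoms = sc,
                                           chis = chis)
    }
  }
  # assemble the mutated residue: backbone rows kept verbatim
  keep_names <- backbone_names
  if (mut_aa != "GLY" && !is.null(cb)) keep_names <- c(keep_names, "CB")
  keep_rows <- rows[a$elety[rows] %in% keep_names]
  new_names <- names(best$atoms) %||% character(0)
  new_atoms <- if (length(new_names)) {
    xyz <- do.call(rbind, best$atoms)
    data.frame(eleno = 0L, elety = new_names, elem = guess_element(new_names),
               alt = "", resid = mut_aa, chain = chain, resno = resno,
               insert = insert, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               o = 1, b = 0,
               radius = vdw_radius(new_names, guess_element(new_names),
                                   rep(mut_aa, length(new_names))),
               stringsAsFactors = FALSE)
  } else NULL
  pre <- a[seq_len(nrow(a)) < rows[1] & !(seq_len(nrow(a)) %in% rows), ,
           drop = FALSE]
  post <- a[seq_len(nrow(a)) > max(rows), , drop = FALSE]
  res <- a[keep_rows, , drop = FALSE]
  res$resid <- mut_aa
  res <- res[, setdiff(names(res), "ridx"), drop = FALSE]
  pre <- pre[, setdiff(names(pre), "ridx"), drop = FALSE]
  post <- post[, setdiff(names(post), "ridx"), drop = FALSE]
  newa <- rbind(pre, res, new_atoms, post)
  newa$eleno <- seq_len(nrow(newa))
  out_model <- structure_model(newa, title = model$metadata$title,
                               id = model$metadata$id,
                               model = model$metadata$model)
  list(model = out_model, rotamer = best$idx,
       chis = best$chis %||% numeric(0), sc_energy = best$e,
       energy = if (score_total) score_pose(out_model, em) else NULL)
}

scan_fingerprint <- function(em, config, rotlib, seed) {
  paste0("tcrm-scan|", em$version, "|w=",
         paste(names(em$weights), em$weights, sep = ":", collapse = ","),
         "|eps0=", em$eps0, "|cut=", em$cutoff, "|ex=",
         isTRUE(attr(rotlib, "ex")), "|shell=", config$repack_shell,
         "|seed=", seed)
}

#' Scan point mutations and rank by change in binding score
#'
#' For each candidate: the mutant side chain is placed with
#' [place_mutation()] (backbone fixed), the binding score of the mutated
#' complex is computed, and `delta_binding` is the mutant minus wild-type
#' binding total. The ranking is ascending in `delta_binding` (most
#' stabilizing first), ties broken by (chain, residue, mutant) lexicographic
#' order. Identical inputs and seed give identical results.
#'
#' @param partition a `complex_partition`.
#' @param candidates data.frame from [enumerate_substitutions()].
#' @param rotlib a [rotamer_library()].
#' @param em an [energy_model()].
#' @param config a [design_config()].
#' @param seed integer recorded in the result fingerprint (the scan itself
#'   is deterministic).
#' @return list of class `scan_result`: `rows` (per-candidate table),
#'   `ranking` (rows sorted), `wild_type_binding` (a `binding_score`),
#'   `fingerprint`.
#' @export
scan_mutations <- function(partition, candidates, rotlib = rotamer_library(),
                           em = energy_model(), config = design_config(),
                           seed = 1L) {
  wt <- binding_score(partition, em)
  wt_cross <- cross_binding(partition, em)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    res <- tryCatch({
      pm <- place_mutation(partition$model, cand$chain, cand$resno,
                           cand$mut_aa, insert = cand$insert,
                           rotlib = rotlib, em = em, score_total = FALSE)
      mdl <- pm$model
      if (config$repack_shell > 0)
        mdl <- repack_neighbors(mdl, cand, config$repack_shell, rotlib, em)
      p2 <- partition
      p2$model <- mdl
      b <- cross_binding(p2, em)
      data.frame(label = cand$label, chain = cand$chain, role = cand$role,
                 resno = cand$resno, wt_aa = cand$wt_aa,
                 mut_aa = cand$mut_aa, rotamer = pm$rotamer,
                 lj_attr = b$lj_attr, lj_rep = b$lj_rep,
                 coulomb = b$coulomb, solvation = b$solvation,
                 hbond = b$hbond, binding_total = b$total,
                 delta_binding = b$total - wt_cross$total,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(label = cand$label, chain = cand$chain, role = cand$role,
                 resno = cand$resno, wt_aa = cand$wt_aa,
                 mut_aa = cand$mut_aa, rotamer = NA_integer_,
                 lj_attr = NA_real_, lj_rep = NA_real_, coulomb = NA_real_,
                 solvation = NA_real_, hbond = NA_real_,
                 binding_total = NA_real_, delta_binding = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  ord <- order(rows$delta_binding, rows$chain, rows$resno, rows$mut_aa,
               na.last = TRUE)
  out <- list(rows = rows, ranking = rows[ord, , drop = FALSE],
              wild_type_binding = wt,
              fingerprint = scan_fingerprint(em, config, rotlib, seed))
  class(out) <- "scan_result"
  out
}

#' @export
print.scan_result <- function(x, n = 10, ...) {
  cat("scan_result:", nrow(x$rows), "candidates; top", n, "by delta binding:\n")
  print(head(x$ranking[, c("label", "delta_binding", "rotamer")], n))
  invisible(x)
}

# greedy one-pass repack of neighbour side chains within `shell` A of the
# mutated residue (optional; off by default)
repack_neighbors <- function(model, cand, shell, rotlib, em) {
  a <- model$atoms
  mrows <- which(a$chain == cand$chain & a$resno == cand$resno &
                   a$insert == cand$insert)
  X <- coords(model, mrows)
  rt <- residue_table(model)
  for (i in seq_len(nrow(rt))) {
    if (rt$chain[i] == cand$chain && rt$resno[i] == cand$resno) next
    if (!(rt$resid[i] %in% AA3) || rt$resid[i] %in% c("GLY", "ALA", "PRO"))
      next
    rrows <- which(a$ridx == rt$ridx[i])
    Y <- coords(model, rrows)
    dmin <- sqrt(min(outer(rowSums(Y^2), rowSums(X^2), "+") -
                       2 * Y %*% t(X)))
    if (is.finite(dmin) && dmin <= shell) {
      pm <- place_mutation(model, rt$chain[i], rt$resno[i], rt$resid[i],
                           insert = rt$insert[i], rotlib = rotlib, em = em,
                           score_total = FALSE)
      model <- pm$model
      a <- model$atoms
    }
  }
  model
}

#' Combine single mutations into multi-mutants
#'
#' Places each pair (or larger combination) of single mutations on the same
#' fixed backbone. Far-apart mutations are placed sequentially (order cannot
#' matter); if the two mutant side chains fall within interaction range of
#' each other, an exhaustive joint rotamer-pair search replaces the
#' sequential placement. Results are scored and ranked exactly as in
#' [scan_mutations()].
#'
#' @param partition a `complex_partition`.
#' @param singles data.frame of candidates (rows of
#'   [enumerate_substitutions()] output) at pairwise distinct positions.
#' @param rotlib,em,config,seed as in [scan_mutations()].
#' @return a `scan_result` over the pairwise combinations.
#' @export
combine_mutations <- function(partition, singles,
                              rotlib = rotamer_library(),
                              em = energy_model(), config = design_config(),
                              seed = 1L) {
  if (nrow(singles) < 2L) stop("need at least two single mutations")
  key <- paste(singles$chain, singles$resno, singles$insert)
  if (anyDuplicated(key))
    stop("overlapping positions: combinations require distinct residues")
  wt_cross <- cross_binding(partition, em)
  wt <- binding_score(partition, em)
  combos <- utils::combn(nrow(singles), 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    c1 <- singles[combos[1, k], ]; c2 <- singles[combos[2, k], ]
    pm <- place_pair(partition$model, c1, c2, rotlib, em)
    p2 <- partition
    p2$model <- pm$model
    b <- cross_binding(p2, em)
    lab2 <- mutation_label(c2$role, c2$wt_aa, c2$resno, c2$mut_aa)
    if (identical(c1$role, c2$role))
      lab2 <- sub("^.", "", lab2)
    data.frame(label = paste0(c1$label, "-", lab2),
               chain = c1$chain, role = c1$role, resno = c1$resno,
               wt_aa = c1$wt_aa, mut_aa = paste(c1$mut_aa, c2$mut_aa,
                                                sep = "+"),
               rotamer = pm$rotamer1,
               lj_attr = b$lj_attr, lj_rep = b$lj_rep, coulomb = b$coulomb,
               solvation = b$solvation, hbond = b$hbond,
               binding_total = b$total,
               delta_binding = b$total - wt_cross$total,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  ord <- order(rows$delta_binding, rows$chain, rows$resno, rows$mut_aa,
               na.last = TRUE)
  out <- list(rows = rows, ranking = rows[ord, , drop = FALSE],
              wild_type_binding = wt,
              fingerprint = scan_fingerprint(em, config, rotlib, seed))
  class(out) <- "scan_result"
  out
}

place_pair <- function(model, c1, c2, rotlib, em) {
  pm1 <- place_mutation(model, c1$chain, c1$resno, c1$mut_aa,
                        insert = c1$insert, rotlib = rotlib, em = em,
                        score_total = FALSE)
  pm2 <- place_mutation(pm1$model, c2$chain, c2$resno, c2$mut_aa,
                        insert = c2$insert, rotlib = rotlib, em = em,
                        score_total = FALSE)
  m <- pm2$model
  # if the two placed side chains interact, redo as joint exhaustive search
  a <- m$atoms
  sc_rows <- function(ch, rn, ins) {
    r <- which(a$chain == ch & a$resno == rn & a$insert == ins)
    r[!(a$elety[r] %in% backbone_names)]
  }
  r1 <- sc_rows(c1$chain, c1$resno, c1$insert)
  r2 <- sc_rows(c2$chain, c2$resno, c2$insert)
  interacting <- FALSE
  if (length(r1) && length(r2)) {
    X <- coords(m, r1); Y <- coords(m, r2)
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
    interacting <- min(d2) < em$cutoff^2
  }
  if (!interacting)
    return(list(model = m, rotamer1 = pm1$rotamer, rotamer2 = pm2$rotamer))
  joint_rotamer_search(model, c1, c2, rotlib, em)
}

# exhaustive rotamer-pair search for two interacting mutation sites
joint_rotamer_search <- function(model, c1, c2, rotlib, em) {
  a <- model$atoms
  site <- function(cand) {
    rows <- residue_rows(model, cand$chain, cand$resno, cand$insert)
    get <- function(nm) {
      i <- rows[a$elety[rows] == nm]
      if (length(i) != 1L) NULL else as.numeric(a[i, c("x", "y", "z")])
    }
    ridx0 <- a$ridx[rows[1]]
    list(rows = rows, ridx = ridx0, n = get("N"), ca = get("CA"),
         c = get("C"), cb = get("CB"))
  }
  s1 <- site(c1); s2 <- site(c2)
  env_rows <- which(!(a$ridx %in% c(s1$ridx, s2$ridx)))
  ap_env <- atom_params(model, em)
  enumerate_site <- function(s, aa) {
    rot <- rotlib[[aa]]
    nr <- max(1L, nrow(rot))
    lapply(seq_len(nr), function(k) {
      chis <- if (!is.null(rot) && ncol(rot) > 0) rot[k, ] else numeric(0)
      sc <- build_sidechain(aa, chis, s$n, s$ca, s$c, cb = s$cb)
      beyond <- setdiff(names(sc), "CB")
      xyz <- if (length(beyond)) do.call(rbind, sc[beyond]) else
        matrix(0, 0, 3)
      p <- params_for_new(aa, beyond, em)
      e <- env_interaction(model, em, ap_env, env_rows, xyz, p)
      list(k = k, sc = sc, xyz = xyz, p = p, e = e)
    })
  }
  cands1 <- enumerate_site(s1, c1$mut_aa)
  cands2 <- enumerate_site(s2, c2$mut_aa)
  pair_e <- function(x1, x2) {
    if (nrow(x1$xyz) == 0L || nrow(x2$xyz) == 0L) return(0)
    D2 <- outer(rowSums(x1$xyz^2), rowSums(x2$xyz^2), "+") -
      2 * x1$xyz %*% t(x2$xyz)
    hit <- which(D2 < em$cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(0)
    r <- sqrt(pmax(0, D2[hit]))
    t1 <- lapply(x1$p, function(v) v[hit[, 1]])
    t2 <- lapply(x2$p, function(v) v[hit[, 2]])
    terms <- pair_terms(r, t1, t2, em)
    s <- switch_fn(r, em$switch_on, em$cutoff)
    sum(vapply(names(terms), function(t)
      em$weights[[t]] * sum(terms[[t]] * s), 1))
  }
  best <- NULL; best_e <- Inf
  for (x1 in cands1) for (x2 in cands2) {
    e <- x1$e + x2$e + pair_e(x1, x2)
    if (e < best_e - 1e-12) { best_e <- e; best <- list(x1 = x1, x2 = x2) }
  }
  pm1 <- rebuild_with(model, c1, best$x1)
  pm2 <- rebuild_with(pm1, c2, best$x2)
  list(model = pm2, rotamer1 = best$x1$k, rotamer2 = best$x2$k)
}

# replace residue side chain with explicit prebuilt atoms
rebuild_with <- function(model, cand, placed) {
  a <- model$atoms
  rows <- residue_rows(model, cand$chain, cand$resno, cand$insert)
  keep_names <- backbone_names
  if (cand$mut_aa != "GLY" && "CB" %in% a$elety[rows])
    keep_names <- c(keep_names, "CB")
  keep_rows <- rows[a$elety[rows] %in% keep_names]
  nm <- setdiff(names(placed$sc), if ("CB" %in% keep_names) "CB" else character(0))
  new_atoms <- if (length(nm)) {
    xyz <- do.call(rbind, placed$sc[nm])
    data.frame(eleno = 0L, elety = nm, elem = guess_element(nm), alt = "",
               resid = cand$mut_aa, chain = cand$chain, resno = cand$resno,
               insert = cand$insert, x = xyz[, 1], y = xyz[, 2],
               z = xyz[, 3], o = 1, b = 0,
               radius = vdw_radius(nm, guess_element(nm),
                                   rep(cand$mut_aa, length(nm))),
               stringsAsFactors = FALSE)
  } else NULL
  pre <- a[seq_len(nrow(a)) < rows[1] & !(seq_len(nrow(a)) %in% rows), ,
           drop = FALSE]
  post <- a[seq_len(nrow(a)) > max(rows), , drop = FALSE]
  res <- a[keep_rows, , drop = FALSE]
  res$resid <- cand$mut_aa
  strip <- function(d) d[, setdiff(names(d), "ridx"), drop = FALSE]
  newa <- rbind(strip(pre), strip(res), new_atoms, strip(post))
  newa$eleno <- seq_len(nrow(newa))
  structure_model(newa, title = model$metadata$title,
                  id = model$metadata$id, model = model$metadata$model)
}
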