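# Seeded generators for ground-truth fixtures: a five-chain TCR-pMHC
# stand-in with prescribed docking geometry, and a planted-clash benchmark
# case for the mutation scanner. Stand-in domains are geometric
# idealizations (ideal helices, extended strands), not homology models: the
# tests need known ground truth, not biological realism.

# Ideal backbone builder (NeRF): returns per-residue list of N/CA/C/O.
build_backbone <- function(n_res, phi, psi, omega = 180) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  res <- vector("list", n_res)
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  cc <- place_atom(c(-1, 1, 0), n, ca, 1.525, 111.2, -60)  # arbitrary start
  for (i in seq_len(n_res)) {
    if (i > 1) {
      nn <- place_atom(res[[i - 1]]$N, res[[i - 1]]$CA, res[[i - 1]]$C,
                       1.329, 116.2, psi[i - 1])
      ca2 <- place_atom(res[[i - 1]]$CA, res[[i - 1]]$C, nn, 1.458, 121.7,
                        omega)
      cc2 <- place_atom(res[[i - 1]]$C, nn, ca2, 1.525, 111.2, phi[i])
      n <- nn; ca <- ca2; cc <- cc2
    }
    res[[i]] <- list(N = n, CA = ca, C = cc)
  }
  for (i in seq_len(n_res)) {
    ref_psi <- if (i < n_res) psi[i] else psi[i]
    res[[i]]$O <- place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                             1.231, 120.8, ref_psi + 180)
  }
  res
}

# atom table for a chain built from backbone + default side chains
chain_atoms <- function(seq3, phi, psi, chain_id, resno_start = 1L,
                        resnos = NULL) {
  n_res <- length(seq3)
  bb <- build_backbone(n_res, phi, psi)
  if (is.null(resnos)) resnos <- seq(resno_start, length.out = n_res)
  rows <- list()
  for (i in seq_len(n_res)) {
    aa <- seq3[i]
    at <- bb[[i]]
    if (aa != "GLY") {
      nchi <- N_CHI[[aa]]
      chis <- rep(180, max(0, nchi))
      if (aa == "PRO") chis <- c(-25, 38)
      sc <- build_sidechain(aa, chis, at$N, at$CA, at$C, cb = NULL)
      at <- c(at, sc)
    }
    nm <- names(at)
    xyz <- do.call(rbind, at)
    rows[[i]] <- data.frame(elety = nm, resid = aa, chain = chain_id,
                            resno = resnos[i], x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# principal axis of the CA trace, oriented N-term -> C-term
ca_axis <- function(df) {
  ca <- df[df$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), ]
  X <- as.matrix(ca[, c("x", "y", "z")])
  v <- svd(sweep(X, 2, colMeans(X)))$v[, 1]
  if (sum(v * (X[nrow(X), ] - X[1, ])) < 0) v <- -v
  unit(v)
}

rotate_df <- function(df, R) {
  X <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- X[, 1]; df$y <- X[, 2]; df$z <- X[, 3]
  df
}

translate_df <- function(df, t) {
  df$x <- df$x + t[1]; df$y <- df$y + t[2]; df$z <- df$z + t[3]
  df
}

# rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- pracma_cross(a, b)
  c0 <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c0 > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) unit(pracma_cross(a, c(1, 0, 0))) else
      unit(pracma_cross(a, c(0, 1, 0)))
    return(rotation_about(p, pi))
  }
  rotation_about(unit(v), acos(max(-1, min(1, c0))))
}

# align chain axis to `dir`, then place its centroid at `at`; with
# `roll_flat = TRUE` the backbone zig-zag plane is rolled horizontal so the
# side chains point along +-z (used for the peptide in the groove)
place_chain <- function(df, dir, at, roll_flat = FALSE) {
  R <- rotation_between(ca_axis(df), dir)
  df <- rotate_df(df, R)
  if (roll_flat) {
    bb <- df[df$elety %in% c("N", "CA", "C"), , drop = FALSE]
    X <- as.matrix(bb[, c("x", "y", "z")])
    n <- svd(sweep(X, 2, colMeans(X)))$v[, 3]
    n <- n - sum(n * dir) * dir
    if (vnorm(n) > 1e-9) {
      n <- unit(n)
      zp <- unit(c(0, 0, 1) - sum(c(0, 0, 1) * dir) * dir)
      angle <- atan2(sum(pracma_cross(n, zp) * dir), sum(n * zp))
      df <- rotate_df(df, rotation_about(dir, angle))
    }
  }
  ctr <- colMeans(as.matrix(df[df$elety == "CA", c("x", "y", "z")]))
  translate_df(df, at - ctr)
}

#' Specification for a synthetic TCR-pMHC complex
#'
#' @param crossing_angle_target desired crossing angle (degrees, (0, 180)).
#' @param incident_angle_target desired TCR tilt out of the groove plane
#'   (degrees, [0, 45]).
#' @param peptide_length peptide residues (default 9).
#' @param interface_gap vertical clearance between the TCR domain tips and
#'   the peptide plane (A, default 6.5).
#' @param seed integer seed (coordinate jitter and global pose).
#' @return list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(crossing_angle_target = 62,
                             incident_angle_target = 8,
                             peptide_length = 9, interface_gap = 6.5,
                             seed = 1L) {
  stopifnot(crossing_angle_target > 0, crossing_angle_target < 180,
            incident_angle_target >= 0, incident_angle_target <= 45,
            peptide_length >= 5)
  structure(list(crossing_angle_target = crossing_angle_target,
                 incident_angle_target = incident_angle_target,
                 peptide_length = peptide_length,
                 interface_gap = interface_gap, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# build one TCR variable-domain stand-in: a two-strand hairpin with a
# CYS-CYS disulfide mid-height; returns atom rows (local placement done by
# the caller through the returned reference points)
tcr_domain_atoms <- function(chain_id, center_xy, tip_z, sep_dir) {
  # strands: residues 1-7 descending, 8-14 ascending; CYS at 4 and 11
  seq1 <- rep("ALA", 7); seq1[4] <- "CYS"
  seq2 <- rep("ALA", 7); seq2[4] <- "CYS"
  s <- 11.5  # strand separation so the inward CYS C-betas sit ~5.6 A apart
  mk <- function(seqs, dirz, resno_start, offset_sign) {
    df <- chain_atoms(seqs, -140, 140, chain_id, resno_start)
    R <- rotation_between(ca_axis(df), c(0, 0, dirz))
    df <- rotate_df(df, R)
    # roll: CYS CB horizontal direction -> toward the other strand
    cys_rn <- resno_start + 3L
    cb <- as.numeric(df[df$resno == cys_rn & df$elety == "CB",
                        c("x", "y", "z")])
    ca <- as.numeric(df[df$resno == cys_rn & df$elety == "CA",
                        c("x", "y", "z")])
    v <- cb - ca; v[3] <- 0
    want <- -offset_sign * sep_dir
    if (vnorm(v) > 1e-6) {
      axis <- c(0, 0, 1)
      angle <- atan2(sum(pracma_cross(unit(v), want) * axis),
                     sum(unit(v) * want))
      df <- rotate_df(df, rotation_about(axis, angle))
    }
    # put the tip CA (lowest residue) at the prescribed point
    tip_rn <- if (dirz < 0) resno_start + 6L else resno_start
    tip <- as.numeric(df[df$resno == tip_rn & df$elety == "CA",
                         c("x", "y", "z")])
    target <- c(center_xy + offset_sign * (s / 2) * sep_dir[1:2], tip_z)
    translate_df(df, target - tip)
  }
  d1 <- mk(seq1, -1, 1L, -1)
  d2 <- mk(seq2, +1, 8L, +1)
  df <- rbind(d1, d2)
  # explicit disulfide: SG along the CB-CB axis, 2.03 A apart
  cb1 <- as.numeric(df[df$resno == 4 & df$elety == "CB", c("x", "y", "z")])
  cb2 <- as.numeric(df[df$resno == 11 & df$elety == "CB", c("x", "y", "z")])
  w <- unit(cb2 - cb1)
  mid <- (cb1 + cb2) / 2
  df[df$resno == 4 & df$elety == "SG", c("x", "y", "z")] <-
    as.list(mid - 1.015 * w)
  df[df$resno == 11 & df$elety == "SG", c("x", "y", "z")] <-
    as.list(mid + 1.015 * w)
  df
}

#' Build a synthetic five-chain TCR-pMHC complex with known geometry
#'
#' Chains: A = MHC platform stand-in (two ideal antiparallel alpha-helices,
#' phi/psi -57/-47, numbered 50-85 and 138-175 to match the default groove
#' helix windows), B = beta-2-microglobulin stand-in (a short helix below
#' the platform), C = extended peptide in the groove (default sequence
#' VVGAVGVGK), D/E = TCR alpha/beta variable-domain stand-ins, each a
#' two-strand hairpin carrying one CYS-CYS disulfide. The vector connecting
#' the two disulfide SG midpoints is constructed to make exactly the target
#' crossing and incident angles with the peptide axis and platform plane.
#' Coordinates receive a small seeded jitter (0.02 A) and a random global
#' rigid motion, so different seeds give different coordinates but identical
#' recovered geometry.
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `model` (a `structure_model`), `truth` (list:
#'   `crossing_angle`, `incident_angle`, `chain_map`, `interface_residues`,
#'   `atom_counts`, `seed`).
#' @export
build_toy_complex <- function(spec = toy_complex_spec()) {
  theta <- deg2rad(spec$crossing_angle_target)
  iota <- deg2rad(spec$incident_angle_target)
  d_hat <- c(cos(iota) * cos(theta), cos(iota) * sin(theta), sin(iota))
  d_h <- c(cos(theta), sin(theta), 0)
  if (vnorm(d_h) < 1e-9) stop("geometrically infeasible spec: vertical TCR axis")
  perp <- unit(pracma_cross(c(0, 0, 1), d_h))
  L <- 14

  pep_seq3 <- aa123(strsplit("VVGAVGVGK", "")[[1]])
  if (spec$peptide_length != 9)
    pep_seq3 <- rep_len(c("VAL", "ALA", "GLY"), spec$peptide_length)
  pep <- chain_atoms(pep_seq3, -140, 140, "C")
  pep <- place_chain(pep, c(1, 0, 0), c(0, 0, 0), roll_flat = TRUE)

  h1 <- chain_atoms(rep("ALA", 36), -57, -47, "A", resnos = 50:85)
  h1 <- place_chain(h1, c(1, 0, 0), c(0, -11.0, -3.0))
  h2 <- chain_atoms(rep("ALA", 38), -57, -47, "A", resnos = 138:175)
  h2 <- place_chain(h2, c(-1, 0, 0), c(0, 11.0, -3.0))
  b2m <- chain_atoms(rep("ALA", 25), -57, -47, "B")
  b2m <- place_chain(b2m, c(1, 0, 0), c(0, 0, -13))

  tip_z <- spec$interface_gap
  h0 <- tip_z + 10.2
  dA <- tcr_domain_atoms("D", c(0, 0) - (L / 2) * d_h[1:2], tip_z, perp)
  dB <- tcr_domain_atoms("E", c(0, 0) + (L / 2) * d_h[1:2], tip_z, perp)
  # lift both domains so the alpha disulfide midpoint sits at height h0,
  # then shift the beta domain so the SG-midpoint vector is exactly L*d_hat
  sg_mid <- function(df) {
    sg <- as.matrix(df[df$elety == "SG", c("x", "y", "z")])
    colMeans(sg)
  }
  dA <- translate_df(dA, c(0, 0, h0 - sg_mid(dA)[3]))
  m1 <- sg_mid(dA)
  dB <- translate_df(dB, m1 + L * d_hat - sg_mid(dB))

  atoms <- rbind(h1, h2, b2m, pep, dA, dB)
  atoms$eleno <- seq_len(nrow(atoms))

  jr <- with_seed(spec$seed, {
    jit <- matrix(rnorm(3L * nrow(atoms), 0, 0.02), ncol = 3)
    M <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(M)
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    list(jit = jit, R = R, t = runif(3, -20, 20))
  })
  X <- as.matrix(atoms[, c("x", "y", "z")]) + jr$jit
  X <- sweep(X %*% t(jr$R), 2, jr$t, "+")
  atoms$x <- X[, 1]; atoms$y <- X[, 2]; atoms$z <- X[, 3]

  model <- structure_model(atoms, title = "synthetic TCR-pMHC toy complex",
                           id = sprintf("TOY-%d", spec$seed))
  chain_map <- c(A = "mhc_heavy", B = "b2m", C = "peptide",
                 D = "tcr_alpha", E = "tcr_beta")
  part <- partition_complex(model, chain_map)[[1]]
  interface <- select_design_positions(part, 8.0)
  counts <- table(model$atoms$chain)
  # sanity: no accidental severe clash between chains
  if (min_interchain_dist(model) < 2.0)
    stop("geometrically infeasible spec: inter-chain clash in generated complex")
  truth <- list(crossing_angle = spec$crossing_angle_target,
                incident_angle = spec$incident_angle_target,
                chain_map = as.list(chain_map),
                interface_residues = interface[, c("chain", "resno", "resid")],
                atom_counts = as.list(counts), seed = spec$seed)
  list(model = model, truth = truth)
}

min_interchain_dist <- function(model) {
  a <- model$atoms
  X <- coords(model)
  D <- as.matrix(stats::dist(X))
  same <- outer(a$chain, a$chain, "==")
  diag(D) <- Inf
  D[same] <- Inf
  min(D)
}

#' Plant a clash benchmark case for the mutation scanner
#'
#' Builds a toy complex and rebuilds one TCR-beta tip residue as an ARG
#' whose C-beta overlaps a peptide heavy atom (distance < 0.8 x the contact
#' distance, i.e. a hard van der Waals clash that every substitution
#' retaining C-beta inherits) with the guanidinium arm directed further into
#' the peptide. The only substitution that removes the clash is glycine, so
#' `expected_best = "GLY"` by construction; the generator verifies the
#' planted repulsion through the scoring function before returning.
#'
#' @param seed integer seed.
#' @param rep_threshold minimum planted cross-interface `lj_rep`
#'   (kcal/mol, default 5).
#' @return list of class `planted_case`: `model`, `partition`,
#'   `clash_position` (list: role, chain, resno), `wt_aa`, `expected_best`,
#'   `lj_rep_wt`, `seed`.
#' @export
plant_clash_case <- function(seed = 1L, rep_threshold = 5) {
  toy <- build_toy_complex(toy_complex_spec(seed = seed))
  model <- toy$model
  a <- model$atoms
  # tip residue of the beta chain nearest the peptide
  pep <- coords(model, a$chain == "C")
  cand_rn <- c(7L, 8L)
  tip_d <- vapply(cand_rn, function(rn) {
    X <- coords(model, a$chain == "E" & a$resno == rn)
    sqrt(max(0, min(outer(rowSums(X^2), rowSums(pep^2), "+") -
                      2 * X %*% t(pep))))
  }, 1)
  rn <- cand_rn[which.min(tip_d)]
  rows <- which(a$chain == "E" & a$resno == rn)
  cb <- as.numeric(a[rows[a$elety[rows] == "CB"], c("x", "y", "z")])
  # peptide target: heavy atom nearest the tip CB
  pep_rows <- which(a$chain == "C")
  dp <- sqrt(rowSums(sweep(coords(model, pep_rows), 2, cb)^2))
  tgt_row <- pep_rows[which.min(dp)]
  tgt <- as.numeric(a[tgt_row, c("x", "y", "z")])
  clash_dist <- 0.75 * (1.87 + a$radius[tgt_row])
  # translate the residue rigidly so CB lands clash_dist above the target
  # (along the current CB->target direction, stopping short)
  shift <- (tgt - clash_dist * unit(tgt - cb)) - cb
  model$atoms[rows, c("x", "y", "z")] <-
    sweep(as.matrix(a[rows, c("x", "y", "z")]), 2, -shift)
  # rebuild as ARG, rotamer chosen geometrically: closest approach to the
  # peptide (maximal planted clash), no scoring involved
  get <- function(nm) {
    i <- rows[model$atoms$elety[rows] == nm]
    as.numeric(model$atoms[i, c("x", "y", "z")])
  }
  rot <- rotamer_library()[["ARG"]]
  best_k <- 1L; best_d <- Inf
  for (k in seq_len(nrow(rot))) {
    sc <- build_sidechain("ARG", rot[k, ], get("N"), get("CA"), get("C"),
                          cb = get("CB"))
    X <- do.call(rbind, sc)
    dmin <- sqrt(max(0, min(outer(rowSums(X^2), rowSums(pep^2), "+") -
                              2 * X %*% t(pep))))
    if (dmin < best_d) { best_d <- dmin; best_k <- k }
  }
  sc <- build_sidechain("ARG", rot[best_k, ], get("N"), get("CA"), get("C"),
                        cb = get("CB"))
  keep <- rows[model$atoms$elety[rows] %in% c(backbone_names, "CB")]
  drop_rows <- setdiff(rows, keep)
  newa <- if (length(drop_rows)) model$atoms[-drop_rows, , drop = FALSE] else
    model$atoms
  newa$resid[newa$chain == "E" & newa$resno == rn] <- "ARG"
  xyz <- do.call(rbind, sc)
  add <- data.frame(eleno = 0L, elety = names(sc),
                    elem = guess_element(names(sc)), alt = "", resid = "ARG",
                    chain = "E", resno = rn, insert = "",
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
                    radius = vdw_radius(names(sc), guess_element(names(sc)),
                                        rep("ARG", length(sc))),
                    stringsAsFactors = FALSE)
  ins_at <- max(which(newa$chain == "E" & newa$resno == rn))
  strip <- function(d) d[, setdiff(names(d), "ridx"), drop = FALSE]
  newa <- rbind(strip(newa[seq_len(ins_at), ]), add,
                strip(newa[seq(ins_at + 1L, nrow(newa)), ]))
  newa$eleno <- seq_len(nrow(newa))
  model <- structure_model(newa, title = "planted-clash toy complex",
                           id = sprintf("CLASH-%d", seed))
  part <- partition_complex(model, unlist(toy$truth$chain_map))[[1]]
  em <- energy_model()
  rep_wt <- cross_binding(part, em)$lj_rep
  if (rep_wt < rep_threshold)
    stop("planted clash below repulsion threshold (", signif(rep_wt, 3),
         " < ", rep_threshold, ")")
  out <- list(model = model, partition = part,
              clash_position = list(role = "tcr_beta", chain = "E",
                                    resno = rn),
              wt_aa = "ARG", expected_best = "GLY",
              lj_rep_wt = rep_wt, seed = as.integer(seed))
  class(out) <- "planted_case"
  out
}
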