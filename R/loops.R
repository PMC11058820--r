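# CDR loop refinement: random phi/psi proposals on loop residues, cyclic
# coordinate descent (CCD) closure of the chain break against the fixed
# C-terminal anchor, and Metropolis acceptance on the total pose energy.

loop_torsions <- function(model, loop) {
  # per loop residue: phi (N->CA axis) and psi (CA->C axis) descriptors with
  # the model rows they move; virtual anchor atoms are handled separately.
  a <- model$atoms
  res_rows <- function(rn) which(a$chain == loop$chain & a$resno == rn &
                                   a$insert == "")
  atom_row <- function(rn, nm) {
    r <- res_rows(rn)
    r[a$elety[r] == nm]
  }
  resnos <- loop$start:loop$end
  tor <- list()
  for (i in seq_along(resnos)) {
    rn <- resnos[i]
    later <- unlist(lapply(resnos[seq_along(resnos) > i], res_rows))
    rows_i <- res_rows(rn)
    phi_moving <- c(setdiff(rows_i, c(atom_row(rn, "N"), atom_row(rn, "CA"))),
                    later)
    psi_moving <- c(atom_row(rn, "O"), later)
    tor[[length(tor) + 1L]] <- list(
      kind = "phi", resno = rn,
      p1 = atom_row(rn, "N"), p2 = atom_row(rn, "CA"), moving = phi_moving)
    tor[[length(tor) + 1L]] <- list(
      kind = "psi", resno = rn,
      p1 = atom_row(rn, "CA"), p2 = atom_row(rn, "C"), moving = psi_moving)
  }
  tor
}

rotate_rows <- function(xyz, virt, rows, origin, axis, theta) {
  R <- rotation_about(axis, theta)
  if (length(rows)) {
    xyz[rows, ] <- sweep(sweep(xyz[rows, , drop = FALSE], 2, origin) %*% t(R),
                         2, origin, "+")
  }
  virt <- sweep(sweep(virt, 2, origin) %*% t(R), 2, origin, "+")
  list(xyz = xyz, virt = virt)
}

# optimal CCD rotation angle about (origin, axis) aligning `virt` to `targets`
ccd_angle <- function(virt, targets, origin, axis) {
  u <- unit(axis)
  num <- 0; den <- 0
  for (k in seq_len(nrow(virt))) {
    m <- virt[k, ] - origin
    f <- targets[k, ] - origin
    axial <- sum(m * u)
    r <- m - axial * u
    rl <- vnorm(r)
    if (rl < 1e-9) next
    fperp <- f - sum(f * u) * u
    den <- den + rl * sum(unit(r) * fperp)
    num <- num + rl * sum(pracma_cross(u, unit(r)) * fperp)
  }
  atan2(num, den)
}

# CCD sweeps on raw coordinates: adjust loop torsions until the virtual
# anchor copies `virt` land on `targets`.
ccd_sweeps <- function(xyz, virt, targets, tor, tol = 0.1, max_pass = 100L) {
  closure <- function(v) sqrt(mean(rowSums((v - targets)^2)))
  pass <- 0L
  while (closure(virt) > tol && pass < max_pass) {
    pass <- pass + 1L
    for (t in tor) {
      origin <- xyz[t$p1, ]
      axis <- xyz[t$p2, ] - xyz[t$p1, ]
      theta <- ccd_angle(virt, targets, origin, axis)
      if (abs(theta) < 1e-12) next
      rot <- rotate_rows(xyz, virt, t$moving, origin, axis, theta)
      xyz <- rot$xyz; virt <- rot$virt
    }
  }
  list(xyz = xyz, virt = virt, closure = closure(virt),
       converged = closure(virt) <= tol, passes = pass)
}

#' Close a loop onto anchor targets by cyclic coordinate descent
#'
#' Iteratively adjusts the phi/psi torsions of the loop residues so that the
#' moving copies of the C-terminal anchor backbone atoms (N, CA, C of
#' residue `end + 1`) land on `targets`. Used after torsion perturbations to
#' repair the chain break, and directly to re-close an artificially opened
#' loop.
#'
#' @param model a `structure_model`.
#' @param loop list with `chain`, `start`, `end` (author residue numbers).
#' @param targets 3 x 3 matrix of target N/CA/C coordinates for the anchor
#'   residue (default: its current coordinates).
#' @param tol closure RMSD tolerance (A, default 0.1).
#' @param max_pass maximum CCD sweeps (default 100).
#' @return list with `model` (loop atoms moved), `closure` (final anchor
#'   RMSD, A), `converged`, `passes`.
#' @export
ccd_close <- function(model, loop, targets = NULL, tol = 0.1,
                      max_pass = 100L) {
  a <- model$atoms
  anchor_rn <- loop$end + 1L
  arow <- vapply(c("N", "CA", "C"), function(nm)
    which(a$chain == loop$chain & a$resno == anchor_rn & a$elety == nm)[1],
    1L)
  if (anyNA(arow)) stop("C-terminal anchor residue ", anchor_rn,
                        " lacks backbone atoms")
  xyz <- coords(model)
  virt <- xyz[arow, , drop = FALSE]
  if (is.null(targets)) targets <- virt
  tor <- loop_torsions(model, loop)
  res <- ccd_sweeps(xyz, virt, targets, tor, tol, max_pass)
  list(model = set_coords(model, res$xyz), closure = res$closure,
       converged = res$converged, passes = res$passes)
}

#' Refine CDR loop backbones by CCD plus Monte Carlo
#'
#' Each cycle proposes a uniform phi/psi perturbation on a random loop
#' residue, re-closes the chain break by CCD (proposals that cannot be
#' closed to within 0.1 A anchor RMSD are rejected and counted), and applies
#' Metropolis acceptance at temperature `kT` on the total pose energy. All
#' randomness flows through the seed in `config$loop_refine`; the
#' best-energy conformation seen is returned.
#'
#' @param model a `structure_model`.
#' @param loops list of loops, each `list(chain =, start =, end =)` with at
#'   least 3 residues and intact anchor residues on both sides.
#' @param em an [energy_model()].
#' @param config a [design_config()]; uses `config$loop_refine`.
#' @return list with `model` (best-energy conformation), `trajectory`
#'   (data.frame: cycle, loop, resno, kind, closure, energy, accepted,
#'   best_energy), `n_unclosable`, `start_energy`, `best_energy`.
#' @export
refine_cdr_loops <- function(model, loops, em = energy_model(),
                             config = design_config()) {
  cfg <- config$loop_refine
  for (lp in loops) {
    if (lp$end - lp$start + 1L < 3L)
      stop("loop ", lp$chain, ":", lp$start, "-", lp$end,
           " has fewer than 3 residues")
    a <- model$atoms
    for (rn in c(lp$start - 1L, lp$end + 1L))
      if (!any(a$chain == lp$chain & a$resno == rn))
        stop("anchor residue ", lp$chain, ":", rn, " missing")
  }
  e0 <- score_pose(model, em)$total
  cur_model <- model; cur_e <- e0
  best_model <- model; best_e <- e0
  n_unclosable <- 0L
  traj <- list()
  if (cfg$n_cycles > 0) with_seed(cfg$seed, {
    for (cyc in seq_len(cfg$n_cycles)) {
      li <- sample.int(length(loops), 1L)
      lp <- loops[[li]]
      rn <- sample(lp$start:lp$end, 1L)
      kind <- sample(c("phi", "psi"), 1L)
      delta <- runif(1, -cfg$torsion_step, cfg$torsion_step)
      tor <- loop_torsions(cur_model, lp)
      t <- Filter(function(x) x$resno == rn && x$kind == kind, tor)[[1]]
      xyz <- coords(cur_model)
      a <- cur_model$atoms
      arow <- vapply(c("N", "CA", "C"), function(nm)
        which(a$chain == lp$chain & a$resno == lp$end + 1L &
                a$elety == nm)[1], 1L)
      targets <- xyz[arow, , drop = FALSE]
      # the virtual anchor copies ride along with the perturbed chain, then
      # CCD pulls them back onto the fixed anchor
      rot <- rotate_rows(xyz, targets, t$moving, xyz[t$p1, ],
                         xyz[t$p2, ] - xyz[t$p1, ], deg2rad(delta))
      cl <- ccd_sweeps(rot$xyz, rot$virt, targets, tor)
      accepted <- FALSE; e <- NA_real_
      if (!cl$converged) {
        n_unclosable <- n_unclosable + 1L
      } else {
        cl$model <- set_coords(cur_model, cl$xyz)
        e <- score_pose(cl$model, em)$total
        if (e <= cur_e || runif(1) < exp(-(e - cur_e) / cfg$kT)) {
          accepted <- TRUE
          cur_model <- cl$model; cur_e <- e
          if (e < best_e) { best_e <- e; best_model <- cl$model }
        }
      }
      traj[[cyc]] <- data.frame(cycle = cyc, loop = li, resno = rn,
                                kind = kind, closure = cl$closure,
                                energy = e, accepted = accepted,
                                best_energy = best_e)
    }
  })
  list(model = best_model,
       trajectory = if (length(traj)) do.call(rbind, traj) else
         data.frame(cycle = integer(0)),
       n_unclosable = n_unclosable, start_energy = e0, best_energy = best_e)
}
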