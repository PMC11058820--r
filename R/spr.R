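# 1:1 Langmuir SPR kinetics: closed-form simulation and global fitting.

langmuir_response <- function(t, conc, ka, kd, Rmax, t_assoc) {
  keff <- conc * ka + kd
  Req <- conc * ka * Rmax / keff
  R <- ifelse(t <= t_assoc,
              Req * (1 - exp(-keff * t)),
              Req * (1 - exp(-keff * t_assoc)) * exp(-kd * (t - t_assoc)))
  R
}

#' Simulate 1:1 Langmuir sensorgrams
#'
#' Association `R(t) = (C ka Rmax/(C ka + kd)) (1 - exp(-(C ka + kd) t))`,
#' dissociation `R(t) = R(t_assoc) exp(-kd (t - t_assoc))`, plus seeded
#' Gaussian noise. With `noise_sd = 0` the closed form is returned exactly.
#'
#' @param ka association rate (1/(M s)).
#' @param kd dissociation rate (1/s).
#' @param Rmax saturation response (RU).
#' @param conc_series analyte concentrations (M).
#' @param t_assoc association phase length (s).
#' @param t_dissoc dissociation phase length (s).
#' @param dt time step (s).
#' @param noise_sd Gaussian noise standard deviation (RU).
#' @param seed RNG seed for the noise.
#' @return data.frame with columns `time_s`, `response_RU`, `conc_M`,
#'   `phase`; attribute `t_assoc`.
#' @export
simulate_sensorgram <- function(ka, kd, Rmax, conc_series, t_assoc = 60,
                                t_dissoc = 120, dt = 0.5, noise_sd = 0,
                                seed = 1L) {
  if (ka <= 0 || kd <= 0 || Rmax <= 0 || t_assoc <= 0 || t_dissoc <= t_assoc)
    stop("rates, Rmax and phase times must be positive with t_dissoc > t_assoc")
  if (length(conc_series) == 0L || any(conc_series <= 0))
    stop("conc_series must be positive and non-empty")
  t <- seq(0, t_dissoc, by = dt)
  out <- do.call(rbind, lapply(conc_series, function(C) {
    data.frame(time_s = t,
               response_RU = langmuir_response(t, C, ka, kd, Rmax, t_assoc),
               conc_M = C,
               phase = ifelse(t <= t_assoc, "association", "dissociation"),
               stringsAsFactors = FALSE)
  }))
  if (noise_sd > 0)
    out$response_RU <- out$response_RU +
      with_seed(seed, rnorm(nrow(out), 0, noise_sd))
  attr(out, "t_assoc") <- t_assoc
  out
}

#' Global 1:1 kinetic fit of a concentration series
#'
#' Least-squares fit of shared `ka`, `kd` and (by default global) `Rmax`
#' across all curves, in log-parameter space with a multi-start
#' Levenberg-Marquardt search (3 starts spanning +-2 decades around a
#' data-derived guess).
#'
#' @param sensorgrams data.frame as produced by [simulate_sensorgram()] (or
#'   read from CSV with the same columns); attribute or column information
#'   must identify `t_assoc` (taken from the attribute, or the last
#'   association-phase time).
#' @param global_rmax share one Rmax across curves (default `TRUE`);
#'   `FALSE` fits one Rmax per concentration.
#' @return list of class `kinetic_fit`: `ka`, `kd`, `KD` (= kd/ka exactly),
#'   `Rmax`, `residual_sse`, `se` (named standard errors), `converged`,
#'   `n_obs`.
#' @export
fit_1to1 <- function(sensorgrams, global_rmax = TRUE) {
  d <- sensorgrams
  need <- c("time_s", "response_RU", "conc_M")
  if (!all(need %in% names(d))) stop("sensorgram table needs columns: ",
                                     paste(need, collapse = ", "))
  t_assoc <- attr(d, "t_assoc")
  if (is.null(t_assoc)) {
    if (!"phase" %in% names(d)) stop("cannot determine t_assoc")
    t_assoc <- max(d$time_s[d$phase == "association"])
  }
  concs <- sort(unique(d$conc_M))
  if (length(concs) < 2L)
    warning("single-concentration fit is degenerate: ka and Rmax are only ",
            "jointly determined; interpret with care")
  rmax0 <- max(d$response_RU) * 1.5
  # crude kd guess from late-dissociation decay
  kd0 <- 0.01
  ka0 <- kd0 / (median(concs))
  n_rmax <- if (global_rmax) 1L else length(concs)
  make_resid <- function(p) {
    ka <- exp(p[1]); kd <- exp(p[2]); rmax <- exp(p[3:(2 + n_rmax)])
    rm_of <- if (global_rmax) rep(rmax, length(concs)) else rmax
    pred <- numeric(nrow(d))
    for (ci in seq_along(concs)) {
      m <- d$conc_M == concs[ci]
      pred[m] <- langmuir_response(d$time_s[m], concs[ci], ka, kd,
                                   rm_of[ci], t_assoc)
    }
    pred - d$response_RU
  }
  starts <- lapply(c(-2, 0, 2), function(off)
    c(log(ka0) + off * log(10), log(kd0) + off * log(10),
      rep(log(rmax0), n_rmax)))
  best <- NULL
  for (s in starts) {
    f <- tryCatch(minpack.lm::nls.lm(par = s, fn = make_resid,
                                     control = minpack.lm::nls.lm.control(
                                       maxiter = 500)),
                  error = function(e) NULL)
    if (is.null(f)) next
    sse <- sum(f$fvec^2)
    if (is.null(best) || sse < best_sse) { best <- f; best_sse <- sse }
  }
  if (is.null(best)) stop("1:1 fit failed to converge from any start")
  p <- best$par
  ka <- exp(p[1]); kd <- exp(p[2])
  rmax <- exp(p[3:(2 + n_rmax)])
  # delta-method standard errors on the natural scale
  se <- rep(NA_real_, length(p))
  cv <- tryCatch(chol2inv(chol(best$hessian)) * best_sse /
                   max(1, length(best$fvec) - length(p)),
                 error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(0, diag(cv))) * exp(p)
  out <- list(ka = ka, kd = kd, KD = kd / ka, Rmax = rmax,
              residual_sse = best_sse,
              se = c(ka = se[1], kd = se[2], Rmax = se[3]),
              converged = best$info %in% 1:4, n_obs = nrow(d))
  class(out) <- "kinetic_fit"
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic_fit: ka %.4g 1/(M s), kd %.4g 1/s, KD %.4g M (%.3g uM)\n",
              x$ka, x$kd, x$KD, x$KD * 1e6))
  cat(sprintf("  Rmax %s RU, SSE %.4g, converged %s\n",
              paste(signif(x$Rmax, 4), collapse = "/"), x$residual_sse,
              x$converged))
  invisible(x)
}

#' Equilibrium (steady-state) 1:1 fit
#'
#' Least squares of `Req = Rmax C / (C + KD)` over plateau responses.
#'
#' @param plateaus data.frame with columns `conc_M`, `Req` (>= 3 rows).
#' @return list with `KD` (M), `Rmax` (RU), `residual_sse`.
#' @export
fit_equilibrium <- function(plateaus) {
  if (nrow(plateaus) < 3L) stop("need at least 3 concentrations")
  if (sd(plateaus$Req) < 1e-12)
    stop("degenerate equilibrium data: all plateau responses equal")
  resid <- function(p)
    exp(p[2]) * plateaus$conc_M / (plateaus$conc_M + exp(p[1])) -
      plateaus$Req
  s0 <- c(log(median(plateaus$conc_M)), log(max(plateaus$Req) * 1.5))
  best <- NULL
  for (off in c(-2, 0, 2)) {
    f <- tryCatch(minpack.lm::nls.lm(par = s0 + c(off * log(10), 0),
                                     fn = resid),
                  error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2)) best <- f
  }
  if (is.null(best)) stop("equilibrium fit failed")
  list(KD = exp(best$par[1]), Rmax = exp(best$par[2]),
       residual_sse = sum(best$fvec^2))
}

#' Affinity fold change relative to a reference
#'
#' `KD_reference / KD_variant`, to 3 significant figures: > 1 means the
#' variant binds tighter than the reference.
#'
#' @param kd_reference,kd_variant dissociation constants (same units).
#' @return dimensionless fold change.
#' @export
fold_change <- function(kd_reference, kd_variant) {
  if (kd_reference <= 0 || kd_variant <= 0) stop("KD values must be positive")
  signif(kd_reference / kd_variant, 3)
}

#' Build an affinity table with fold changes
#'
#' @param labels variant names; the first row is the reference.
#' @param kd_uM dissociation constants in micromolar.
#' @return data.frame `label`, `KD_uM`, `fold_change` (reference = 1).
#' @export
affinity_table <- function(labels, kd_uM) {
  stopifnot(length(labels) == length(kd_uM))
  data.frame(label = labels, KD_uM = kd_uM,
             fold_change = vapply(kd_uM, function(k)
               fold_change(kd_uM[1], k), 1),
             stringsAsFactors = FALSE)
}

#' Read / write sensorgram CSV
#'
#' Standard columns `time_s`, `response_RU`, `conc_M`, `phase`.
#'
#' @param path CSV file path.
#' @return data.frame with the `t_assoc` attribute restored.
#' @export
read_sensorgrams <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "response_RU", "conc_M", "phase")
  if (!all(need %in% names(d)))
    stop("sensorgram CSV must have columns: ", paste(need, collapse = ", "))
  attr(d, "t_assoc") <- max(d$time_s[d$phase == "association"])
  d
}

#' @rdname read_sensorgrams
#' @param sensorgrams data.frame to write.
#' @export
write_sensorgrams <- function(sensorgrams, path) {
  write.csv(sensorgrams, path, row.names = FALSE)
  invisible(path)
}
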