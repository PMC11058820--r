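# Injection concentration series used in the SPR experiments (micromolar),
# exposed as package constants for convenience.

#' Standard SPR injection concentration series
#'
#' `spr_series_wt` is the wild-type TCR series over the mutant pMHC
#' (0.78-50 uM, two-fold steps); `spr_series_mh` the double-mutant series
#' (0.63-20 uM). Values in molar.
#' @export
spr_series_wt <- c(0.78, 1.56, 3.12, 6.25, 12.5, 25, 50) * 1e-6

#' @rdname spr_series_wt
#' @export
spr_series_mh <- c(0.63, 1.25, 2.5, 5, 10, 20) * 1e-6

#' Generate a synthetic SPR dataset with known ground truth
#'
#' Wraps [simulate_sensorgram()] and optionally writes the standard CSV with
#' a JSON sidecar recording the simulation truth.
#'
#' @param ka,kd,Rmax ground-truth kinetic parameters.
#' @param conc_series analyte concentrations (M).
#' @param noise_sd Gaussian noise (RU).
#' @param seed integer seed.
#' @param path optional CSV output path; the sidecar is written to
#'   `<path>.truth.json`.
#' @param ... further arguments for [simulate_sensorgram()].
#' @return list with `data` (sensorgram data.frame), `truth` (list with ka,
#'   kd, KD, Rmax, noise_sd, seed), `path` (or `NULL`).
#' @export
generate_spr_dataset <- function(ka, kd, Rmax = 100,
                                 conc_series = spr_series_wt,
                                 noise_sd = 1, seed = 1L, path = NULL, ...) {
  data <- simulate_sensorgram(ka, kd, Rmax, conc_series,
                              noise_sd = noise_sd, seed = seed, ...)
  truth <- list(ka = ka, kd = kd, KD = kd / ka, Rmax = Rmax,
                noise_sd = noise_sd, seed = as.integer(seed),
                conc_series = conc_series)
  if (!is.null(path)) {
    write_sensorgrams(data, path)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(data = data, truth = truth, path = path)
}

#' Generate a synthetic ELISA plate with known percent-positive values
#'
#' Sample ODs are synthesized by inverting the percent-positive formula:
#' `OD = neg + (pos - neg) * p / 100` plus replicate noise. Controls are
#' replicated with the same noise.
#'
#' @param true_percentages named numeric vector (percent) per peptide.
#' @param control_ods named numeric: `negative`, `positive` OD405.
#' @param replicate_sd per-well Gaussian OD noise (default 0.02).
#' @param n_replicates wells per peptide and per control (default 4).
#' @param seed integer seed.
#' @param path optional CSV output path (sidecar `<path>.truth.json`).
#' @return list with `plate` (data.frame: well, role, od405), `truth`,
#'   `path`.
#' @export
generate_elisa_plate <- function(true_percentages,
                                 control_ods = c(negative = 0.08,
                                                 positive = 1.10),
                                 replicate_sd = 0.02, n_replicates = 4L,
                                 seed = 1L, path = NULL) {
  if (abs(control_ods[["positive"]] - control_ods[["negative"]]) < 1e-12)
    stop("control ODs must be distinct")
  roles <- c(rep("negative", n_replicates), rep("positive", n_replicates),
             rep(names(true_percentages), each = n_replicates))
  base <- c(rep(control_ods[["negative"]], n_replicates),
            rep(control_ods[["positive"]], n_replicates),
            rep(control_ods[["negative"]] +
                  (control_ods[["positive"]] - control_ods[["negative"]]) *
                  true_percentages / 100, each = n_replicates))
  od <- base
  if (replicate_sd > 0)
    od <- od + with_seed(seed, rnorm(length(base), 0, replicate_sd))
  plate <- data.frame(well = sprintf("W%03d", seq_along(od)), role = roles,
                      od405 = od, stringsAsFactors = FALSE)
  truth <- list(true_percentages = as.list(true_percentages),
                control_ods = as.list(control_ods),
                replicate_sd = replicate_sd,
                n_replicates = as.integer(n_replicates),
                seed = as.integer(seed))
  if (!is.null(path)) {
    write.csv(plate, path, row.names = FALSE)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(plate = plate, truth = truth, path = path)
}
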