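# UV-exchange HLA ELISA quantification: percent-positive signal relative to
# the positive/negative control peptides, and binder classification.

#' Percent-positive ELISA signal
#'
#' `100 * (OD_sample - OD_negative) / (OD_positive - OD_negative)`. Values
#' may exceed 100% or fall below 0% (no clamping). With replicate inputs the
#' per-replicate percentages are averaged and the SEM reported. The result
#' is invariant to adding a constant to all three ODs.
#'
#' @param od_sample sample OD405 value(s) (replicates allowed).
#' @param od_negative negative-control OD (scalar or replicates, averaged).
#' @param od_positive positive-control OD (scalar or replicates, averaged).
#' @return list with `percent` (mean), `sem` (NA for a single replicate),
#'   `n`.
#' @export
percent_positive <- function(od_sample, od_negative, od_positive) {
  neg <- mean(od_negative); pos <- mean(od_positive)
  if (abs(pos - neg) < 1e-12)
    stop("positive and negative control ODs are equal: percent undefined")
  p <- 100 * (od_sample - neg) / (pos - neg)
  list(percent = mean(p),
       sem = if (length(p) > 1) sd(p) / sqrt(length(p)) else NA_real_,
       n = length(p))
}

#' Classify peptide binders from percent-positive signal
#'
#' Deterministic categories by configurable thresholds: `strong` at or above
#' the strong threshold, `intermediate` at or above the intermediate
#' threshold, otherwise `weak`. The defaults (40 / 10 %) reproduce the usual
#' verbal categories for UV-exchange stability data.
#'
#' @param percentages named numeric vector of percent-positive values.
#' @param thresholds named numeric: `strong`, `intermediate`.
#' @return data.frame `peptide`, `percent`, `category`.
#' @export
classify_binders <- function(percentages,
                             thresholds = c(strong = 40, intermediate = 10)) {
  cat_of <- function(p)
    if (p >= thresholds[["strong"]]) "strong"
    else if (p >= thresholds[["intermediate"]]) "intermediate"
    else "weak"
  data.frame(peptide = names(percentages) %||%
               as.character(seq_along(percentages)),
             percent = as.numeric(percentages),
             category = vapply(percentages, cat_of, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an ELISA plate CSV
#'
#' Expected columns: `well`, `role`, `od405`. Roles are `positive`,
#' `negative` or a sample peptide identifier.
#'
#' @param path CSV file path.
#' @return data.frame of class `elisa_plate`.
#' @export
read_elisa_plate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "od405")
  if (!all(need %in% names(d)))
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  if (!any(d$role == "positive") || !any(d$role == "negative"))
    stop("plate must contain positive and negative control wells")
  class(d) <- c("elisa_plate", class(d))
  d
}

#' Quantify an ELISA plate
#'
#' Computes percent-positive (mean and SEM over replicates) for every sample
#' peptide on the plate, then classifies binders.
#'
#' @param plate data.frame from [read_elisa_plate()] (or equivalent).
#' @param thresholds passed to [classify_binders()].
#' @return data.frame `peptide`, `percent`, `sem`, `n`, `category`.
#' @export
quantify_plate <- function(plate,
                           thresholds = c(strong = 40, intermediate = 10)) {
  neg <- plate$od405[plate$role == "negative"]
  pos <- plate$od405[plate$role == "positive"]
  if (!length(neg) || !length(pos))
    stop("plate must contain positive and negative control wells")
  samples <- setdiff(unique(plate$role), c("positive", "negative"))
  rows <- lapply(samples, function(s) {
    pp <- percent_positive(plate$od405[plate$role == s], neg, pos)
    data.frame(peptide = s, percent = pp$percent, sem = pp$sem, n = pp$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cls <- classify_binders(setNames(out$percent, out$peptide), thresholds)
  out$category <- cls$category
  out
}
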