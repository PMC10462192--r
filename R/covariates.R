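#' @importFrom stats cor.test complete.cases setNames
NULL

#' Per-sample mis-splicing burden
#'
#' For each case sample, the burden is the mean over informative events of
#' `|PSI_sample - mean PSI_control|`, i.e. the sample's average absolute
#' deviation from the control-group mean PSI over a chosen event subset
#' (typically the mis-spliced events of a gene set of interest). Events
#' missing in a sample are skipped for that sample; a sample informative
#' for no event gets a missing burden and should be excluded from
#' downstream correlation.
#'
#' @param psi PSI matrix (events x samples) from [computePsi()].
#' @param controlMeanPsi named numeric vector of control mean PSI per
#'   event, or a character vector of control sample names (the mean is
#'   then computed from `psi`).
#' @param eventSubset event ids to average over (non-empty).
#' @param samples sample names to report (default: all columns of `psi`
#'   not used as controls).
#' @return Named numeric vector of burdens.
#' @export
perSampleBurden <- function(psi, controlMeanPsi, eventSubset,
                            samples = NULL) {
  eventSubset <- intersect(eventSubset, rownames(psi))
  if (length(eventSubset) == 0)
    stop("validation error: empty event subset", call. = FALSE)
  if (is.character(controlMeanPsi)) {
    ctrl <- controlMeanPsi
    if (is.null(samples)) samples <- setdiff(colnames(psi), ctrl)
    controlMeanPsi <- rowMeans(psi[eventSubset, ctrl, drop = FALSE],
                               na.rm = TRUE)
  } else {
    controlMeanPsi <- controlMeanPsi[eventSubset]
    if (is.null(samples)) samples <- colnames(psi)
  }
  dev <- abs(psi[eventSubset, samples, drop = FALSE] - controlMeanPsi)
  ok <- !is.na(controlMeanPsi)
  burden <- colMeans(dev[ok, , drop = FALSE], na.rm = TRUE)
  burden[is.nan(burden)] <- NA_real_
  burden
}

#' Developmental mis-splicing burden per time point
#'
#' Mean `|PSI_t - PSI_reference|` over an event subset at each time point,
#' with the reference defaulting to the earliest (first) time point, so
#' the burden tracks how far splicing has moved from the embryonic state.
#' Events with a missing reference PSI are excluded from all time points.
#'
#' @param psiByTimepoint numeric matrix, events x time points (columns in
#'   temporal order).
#' @param eventSubset event ids to average over.
#' @param reference reference column name or index (default first).
#' @return Named numeric vector of burdens, one per time point (the
#'   reference burden is 0 by construction).
#' @export
developmentalBurden <- function(psiByTimepoint, eventSubset,
                                reference = 1L) {
  if (ncol(psiByTimepoint) < 2)
    stop("validation error: need at least two time points", call. = FALSE)
  eventSubset <- intersect(eventSubset, rownames(psiByTimepoint))
  if (length(eventSubset) == 0)
    stop("validation error: empty event subset", call. = FALSE)
  m <- psiByTimepoint[eventSubset, , drop = FALSE]
  ref <- m[, reference]
  m <- m[!is.na(ref), , drop = FALSE]
  ref <- ref[!is.na(ref)]
  out <- colMeans(abs(m - ref), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Pearson correlation with t-distribution p-value
#'
#' Standard Pearson r over pairwise-complete observations; the two-sided
#' p-value comes from `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of
#' freedom. Inputs with zero variance give an explicit degenerate result
#' instead of a number.
#'
#' @param x,y numeric vectors of equal length.
#' @return `list(r, p, n, degenerate)`.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y))
    stop("validation error: x and y must have equal length", call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("validation error: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}

#' Correlate a covariate with per-sample burden
#'
#' Convenience wrapper: computes [perSampleBurden()] for the case samples
#' and correlates it with a per-sample numeric covariate (for example the
#' 90th-percentile CTG repeat length), dropping samples with a missing
#' burden or covariate.
#'
#' @inheritParams perSampleBurden
#' @param covariate named numeric vector keyed by sample.
#' @return `list(r, p, n, degenerate, burden)`.
#' @export
covariateBurdenCorrelation <- function(psi, controlMeanPsi, eventSubset,
                                       covariate) {
  samples <- intersect(names(covariate), colnames(psi))
  burden <- perSampleBurden(psi, controlMeanPsi, eventSubset,
                            samples = samples)
  res <- pearsonCorr(covariate[samples], burden[samples])
  res$burden <- burden
  res
}
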