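#' @importFrom stats dhyper qnorm
NULL

.check_table <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
    stop("validation error: 2x2 cells must be non-negative integers",
         call. = FALSE)
  if (sum(v) < 1)
    stop("validation error: empty 2x2 table", call. = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by direct enumeration over the feasible
#' range of the table at fixed margins: the sum of hypergeometric point
#' probabilities of all tables whose probability does not exceed that of
#' the observed table (within relative tolerance 1e-7, the conventional
#' tie-handling rule; floating-point ties are otherwise unstable).
#'
#' @param a,b,c,d cell counts (`a` = foreground in set, `b` = foreground
#'   out of set, `c` = background in set, `d` = background out of set);
#'   vectorised.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @examples
#' fisherExact2x2(10, 10, 10, 10)  # 1
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    .check_table(a[i], b[i], c[i], d[i])
    m1 <- a[i] + b[i]          # foreground margin
    m2 <- c[i] + d[i]          # background margin
    k <- a[i] + c[i]           # in-set margin
    x <- max(0L, k - m2):min(k, m1)
    probs <- dhyper(x, m1, m2, k)
    pObs <- dhyper(a[i], m1, m2, k)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  }, 0)
}

#' Odds ratio with Woolf confidence interval
#'
#' The sample cross-product ratio `OR = (a d)/(b c)` with a Woolf log-scale
#' interval `exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell
#' is zero (policy `"on-zero"`, the default) or always (policy `"always"`),
#' 0.5 is added to all four cells first (Haldane-Anscombe); `"never"`
#' leaves zero cells untouched, which can give 0/Inf/NaN estimates.
#'
#' @inheritParams fisherExact2x2
#' @param correction `"on-zero"` (default), `"always"` or `"never"`.
#' @param conf confidence level (default 0.95).
#' @return A `data.frame` with columns `oddsRatio`, `ciLow`, `ciHigh`,
#'   `corrected`.
#' @examples
#' oddsRatioCI(20, 10, 10, 20)$oddsRatio  # 4
#' @export
oddsRatioCI <- function(a, b, c, d,
                        correction = c("on-zero", "always", "never"),
                        conf = 0.95) {
  correction <- match.arg(correction)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  for (i in seq_len(n)) .check_table(a[i], b[i], c[i], d[i])
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  corrected <- switch(correction, `on-zero` = zero,
                      always = rep(TRUE, n), never = rep(FALSE, n))
  a <- a + 0.5 * corrected; b <- b + 0.5 * corrected
  c <- c + 0.5 * corrected; d <- d + 0.5 * corrected
  or <- (a * d) / (b * c)
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.frame(oddsRatio = or, ciLow = exp(log(or) - z * se),
             ciHigh = exp(log(or) + z * se), corrected = corrected)
}

.enrich_row <- function(name, a, b, c, d, correction = "on-zero") {
  orci <- oddsRatioCI(a, b, c, d, correction = correction)
  data.frame(
    name = name, a = a, b = b, c = c, d = d,
    oddsRatio = orci$oddsRatio, ciLow = orci$ciLow, ciHigh = orci$ciHigh,
    pValue = fisherExact2x2(a, b, c, d),
    degenerate = (a == 0 & b == 0) | (c == 0 & d == 0) |
      (a == 0 & c == 0) | (b == 0 & d == 0),
    stringsAsFactors = FALSE
  )
}

#' Gene-set over-representation of mis-spliced genes
#'
#' For each gene set, tabulates mis-spliced versus non-mis-spliced genes of
#' the detected universe against set membership (sets are intersected with
#' the universe first), and reports the odds ratio with Woolf 95% CI,
#' two-sided Fisher p-value and BH FDR across the batch of sets tested
#' together. Rows are ordered by descending odds ratio (forest-plot-ready).
#'
#' @param misSpliced character vector of mis-spliced gene symbols (must be
#'   a subset of `universe`).
#' @param universe character vector of all detected gene symbols.
#' @param geneSets named list of gene-symbol vectors (see
#'   [readGeneSets()]).
#' @param correction zero-cell policy for [oddsRatioCI()].
#' @return `data.frame` with columns `name`, `a`..`d`, `oddsRatio`,
#'   `ciLow`, `ciHigh`, `pValue`, `degenerate`, `fdr`.
#' @export
geneSetEnrichment <- function(misSpliced, universe, geneSets,
                              correction = "on-zero") {
  universe <- unique(toupper(universe))
  misSpliced <- unique(toupper(misSpliced))
  if (length(universe) == 0)
    stop("validation error: empty gene universe", call. = FALSE)
  if (!all(misSpliced %in% universe))
    stop("validation error: mis-spliced genes must be a subset of the universe",
         call. = FALSE)
  nUni <- length(universe); nMis <- length(misSpliced)
  rows <- lapply(names(geneSets), function(nm) {
    s <- intersect(unique(toupper(geneSets[[nm]])), universe)
    a <- length(intersect(misSpliced, s))
    b <- nMis - a
    cc <- length(s) - a
    dd <- nUni - nMis - cc
    .enrich_row(nm, a, b, cc, dd, correction)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$pValue)
  out[order(-out$oddsRatio), , drop = FALSE]
}

#' Microexon disproportion among mis-spliced SE events
#'
#' Tests whether microexons are over-represented among mis-spliced skipped
#' exons: the foreground is the mis-spliced SE events (optionally
#' restricted to those in a gene set), the background is all FDR-evaluable
#' SE events (foreground included, matching the "x% of all detected SE
#' versus y% of mis-spliced SE" comparison), rows are microexon versus
#' non-microexon.
#'
#' @param res a [diffSplicing()] result table.
#' @param geneSet optional character vector of gene symbols restricting the
#'   foreground.
#' @param correction zero-cell policy for [oddsRatioCI()].
#' @return One-row enrichment `data.frame` (see [geneSetEnrichment()]),
#'   with `fdr` equal to the p-value (single test).
#' @export
microexonEnrichment <- function(res, geneSet = NULL,
                                correction = "on-zero") {
  se <- res[res$eventType == "SE" & !is.na(res$fdr), , drop = FALSE]
  fg <- se[se$isMisSpliced, , drop = FALSE]
  if (!is.null(geneSet))
    fg <- fg[toupper(fg$geneSymbol) %in% toupper(geneSet), , drop = FALSE]
  if (nrow(fg) == 0)
    warning("no mis-spliced SE events in scope; degenerate table")
  a <- sum(fg$isMicroexon); b <- nrow(fg) - a
  cc <- sum(se$isMicroexon); dd <- nrow(se) - cc
  out <- .enrich_row(if (is.null(geneSet)) "microexon" else "microexon|set",
                     a, b, cc, dd, correction)
  out$fdr <- out$pValue
  out
}

#' Overlap of two item sets against a universe
#'
#' Fisher's exact test on the 2x2 table
#' `(|A \eqn{\cap}{^} B|, |A \\ B|, |B \\ A|, |universe \\ (A u B)|)`,
#' the standard cross-dataset overlap test for mis-spliced gene or event
#' sets (after any ortholog mapping, see [mapSymbols()]).
#'
#' @param A,B character vectors, both subsets of `universe`.
#' @param universe character vector.
#' @param correction zero-cell policy for [oddsRatioCI()].
#' @param name row label.
#' @return One-row enrichment `data.frame`.
#' @export
overlapTest <- function(A, B, universe, correction = "on-zero",
                        name = "overlap") {
  A <- unique(toupper(A)); B <- unique(toupper(B))
  universe <- unique(toupper(universe))
  if (!all(A %in% universe) || !all(B %in% universe))
    stop("validation error: universe smaller than the union of A and B",
         call. = FALSE)
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  cc <- length(setdiff(B, A))
  dd <- length(universe) - length(union(A, B))
  out <- .enrich_row(name, a, b, cc, dd, correction)
  out$fdr <- out$pValue
  out
}

#' Compare two differential-splicing analyses
#'
#' Cross-dataset comparison at the gene and event level: overlap of
#' mis-spliced gene sets against the shared detected universe (after
#' optional ortholog mapping of the second dataset's symbols), overlap of
#' mis-spliced events among shared event ids, and DPSI sign concordance
#' over the shared mis-spliced events. Events are only compared within
#' matching ids (cross-species event equivalence is not attempted).
#'
#' @param resA,resB [diffSplicing()] result tables.
#' @param orthologs optional two-column `data.frame` (`from`, `to`)
#'   mapping dataset-B gene symbols into dataset-A's namespace.
#' @return `list(genes = , events = , concordance = )`: two one-row
#'   enrichment tables (see [overlapTest()]) and a [dpsiConcordance()]
#'   result. `events` is `NULL` when the datasets share no event ids.
#' @export
compareDiffResults <- function(resA, resB, orthologs = NULL) {
  gA <- misSplicedGenes(resA)
  gB <- misSplicedGenes(resB)
  mapB <- function(x) unique(mapSymbols(x, orthologs))
  uni <- intersect(gA$universe, mapB(gB$universe))
  genes <- overlapTest(intersect(gA$misSpliced, uni),
                       intersect(mapB(gB$misSpliced), uni),
                       uni, name = "mis-spliced genes")
  shared <- intersect(resA$eventID, resB$eventID)
  events <- NULL
  if (length(shared)) {
    evalA <- resA$eventID[!is.na(resA$fdr)]
    evalB <- resB$eventID[!is.na(resB$fdr)]
    evUni <- intersect(intersect(evalA, evalB), shared)
    events <- overlapTest(
      intersect(resA$eventID[resA$isMisSpliced], evUni),
      intersect(resB$eventID[resB$isMisSpliced], evUni),
      evUni, name = "mis-spliced events")
  }
  misA <- stats::setNames(resA$dpsi, resA$eventID)[
    resA$isMisSpliced]
  misB <- stats::setNames(resB$dpsi, resB$eventID)[
    resB$isMisSpliced]
  conc <- dpsiConcordance(misA, misB)
  list(genes = genes, events = events, concordance = conc)
}

#' Sign concordance of DPSI between two datasets
#'
#' Over events shared by two differential-splicing analyses, reports the
#' fraction with the same DPSI sign and, among the concordant events, the
#' fraction excluded in both datasets (DPSI < 0 on both sides). Events
#' with a missing or exactly zero DPSI on either side are excluded from
#' sign classification.
#'
#' @param dpsiA,dpsiB named numeric vectors of DPSI keyed by event id.
#' @param sharedIDs optional explicit vector of shared event ids; defaults
#'   to the intersection of the names.
#' @return `list(n, nSigned, concordant, bothNegativeAmongConcordant)`;
#'   fractions are `NA` when no classifiable pair exists.
#' @export
dpsiConcordance <- function(dpsiA, dpsiB, sharedIDs = NULL) {
  if (is.null(sharedIDs))
    sharedIDs <- intersect(names(dpsiA), names(dpsiB))
  x <- dpsiA[sharedIDs]; y <- dpsiB[sharedIDs]
  n <- length(sharedIDs)
  ok <- !is.na(x) & !is.na(y) & x != 0 & y != 0
  if (!any(ok))
    return(list(n = n, nSigned = 0L, concordant = NA_real_,
                bothNegativeAmongConcordant = NA_real_))
  x <- x[ok]; y <- y[ok]
  conc <- sign(x) == sign(y)
  list(
    n = n, nSigned = sum(ok),
    concordant = mean(conc),
    bothNegativeAmongConcordant =
      if (any(conc)) mean(x[conc] < 0) else NA_real_
  )
}
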