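#' @importFrom stats p.adjust
NULL

#' Length-normalised percent spliced in (PSI)
#'
#' PSI estimates the fraction of transcripts including the alternative
#' segment from inclusion- and skipping-junction read counts, normalising
#' each count by the effective length (number of junction spans) of its
#' isoform: `PSI = (I/lI) / (I/lI + S/lS)`. Events whose total junction
#' coverage `I + S` falls below `minReads` in a sample are reported missing
#' (`NA`) for that sample: low coverage is treated as absence of evidence,
#' not as PSI of zero.
#'
#' @param I,S non-negative integer inclusion/skipping counts (vectorised);
#'   `NA` propagates.
#' @param lI,lS effective lengths of inclusion and skipping forms (>= 1).
#' @param minReads minimum `I + S` per sample for a PSI value (default 10).
#' @return Numeric vector of PSI values in `[0, 1]`, `NA` where missing.
#' @examples
#' psiFromCounts(30, 10, lI = 2, lS = 1)  # 0.6
#' @export
psiFromCounts <- function(I, S, lI, lS, minReads = 10) {
  if (any(I < 0, na.rm = TRUE) || any(S < 0, na.rm = TRUE))
    stop("validation error: counts must be non-negative", call. = FALSE)
  if (any(lI < 1, na.rm = TRUE) || any(lS < 1, na.rm = TRUE))
    stop("validation error: effective lengths must be >= 1", call. = FALSE)
  ni <- I / lI
  ns <- S / lS
  psi <- ni / (ni + ns)
  psi[!is.na(I) & !is.na(S) & (I + S) < minReads] <- NA_real_
  psi
}

#' Compute the PSI matrix of a SplicingExperiment
#'
#' @param x a [SplicingExperiment-class].
#' @param minReads per-sample coverage floor, see [psiFromCounts()].
#' @return Numeric events x samples matrix with `minReads` recorded in
#'   `attr(, "minReads")`.
#' @export
computePsi <- function(x, minReads = 10) {
  inc <- inclusionCounts(x)
  skp <- skippingCounts(x)
  lI <- incFormLen(x)
  lS <- skipFormLen(x)
  psi <- psiFromCounts(inc, skp, matrix(lI, nrow(inc), ncol(inc)),
                       matrix(lS, nrow(inc), ncol(inc)),
                       minReads = minReads)
  psi <- matrix(psi, nrow(inc), ncol(inc), dimnames = dimnames(inc))
  attr(psi, "minReads") <- minReads
  psi
}

# Two-sided label-permutation p-values on per-sample PSI, vectorised over
# events sharing the same pattern of informative samples. Exhaustive over
# all distinct label assignments when their number is <= maxExhaustive,
# otherwise Monte-Carlo with add-one smoothing.
.permPvalues <- function(psi, isCase, nPerm = 9999, seed = 1,
                         exact = c("auto", "always", "never"),
                         maxExhaustive = 10000) {
  exact <- match.arg(exact)
  set.seed(seed)
  E <- nrow(psi)
  p <- rep(NA_real_, E)
  if (E == 0L) return(p)
  inf <- !is.na(psi)
  key <- apply(inf, 1L, function(z) paste(which(z), collapse = ","))
  for (k in unique(key)) {
    idx <- which(key == k)
    cols <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    if (length(cols) == 0L) next
    lab <- isCase[cols]
    n1 <- sum(lab); n0 <- sum(!lab); n <- length(cols)
    if (n1 < 1L || n0 < 1L) next
    K <- choose(n, n1)
    if (K < 2) { p[idx] <- 1; next }
    useExact <- switch(exact, always = TRUE, never = FALSE,
                       auto = K <= maxExhaustive)
    if (useExact) {
      cmb <- utils::combn(n, n1)
      W <- matrix(-1 / n0, ncol(cmb), n)
      for (j in seq_len(ncol(cmb))) W[j, cmb[, j]] <- 1 / n1
    } else {
      W <- matrix(-1 / n0, nPerm, n)
      for (j in seq_len(nPerm)) W[j, sample.int(n, n1)] <- 1 / n1
    }
    for (block in split(idx, ceiling(seq_along(idx) / 500))) {
      sub <- psi[block, cols, drop = FALSE]
      obs <- abs(rowMeans(sub[, lab, drop = FALSE]) -
                 rowMeans(sub[, !lab, drop = FALSE]))
      stat <- abs(W %*% t(sub))
      extreme <- stat >= rep(obs - 1e-12, each = nrow(stat))
      cnt <- colSums(extreme)
      p[block] <- if (useExact) cnt / nrow(stat) else
        (1 + cnt) / (nPerm + 1)
    }
  }
  p
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH q-values via [stats::p.adjust()], with input validation and
#' pass-through of missing p-values (missing p is excluded from the
#' correction and returned missing).
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA` allowed.
#' @return q-values in `[0, 1]`, `NA` where `p` was `NA`; order-equivariant.
#' @export
bhFdr <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Microexon classification
#'
#' A microexon is operationally a very short skipped exon: an SE event whose
#' alternative exon is 3-33 nt long (bounds inclusive). Events of any other
#' type are never microexons, whatever their exon lengths.
#'
#' @param eventType character vector of event types.
#' @param altExonLength alternative-exon length in nt (NA for non-SE).
#' @param minLen,maxLen inclusive length bounds (defaults 3 and 33).
#' @return Logical vector.
#' @export
classifyMicroexon <- function(eventType, altExonLength,
                              minLen = 3, maxLen = 33) {
  eventType == "SE" & !is.na(altExonLength) &
    altExonLength >= minLen & altExonLength <= maxLen
}

#' Mis-splicing decision rule
#'
#' An event is called mis-spliced when `|DPSI|` strictly exceeds
#' `dpsiThresh` and its FDR is strictly below `fdrThresh` (both
#' inequalities strict, so DPSI of exactly 0.1 is not called). Missing DPSI
#' or FDR never flags.
#'
#' @param dpsi,fdr numeric vectors.
#' @param dpsiThresh,fdrThresh thresholds (defaults 0.1 and 0.05).
#' @return Logical vector.
#' @export
classifyMisSpliced <- function(dpsi, fdr, dpsiThresh = 0.1,
                               fdrThresh = 0.05) {
  !is.na(dpsi) & !is.na(fdr) & abs(dpsi) > dpsiThresh & fdr < fdrThresh
}

#' Replicate-aware differential splicing
#'
#' For every event, computes group mean PSI over informative samples, the
#' difference `DPSI = mean PSI(case) - mean PSI(control)`, a two-sided
#' label-permutation p-value on per-sample PSI (exhaustive over all distinct
#' label assignments when there are at most `maxExhaustive` of them,
#' otherwise Monte-Carlo with `nPerm` draws and add-one smoothing),
#' BH FDR, and the mis-splicing and microexon flags.
#'
#' FDR is by default computed within each event type separately, mirroring
#' per-type upstream tables; `fdrScope = "joint"` pools all events. Events
#' with an entirely uninformative group keep a missing p-value and are
#' excluded from the FDR computation; events informative in no sample at
#' all are dropped with a warning.
#'
#' @param x a [SplicingExperiment-class].
#' @param group factor/character of group labels per sample; defaults to
#'   `colData(x)$group`.
#' @param control,case the two group levels; default: first level is the
#'   control (reference), second the case, so planted case-specific exon
#'   exclusion yields DPSI < 0.
#' @param dpsiThresh,fdrThresh mis-splicing thresholds (0.1, 0.05).
#' @param minReads PSI coverage floor per sample (10).
#' @param nPerm Monte-Carlo permutation count (9999).
#' @param seed RNG seed for Monte-Carlo permutations; recorded in the
#'   result metadata and output headers.
#' @param fdrScope `"per-type"` (default) or `"joint"`.
#' @param exact `"auto"` (exhaustive when feasible), `"always"`, `"never"`.
#' @param maxExhaustive assignment-count ceiling for the exhaustive test.
#' @return A `DataFrame` with one row per retained event: event/gene
#'   annotation, per-group informative sample counts and mean PSI, `dpsi`,
#'   `pValue`, `fdr`, `isMisSpliced`, `isMicroexon`. Run parameters are in
#'   `metadata()`.
#' @export
diffSplicing <- function(x, group = NULL, control = NULL, case = NULL,
                         dpsiThresh = 0.1, fdrThresh = 0.05, minReads = 10,
                         nPerm = 9999, seed = 1,
                         fdrScope = c("per-type", "joint"),
                         exact = c("auto", "always", "never"),
                         maxExhaustive = 10000) {
  fdrScope <- match.arg(fdrScope)
  exact <- match.arg(exact)
  if (is.null(group)) group <- colData(x)$group
  if (is.null(group))
    stop("no group labels: supply `group` or a colData 'group' column",
         call. = FALSE)
  group <- as.character(group)
  lv <- unique(group)
  if (is.null(control)) control <- lv[1]
  if (is.null(case)) case <- setdiff(lv, control)[1]
  keep_s <- group %in% c(control, case)
  xs <- x[, keep_s]
  isCase <- group[keep_s] == case
  if (sum(isCase) < 1 || sum(!isCase) < 1)
    stop("both groups need at least one sample", call. = FALSE)
  psi <- computePsi(xs, minReads = minReads)

  infC <- rowSums(!is.na(psi[, isCase, drop = FALSE]))
  infK <- rowSums(!is.na(psi[, !isCase, drop = FALSE]))
  dead <- infC + infK == 0
  if (any(dead)) {
    warning(sum(dead), " event(s) informative in no sample; dropped")
    xs <- xs[!dead, ]; psi <- psi[!dead, , drop = FALSE]
    infC <- infC[!dead]; infK <- infK[!dead]
  }
  meanC <- unname(rowMeans(psi[, isCase, drop = FALSE], na.rm = TRUE))
  meanK <- unname(rowMeans(psi[, !isCase, drop = FALSE], na.rm = TRUE))
  infC <- unname(infC); infK <- unname(infK)
  meanC[infC == 0] <- NA_real_
  meanK[infK == 0] <- NA_real_
  dpsi <- meanC - meanK
  p <- .permPvalues(psi, isCase, nPerm = nPerm, seed = seed, exact = exact,
                    maxExhaustive = maxExhaustive)
  rd <- rowData(xs)
  fdr <- if (fdrScope == "per-type") {
    out <- rep(NA_real_, length(p))
    for (tp in unique(rd$eventType)) {
      sel <- rd$eventType == tp
      out[sel] <- bhFdr(p[sel])
    }
    out
  } else bhFdr(p)
  res <- DataFrame(
    eventID = rownames(xs),
    eventType = rd$eventType,
    geneID = rd$geneID,
    geneSymbol = rd$geneSymbol,
    altExonLength = rd$altExonLength,
    nCase = infC, nControl = infK,
    meanPsiCase = meanC, meanPsiControl = meanK,
    dpsi = dpsi, pValue = p, fdr = fdr,
    isMisSpliced = classifyMisSpliced(dpsi, fdr, dpsiThresh, fdrThresh),
    isMicroexon = classifyMicroexon(rd$eventType, rd$altExonLength),
    row.names = rownames(xs)
  )
  metadata(res) <- list(
    control = control, case = case, dpsiThresh = dpsiThresh,
    fdrThresh = fdrThresh, minReads = minReads, nPerm = nPerm, seed = seed,
    fdrScope = fdrScope, method = "label-permutation"
  )
  res
}

#' Mis-spliced genes and the detected-gene universe
#'
#' A gene is mis-spliced when at least one of its events carries the
#' mis-splicing flag; the universe is every gene with at least one
#' FDR-evaluable event. Events without a gene symbol are excluded with a
#' warning.
#'
#' @param res a result table from [diffSplicing()].
#' @return `list(misSpliced = , universe = )` of uppercase gene symbols.
#' @export
misSplicedGenes <- function(res) {
  sym <- toupper(res$geneSymbol)
  nosym <- is.na(sym) | !nzchar(sym)
  if (any(nosym)) {
    warning(sum(nosym), " event(s) without gene symbol excluded")
    res <- res[!nosym, , drop = FALSE]
    sym <- sym[!nosym]
  }
  universe <- unique(sym[!is.na(res$fdr)])
  mis <- unique(sym[res$isMisSpliced])
  list(misSpliced = intersect(mis, universe), universe = universe)
}

#' Write / read a differential-splicing result table
#'
#' The TSV carries `#`-prefixed header lines recording the thresholds,
#' test method and seed, then the result columns; [readDiffResults()]
#' parses the file back (closure property of the pipeline outputs).
#'
#' @param res result of [diffSplicing()].
#' @param path output path.
#' @export
writeDiffResults <- function(res, path) {
  md <- metadata(res)
  hdr <- c(
    sprintf("# missplice diffSplicing v%s",
            as.character(utils::packageVersion("missplice"))),
    sprintf("# control=%s case=%s", md$control, md$case),
    sprintf("# dpsiThresh=%g fdrThresh=%g minReads=%g", md$dpsiThresh,
            md$fdrThresh, md$minReads),
    sprintf("# method=%s nPerm=%d seed=%d fdrScope=%s", md$method,
            md$nPerm, as.integer(md$seed), md$fdrScope)
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(res), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeDiffResults
#' @export
readDiffResults <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  DataFrame(tab, row.names = tab$eventID)
}
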