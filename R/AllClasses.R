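#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowData<- colData<-
NULL

.EVENT_TYPES <- c("SE", "MXE", "A5SS", "A3SS", "RI")

# rowData columns every SplicingExperiment must carry. All coordinates are
# 0-based half-open (BED-style) on the genome; alt2Start/alt2End are NA for
# everything but MXE. upStart/upEnd and downStart/downEnd hold the
# transcript-upstream and transcript-downstream flanking constitutive exons
# (so on the minus strand the upstream exon has the larger coordinates).
.REQUIRED_ROWDATA <- c(
  "eventType", "geneID", "geneSymbol", "chrom", "strand",
  "altStart", "altEnd", "alt2Start", "alt2End",
  "upStart", "upEnd", "downStart", "downEnd",
  "incFormLen", "skipFormLen", "altExonLength"
)

#' SplicingExperiment: junction counts for alternative-splicing events
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding, for each
#' alternative-splicing event (rows) and sample (columns), the inclusion- and
#' skipping-junction read counts in the assays `"inclusion"` and
#' `"skipping"`. Event annotation (type, gene, genomic intervals of the
#' alternative and flanking exons, effective form lengths, alternative-exon
#' length) lives in `rowData`; the sample sheet (group labels, numeric
#' covariates) in `colData`.
#'
#' Coordinates are stored 0-based half-open throughout; conversions happen
#' only in the readers/writers.
#'
#' @aliases SplicingExperiment-class
#' @export
setClass("SplicingExperiment", contains = "SummarizedExperiment")

setValidity("SplicingExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("inclusion", "skipping") %in% an))
    return("assays must include 'inclusion' and 'skipping'")
  inc <- assay(object, "inclusion")
  skp <- assay(object, "skipping")
  if (any(inc < 0, na.rm = TRUE) || any(skp < 0, na.rm = TRUE))
    msg <- c(msg, "junction counts must be non-negative")
  rd <- rowData(object)
  missing_cols <- setdiff(.REQUIRED_ROWDATA, colnames(rd))
  if (length(missing_cols))
    return(paste0("rowData lacks column(s): ",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(object)) {
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "event ids (rownames) must be present and unique")
    if (!all(rd$eventType %in% .EVENT_TYPES))
      msg <- c(msg, sprintf("eventType must be one of %s",
                            paste(.EVENT_TYPES, collapse = "/")))
    if (!all(rd$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (any(rd$incFormLen < 1, na.rm = TRUE) ||
        any(rd$skipFormLen < 1, na.rm = TRUE))
      msg <- c(msg, "effective form lengths must be >= 1")
    bad <- !is.na(rd$altStart) & !is.na(rd$altEnd) &
      !(rd$altStart >= 0 & rd$altStart < rd$altEnd)
    if (any(bad))
      msg <- c(msg, "alternative exon intervals must satisfy 0 <= start < end")
    is_mxe <- rd$eventType == "MXE"
    if (any(is_mxe & (is.na(rd$alt2Start) | is.na(rd$alt2End))))
      msg <- c(msg, "MXE events need a second alternative exon interval")
    se_rows <- rd$eventType == "SE"
    if (any(se_rows & (is.na(rd$altExonLength) | rd$altExonLength < 1)))
      msg <- c(msg, "SE events need altExonLength >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SplicingExperiment
#'
#' @param inclusion,skipping integer matrices (events x samples) of
#'   inclusion- and skipping-junction counts; `NA` marks a missing
#'   measurement (for example a sample the event was not quantified in).
#' @param rowData a `DataFrame`/`data.frame` of event annotation carrying at
#'   least the columns listed under [SplicingExperiment-class]; its rownames
#'   (or an `eventID` column) become the event ids.
#' @param colData sample sheet; rownames (or a `sampleID` column) must match
#'   the count matrix columns.
#' @param metadata optional list stored in the object metadata.
#'
#' @return A [SplicingExperiment-class] object.
#' @examples
#' rd <- exampleEventRowData(2)
#' se <- SplicingExperiment(
#'   inclusion = matrix(10L, 2, 3), skipping = matrix(5L, 2, 3),
#'   rowData = rd,
#'   colData = data.frame(group = c("ctrl", "ctrl", "case"),
#'                        row.names = paste0("s", 1:3))
#' )
#' se
#' @export
SplicingExperiment <- function(inclusion, skipping, rowData, colData,
                               metadata = list()) {
  inclusion <- as.matrix(inclusion)
  skipping <- as.matrix(skipping)
  rowData <- as(rowData, "DataFrame")
  if ("eventID" %in% colnames(rowData) && is.null(rownames(rowData)))
    rownames(rowData) <- rowData$eventID
  if (is.data.frame(colData) || is(colData, "DataFrame")) {
    colData <- as(colData, "DataFrame")
    if ("sampleID" %in% colnames(colData) && is.null(rownames(colData)))
      rownames(colData) <- colData$sampleID
  }
  rownames(inclusion) <- rownames(skipping) <- rownames(rowData)
  if (is.null(colnames(inclusion)))
    colnames(inclusion) <- colnames(skipping) <- rownames(colData)
  obj <- SummarizedExperiment(
    assays = list(inclusion = inclusion, skipping = skipping),
    rowData = rowData, colData = colData
  )
  obj <- new("SplicingExperiment", obj)
  metadata(obj) <- metadata
  obj
}

#' Minimal event annotation for examples and tests
#'
#' Builds a small, valid `rowData` table of plus-strand SE events laid out on
#' one synthetic chromosome, mainly for documentation examples.
#'
#' @param n number of events.
#' @return A `DataFrame` with the required event annotation columns.
#' @export
exampleEventRowData <- function(n = 2) {
  off <- (seq_len(n) - 1L) * 2000L
  DataFrame(
    eventType = rep("SE", n),
    geneID = sprintf("G%03d", seq_len(n)),
    geneSymbol = sprintf("GENE%d", seq_len(n)),
    chrom = rep("chrS", n),
    strand = rep("+", n),
    altStart = off + 800L, altEnd = off + 900L,
    alt2Start = rep(NA_integer_, n), alt2End = rep(NA_integer_, n),
    upStart = off + 100L, upEnd = off + 250L,
    downStart = off + 1500L, downEnd = off + 1650L,
    incFormLen = rep(2, n), skipFormLen = rep(1, n),
    altExonLength = rep(100L, n),
    row.names = sprintf("ev%04d", seq_len(n))
  )
}

#' @describeIn SplicingExperiment inclusion-junction count matrix.
#' @param x a `SplicingExperiment`.
#' @export
inclusionCounts <- function(x) assay(x, "inclusion")

#' @describeIn SplicingExperiment skipping-junction count matrix.
#' @export
skippingCounts <- function(x) assay(x, "skipping")

#' @describeIn SplicingExperiment event type vector (SE/MXE/A5SS/A3SS/RI).
#' @export
eventType <- function(x) rowData(x)$eventType

#' @describeIn SplicingExperiment gene symbol per event.
#' @export
geneSymbols <- function(x) rowData(x)$geneSymbol

#' @describeIn SplicingExperiment effective inclusion-form length per event.
#' @export
incFormLen <- function(x) rowData(x)$incFormLen

#' @describeIn SplicingExperiment effective skipping-form length per event.
#' @export
skipFormLen <- function(x) rowData(x)$skipFormLen

#' @describeIn SplicingExperiment alternative-exon length (nt; SE events).
#' @export
altExonLength <- function(x) rowData(x)$altExonLength

setMethod("show", "SplicingExperiment", function(object) {
  cat("SplicingExperiment with", nrow(object), "events and",
      ncol(object), "samples\n")
  if (nrow(object)) {
    tab <- table(factor(eventType(object), levels = .EVENT_TYPES))
    cat("  event types:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    n_mie <- sum(classifyMicroexon(eventType(object),
                                   altExonLength(object)))
    cat("  microexons (3-33 nt SE):", n_mie, "\n")
  }
  if (ncol(object) && "group" %in% colnames(colData(object))) {
    gt <- table(colData(object)$group)
    cat("  groups:",
        paste(sprintf("%s=%d", names(gt), gt), collapse = " "), "\n")
  }
  invisible(NULL)
})
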