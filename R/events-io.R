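#' @importFrom utils read.delim write.table
#' @importFrom Biostrings DNAStringSet reverseComplement subseq width
NULL

#' Coordinate convention converters
#'
#' The package stores all genomic intervals 0-based half-open (BED-style).
#' GTF-style tables are 1-based inclusive; these helpers convert at the I/O
#' boundary and are exact inverses of each other.
#'
#' @param start,end interval bounds in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @examples
#' coordsTo0Based(101, 200)  # -> start 100, end 200
#' @export
coordsTo0Based <- function(start, end) list(start = start - 1L, end = end)

#' @rdname coordsTo0Based
#' @export
coordsTo1Based <- function(start, end) list(start = start + 1L, end = end)

.parse_count_field <- function(x, n_samples, what, line_no) {
  parts <- strsplit(x, ",", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != n_samples))
    stop(sprintf(
      "configuration error: %s field on line %d has %d value(s), expected %d samples",
      what, line_no[which(lens != n_samples)[1]],
      lens[lens != n_samples][1], n_samples
    ), call. = FALSE)
  out <- matrix(NA_integer_, length(x), n_samples)
  for (i in seq_along(parts)) {
    v <- parts[[i]]
    v[v %in% c("", "NA", "na", ".")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & (is.na(num) | num < 0 | num != floor(num))
    if (any(bad))
      stop(sprintf("parse error: non-integer %s count '%s' on line %d",
                   what, v[bad][1], line_no[i]), call. = FALSE)
    out[i, ] <- as.integer(num)
  }
  out
}

.rmats_coord_map <- function(type) {
  switch(type,
    SE = list(alt = c("exonStart_0base", "exonEnd"),
              alt2 = NULL,
              up = c("upstreamES", "upstreamEE"),
              down = c("downstreamES", "downstreamEE")),
    MXE = list(alt = c("X1stExonStart_0base", "X1stExonEnd"),
               alt2 = c("X2ndExonStart_0base", "X2ndExonEnd"),
               up = c("upstreamES", "upstreamEE"),
               down = c("downstreamES", "downstreamEE")),
    A5SS = ,
    A3SS = list(alt = c("longExonStart_0base", "longExonEnd"),
                alt2 = NULL,
                up = c("shortES", "shortEE"),
                down = c("flankingES", "flankingEE")),
    RI = list(alt = c("riExonStart_0base", "riExonEnd"),
              alt2 = NULL,
              up = c("upstreamES", "upstreamEE"),
              down = c("downstreamES", "downstreamEE")),
    stop("unknown rMATS event type: ", type, call. = FALSE)
  )
}

#' Read an events/counts table
#'
#' Reads per-event inclusion/skipping junction counts together with event
#' annotation into a [SplicingExperiment-class]. Two dialects are supported:
#'
#' * `"native-tsv"`: the package's own flat format (one row per event,
#'   comma-separated per-sample `ijc`/`sjc` fields) as written by
#'   [writeEventsTable()].
#' * `"rmats-jc"`: the per-type junction-count tables of the rMATS family of
#'   tools (e.g. `SE.MATS.JC.txt`), with `IJC_SAMPLE_1/2` comma lists and
#'   0-based half-open exon coordinate columns (`exonStart_0base`/`exonEnd`),
#'   which are ingested unchanged. The rMATS upstream/downstream exon columns
#'   are taken as written and swapped on the minus strand so that internally
#'   `up*` is always the transcript-upstream flanking exon. Requires
#'   `eventType`.
#'
#' Missing count fields (`NA` or empty) become missing samples for that
#' event, not zeros.
#'
#' @param path file path.
#' @param dialect one of `"native-tsv"`, `"rmats-jc"`.
#' @param eventType event type of an rMATS table (its tables are per type).
#' @param sampleNames optional character vector of sample names; for
#'   `rmats-jc` these cover group 1 then group 2. An arity mismatch with the
#'   count fields is a configuration error.
#' @param groupSizes for `rmats-jc`, integer vector `c(n1, n2)`; inferred
#'   from the first row when omitted.
#' @param groupLabels labels for the two rMATS sample groups
#'   (default `c("sample1", "sample2")`).
#'
#' @return A [SplicingExperiment-class].
#' @export
readEventsTable <- function(path, dialect = c("native-tsv", "rmats-jc"),
                            eventType = NULL, sampleNames = NULL,
                            groupSizes = NULL,
                            groupLabels = c("sample1", "sample2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(.empty_splicing_experiment())
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  if (nrow(tab) == 0L) return(.empty_splicing_experiment())
  line_no <- seq_len(nrow(tab)) + 1L  # header is line 1
  if (dialect == "native-tsv") {
    .read_native_tsv(tab, line_no, sampleNames)
  } else {
    if (is.null(eventType))
      stop("eventType is required for the rmats-jc dialect", call. = FALSE)
    .read_rmats_jc(tab, line_no, eventType, sampleNames, groupSizes,
                   groupLabels)
  }
}

.empty_splicing_experiment <- function() {
  rd <- exampleEventRowData(0)
  SplicingExperiment(matrix(integer(), 0, 0), matrix(integer(), 0, 0),
                     rowData = rd, colData = DataFrame())
}

.read_native_tsv <- function(tab, line_no, sampleNames) {
  need <- c("event_id", "event_type", "gene_id", "gene_symbol", "chrom",
            "strand", "alt_start", "alt_end", "alt2_start", "alt2_end",
            "up_start", "up_end", "down_start", "down_end",
            "inc_form_len", "skip_form_len", "ijc", "sjc")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("parse error: native-tsv table lacks column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  n_samples <- length(strsplit(tab$ijc[1], ",", fixed = TRUE)[[1]])
  if (!is.null(sampleNames)) {
    if (length(sampleNames) != n_samples)
      stop(sprintf(
        "configuration error: %d sample names supplied for %d count columns",
        length(sampleNames), n_samples), call. = FALSE)
  } else sampleNames <- sprintf("s%d", seq_len(n_samples))
  inc <- .parse_count_field(as.character(tab$ijc), n_samples, "inclusion",
                            line_no)
  skp <- .parse_count_field(as.character(tab$sjc), n_samples, "skipping",
                            line_no)
  rd <- DataFrame(
    eventType = tab$event_type, geneID = tab$gene_id,
    geneSymbol = tab$gene_symbol, chrom = tab$chrom, strand = tab$strand,
    altStart = as.integer(tab$alt_start), altEnd = as.integer(tab$alt_end),
    alt2Start = as.integer(tab$alt2_start),
    alt2End = as.integer(tab$alt2_end),
    upStart = as.integer(tab$up_start), upEnd = as.integer(tab$up_end),
    downStart = as.integer(tab$down_start),
    downEnd = as.integer(tab$down_end),
    incFormLen = as.numeric(tab$inc_form_len),
    skipFormLen = as.numeric(tab$skip_form_len),
    altExonLength = ifelse(tab$event_type == "SE",
                           as.integer(tab$alt_end) - as.integer(tab$alt_start),
                           NA_integer_),
    row.names = tab$event_id
  )
  cd <- DataFrame(row.names = sampleNames)
  colnames(inc) <- colnames(skp) <- sampleNames
  SplicingExperiment(inc, skp, rowData = rd, colData = cd)
}

.read_rmats_jc <- function(tab, line_no, eventType, sampleNames, groupSizes,
                           groupLabels) {
  cm <- .rmats_coord_map(eventType)
  need <- c("GeneID", "geneSymbol", "chr", "strand",
            unlist(cm), "IJC_SAMPLE_1", "SJC_SAMPLE_1",
            "IJC_SAMPLE_2", "SJC_SAMPLE_2", "IncFormLen", "SkipFormLen")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("parse error: rMATS ", eventType, " table lacks column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(groupSizes)) {
    groupSizes <- c(
      length(strsplit(as.character(tab$IJC_SAMPLE_1[1]), ",")[[1]]),
      length(strsplit(as.character(tab$IJC_SAMPLE_2[1]), ",")[[1]])
    )
  }
  n <- sum(groupSizes)
  if (!is.null(sampleNames)) {
    if (length(sampleNames) != n)
      stop(sprintf(
        "configuration error: %d sample names supplied for %d count columns",
        length(sampleNames), n), call. = FALSE)
  } else {
    sampleNames <- c(sprintf("%s_%d", groupLabels[1], seq_len(groupSizes[1])),
                     sprintf("%s_%d", groupLabels[2], seq_len(groupSizes[2])))
  }
  inc <- cbind(
    .parse_count_field(as.character(tab$IJC_SAMPLE_1), groupSizes[1],
                       "IJC_SAMPLE_1", line_no),
    .parse_count_field(as.character(tab$IJC_SAMPLE_2), groupSizes[2],
                       "IJC_SAMPLE_2", line_no)
  )
  skp <- cbind(
    .parse_count_field(as.character(tab$SJC_SAMPLE_1), groupSizes[1],
                       "SJC_SAMPLE_1", line_no),
    .parse_count_field(as.character(tab$SJC_SAMPLE_2), groupSizes[2],
                       "SJC_SAMPLE_2", line_no)
  )
  gi <- function(cols) {
    if (is.null(cols)) return(list(s = rep(NA_integer_, nrow(tab)),
                                   e = rep(NA_integer_, nrow(tab))))
    list(s = as.integer(tab[[cols[1]]]), e = as.integer(tab[[cols[2]]]))
  }
  alt <- gi(cm$alt); alt2 <- gi(cm$alt2); up <- gi(cm$up); down <- gi(cm$down)
  # rMATS up/down columns follow genomic order; mirror on the minus strand so
  # that internally upstream always means transcript-upstream.
  neg <- tab$strand == "-"
  upS <- ifelse(neg, down$s, up$s); upE <- ifelse(neg, down$e, up$e)
  dnS <- ifelse(neg, up$s, down$s); dnE <- ifelse(neg, up$e, down$e)
  ev_id <- if ("ID" %in% colnames(tab))
    sprintf("%s_%s", eventType, tab$ID) else
    sprintf("%s_%d", eventType, seq_len(nrow(tab)))
  rd <- DataFrame(
    eventType = rep(eventType, nrow(tab)),
    geneID = tab$GeneID, geneSymbol = tab$geneSymbol,
    chrom = tab$chr, strand = tab$strand,
    altStart = alt$s, altEnd = alt$e,
    alt2Start = alt2$s, alt2End = alt2$e,
    upStart = upS, upEnd = upE, downStart = dnS, downEnd = dnE,
    incFormLen = as.numeric(tab$IncFormLen),
    skipFormLen = as.numeric(tab$SkipFormLen),
    altExonLength = if (eventType == "SE") alt$e - alt$s else
      rep(NA_integer_, nrow(tab)),
    row.names = ev_id
  )
  cd <- DataFrame(
    group = rep(groupLabels, groupSizes),
    row.names = sampleNames
  )
  colnames(inc) <- colnames(skp) <- sampleNames
  SplicingExperiment(inc, skp, rowData = rd, colData = cd)
}

#' Write a SplicingExperiment as a native-tsv events table
#'
#' Writes the flat tab-separated format that [readEventsTable()] reads back
#' (`dialect = "native-tsv"`); reading the written file reproduces the
#' events and counts exactly. UTF-8, '.' decimal separator, `NA` for missing
#' counts.
#'
#' @param x a [SplicingExperiment-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeEventsTable <- function(x, path) {
  inc <- inclusionCounts(x); skp <- skippingCounts(x)
  rd <- rowData(x)
  tab <- data.frame(
    event_id = rownames(x),
    event_type = rd$eventType,
    gene_id = rd$geneID, gene_symbol = rd$geneSymbol,
    chrom = rd$chrom, strand = rd$strand,
    alt_start = rd$altStart, alt_end = rd$altEnd,
    alt2_start = rd$alt2Start, alt2_end = rd$alt2End,
    up_start = rd$upStart, up_end = rd$upEnd,
    down_start = rd$downStart, down_end = rd$downEnd,
    inc_form_len = rd$incFormLen, skip_form_len = rd$skipFormLen,
    ijc = apply(inc, 1, paste, collapse = ","),
    sjc = apply(skp, 1, paste, collapse = ","),
    check.names = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write sample sheets
#'
#' A sample sheet is a TSV with a `sample_id` column, a `group` column and
#' any number of numeric covariate columns (for example CTG repeat length).
#'
#' @param path file path.
#' @return `readSampleTable`: a `DataFrame` keyed by sample id.
#' @export
readSampleTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(tab)))
    stop("parse error: sample table needs 'sample_id' and 'group' columns",
         call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("sample ids must be unique", call. = FALSE)
  DataFrame(tab[, setdiff(colnames(tab), "sample_id"), drop = FALSE],
            row.names = tab$sample_id)
}

#' @rdname readSampleTable
#' @param x a `DataFrame`/`data.frame` keyed by sample id.
#' @export
writeSampleTable <- function(x, path) {
  out <- cbind(sample_id = rownames(x), as.data.frame(x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Parses the standard GMT format (set name, description, then tab-separated
#' gene symbols). Symbols are case-normalised to uppercase and deduplicated
#' within each set, so cross-species matching defaults to case-insensitive
#' symbol identity; an explicit ortholog table can be applied afterwards
#' with [mapSymbols()].
#'
#' @param path GMT file path.
#' @return A named list of character vectors of uppercase gene symbols, with
#'   set descriptions in `attr(, "description")`.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("parse error: GMT line %d has fewer than 3 fields",
                 short[1]), call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("gene-set names must be unique", call. = FALSE)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    syms <- toupper(f[-(1:2)])
    unique(syms[nzchar(syms)])
  })
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' @rdname readGeneSets
#' @param sets a named list of character vectors.
#' @param description optional per-set description (recycled).
#' @export
writeGeneSets <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Map gene symbols through a two-column ortholog table
#'
#' @param symbols character vector of symbols.
#' @param orthologs `data.frame` with columns `from`, `to`; symbols without
#'   a row pass through unchanged (case-insensitive identity default).
#' @return Mapped, uppercase symbols.
#' @export
mapSymbols <- function(symbols, orthologs = NULL) {
  symbols <- toupper(symbols)
  if (is.null(orthologs)) return(symbols)
  from <- toupper(orthologs$from); to <- toupper(orthologs$to)
  hit <- match(symbols, from)
  ifelse(is.na(hit), symbols, to[hit])
}

# Slice a genome (named DNAStringSet) with 0-based half-open coordinates,
# returning the sense-strand sequence (reverse complement on '-').
.slice0 <- function(genome, chrom, start0, end0, strand) {
  if (!chrom %in% names(genome))
    stop("lookup error: chromosome '", chrom, "' absent from genome",
         call. = FALSE)
  L <- width(genome)[match(chrom, names(genome))]
  if (start0 < 0 || end0 > L || start0 >= end0)
    stop(sprintf("range error: [%d,%d) outside chromosome %s (length %d)",
                 start0, end0, chrom, L), call. = FALSE)
  s <- subseq(genome[[chrom]], start = start0 + 1L, end = end0)
  s <- DNAStringSet(toupper(chartr("Uu", "Tt", as.character(s))))[[1]]
  if (strand == "-") s <- reverseComplement(s)
  as.character(s)
}

#' Fetch sense-strand sequence for genomic intervals
#'
#' Returns uppercase DNA (U is treated as T) for each interval, reverse
#' complemented when the interval is on the minus strand, so the result
#' always reads in the transcript (sense) orientation.
#'
#' @param genome a named [Biostrings::DNAStringSet] (or path to a FASTA
#'   file, loaded with [Biostrings::readDNAStringSet]).
#' @param gr a [GenomicRanges::GRanges] (1-based inclusive, the Bioconductor
#'   convention) with strand `+` or `-`.
#' @return Character vector of sequences, one per range.
#' @export
fetchSequence <- function(genome, gr) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  ch <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sd <- as.character(GenomicRanges::strand(gr))
  sd[sd == "*"] <- "+"
  vapply(seq_along(gr), function(i) {
    .slice0(genome, ch[i], st[i] - 1L, en[i], sd[i])
  }, "")
}
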