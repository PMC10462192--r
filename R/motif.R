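.IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

.normalize_pattern <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("–|—", "-", x)  # en/em dash in gap bounds
}

.block_regex <- function(letters) {
  paste(vapply(strsplit(letters, "")[[1]], function(ch) {
    exp <- .IUPAC[[ch]]
    if (nchar(exp) == 1) exp else paste0("[", exp, "]")
  }, ""), collapse = "")
}

#' Gapped degenerate motif grammar
#'
#' A motif grammar is an ordered list of tokens: degenerate IUPAC blocks
#' (e.g. `YGCY`, with `Y` = C/T) separated by bounded gaps written
#' `(N)min-max`, `(N)k` (a fixed gap) or `N{min,max}`. The first and last
#' tokens must be blocks. `U` is treated as `T` so RNA-style patterns such
#' as the MBNL high-affinity site `YGCY(N)0-5YGCY` parse directly.
#'
#' @slot pattern the normalised pattern string.
#' @slot tokens list of token records (`type` "block" or "gap").
#' @aliases MotifGrammar-class
#' @export
setClass("MotifGrammar",
         representation(pattern = "character", tokens = "list"))

setMethod("show", "MotifGrammar", function(object) {
  blocks <- sum(vapply(object@tokens, function(t) t$type == "block", TRUE))
  cat(sprintf("MotifGrammar '%s': %d token(s), %d block(s), width %d-%d\n",
              object@pattern, length(object@tokens), blocks,
              grammarWidth(object)[1], grammarWidth(object)[2]))
})

#' @describeIn parseGrammar minimum and maximum match width of a grammar.
#' @param grammar a `MotifGrammar`.
#' @export
grammarWidth <- function(grammar) {
  lo <- hi <- 0L
  for (t in grammar@tokens) {
    if (t$type == "block") { lo <- lo + t$len; hi <- hi + t$len }
    else { lo <- lo + t$min; hi <- hi + t$max }
  }
  c(lo, hi)
}

#' Parse a motif grammar pattern
#'
#' @param pattern pattern string, e.g. `"YGCYGCY"`, `"YGCY(N)0-5YGCY"` or
#'   `"TGCT(N)3TGCT(N)13-18TGCY"`.
#' @return A [MotifGrammar-class] object.
#' @examples
#' parseGrammar("YGCY(N)0-5YGCY")
#' @export
parseGrammar <- function(pattern) {
  raw <- pattern
  pattern <- .normalize_pattern(pattern)
  tokens <- list()
  pos <- 1L
  n <- nchar(pattern)
  while (pos <= n) {
    rest <- substr(pattern, pos, n)
    m <- regmatches(rest, regexec("^\\(N\\)([0-9]+)(?:-([0-9]+))?", rest))[[1]]
    if (length(m)) {
      gmin <- as.integer(m[2])
      gmax <- if (nzchar(m[3])) as.integer(m[3]) else gmin
      if (gmin > gmax)
        stop("parse error in gap token '", m[1], "': min > max", call. = FALSE)
      tokens[[length(tokens) + 1L]] <- list(type = "gap", min = gmin,
                                            max = gmax)
      pos <- pos + nchar(m[1])
      next
    }
    m <- regmatches(rest, regexec("^N\\{([0-9]+),([0-9]+)\\}", rest))[[1]]
    if (length(m)) {
      gmin <- as.integer(m[2]); gmax <- as.integer(m[3])
      if (gmin > gmax)
        stop("parse error in gap token '", m[1], "': min > max", call. = FALSE)
      tokens[[length(tokens) + 1L]] <- list(type = "gap", min = gmin,
                                            max = gmax)
      pos <- pos + nchar(m[1])
      next
    }
    m <- regmatches(rest,
                    regexpr("^(?:[ACGTRYSWKMBDHV]|N(?!\\{))+", rest,
                            perl = TRUE))
    if (length(m) && nzchar(m)) {
      tokens[[length(tokens) + 1L]] <- list(
        type = "block", letters = m, len = nchar(m),
        regex = .block_regex(m)
      )
      pos <- pos + nchar(m)
      next
    }
    stop("parse error: unrecognised token at '",
         substr(pattern, pos, min(n, pos + 5L)), "' in pattern '", raw, "'",
         call. = FALSE)
  }
  if (length(tokens) == 0L)
    stop("parse error: empty pattern", call. = FALSE)
  if (tokens[[1L]]$type != "block" ||
      tokens[[length(tokens)]]$type != "block")
    stop("parse error: pattern must start and end with an IUPAC block",
         call. = FALSE)
  new("MotifGrammar", pattern = pattern, tokens = tokens)
}

.as_grammars <- function(grammars) {
  if (is(grammars, "MotifGrammar")) grammars <- list(grammars)
  lapply(grammars, function(g) if (is.character(g)) parseGrammar(g) else g)
}

# All start positions (1-based) where a fixed-width block matches,
# including overlapping matches, via a zero-width lookahead.
.match_starts <- function(sequence, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a sequence with a motif grammar
#'
#' Reports every match of the grammar, including overlapping matches and,
#' for gapped grammars, every distinct `(start, end)` realisation of the
#' gap lengths. Hits are ordered left to right by start and, at equal
#' start, shortest first. Offsets are 0-based half-open within the scanned
#' sequence (BED-style), in sense orientation.
#'
#' @param sequence DNA string (`U` is converted to `T`, case-insensitive).
#' @param grammar a [MotifGrammar-class] or pattern string.
#' @return `data.frame` with columns `start`, `end` (0-based half-open),
#'   `match`, `grammar`; zero rows when nothing matches.
#' @examples
#' scanGrammar("TGCTGCTGCT", "YGCYGCY")  # hits at offsets 0 and 3
#' @export
scanGrammar <- function(sequence, grammar) {
  if (is.character(grammar)) grammar <- parseGrammar(grammar)
  sequence <- .normalize_pattern(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      match = character(0), grammar = character(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  toks <- grammar@tokens
  blocks <- which(vapply(toks, function(t) t$type == "block", TRUE))
  starts <- lapply(blocks, function(i) .match_starts(sequence,
                                                     toks[[i]]$regex))
  if (any(lengths(starts) == 0L)) return(empty)
  # chain block matches across gaps; `nxt` = 1-based position after the
  # last matched block
  cand_start <- starts[[1L]]
  cand_nxt <- cand_start + toks[[blocks[1L]]]$len
  bi <- 2L
  for (ti in seq_along(toks)[-1L]) {
    t <- toks[[ti]]
    if (t$type != "gap") next  # consecutive blocks are merged by parsing
    nx <- toks[[blocks[bi]]]
    sj <- starts[[bi]]
    idx <- rep(seq_along(cand_start), each = length(sj))
    sjj <- rep(sj, times = length(cand_start))
    gap <- sjj - cand_nxt[idx]
    keep <- gap >= t$min & gap <= t$max
    if (!any(keep)) return(empty)
    cand_start <- cand_start[idx][keep]
    cand_nxt <- sjj[keep] + nx$len
    dup <- duplicated(paste(cand_start, cand_nxt))
    cand_start <- cand_start[!dup]; cand_nxt <- cand_nxt[!dup]
    bi <- bi + 1L
  }
  o <- order(cand_start, cand_nxt)
  s1 <- cand_start[o]; e1 <- cand_nxt[o]
  data.frame(
    start = s1 - 1L, end = e1 - 1L,
    match = substring(sequence, s1, e1 - 1L),
    grammar = grammar@pattern,
    stringsAsFactors = FALSE
  )
}

#' Splice-site-anchored intronic windows of SE events
#'
#' For each skipped-exon event, extracts up to two intronic windows of at
#' most `width` nt abutting the alternative exon's splice sites: the
#' `upstream-intron` window ends at the exon's 3'SS and the
#' `downstream-intron` window starts at its 5'SS. Windows are truncated at
#' the neighbouring constitutive exon when the intron is shorter than
#' `width`, never overlap exons of the event's own model, and their
#' sequences are returned in sense (transcript) orientation, so upstream
#' and downstream are mirrored on the minus strand. Zero-length introns
#' (abutting exons) yield no window, with a warning.
#'
#' @param x a [SplicingExperiment-class].
#' @param genome named [Biostrings::DNAStringSet] (or FASTA path).
#' @param width maximum window width in nt (default 500, the usual span
#'   scanned for intronic RNA-binding-protein motifs around SE splice
#'   sites).
#' @param events optional event ids to restrict to (SE events only).
#' @return `data.frame` with columns `eventID`, `side`, `chrom`, `start`,
#'   `end` (0-based half-open genomic), `strand`, `seq`.
#' @export
extractSpliceWindows <- function(x, genome, width = 500, events = NULL) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  rd <- rowData(x)
  sel <- rd$eventType == "SE"
  if (!is.null(events)) sel <- sel & rownames(x) %in% events
  rd <- rd[sel, , drop = FALSE]
  ids <- rownames(x)[sel]
  rows <- vector("list", 2L * length(ids))
  n_empty <- 0L
  for (i in seq_along(ids)) {
    plus <- rd$strand[i] == "+"
    if (plus) {
      up <- c(lo = rd$upEnd[i], hi = rd$altStart[i])
      dn <- c(lo = rd$altEnd[i], hi = rd$downStart[i])
      upW <- c(max(up["lo"], up["hi"] - width), up["hi"])
      dnW <- c(dn["lo"], min(dn["hi"], dn["lo"] + width))
    } else {
      up <- c(lo = rd$altEnd[i], hi = rd$upStart[i])
      dn <- c(lo = rd$downEnd[i], hi = rd$altStart[i])
      upW <- c(up["lo"], min(up["hi"], up["lo"] + width))
      dnW <- c(max(dn["lo"], dn["hi"] - width), dn["hi"])
    }
    for (side in c("upstream-intron", "downstream-intron")) {
      w <- if (side == "upstream-intron") upW else dnW
      if (w[2] <= w[1]) { n_empty <- n_empty + 1L; next }
      rows[[2L * (i - 1L) + (side == "downstream-intron") + 1L]] <-
        data.frame(
          eventID = ids[i], side = side, chrom = rd$chrom[i],
          start = as.integer(w[1]), end = as.integer(w[2]),
          strand = rd$strand[i],
          seq = .slice0(genome, rd$chrom[i], w[1], w[2], rd$strand[i]),
          stringsAsFactors = FALSE
        )
    }
  }
  if (n_empty > 0L)
    warning(n_empty, " zero-length intron window(s) omitted")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(eventID = character(0), side = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Motif presence per event
#'
#' An event is motif-positive when at least one grammar matches at least
#' once in either of its intronic windows (presence/absence, not hit
#' counts, so the downstream 2x2 test is well defined).
#'
#' @inheritParams extractSpliceWindows
#' @param grammars list of [MotifGrammar-class] objects or pattern strings.
#' @return Named logical vector over the requested SE events; events with
#'   no extractable window are dropped with a warning.
#' @export
motifPositive <- function(x, events, genome, grammars, width = 500) {
  grammars <- .as_grammars(grammars)
  win <- extractSpliceWindows(x, genome, width = width, events = events)
  if (nrow(win) == 0L) return(stats::setNames(logical(0), character(0)))
  have <- unique(win$eventID)
  lost <- setdiff(intersect(events,
                            rownames(x)[eventType(x) == "SE"]), have)
  if (length(lost))
    warning(length(lost), " event(s) without any window excluded")
  pos_win <- vapply(win$seq, function(s) {
    for (g in grammars) if (nrow(scanGrammar(s, g))) return(TRUE)
    FALSE
  }, TRUE, USE.NAMES = FALSE)
  tapply(pos_win, factor(win$eventID, levels = have), any)[have]
}

#' Motif enrichment in foreground versus background events
#'
#' Tests whether motif-positive events (see [motifPositive()]) are
#' over-represented among foreground SE events relative to background SE
#' events (background events also present in the foreground are removed
#' first). Odds ratio, Woolf CI and two-sided Fisher p-value as in
#' [geneSetEnrichment()].
#'
#' @inheritParams motifPositive
#' @param foreground,background character vectors of SE event ids.
#' @param correction zero-cell policy for [oddsRatioCI()].
#' @return One-row enrichment `data.frame`, with the per-event positivity
#'   in `attr(, "positive")`.
#' @export
motifEnrichment <- function(x, foreground, background, genome, grammars,
                            width = 500, correction = "on-zero") {
  background <- setdiff(background, foreground)
  pos <- motifPositive(x, c(foreground, background), genome, grammars,
                       width = width)
  fg <- pos[names(pos) %in% foreground]
  bg <- pos[names(pos) %in% background]
  out <- .enrich_row("motif", sum(fg), sum(!fg), sum(bg), sum(!bg),
                     correction)
  out$fdr <- out$pValue
  attr(out, "positive") <- pos
  out
}

#' Presence of an SRRM4-style intronic UGC site upstream of the 3'SS
#'
#' SRRM4 promotes neuronal microexon inclusion through an intronic UGC
#' motif close to the acceptor site, roughly 15 nt upstream of the 3'SS.
#' This predicate reports, per SE event, whether `TGC` (DNA alphabet)
#' occurs with its 3' end inside the offset window relative to the
#' alternative exon's 3'SS on the intronic side (default `(-25, -6)`,
#' operationalising "approximately 15 nt upstream"). A shorter upstream
#' intron truncates the search.
#'
#' @inheritParams extractSpliceWindows
#' @param window integer offsets (relative to the 3'SS; negative =
#'   intronic) that the `TGC` 3' end must fall in, bounds inclusive.
#' @return Named logical vector over the selected SE events.
#' @export
srrm4SitePresent <- function(x, genome, events = NULL,
                             window = c(-25, -6)) {
  span <- abs(window[1]) + 3L   # a TGC ending at the far bound needs 3 more nt
  win <- extractSpliceWindows(x, genome, width = span, events = events)
  win <- win[win$side == "upstream-intron", , drop = FALSE]
  rd <- rowData(x)
  sel <- rd$eventType == "SE"
  if (!is.null(events)) sel <- sel & rownames(x) %in% events
  ids <- rownames(x)[sel]
  out <- stats::setNames(rep(FALSE, length(ids)), ids)
  for (i in seq_len(nrow(win))) {
    u <- win$seq[i]           # sense; its right edge abuts the 3'SS
    L <- nchar(u)
    st <- .match_starts(u, "TGC")
    if (!length(st)) next
    off <- (st - 1L + 3L) - L  # 0 would mean abutting the exon
    out[win$eventID[i]] <- any(off >= window[1] & off <= window[2])
  }
  out
}

#' Export windows or motif hits as BED6
#'
#' Converts a window table from [extractSpliceWindows()] (optionally with
#' scan hits mapped back to the genome) to BED6 and writes it.
#'
#' @param windows window table from [extractSpliceWindows()].
#' @param path output path.
#' @param hits optional per-window hit tables: a list parallel to
#'   `windows` rows of [scanGrammar()] results; when given, hit intervals
#'   (window offsets, sense) are lifted to genome coordinates.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(windows, path, hits = NULL) {
  if (is.null(hits)) {
    bed <- data.frame(windows$chrom, windows$start, windows$end,
                      paste(windows$eventID, windows$side, sep = "|"),
                      0L, windows$strand)
  } else {
    rows <- list()
    for (i in seq_len(nrow(windows))) {
      h <- hits[[i]]
      if (is.null(h) || !nrow(h)) next
      plus <- windows$strand[i] == "+"
      gs <- if (plus) windows$start[i] + h$start else
        windows$end[i] - h$end
      ge <- if (plus) windows$start[i] + h$end else
        windows$end[i] - h$start
      rows[[length(rows) + 1L]] <- data.frame(
        windows$chrom[i], gs, ge,
        paste(windows$eventID[i], h$grammar, sep = "|"),
        0L, windows$strand[i]
      )
    }
    bed <- if (length(rows)) do.call(rbind, rows) else
      data.frame(character(0), integer(0), integer(0), character(0),
                 integer(0), character(0))
  }
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
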