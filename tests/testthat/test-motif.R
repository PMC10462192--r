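test_that("grammar parsing tokenises blocks and bounded gaps", {
  g1 <- parseGrammar("YGCY")
  expect_length(g1@tokens, 1)
  expect_equal(g1@tokens[[1]]$regex, "[CT]GC[CT]")

  g2 <- parseGrammar("YGCY(N)0-5YGCY")
  expect_length(g2@tokens, 3)
  expect_equal(g2@tokens[[2]][c("min", "max")], list(min = 0L, max = 5L))
  expect_equal(grammarWidth(g2), c(8L, 13L))

  # fixed gap (N)3 is a (3,3) gap; en-dash bounds also accepted
  g3 <- parseGrammar("TGCT(N)3TGCT(N)13–18TGCY")
  expect_length(g3@tokens, 5)
  expect_equal(g3@tokens[[2]][c("min", "max")], list(min = 3L, max = 3L))
  expect_equal(g3@tokens[[4]][c("min", "max")], list(min = 13L, max = 18L))

  g4 <- parseGrammar("ugcuN{1,2}ugcu")   # RNA letters, brace gap syntax
  expect_equal(g4@tokens[[1]]$letters, "TGCT")
  expect_equal(g4@tokens[[2]]$min, 1L)

  expect_error(parseGrammar("YGXZ"), "unrecognised token")
  expect_error(parseGrammar("YGCY(N)5-2YGCY"), "min > max")
  expect_error(parseGrammar("(N)1-2YGCY"), "start and end")
  expect_error(parseGrammar("YGCY(N)1-2"), "start and end")
})

test_that("scanner reports all overlapping hits and gap realisations", {
  expect_equal(scanGrammar("TGCTGCT", "YGCYGCY")[, c("start", "end")],
               data.frame(start = 0L, end = 7L))
  h <- scanGrammar("TGCTAAATGCT", "YGCY(N)0-5YGCY")
  expect_equal(h$start, 0L)
  expect_equal(h$end, 11L)
  expect_equal(h$match, "TGCTAAATGCT")
  expect_equal(nrow(scanGrammar("TGCTAAAAAATGCT", "YGCY(N)0-5YGCY")), 0L)
  h2 <- scanGrammar("TGCTGCTGCT", "YGCYGCY")
  expect_equal(h2$start, c(0L, 3L))
  expect_equal(nrow(scanGrammar("", "YGCY")), 0L)
})

test_that("scanner equals the brute-force realisation oracle on random DNA", {
  set.seed(53)
  grammars <- c("YGCYGCY", "YGCY(N)0-5YGCY", "TGCT(N)3TGCT(N)13-18TGCY")
  for (i in 1:60) {
    s <- rand_dna(sample(40:150, 1))
    for (g in grammars) {
      got <- scanGrammar(s, g)[, c("start", "end")]
      want <- oracle_scan(s, g)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("every reported hit re-matches its grammar in isolation", {
  set.seed(54)
  for (i in 1:25) {
    s <- rand_dna(200)
    h <- scanGrammar(s, "YGCY(N)0-5YGCY")
    for (j in seq_len(nrow(h))) {
      sub <- substr(s, h$start[j] + 1, h$end[j])
      expect_equal(sub, h$match[j])
      again <- scanGrammar(sub, "YGCY(N)0-5YGCY")
      expect_true(any(again$start == 0 & again$end == nchar(sub)))
    }
  }
})

test_that("splice windows abut the alternative exon and truncate at neighbours", {
  sim <- simulateDataset(simConfig(seed = 61, nGenes = 40,
                                   intronLenRange = c(300, 900)))
  win <- extractSpliceWindows(sim$se, sim$genome, width = 500)
  expect_true(all(win$end - win$start <= 500))
  rd <- as.data.frame(rowData(sim$se))
  for (i in seq_len(nrow(win))) {
    e <- rd[win$eventID[i], ]
    w <- win[i, ]
    up_side <- w$side == "upstream-intron"
    if (e$strand == "+") {
      if (up_side) expect_equal(w$end, e$altStart) else
        expect_equal(w$start, e$altEnd)
    } else {
      if (up_side) expect_equal(w$start, e$altEnd) else
        expect_equal(w$end, e$altStart)
    }
    # intronic: never overlaps the event's own exons
    exons <- rbind(c(e$upStart, e$upEnd), c(e$altStart, e$altEnd),
                   c(e$downStart, e$downEnd))
    expect_true(all(w$end <= exons[, 1] | w$start >= exons[, 2]))
    # truncation: window stays inside the intron
    intron_len <- if (xor(up_side, e$strand == "-"))
      e$altStart - e$upEnd else e$downStart - e$altEnd
  }
})

test_that("minus-strand windows mirror the plus-strand sense extraction", {
  toy <- make_toy_locus()
  win <- extractSpliceWindows(toy$se, toy$genome, width = 500)
  wp <- win[win$eventID == "evP", ]
  wm <- win[win$eventID == "evM", ]
  for (side in c("upstream-intron", "downstream-intron")) {
    expect_equal(wm$seq[wm$side == side], wp$seq[wp$side == side])
  }
  # sense content check against the hand-built locus
  up_expected <- substr(toy$sense, toy$flank + 1, toy$flank + toy$i1)
  expect_equal(wp$seq[wp$side == "upstream-intron"], up_expected)
})

test_that("zero-length introns yield no window, with a warning", {
  toy <- make_toy_locus()
  rd <- rowData(toy$se)
  rd$upEnd[1] <- rd$altStart[1]  # abutting exon on the plus-strand event
  se2 <- SplicingExperiment(inclusionCounts(toy$se),
                            skippingCounts(toy$se), rd, colData(toy$se))
  expect_warning(win <- extractSpliceWindows(se2, toy$genome),
                 "zero-length")
  expect_false(any(win$eventID == "evP" & win$side == "upstream-intron"))
})

test_that("planted motifs are recovered at their recorded window offsets", {
  sim <- simulateDataset(simConfig(seed = 71, nGenes = 50,
                                   motifFgProb = 1, motifBgProb = 1))
  win <- extractSpliceWindows(sim$se, sim$genome, width = 500)
  truth <- sim$truth[sim$truth$motifPlanted, ]
  expect_gt(nrow(truth), 10)
  for (i in seq_len(nrow(truth))) {
    w <- win[win$eventID == truth$eventID[i] &
               win$side == "downstream-intron", ]
    h <- scanGrammar(w$seq, sim$config@plantGrammar)
    expect_true(any(h$start == truth$motifWindowOffset[i]))
  }
})

test_that("minigene-style YGCY disruption removes all planted-site hits", {
  flank <- strrep("A", 30)
  gap1 <- strrep("A", 3); gap2 <- strrep("A", 14)
  s <- paste0(flank, "TGCT", gap1, "TGCT", gap2, "TGCT", flank)
  grammars <- c("YGCYGCY", "YGCY(N)0-5YGCY", "TGCT(N)3TGCT(N)13-18TGCY")
  expect_true(any(vapply(grammars,
                         function(g) nrow(scanGrammar(s, g)) > 0, TRUE)))
  # the minigene-style block substitutions TGCT -> GGCT / TGAT / TGTT
  mut <- paste0(flank, "GGCT", gap1, "TGAT", gap2, "TGTT", flank)
  for (g in grammars) expect_equal(nrow(scanGrammar(mut, g)), 0L)
})

test_that("motif enrichment recovers differential planting on events", {
  sim <- simulateDataset(simConfig(
    seed = 81, nGenes = 150, typeMix = c(SE = 1, MXE = 0, A5SS = 0,
                                         A3SS = 0, RI = 0),
    fractionMisSpliced = 0.2, motifFgProb = 0.7, motifBgProb = 0.2))
  fg <- sim$truth$eventID[sim$truth$isMisSpliced]
  bg <- setdiff(sim$truth$eventID, fg)
  en <- motifEnrichment(sim$se, fg, bg, sim$genome,
                        c("YGCYGCY", "YGCY(N)0-5YGCY"))
  expect_gt(en$oddsRatio, 2)
  expect_gt(en$ciLow, 1)
  pos <- attr(en, "positive")
  # planted events are always positive (plant-scan round trip)
  planted <- sim$truth$eventID[sim$truth$motifPlanted]
  expect_true(all(pos[names(pos) %in% planted]))
})

test_that("SRRM4-style UGC site detection honours the 3'SS offset window", {
  base <- strsplit(paste(rep("A", 300), collapse = ""), "")[[1]]
  place_tgc <- function(end_offset) {
    # end_offset: 3' end of TGC relative to the 3'SS (negative = intronic)
    s <- base
    i1 <- 300 + end_offset - 2
    s[i1:(i1 + 2)] <- c("T", "G", "C")
    paste(s, collapse = "")
  }
  mk <- function(upstream_seq) {
    toy <- make_toy_locus(i1 = 300)
    g <- as.character(toy$genome[["chrP"]])
    substr(g, toy$flank + 1, toy$flank + 300) <- upstream_seq
    list(se = toy$se[1, ], genome = Biostrings::DNAStringSet(c(chrP = g)))
  }
  at12 <- mk(place_tgc(-12))
  expect_true(srrm4SitePresent(at12$se, at12$genome)[["evP"]])
  at2 <- mk(place_tgc(-2))
  expect_false(srrm4SitePresent(at2$se, at2$genome)[["evP"]])
  none <- mk(paste(base, collapse = ""))
  expect_false(srrm4SitePresent(none$se, none$genome)[["evP"]])
  # boundary: -6 inside, -26 outside
  at6 <- mk(place_tgc(-6))
  expect_true(srrm4SitePresent(at6$se, at6$genome)[["evP"]])
  at26 <- mk(place_tgc(-26))
  expect_false(srrm4SitePresent(at26$se, at26$genome)[["evP"]])
})

test_that("windows and lifted hits export as BED6", {
  toy <- make_toy_locus()
  win <- extractSpliceWindows(toy$se, toy$genome)
  path <- withr::local_tempfile(fileext = ".bed")
  writeBed(win, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(nrow(bed), nrow(win))
  expect_true(all(bed$V2 < bed$V3))
  hits <- lapply(win$seq, scanGrammar, grammar = "YGCY")
  writeBed(win, path, hits = hits)
  bed2 <- read.delim(path, header = FALSE)
  # every lifted hit slices back out of the genome as a YGCY-class match
  for (i in seq_len(min(nrow(bed2), 20))) {
    gr <- GenomicRanges::GRanges(bed2$V1[i],
                                 IRanges::IRanges(bed2$V2[i] + 1, bed2$V3[i]),
                                 strand = bed2$V6[i])
    expect_match(fetchSequence(toy$genome, gr), "^[CT]GC[CT]$")
  }
})
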