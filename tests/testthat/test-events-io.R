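test_that("native-tsv events table round-trips events and counts exactly", {
  sim <- simulateDataset(simConfig(seed = 11, nGenes = 40,
                                   withGenome = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEventsTable(sim$se, path)
  back <- readEventsTable(path, dialect = "native-tsv",
                          sampleNames = colnames(sim$se))
  expect_identical(rownames(back), rownames(sim$se))
  expect_identical(inclusionCounts(back), inclusionCounts(sim$se))
  expect_identical(skippingCounts(back), skippingCounts(sim$se))
  for (col in c("eventType", "geneSymbol", "strand", "altStart", "altEnd",
                "upStart", "upEnd", "downStart", "downEnd"))
    expect_equal(rowData(back)[[col]], rowData(sim$se)[[col]])
})

test_that("rMATS-dialect tables split replicate counts and keep 0-based exon coords", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("ID", "GeneID", "geneSymbol", "chr", "strand",
          "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
          "downstreamES", "downstreamEE",
          "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
          "IncFormLen", "SkipFormLen", sep = "\t"),
    paste("1", "g1", "Ank2", "chr1", "+", "1000", "1012", "600", "700",
          "1500", "1600", "30,25,28", "5,6,4", "10,12,11", "20,18,22",
          "98", "49", sep = "\t"),
    paste("2", "g2", "Tanc2", "chr1", "-", "5000", "5100", "4600", "4700",
          "5500", "5600", "7,8,9", "1,2,3", "4,5,6", "7,8,9",
          "98", "49", sep = "\t")
  ), path)
  se <- readEventsTable(path, dialect = "rmats-jc", eventType = "SE")
  expect_equal(dim(se), c(2L, 6L))
  expect_equal(unname(inclusionCounts(se)[1, ]),
               c(30L, 25L, 28L, 10L, 12L, 11L))
  # exonStart_0base/exonEnd are already 0-based half-open: identity ingest
  expect_equal(rowData(se)$altStart[1], 1000L)
  expect_equal(rowData(se)$altEnd[1], 1012L)
  expect_equal(rowData(se)$altExonLength[1], 12L)
  # minus-strand event: transcript-upstream exon is the genomically right one
  expect_equal(rowData(se)$upStart[2], 5500L)
  expect_equal(rowData(se)$downEnd[2], 4700L)
  expect_equal(as.character(colData(se)$group),
               rep(c("sample1", "sample2"), each = 3))
})

test_that("degenerate and malformed event tables are handled as specified", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  se <- readEventsTable(empty, dialect = "native-tsv")
  expect_equal(nrow(se), 0L)

  sim <- simulateDataset(simConfig(seed = 2, nGenes = 5,
                                   withGenome = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEventsTable(sim$se, path)
  expect_error(readEventsTable(path, sampleNames = c("a", "b")),
               "configuration error")

  # corrupt one count field and expect a parse error naming the line
  lines <- readLines(path)
  lines[3] <- sub("(\t)(\\d+(,\\d+)+)(\t[^\t]*)$", "\\1oops\\4", lines[3])
  writeLines(lines, path)
  expect_error(readEventsTable(path), "line 3")
})

test_that("missing count fields become missing samples, not zeros", {
  sim <- simulateDataset(simConfig(seed = 5, nGenes = 5,
                                   withGenome = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEventsTable(sim$se, path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$ijc[1] <- sub("^[0-9]+", "NA", tab$ijc[1])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readEventsTable(path)
  expect_true(is.na(inclusionCounts(back)[1, 1]))
  expect_false(any(is.na(inclusionCounts(back)[-1, ])))
})

test_that("GMT parsing dedups, case-normalises and validates", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "SFARI_S1\tdesc\tSCN2A\tANK2",
    "DUP\tdesc\tANK2\tANK2",
    "CASE\tdesc\tank2\tANK2"
  ), path)
  sets <- readGeneSets(path)
  expect_equal(sets$SFARI_S1, c("SCN2A", "ANK2"))
  expect_equal(sets$DUP, "ANK2")
  expect_equal(sets$CASE, "ANK2")

  writeLines(c("OK\td\tA", "BAD\tonly-two-fields"), path)
  expect_error(readGeneSets(path), "line 2")

  sets <- list(S1 = c("A", "B"), S2 = c("C"))
  writeGeneSets(sets, path)
  expect_equal(readGeneSets(path)[1:2], sets)
})

test_that("fetchSequence returns sense-strand uppercase DNA", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "aacgtTACG", chr2 = "ACGT"))
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(1, 1, 1), end = c(4, 4, 4)),
    strand = c("+", "-", "+")
  )
  seqs <- fetchSequence(genome, gr)
  expect_equal(seqs[1], "AACG")           # casefolded
  expect_equal(seqs[2], "CGTT")           # reverse complement of AACG
  expect_equal(seqs[3], "ACGT")
  expect_error(fetchSequence(genome, GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(1, 2))), "lookup error")
  expect_error(fetchSequence(genome, GenomicRanges::GRanges(
    "chr2", IRanges::IRanges(2, 9))), "range error")
})

test_that("minus-strand fetch equals reverse complement of plus-strand fetch", {
  set.seed(42)
  genome <- Biostrings::DNAStringSet(c(chrR = rand_dna(2000)))
  st <- sample(1500, 50)
  gr_p <- GenomicRanges::GRanges("chrR", IRanges::IRanges(st, st + 99),
                                 strand = "+")
  gr_m <- GenomicRanges::GRanges("chrR", IRanges::IRanges(st, st + 99),
                                 strand = "-")
  plus <- fetchSequence(genome, gr_p)
  minus <- fetchSequence(genome, gr_m)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(plus)))
  expect_equal(minus, unname(rc))
})

test_that("coordinate convention conversion is an identity round trip", {
  set.seed(7)
  s1 <- sample(1e6, 1000)
  e1 <- s1 + sample(1000, 1000, replace = TRUE)
  z <- coordsTo0Based(s1, e1)
  back <- coordsTo1Based(z$start, z$end)
  expect_identical(back$start, s1)
  expect_identical(back$end, e1)
  expect_true(all(z$start < z$end))
})

test_that("sample sheets round-trip with covariates intact", {
  cd <- S4Vectors::DataFrame(group = c("case", "control"),
                             ctg = c(750.5, NA),
                             row.names = c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSampleTable(cd, path)
  back <- readSampleTable(path)
  expect_equal(rownames(back), c("s1", "s2"))
  expect_equal(back$ctg, c(750.5, NA))
  writeLines(c("sample_id\tgroup", "a\tx", "a\ty"), path)
  expect_error(readSampleTable(path), "unique")
})

test_that("ortholog mapping falls back to case-insensitive identity", {
  map <- data.frame(from = "Scn2a1", to = "SCN2A")
  expect_equal(mapSymbols(c("scn2a1", "Ank2"), map), c("SCN2A", "ANK2"))
  expect_equal(mapSymbols("ank2"), "ANK2")
})
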