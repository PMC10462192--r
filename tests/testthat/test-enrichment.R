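test_that("Fisher p matches enumeration oracle and base R on random tables", {
  expect_equal(fisherExact2x2(10, 10, 10, 10), 1)
  expect_equal(fisherExact2x2(20, 10, 10, 20), oracle_fisher(20, 10, 10, 20),
               tolerance = 1e-12)
  expect_equal(fisherExact2x2(0, 10, 10, 0), oracle_fisher(0, 10, 10, 0),
               tolerance = 1e-12)
  set.seed(17)
  for (i in 1:50) {
    tb <- sample(0:25, 4, replace = TRUE)
    if (sum(tb) == 0) next
    p <- fisherExact2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, oracle_fisher(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    # independent cross-check against the standard implementation
    pf <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(p, pf, tolerance = 1e-7)
  }
})

test_that("odds ratio, Haldane-Anscombe correction and Woolf CI are exact", {
  expect_equal(oddsRatioCI(10, 10, 10, 10)$oddsRatio, 1)
  expect_equal(oddsRatioCI(20, 10, 10, 20)$oddsRatio, 4)
  # zero cell: 0.5 added to all four cells -> (5.5*7.5)/(0.5*3.5)
  z <- oddsRatioCI(5, 0, 3, 7)
  expect_true(z$corrected)
  expect_equal(z$oddsRatio, (5.5 * 7.5) / (0.5 * 3.5), tolerance = 1e-12)
  # Woolf CI from the corrected cells
  se <- sqrt(1 / 5.5 + 1 / 0.5 + 1 / 3.5 + 1 / 7.5)
  expect_equal(z$ciLow, exp(log(z$oddsRatio) - qnorm(0.975) * se))
  expect_equal(z$ciHigh, exp(log(z$oddsRatio) + qnorm(0.975) * se))
  expect_false(oddsRatioCI(5, 1, 3, 7, correction = "never")$corrected)
  expect_true(oddsRatioCI(5, 1, 3, 7, correction = "always")$corrected)
  expect_error(oddsRatioCI(-1, 1, 1, 1), "validation")
})

test_that("OR obeys inversion and row-swap symmetries", {
  set.seed(23)
  for (i in 1:100) {
    tb <- sample(1:30, 4, replace = TRUE)
    o1 <- oddsRatioCI(tb[1], tb[2], tb[3], tb[4])$oddsRatio
    o2 <- oddsRatioCI(tb[2], tb[1], tb[4], tb[3])$oddsRatio
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
    # swapping foreground/background rows inverts OR, preserves p
    o3 <- oddsRatioCI(tb[3], tb[4], tb[1], tb[2])$oddsRatio
    expect_equal(o3, 1 / o1, tolerance = 1e-12)
    expect_equal(fisherExact2x2(tb[1], tb[2], tb[3], tb[4]),
                 fisherExact2x2(tb[3], tb[4], tb[1], tb[2]),
                 tolerance = 1e-12)
  }
})

test_that("gene-set enrichment tabulates against the universe as specified", {
  universe <- sprintf("G%03d", 1:100)
  set20 <- universe[1:20]
  mis <- c(universe[1:6], universe[30:33])  # 10 mis-spliced, 6 in set
  en <- geneSetEnrichment(mis, universe, list(S = set20))
  expect_equal(unlist(en[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(6, 4, 14, 76))
  expect_equal(en$oddsRatio, (6 * 76) / (4 * 14), tolerance = 1e-12)

  expect_error(geneSetEnrichment(mis, character(), list(S = set20)),
               "empty gene universe")
  expect_error(geneSetEnrichment(c(mis, "NOT_THERE"), universe,
                                 list(S = set20)), "subset")
  # set spanning the whole universe: corrected, degenerate-flagged
  full <- geneSetEnrichment(mis, universe, list(ALL = universe))
  expect_true(full$degenerate)
  expect_true(is.finite(full$oddsRatio))
})

test_that("uniformly drawn foregrounds give null-calibrated set enrichment", {
  set.seed(41)
  universe <- sprintf("G%04d", 1:500)
  sets <- lapply(1:38, function(i) sample(universe, sample(20:80, 1)))
  names(sets) <- paste0("S", 1:38)
  flagged <- numeric(50)
  med_or <- numeric(50)
  for (i in 1:50) {
    mis <- sample(universe, 50)
    en <- geneSetEnrichment(mis, universe, sets)
    flagged[i] <- mean(en$fdr < 0.05)
    med_or[i] <- median(en$oddsRatio)
  }
  expect_lte(mean(flagged), 0.08)
  expect_gt(median(med_or), 0.7)
  expect_lt(median(med_or), 1.4)
})

test_that("microexon disproportion uses mis-spliced SE vs all evaluable SE", {
  n_bg <- 1000; n_fg <- 100
  is_mis <- c(rep(TRUE, n_fg), rep(FALSE, n_bg - n_fg))
  is_mie <- c(rep(TRUE, 10), rep(FALSE, 90),        # 10/100 in foreground
              rep(TRUE, 30), rep(FALSE, 870))       # 40/1000 in background
  res <- S4Vectors::DataFrame(
    eventID = paste0("e", 1:n_bg), eventType = "SE",
    geneID = paste0("g", 1:n_bg), geneSymbol = paste0("g", 1:n_bg),
    fdr = 0.5, dpsi = 0, isMisSpliced = is_mis, isMicroexon = is_mie
  )
  en <- microexonEnrichment(res)
  expect_equal(unlist(en[, c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 90, 40, 960))
  expect_equal(en$oddsRatio, (10 * 960) / (90 * 40), tolerance = 1e-12)
  # equal proportions -> OR 1
  res$isMicroexon <- rep(c(TRUE, FALSE, FALSE, FALSE), 250)
  expect_equal(microexonEnrichment(res)$oddsRatio, 1, tolerance = 1e-12)
  # no mis-spliced SE in scope -> degenerate table with warning
  res$isMisSpliced <- FALSE
  expect_warning(en0 <- microexonEnrichment(res), "degenerate")
  expect_equal(en0$a + en0$b, 0)
})

test_that("overlap test builds the A/B/universe table and handles extremes", {
  universe <- sprintf("U%04d", 1:1000)
  A <- universe[1:100]
  B <- c(universe[71:100], universe[101:150])  # |B| = 80, overlap 30
  ov <- overlapTest(A, B, universe)
  expect_equal(unlist(ov[, c("a", "b", "c", "d")], use.names = FALSE),
               c(30, 70, 50, 850))
  expect_equal(ov$oddsRatio, (30 * 850) / (70 * 50), tolerance = 1e-12)
  disj <- overlapTest(universe[1:50], universe[51:100], universe)
  expect_lt(disj$oddsRatio, 1)
  same <- overlapTest(A, A, universe)
  expect_gt(same$oddsRatio, 100)
  expect_error(overlapTest(c(A, "XX"), B, universe), "universe smaller")
})

test_that("DPSI concordance counts signs and excludes zeros", {
  a <- c(e1 = -0.2, e2 = 0.2)
  b <- c(e1 = -0.3, e2 = -0.1)
  cc <- dpsiConcordance(a, b)
  expect_equal(cc$concordant, 0.5)
  expect_equal(cc$bothNegativeAmongConcordant, 1)
  same <- dpsiConcordance(c(x = 0.1, y = -0.4), c(x = 0.5, y = -0.2))
  expect_equal(same$concordant, 1)
  zero <- dpsiConcordance(c(x = 0, y = -0.4), c(x = 0.5, y = -0.2))
  expect_equal(zero$nSigned, 1)
  none <- dpsiConcordance(c(p = 0.1), c(q = 0.2))
  expect_equal(none$n, 0)
  expect_true(is.na(none$concordant))
})

test_that("two analyses compare by gene overlap, event overlap and concordance", {
  cfg <- simConfig(nGenes = 150, coverageMean = 200,
                   dpsiSign = "negative", withGenome = FALSE, nSets = 0)
  simA <- simulateDataset(cfg, seed = 301)
  # same event universe, same planted truth, fresh counts
  simB <- simulateDataset(cfg, seed = 301)
  inc <- inclusionCounts(simB$se)
  set.seed(302)
  jitter <- matrix(rbinom(length(inc), 3, 0.5), nrow(inc))
  simB$se <- SplicingExperiment(inc + jitter, skippingCounts(simB$se),
                                rowData(simB$se), colData(simB$se))
  resA <- diffSplicing(simA$se, seed = 301)
  resB <- diffSplicing(simB$se, seed = 303)
  cmp <- compareDiffResults(resA, resB)
  # the same effects are planted, so overlaps are far beyond chance
  expect_gt(cmp$genes$oddsRatio, 5)
  expect_lt(cmp$genes$pValue, 1e-4)
  expect_gt(cmp$events$oddsRatio, 5)
  # forced-exclusion effects agree in sign and are negative in both
  expect_gt(cmp$concordance$concordant, 0.9)
  expect_equal(cmp$concordance$bothNegativeAmongConcordant, 1)
})
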