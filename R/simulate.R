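#' @importFrom stats rpois rbinom rnbinom rbeta runif
NULL

#' Simulation configuration
#'
#' Describes a complete synthetic splicing study: gene/event layout, group
#' sizes, the beta-binomial junction-count model, planted mis-splicing
#' effects (optionally concentrated in one gene set or on microexons),
#' planted intronic motifs, and an optional per-sample dose covariate.
#' Built with [simConfig()]; all fields are validated before any sampling.
#'
#' @aliases SimConfig-class
#' @export
setClass("SimConfig", representation(
  seed = "numeric", nGenes = "numeric", meanEventsPerGene = "numeric",
  typeMix = "numeric", microexonFrac = "numeric",
  nCases = "numeric", nControls = "numeric",
  fractionMisSpliced = "numeric", dpsiRange = "numeric",
  dpsiSign = "character",
  coverageMean = "numeric", coverageSize = "numeric",
  bbPrecision = "numeric",
  nSets = "numeric", setSizeRange = "numeric",
  enrichedSetSize = "numeric", enrichedSetOR = "numeric",
  enrichedSetBaseRate = "numeric",
  microexonOR = "numeric",
  motifFgProb = "numeric", motifBgProb = "numeric",
  plantGrammar = "character",
  covariateName = "character", covariateRange = "numeric",
  exonLenRange = "numeric", flankLen = "numeric",
  intronLenRange = "numeric", spacerLen = "numeric",
  withGenome = "logical"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  tm <- object@typeMix
  if (!setequal(names(tm), .EVENT_TYPES) || abs(sum(tm) - 1) > 1e-8)
    msg <- c(msg, "typeMix must be named SE/MXE/A5SS/A3SS/RI and sum to 1")
  probs <- c(object@microexonFrac, object@fractionMisSpliced,
             object@motifFgProb, object@motifBgProb)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@nCases < 1 || object@nControls < 1)
    msg <- c(msg, "need at least one sample per group")
  for (rg in list(object@dpsiRange, object@setSizeRange,
                  object@exonLenRange, object@intronLenRange)) {
    if (length(rg) != 2 || any(is.na(rg)) || rg[1] > rg[2])
      msg <- c(msg, "ranges must be length-2, ordered, non-missing")
  }
  if (object@dpsiRange[1] < 0 || object@dpsiRange[2] > 0.96)
    msg <- c(msg, "dpsiRange must lie in [0, 0.96]")
  if (!is.na(object@enrichedSetSize)) {
    if (object@enrichedSetSize > object@nGenes)
      msg <- c(msg, "infeasible config: enriched set larger than gene pool")
    if (is.na(object@enrichedSetOR) || is.na(object@enrichedSetBaseRate) ||
        object@enrichedSetBaseRate <= 0 || object@enrichedSetBaseRate >= 1)
      msg <- c(msg,
               "enriched-set design needs an odds ratio and base rate in (0,1)")
  }
  if (object@microexonOR != 1) {
    pm <- .mie_plant_rate(object)
    if (is.na(pm) || pm > 1)
      msg <- c(msg, sprintf(
        "infeasible config: microexon planting rate %.2f exceeds 1", pm))
  }
  if (object@bbPrecision <= 0)
    msg <- c(msg, "bbPrecision must be positive (Inf for pure binomial)")
  if (length(msg)) msg else TRUE
})

# Planting rate on microexon SE events implied by the target disproportion
# odds ratio of the miE 2x2 (foreground = mis-spliced SE, background = all
# SE, so the background miE fraction is microexonFrac itself).
.mie_plant_rate <- function(cfg) {
  q0 <- cfg@microexonFrac
  p0 <- cfg@fractionMisSpliced
  if (q0 <= 0 || q0 >= 1 || p0 <= 0) return(NA_real_)
  odds1 <- cfg@microexonOR * q0 / (1 - q0)
  p1 <- odds1 / (1 + odds1)          # target miE share among mis-spliced
  p1 * p0 * (1 - q0) / (q0 * (1 - p1))
}

#' Build a simulation configuration
#'
#' Defaults describe a bulk RNA-seq splicing study with eight case and
#' eight control replicates, ~100 junction reads per event and sample
#' (negative-binomial across events), beta-binomial inclusion counts with
#' precision 50 (between-replicate biological overdispersion), a 70/10/8/8/4
#' SE/MXE/A5SS/A3SS/RI event mixture, 5% of SE exons drawn from the
#' microexon range (3-33 nt), 10% of events truly mis-spliced with
#' |DPSI| ~ U(0.15, 0.5), and genes laid out 50/50 on both strands.
#'
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the configuration including this seed.
#' @param nGenes,meanEventsPerGene gene count and mean events per gene
#'   (each gene has at least one event).
#' @param typeMix named event-type mixture over SE/MXE/A5SS/A3SS/RI.
#' @param microexonFrac fraction of SE exons drawn from 3-33 nt.
#' @param nCases,nControls group sizes.
#' @param fractionMisSpliced fraction of events with a true effect.
#' @param dpsiRange range of true |DPSI|.
#' @param dpsiSign `"random"`, `"negative"` (forced exclusion) or
#'   `"positive"`.
#' @param coverageMean,coverageSize negative-binomial mean and size of the
#'   per-event per-sample total junction reads.
#' @param bbPrecision beta-binomial precision of the inclusion fraction
#'   (`Inf` = pure binomial).
#' @param nSets,setSizeRange number and size range of random gene sets.
#' @param enrichedSetSize,enrichedSetOR,enrichedSetBaseRate optional
#'   gene-set effect design: genes inside a designated set of this size are
#'   mis-spliced with odds `enrichedSetOR` times the base odds
#'   (`enrichedSetBaseRate` outside the set); each selected gene gets one
#'   mis-spliced event. Overrides `fractionMisSpliced`/`microexonOR`.
#' @param microexonOR target microexon disproportion odds ratio (see
#'   [microexonEnrichment()]); 1 = no disproportion.
#' @param motifFgProb,motifBgProb probability of planting one instance of
#'   `plantGrammar` in the downstream intronic window of a truly
#'   mis-spliced (foreground) / unaffected (background) SE event.
#' @param plantGrammar grammar pattern planted into introns.
#' @param covariateName,covariateRange optional per-case-sample dose
#'   covariate (e.g. CTG repeat length): each case sample's effect size is
#'   scaled by `value / max(value)`.
#' @param exonLenRange,flankLen,intronLenRange,spacerLen gene geometry (nt).
#' @param withGenome build the synthetic genome sequence (needed for motif
#'   scanning; skip for count-only studies).
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1, nGenes = 300, meanEventsPerGene = 2,
                      typeMix = c(SE = 0.7, MXE = 0.1, A5SS = 0.08,
                                  A3SS = 0.08, RI = 0.04),
                      microexonFrac = 0.05,
                      nCases = 8, nControls = 8,
                      fractionMisSpliced = 0.1,
                      dpsiRange = c(0.15, 0.5),
                      dpsiSign = c("random", "negative", "positive"),
                      coverageMean = 100, coverageSize = 10,
                      bbPrecision = 50,
                      nSets = 38, setSizeRange = c(20, 80),
                      enrichedSetSize = NA_real_,
                      enrichedSetOR = NA_real_,
                      enrichedSetBaseRate = NA_real_,
                      microexonOR = 1,
                      motifFgProb = 0.2, motifBgProb = 0.2,
                      plantGrammar = "YGCY(N)0-5YGCY",
                      covariateName = NA_character_,
                      covariateRange = c(200, 800),
                      exonLenRange = c(80, 300), flankLen = 150,
                      intronLenRange = c(600, 1200), spacerLen = 100,
                      withGenome = TRUE) {
  dpsiSign <- match.arg(dpsiSign)
  new("SimConfig", seed = seed, nGenes = nGenes,
      meanEventsPerGene = meanEventsPerGene,
      typeMix = typeMix[.EVENT_TYPES], microexonFrac = microexonFrac,
      nCases = nCases, nControls = nControls,
      fractionMisSpliced = fractionMisSpliced, dpsiRange = dpsiRange,
      dpsiSign = dpsiSign, coverageMean = coverageMean,
      coverageSize = coverageSize, bbPrecision = bbPrecision,
      nSets = nSets, setSizeRange = setSizeRange,
      enrichedSetSize = enrichedSetSize, enrichedSetOR = enrichedSetOR,
      enrichedSetBaseRate = enrichedSetBaseRate,
      microexonOR = microexonOR, motifFgProb = motifFgProb,
      motifBgProb = motifBgProb, plantGrammar = plantGrammar,
      covariateName = covariateName, covariateRange = covariateRange,
      exonLenRange = exonLenRange, flankLen = flankLen,
      intronLenRange = intronLenRange, spacerLen = spacerLen,
      withGenome = withGenome)
}

#' @describeIn simConfig return a copy with some fields replaced.
#' @param config a `SimConfig`.
#' @param ... fields to replace.
#' @export
updateConfig <- function(config, ...) {
  repl <- list(...)
  obj <- config
  for (nm in names(repl)) slot(obj, nm) <- repl[[nm]]
  validObject(obj)
  obj
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d genes, ~%.1f events/gene, %dv%d samples, seed %d\n",
    object@nGenes, object@meanEventsPerGene, as.integer(object@nCases),
    as.integer(object@nControls), as.integer(object@seed)))
  cat(sprintf("  mis-spliced fraction %.3g, |DPSI| ~ U(%.2f, %.2f), sign %s\n",
              object@fractionMisSpliced, object@dpsiRange[1],
              object@dpsiRange[2], object@dpsiSign))
  cat(sprintf("  coverage NB(mean=%g, size=%g), beta-binomial precision %g\n",
              object@coverageMean, object@coverageSize, object@bbPrecision))
})

# Random DNA depleted of the GC dinucleotide, so that YGCY-family motif
# presence in synthetic introns is entirely generator-controlled (random
# DNA would contain a YGCY-class match in nearly every 500 nt window).
.rand_seq_nogc <- function(n) {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
             collapse = "")
  gsub("GC", "GA", s, fixed = TRUE)
}

.revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Sample one concrete realisation of a grammar: degenerate letters drawn
# uniformly from their IUPAC sets, gap lengths uniform in bounds, gap
# letters from {A, T} so the realisation stays exactly the planted site.
.realize_grammar <- function(grammar) {
  parts <- vapply(grammar@tokens, function(t) {
    if (t$type == "block") {
      paste(vapply(strsplit(t$letters, "")[[1]], function(ch) {
        sample(strsplit(.IUPAC[[ch]], "")[[1]], 1L)
      }, ""), collapse = "")
    } else {
      k <- if (t$max > t$min) sample(t$min:t$max, 1L) else t$min
      if (k == 0L) "" else
        paste(sample(c("A", "T"), k, replace = TRUE), collapse = "")
    }
  }, "")
  paste(parts, collapse = "")
}

#' Simulate a complete splicing dataset with recorded ground truth
#'
#' Draws a full synthetic study from a [SimConfig-class]: event annotation
#' and a synthetic genome with real exon/intron structure (planted motifs
#' at recorded positions), beta-binomial junction counts for every sample,
#' random gene sets (plus the designated enriched set, when configured),
#' per-sample covariates, and a truth table covering every emitted event.
#' Deterministic given the configuration seed.
#'
#' @param config a [SimConfig-class].
#' @param seed optional override of `config@seed` (convenience for
#'   multi-seed studies).
#' @return A list of class `missplice_sim` with elements `se`
#'   ([SplicingExperiment-class]), `genome` (named
#'   [Biostrings::DNAStringSet] or `NULL`), `geneSets`, `truth`
#'   (`data.frame`), `config`.
#' @export
simulateDataset <- function(config, seed = NULL) {
  validObject(config)
  if (!is.null(seed)) config@seed <- seed
  set.seed(as.integer(config@seed))
  cfg <- config

  ## ---- gene/event layout -------------------------------------------------
  nG <- as.integer(cfg@nGenes)
  nEv <- 1L + rpois(nG, max(cfg@meanEventsPerGene - 1, 0))
  geneIdx <- rep(seq_len(nG), nEv)
  E <- length(geneIdx)
  geneID <- sprintf("G%05d", seq_len(nG))
  geneSym <- sprintf("GN%05d", seq_len(nG))
  geneStrand <- sample(c("+", "-"), nG, replace = TRUE)
  type <- sample(names(cfg@typeMix), E, replace = TRUE, prob = cfg@typeMix)
  eventID <- sprintf("ev%06d", seq_len(E))
  isSE <- type == "SE"
  isMiE_exon <- isSE & runif(E) < cfg@microexonFrac
  altLen <- integer(E)
  altLen[isMiE_exon] <- sample(3:33, sum(isMiE_exon), replace = TRUE)
  longIdx <- !isMiE_exon
  altLen[longIdx] <- sample(cfg@exonLenRange[1]:cfg@exonLenRange[2],
                            sum(longIdx), replace = TRUE)

  ## ---- truth: which events carry an effect -------------------------------
  inEnriched <- rep(FALSE, nG)
  if (!is.na(cfg@enrichedSetSize)) {
    enrichedGenes <- sample(nG, cfg@enrichedSetSize)
    inEnriched[enrichedGenes] <- TRUE
    p0 <- cfg@enrichedSetBaseRate
    odds1 <- cfg@enrichedSetOR * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    geneMis <- runif(nG) < ifelse(inEnriched, p1, p0)
    isMis <- rep(FALSE, E)
    for (g in which(geneMis)) {
      ev_g <- which(geneIdx == g)
      isMis[if (length(ev_g) == 1L) ev_g else sample(ev_g, 1L)] <- TRUE
    }
  } else if (cfg@microexonOR != 1) {
    pMiE <- .mie_plant_rate(cfg)
    pEv <- ifelse(isMiE_exon, pMiE, cfg@fractionMisSpliced)
    isMis <- runif(E) < pEv
  } else {
    isMis <- runif(E) < cfg@fractionMisSpliced
  }

  dpsi <- numeric(E)
  nMis <- sum(isMis)
  if (nMis) {
    mag <- runif(nMis, cfg@dpsiRange[1], cfg@dpsiRange[2])
    sgn <- switch(cfg@dpsiSign,
                  random = sample(c(-1, 1), nMis, replace = TRUE),
                  negative = rep(-1, nMis),
                  positive = rep(1, nMis))
    dpsi[isMis] <- mag * sgn
  }
  lo <- pmax(0.05, 0.02 - pmin(dpsi, 0))
  hi <- pmin(0.95, 0.98 - pmax(dpsi, 0))
  psiCtrl <- runif(E, lo, hi)

  ## ---- samples and covariate --------------------------------------------
  nCa <- as.integer(cfg@nCases); nCo <- as.integer(cfg@nControls)
  sampleID <- c(sprintf("ctrl_%02d", seq_len(nCo)),
                sprintf("case_%02d", seq_len(nCa)))
  group <- rep(c("control", "case"), c(nCo, nCa))
  doseScale <- rep(1, nCa)
  covValues <- rep(NA_real_, nCo + nCa)
  if (!is.na(cfg@covariateName)) {
    v <- runif(nCa, cfg@covariateRange[1], cfg@covariateRange[2])
    doseScale <- v / max(v)
    covValues[group == "case"] <- v
  }

  ## ---- counts: NB totals, beta-binomial inclusion ------------------------
  lImap <- c(SE = 2, MXE = 2, A5SS = 1, A3SS = 1, RI = 2)
  lSmap <- c(SE = 1, MXE = 2, A5SS = 1, A3SS = 1, RI = 1)
  lI <- lImap[type]; lS <- lSmap[type]
  n <- nCo + nCa
  psiTrue <- matrix(psiCtrl, E, n)
  caseCols <- which(group == "case")
  for (j in seq_along(caseCols))
    psiTrue[, caseCols[j]] <- pmin(pmax(psiCtrl + dpsi * doseScale[j],
                                        0.01), 0.99)
  mu <- psiTrue * lI / (psiTrue * lI + (1 - psiTrue) * lS)
  tot <- matrix(rnbinom(E * n, mu = cfg@coverageMean,
                        size = cfg@coverageSize), E, n)
  theta <- if (is.finite(cfg@bbPrecision)) {
    matrix(rbeta(E * n, mu * cfg@bbPrecision,
                 (1 - mu) * cfg@bbPrecision), E, n)
  } else mu
  inc <- matrix(rbinom(E * n, as.vector(tot), as.vector(theta)), E, n)
  skp <- tot - inc
  storage.mode(inc) <- storage.mode(skp) <- "integer"
  dimnames(inc) <- dimnames(skp) <- list(eventID, sampleID)

  ## ---- genome and coordinates -------------------------------------------
  plantFlag <- rep(FALSE, E)
  plantOffset <- rep(NA_integer_, E)
  plantMatch <- rep(NA_character_, E)
  chrom <- rep("chrS", E)
  coords <- matrix(NA_integer_, E, 8,
                   dimnames = list(NULL, c("altStart", "altEnd",
                                           "alt2Start", "alt2End",
                                           "upStart", "upEnd",
                                           "downStart", "downEnd")))
  genome <- NULL
  if (cfg@withGenome) {
    grammar <- parseGrammar(cfg@plantGrammar)
    f <- as.integer(cfg@flankLen)
    i1 <- sample(cfg@intronLenRange[1]:cfg@intronLenRange[2], E,
                 replace = TRUE)
    i2 <- sample(cfg@intronLenRange[1]:cfg@intronLenRange[2], E,
                 replace = TRUE)
    wantPlant <- isSE & (runif(E) < ifelse(isMis, cfg@motifFgProb,
                                           cfg@motifBgProb))
    pieces <- vector("list", E)
    cursor <- 0L
    spacer <- as.integer(cfg@spacerLen)
    for (e in seq_len(E)) {
      L <- 2L * f + i1[e] + altLen[e] + i2[e]
      seqs <- c(.rand_seq_nogc(f), .rand_seq_nogc(i1[e]),
                .rand_seq_nogc(altLen[e]), .rand_seq_nogc(i2[e]),
                .rand_seq_nogc(f))
      if (wantPlant[e]) {
        site <- .realize_grammar(grammar)
        wlen <- nchar(site)
        maxoff <- min(i2[e], 500L) - wlen
        off <- sample.int(maxoff + 1L, 1L) - 1L
        substr(seqs[4], off + 1L, off + wlen) <- site
        plantFlag[e] <- TRUE
        plantOffset[e] <- off
        plantMatch[e] <- site
      }
      sense <- paste(seqs, collapse = "")
      o <- cursor + spacer
      # sense intervals within the locus (0-based half-open)
      sUp <- c(0L, f)
      sAlt <- c(f + i1[e], f + i1[e] + altLen[e])
      sDown <- c(L - f, L)
      sAlt2 <- if (type[e] == "MXE") {
        a2 <- min(altLen[e], 100L)
        c(sAlt[2] + 150L, sAlt[2] + 150L + a2)
      } else c(NA_integer_, NA_integer_)
      strand_e <- geneStrand[geneIdx[e]]
      g <- function(iv) {
        if (any(is.na(iv))) return(c(NA_integer_, NA_integer_))
        if (strand_e == "+") c(o + iv[1], o + iv[2])
        else c(o + L - iv[2], o + L - iv[1])
      }
      coords[e, ] <- c(g(sAlt), g(sAlt2), g(sUp), g(sDown))
      pieces[[e]] <- paste0(
        .rand_seq_nogc(spacer),
        if (strand_e == "+") sense else .revcomp_str(sense)
      )
      cursor <- o + L
    }
    genome <- Biostrings::DNAStringSet(
      c(chrS = paste(c(pieces, .rand_seq_nogc(spacer)), collapse = ""))
    )
  } else {
    # count-only study: synthesise consistent coordinates without sequence
    f <- as.integer(cfg@flankLen)
    span <- 2L * f + 2L * cfg@intronLenRange[1] + altLen
    o <- cumsum(c(0L, span[-E] + cfg@spacerLen))
    coords[, "upStart"] <- o
    coords[, "upEnd"] <- o + f
    coords[, "altStart"] <- o + f + cfg@intronLenRange[1]
    coords[, "altEnd"] <- coords[, "altStart"] + altLen
    coords[, "downStart"] <- coords[, "altEnd"] + cfg@intronLenRange[1]
    coords[, "downEnd"] <- coords[, "downStart"] + f
    mxe <- type == "MXE"
    coords[mxe, "alt2Start"] <- coords[mxe, "altEnd"] + 150L
    coords[mxe, "alt2End"] <- coords[mxe, "alt2Start"] +
      pmin(altLen[mxe], 100L)
    geneStrand <- rep("+", nG)
  }

  ## ---- assemble objects --------------------------------------------------
  rd <- DataFrame(
    eventType = type, geneID = geneID[geneIdx],
    geneSymbol = geneSym[geneIdx], chrom = chrom,
    strand = geneStrand[geneIdx],
    altStart = coords[, "altStart"], altEnd = coords[, "altEnd"],
    alt2Start = coords[, "alt2Start"], alt2End = coords[, "alt2End"],
    upStart = coords[, "upStart"], upEnd = coords[, "upEnd"],
    downStart = coords[, "downStart"], downEnd = coords[, "downEnd"],
    incFormLen = unname(lI), skipFormLen = unname(lS),
    altExonLength = ifelse(isSE, altLen, NA_integer_),
    row.names = eventID
  )
  cd <- DataFrame(group = group, row.names = sampleID)
  if (!is.na(cfg@covariateName)) cd[[cfg@covariateName]] <- covValues
  se <- SplicingExperiment(inc, skp, rowData = rd, colData = cd,
                           metadata = list(seed = cfg@seed))

  sets <- list()
  if (cfg@nSets > 0) {
    sizes <- sample(cfg@setSizeRange[1]:cfg@setSizeRange[2],
                    cfg@nSets, replace = TRUE)
    sets <- lapply(seq_len(as.integer(cfg@nSets)), function(i)
      sample(geneSym, min(sizes[i], nG)))
    names(sets) <- sprintf("SET%02d", seq_along(sets))
  }
  if (!is.na(cfg@enrichedSetSize)) {
    sets <- c(list(SET_ENRICHED = geneSym[inEnriched]), sets)
  }

  truth <- data.frame(
    eventID = eventID, geneID = geneID[geneIdx],
    geneSymbol = geneSym[geneIdx], eventType = type,
    altExonLength = ifelse(isSE, altLen, NA_integer_),
    isMicroexon = classifyMicroexon(type, ifelse(isSE, altLen, NA)),
    psiControl = psiCtrl, trueDpsi = dpsi, isMisSpliced = isMis,
    inEnrichedSet = inEnriched[geneIdx],
    motifPlanted = plantFlag, motifWindowOffset = plantOffset,
    motifMatch = plantMatch,
    stringsAsFactors = FALSE
  )

  structure(list(se = se, genome = genome, geneSets = sets, truth = truth,
                 config = cfg),
            class = "missplice_sim")
}

#' Simulate under the global null
#'
#' Identical generative process with all effect sizes zero, no enriched
#' set, no microexon disproportion and uniform motif planting (foreground
#' probability set to the background probability).
#'
#' @inheritParams simulateDataset
#' @return As [simulateDataset()].
#' @export
simulateNull <- function(config, seed = NULL) {
  config <- updateConfig(config,
                         fractionMisSpliced = 0,
                         enrichedSetSize = NA_real_,
                         enrichedSetOR = NA_real_,
                         enrichedSetBaseRate = NA_real_,
                         microexonOR = 1,
                         motifFgProb = config@motifBgProb)
  simulateDataset(config, seed = seed)
}

#' @export
print.missplice_sim <- function(x, ...) {
  cat("Simulated splicing dataset (seed", x$config@seed, ")\n")
  show(x$se)
  cat("  truly mis-spliced events:", sum(x$truth$isMisSpliced), "\n")
  cat("  gene sets:", length(x$geneSets),
      if ("SET_ENRICHED" %in% names(x$geneSets)) "(one enriched)" else "",
      "\n")
  invisible(x)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits the exact formats the readers consume: a native-tsv events table,
#' a TSV sample sheet, a GMT gene-set collection, a FASTA genome (when
#' simulated) and the ground-truth TSV.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    events = file.path(dir, "events.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.tsv")
  )
  writeEventsTable(sim$se, paths["events"])
  writeSampleTable(colData(sim$se), paths["samples"])
  writeGeneSets(sim$geneSets, paths["gene_sets"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sim$genome)) {
    paths["genome"] <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim$genome, paths["genome"])
  }
  paths
}
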