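# Independent oracles used to freeze expected values. Each takes a route
# different from the implementation it checks.

# Two-sided Fisher p by enumeration with log-binomial-coefficient point
# probabilities (no dhyper).
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(n, k)
  p <- exp(logp)
  pObs <- exp(lchoose(m1, a) + lchoose(m2, k - a) - lchoose(n, k))
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

# Exhaustive two-sided permutation p for a two-group mean-difference test,
# enumerating every label assignment directly.
oracle_perm_p <- function(vals, isCase) {
  n <- length(vals); n1 <- sum(isCase)
  obs <- abs(mean(vals[isCase]) - mean(vals[!isCase]))
  cmb <- combn(n, n1)
  stats <- apply(cmb, 2, function(idx) {
    abs(mean(vals[idx]) - mean(vals[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# Hand Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Brute-force grammar matcher: for every gap-length combination build the
# full fixed-width regex and collect all (start, end) realisations via a
# zero-width lookahead (a route independent of the block-chaining scanner).
oracle_scan <- function(sequence, pattern) {
  g <- parseGrammar(pattern)
  toks <- g@tokens
  gapIdx <- which(vapply(toks, function(t) t$type == "gap", TRUE))
  combos <- if (length(gapIdx)) {
    do.call(expand.grid, lapply(gapIdx, function(i)
      toks[[i]]$min:toks[[i]]$max))
  } else data.frame(row.names = 1)
  hits <- NULL
  for (r in seq_len(nrow(combos))) {
    rx <- ""
    width <- 0L
    gi <- 1L
    for (t in toks) {
      if (t$type == "block") {
        rx <- paste0(rx, t$regex); width <- width + t$len
      } else {
        k <- combos[r, gi]; gi <- gi + 1L
        rx <- paste0(rx, sprintf(".{%d}", k)); width <- width + k
      }
    }
    m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] != -1)
      hits <- rbind(hits, data.frame(start = as.integer(m) - 1L,
                                     end = as.integer(m) - 1L + width))
  }
  if (is.null(hits))
    return(data.frame(start = integer(0), end = integer(0)))
  hits <- unique(hits)
  hits[order(hits$start, hits$end), , drop = FALSE]
}

# Pearson r and t-based p straight from the defining formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# A tiny hand-built SplicingExperiment with a known two-exon-flank genome,
# one SE event per strand with identical sense-layout sequences.
make_toy_locus <- function(flank = 60, i1 = 200, exon = 40, i2 = 220) {
  set.seed(99)
  sense <- paste0(rand_dna(flank), rand_dna(i1), rand_dna(exon),
                  rand_dna(i2), rand_dna(flank))
  L <- nchar(sense)
  genome <- Biostrings::DNAStringSet(c(
    chrP = sense,
    chrM = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sense)))
  ))
  mk <- function(strand, chrom) {
    if (strand == "+") {
      c(up = 0, upE = flank, aS = flank + i1, aE = flank + i1 + exon,
        dS = L - flank, dE = L)
    } else {
      # mirror sense intervals into chrM coordinates
      m <- function(s, e) c(L - e, L - s)
      u <- m(0, flank); a <- m(flank + i1, flank + i1 + exon)
      d <- m(L - flank, L)
      c(up = u[1], upE = u[2], aS = a[1], aE = a[2], dS = d[1], dE = d[2])
    }
  }
  p <- mk("+", "chrP"); m <- mk("-", "chrM")
  rd <- S4Vectors::DataFrame(
    eventType = c("SE", "SE"),
    geneID = c("G1", "G2"), geneSymbol = c("GENEP", "GENEM"),
    chrom = c("chrP", "chrM"), strand = c("+", "-"),
    altStart = as.integer(c(p["aS"], m["aS"])),
    altEnd = as.integer(c(p["aE"], m["aE"])),
    alt2Start = NA_integer_, alt2End = NA_integer_,
    upStart = as.integer(c(p["up"], m["up"])),
    upEnd = as.integer(c(p["upE"], m["upE"])),
    downStart = as.integer(c(p["dS"], m["dS"])),
    downEnd = as.integer(c(p["dE"], m["dE"])),
    incFormLen = 2, skipFormLen = 1, altExonLength = as.integer(exon),
    row.names = c("evP", "evM")
  )
  se <- SplicingExperiment(
    inclusion = matrix(20L, 2, 2), skipping = matrix(10L, 2, 2),
    rowData = rd,
    colData = S4Vectors::DataFrame(group = c("control", "case"),
                                   row.names = c("s1", "s2"))
  )
  list(se = se, genome = genome, sense = sense, flank = flank, i1 = i1,
       exon = exon, i2 = i2)
}
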