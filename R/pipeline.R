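.default_run_config <- function() {
  list(
    seed = 1,
    outDir = "missplice_run",
    stages = c("simulate", "diff", "enrich", "motifscan", "correlate",
               "report"),
    simulate = list(),
    inputs = list(),
    thresholds = list(dpsi = 0.1, fdr = 0.05, minReads = 10),
    method = list(
      fdrScope = "per-type", nPerm = 9999, window = 500,
      orCorrection = "on-zero",
      grammars = c("YGCYGCY", "YGCY(N)0-5YGCY")
    ),
    covariate = NULL
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline run configuration
#'
#' A run configuration is a single declarative YAML document whose keys
#' mirror the arguments of the analysis functions: `seed`, `outDir`,
#' `stages`, a `simulate` block (fields of [simConfig()]) or an `inputs`
#' block (paths to events/samples/genome/geneSets tables), `thresholds`
#' (`dpsi`, `fdr`, `minReads`), `method` (`fdrScope`, `nPerm`, `window`,
#' `orCorrection`, `grammars`) and `covariate`. Unspecified keys take the
#' documented defaults; arguments passed directly to [runPipeline()] win
#' over file values.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("configuration error: config file not found: ", path,
           call. = FALSE)
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

.write_tsv <- function(df, path, header = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.prov_header <- function(cfg, extra = character()) {
  c(sprintf("missplice v%s",
            as.character(utils::packageVersion("missplice"))),
    sprintf("seed=%d", as.integer(cfg$seed)),
    sprintf("dpsi=%g fdr=%g minReads=%g", cfg$thresholds$dpsi,
            cfg$thresholds$fdr, cfg$thresholds$minReads),
    extra)
}

#' Run the mis-splicing analysis pipeline
#'
#' Wires the stages into one reproducible run: `simulate` (or load the
#' configured inputs), `diff` (PSI + differential splicing), `enrich`
#' (gene-set and microexon enrichment), `motifscan` (motif enrichment
#' around mis-spliced SE events), `correlate` (per-sample burden versus
#' covariate) and `report` (run summary). Every output TSV starts with
#' `#`-prefixed provenance lines (package version, seed, thresholds) and
#' is re-parseable by the package's own readers. A failing stage raises an
#' error naming the stage.
#'
#' @param config path to a YAML run configuration, or a configuration
#'   list from [readRunConfig()].
#' @param outDir output directory; overrides the config value.
#' @param ... top-level configuration overrides (e.g. `seed = 7`), which
#'   win over file values.
#' @return Invisibly, a list with the in-memory results (`sim`, `diff`,
#'   `genes`, `geneSetEnrichment`, `microexon`, `motif`, `correlation`,
#'   `summary`) and `outDir`.
#' @export
runPipeline <- function(config = NULL, outDir = NULL, ...) {
  cfg <- if (is.list(config)) .merge_config(.default_run_config(), config)
  else readRunConfig(config)
  cfg <- .merge_config(cfg, list(...))
  if (!is.null(outDir)) cfg$outDir <- outDir
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- list(outDir = cfg$outDir)
  stages <- cfg$stages

  ## ---- simulate / load ---------------------------------------------------
  se <- NULL; genome <- NULL; geneSets <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", {
      simcfg <- do.call(simConfig, c(cfg$simulate, list(seed = cfg$seed)))
      out$sim <- simulateDataset(simcfg)
      writeDataset(out$sim, file.path(cfg$outDir, "sim"))
      se <- out$sim$se; genome <- out$sim$genome
      geneSets <- out$sim$geneSets
    })
  } else {
    run_stage("load", {
      inp <- cfg$inputs
      if (is.null(inp$events))
        stop("configuration error: no 'inputs: events' table and no ",
             "simulate stage")
      se <- readEventsTable(inp$events,
                            dialect = inp$dialect %||% "native-tsv",
                            eventType = inp$eventType)
      if (!is.null(inp$samples)) {
        cd <- readSampleTable(inp$samples)
        colData(se) <- cd[colnames(se), , drop = FALSE]
      }
      if (!is.null(inp$genome)) {
        genome <- Biostrings::readDNAStringSet(inp$genome)
        names(genome) <- sub("\\s.*$", "", names(genome))
      }
      if (!is.null(inp$geneSets)) geneSets <- readGeneSets(inp$geneSets)
    })
  }
  if ("motifscan" %in% stages && is.null(genome))
    stop("configuration error: stage 'motifscan' requested but no genome ",
         "was simulated or supplied via 'inputs: genome'", call. = FALSE)

  ## ---- differential splicing ---------------------------------------------
  res <- NULL
  if ("diff" %in% stages) {
    run_stage("diff", {
      res <- diffSplicing(
        se, dpsiThresh = cfg$thresholds$dpsi,
        fdrThresh = cfg$thresholds$fdr, minReads = cfg$thresholds$minReads,
        nPerm = cfg$method$nPerm, seed = cfg$seed,
        fdrScope = cfg$method$fdrScope
      )
      out$diff <- res
      writeDiffResults(res, file.path(cfg$outDir, "diff.tsv"))
      psi <- computePsi(se, minReads = cfg$thresholds$minReads)
      .write_tsv(data.frame(event_id = rownames(psi),
                            round(psi, 6), check.names = FALSE),
                 file.path(cfg$outDir, "psi.tsv"),
                 .prov_header(cfg, "table=per-sample PSI"))
    })
  }

  ## ---- enrichment ---------------------------------------------------------
  if ("enrich" %in% stages && !is.null(res)) {
    run_stage("enrich", {
      out$genes <- misSplicedGenes(res)
      if (!is.null(geneSets) && length(geneSets)) {
        out$geneSetEnrichment <- geneSetEnrichment(
          out$genes$misSpliced, out$genes$universe, geneSets,
          correction = cfg$method$orCorrection)
        .write_tsv(out$geneSetEnrichment,
                   file.path(cfg$outDir, "enrichment_gene_sets.tsv"),
                   .prov_header(cfg, "table=gene-set enrichment"))
      }
      out$microexon <- microexonEnrichment(
        res, correction = cfg$method$orCorrection)
      .write_tsv(out$microexon,
                 file.path(cfg$outDir, "enrichment_microexon.tsv"),
                 .prov_header(cfg, "table=microexon disproportion"))
    })
  }

  ## ---- motif enrichment ---------------------------------------------------
  if ("motifscan" %in% stages && !is.null(res)) {
    run_stage("motifscan", {
      seIDs <- res$eventID[res$eventType == "SE" & !is.na(res$fdr)]
      fg <- res$eventID[res$eventType == "SE" & res$isMisSpliced]
      if (length(fg)) {
        out$motif <- motifEnrichment(
          se, fg, setdiff(seIDs, fg), genome, cfg$method$grammars,
          width = cfg$method$window, correction = cfg$method$orCorrection)
        .write_tsv(out$motif, file.path(cfg$outDir, "motif_enrichment.tsv"),
                   .prov_header(cfg, sprintf(
                     "grammars=%s window=%d",
                     paste(cfg$method$grammars, collapse = ","),
                     cfg$method$window)))
      }
    })
  }

  ## ---- covariate correlation ----------------------------------------------
  if ("correlate" %in% stages && !is.null(res)) {
    run_stage("correlate", {
      covName <- cfg$covariate
      cd <- colData(se)
      if (is.null(covName)) {
        numcols <- colnames(cd)[vapply(cd, is.numeric, TRUE)]
        covName <- if (length(numcols)) numcols[1] else NULL
      }
      misIDs <- res$eventID[res$isMisSpliced]
      if (!is.null(covName) && length(misIDs)) {
        psi <- computePsi(se, minReads = cfg$thresholds$minReads)
        ctrl <- rownames(cd)[cd$group == metadata(res)$control]
        covv <- stats::setNames(cd[[covName]], rownames(cd))
        covv <- covv[!is.na(covv)]
        corr <- covariateBurdenCorrelation(psi, ctrl, misIDs, covv)
        out$correlation <- data.frame(
          covariate = covName, n = corr$n, r = corr$r, p = corr$p)
        .write_tsv(out$correlation,
                   file.path(cfg$outDir, "correlation.tsv"),
                   .prov_header(cfg, "table=covariate vs burden"))
        .write_tsv(data.frame(sample = names(corr$burden),
                              burden = corr$burden),
                   file.path(cfg$outDir, "burden.tsv"),
                   .prov_header(cfg, "table=per-sample burden"))
      }
    })
  }

  ## ---- summary -------------------------------------------------------------
  if ("report" %in% stages && !is.null(res)) {
    run_stage("report", {
      tab <- table(factor(res$eventType, levels = .EVENT_TYPES))
      mis <- table(factor(res$eventType[res$isMisSpliced],
                          levels = .EVENT_TYPES))
      out$summary <- data.frame(
        eventType = .EVENT_TYPES,
        detected = as.integer(tab),
        misSpliced = as.integer(mis),
        misSplicedPct = round(100 * as.integer(mis) /
                                pmax(as.integer(tab), 1L), 2)
      )
      .write_tsv(out$summary, file.path(cfg$outDir, "summary.tsv"),
                 .prov_header(cfg, c(
                   sprintf("genes_universe=%d",
                           length(out$genes$universe %||% character())),
                   sprintf("genes_mis_spliced=%d",
                           length(out$genes$misSpliced %||% character())))))
    })
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
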