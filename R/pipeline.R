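## End-to-end orchestration: synthesis (or external input) -> filtering ->
## functional consequence -> cohort statistics -> survival, with a run
## manifest. Rerunning with the same config and seed reproduces every
## output byte-identically (the manifest differs only in its timestamp).

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.readTableDir <- function(dir, what) {
  if (!dir.exists(dir))
    stop("directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no ", what, " tables in ", dir, call. = FALSE)
  tbls <- lapply(files, readVariantTable)
  names(tbls) <- sub("\\.tsv$", "", basename(files))
  tbls
}

#' Run the full screening pipeline
#'
#' Orchestrates cohort synthesis (or reading of external variant tables),
#' the exome and targeted filtering cascades, the consequence vote,
#' spectrum/burden/recurrence statistics, and mutation-stratified survival
#' analysis. Writes `retained.tsv`, `trace.tsv`, `summary.json`,
#' `recurrence.tsv`, `km.json` and `manifest.json` (plus
#' `wes_retained.tsv`/`wes_trace.tsv` when the exome stage runs) to the
#' output directory.
#'
#' The YAML config carries: `profile` ("reference" or a profile path),
#' `seed`, optional `thresholds` overrides (any [filterThresholds()]
#' argument), `outdir`, and optionally an `inputs` block
#' (`targeted_dir`, `annotations`, `saliva_dir`, `hyperplastic_dir`,
#' `clinical`) replacing the synthetic cohort with external tables.
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @param outdir output directory; overrides the config's.
#' @return (invisibly) list with the run `manifest` and the in-memory
#'   results (`retained`, `recurrence`, `survival`, ...).
#' @export
runPipeline <- function(config, outdir = NULL) {
  cfgPath <- NULL
  if (is.character(config)) {
    cfgPath <- config
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- do.call(filterThresholds, config$thresholds %||% list())
  manifest <- list(
    package = "SomaticScreen",
    version = as.character(packageVersion("SomaticScreen")),
    config_hash = if (!is.null(cfgPath)) unname(tools::md5sum(cfgPath))
                  else NA_character_,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list())
  counts <- list()
  results <- list()

  external <- !is.null(config$inputs)
  if (external) {
    inp <- config$inputs
    dat <- .stage("read_inputs", {
      for (f in c("annotations", "clinical"))
        if (!is.null(inp[[f]]) && !file.exists(inp[[f]]))
          stop("file not found: ", inp[[f]])
      list(targeted = .readTableDir(inp$targeted_dir, "targeted"),
           annotations = readAnnotationTable(inp$annotations),
           saliva = .readTableDir(inp$saliva_dir, "saliva"),
           hyperplastic = .readTableDir(inp$hyperplastic_dir,
                                        "hyperplastic control"),
           clinical = if (!is.null(inp$clinical))
             readClinicalTable(inp$clinical))
    })
    controls <- .stage("controls",
      buildPon(c(dat$saliva, dat$hyperplastic),
               minReads = th$pon_min_reads))
    tgt <- .stage("targeted_filter", {
      res <- lapply(dat$targeted, function(tb)
        targetedFilter(tb, dat$annotations, controls, thresholds = th))
      list(results = res,
           retained = do.call(rbind, lapply(res, retainedCalls)))
    })
    clinical <- dat$clinical
    tumorIds <- names(dat$targeted)
    geneUniverse <- unique(dat$annotations$gene)
    wesStats <- NULL
  } else {
    profile <- .stage("profile", {
      p <- config$profile %||% "reference"
      if (identical(p, "reference")) referenceProfile()
      else readCohortProfile(p)
    })
    seed <- config$seed %||% profileSeed(profile)
    bundle <- .stage("synth", generateCohort(profile, seed = seed))
    results$bundle <- bundle
    counts$tumors <- sum(grepl("^tumor", bundle@samples$role))

    wesRun <- .stage("wes_filter", wesFilterCohort(bundle, thresholds = th))
    counts$wes_input <- sum(vapply(bundle@wes, nrow, integer(1)))
    counts$wes_retained <- nrow(wesRun$retained)
    writeMafLike(wesRun$retained, file.path(outdir, "wes_retained.tsv"),
                 retainedOnly = FALSE)
    wesTrace <- do.call(rbind, lapply(wesRun$results, filterTrace))
    write.table(wesTrace, file.path(outdir, "wes_trace.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    wesStats <- mutationBurden(wesRun$retained, profile@exomeMb,
                               samples = names(bundle@wes))

    tgt <- .stage("targeted_filter",
                  targetedFilterCohort(bundle, thresholds = th))
    counts$targeted_input <- sum(vapply(bundle@targeted, nrow, integer(1)))
    clinical <- bundle@clinical
    tumorIds <- names(bundle@targeted)
    geneUniverse <- unique(bundle@annotations$gene)
    results$wes <- wesRun
  }
  counts$targeted_retained <- nrow(tgt$retained)

  consequential <- .stage("consequence",
                          consequenceFilter(tgt$retained, th$vote_min))
  counts$consequence_retained <- nrow(consequential)
  writeMafLike(consequential, file.path(outdir, "retained.tsv"),
               retainedOnly = FALSE)
  trace <- do.call(rbind, lapply(tgt$results, filterTrace))
  write.table(trace, file.path(outdir, "trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  rec <- .stage("recurrence",
    recurrenceMatrix(consequential, samples = tumorIds,
                     minSamples = th$recurrence_min))
  recDf <- data.frame(gene = rownames(rec@mat), rec@mat,
                      check.names = FALSE)
  write.table(recDf, file.path(outdir, "recurrence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  spectrum <- .stage("spectrum", spectrumSummary(consequential))
  summaryJson <- list(
    n_samples = length(tumorIds),
    targeted_retained = counts$targeted_retained,
    consequence_retained = counts$consequence_retained,
    spectrum = list(ti = spectrum@tiCount, tv = spectrum@tvCount,
                    ratio = spectrum@ratio,
                    ratio_truncated = spectrum@ratioTruncated,
                    six_class = as.list(spectrum@sixClass),
                    gc_targeted_fraction = spectrum@gcTargetedFraction),
    recurrent_genes = recurrentGenes(rec),
    burden = if (!is.null(wesStats)) list(
      median_count = wesStats$medianCount,
      range_count = wesStats$rangeCount,
      median_rate_per_mb = wesStats$medianRate,
      range_rate_per_mb = wesStats$rangeRate))
  jsonlite::write_json(summaryJson, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  kmOut <- NULL
  if (!is.null(clinical) && nrow(clinical)) {
    survGene <- config$survival_gene %||%
      (if (!external) survivalSpec(results$bundle@profile)$gene
       else "FAT1")
    kmOut <- .stage("survival", {
      strata <- stratifyByGene(consequential, clinical, survGene,
                               knownGenes = geneUniverse)
      kmAll <- kmEstimate(clinical)
      kmM <- kmEstimate(strata$mutated)
      kmW <- kmEstimate(strata$wildtype)
      lr <- logrankTest(strata$mutated, strata$wildtype,
                        labels = c("mutated", "wildtype"))
      list(gene = survGene,
           n_clinical = nrow(clinical),
           n_mutated = nrow(strata$mutated),
           n_wildtype = nrow(strata$wildtype),
           median_mutated = kmMedian(kmM),
           median_wildtype = kmMedian(kmW),
           overall_survival_36m = survivalAt(kmAll, 36),
           logrank_chisq = lr@chisq, logrank_p = lr@pValue)
    })
    jsonlite::write_json(kmOut, file.path(outdir, "km.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  manifest$stages <- counts
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results <- c(results, list(
    manifest = manifest, retained = consequential, recurrence = rec,
    spectrum = spectrum, burden = wesStats, survival = kmOut,
    thresholds = th, outdir = outdir))
  invisible(results)
}
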