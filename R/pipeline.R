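#' Demo configuration for the end-to-end pipeline
#'
#' A small, fast configuration: 12 LINE-1 loci across the three intactness
#' classes and a reduced host-gene panel with 50k fragments per library.
#' Completes on one CPU in well under five minutes.
#'
#' @param seed master seed.
#' @return An [L1SimConfig-class].
#' @export
demoConfig <- function(seed = 1L) {
  simConfig(seed = seed, nL1Loci = 12L,
            hostCategories = c(mRNA = 40L, histone = 8L, MT = 4L,
                               rRNA = 2L, lncRNA = 10L, circRNA_host = 4L),
            nReadsInput = 50000L, nReadsIP = 50000L)
}

#' Load a simulation configuration from YAML
#'
#' Reads a YAML file whose keys are [simConfig()] arguments
#' (`class_proportions`, `host_categories` and `enrichment_model` map to the
#' corresponding named vectors/lists; snake_case keys are accepted).
#'
#' @param path YAML file path.
#' @return An [L1SimConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  toCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(y) <- toCamel(names(y))
  names(y)[names(y) == "nReadsIp"] <- "nReadsIP"
  for (nm in c("classProportions", "hostCategories"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  bad <- setdiff(names(y), names(formals(simConfig)))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(simConfig, y)
}

.logStage <- function(logPath, stage, status, elapsed = NULL, extra = list()) {
  rec <- c(list(stage = stage, status = status),
           if (!is.null(elapsed)) list(elapsed_sec = round(elapsed, 3)), extra)
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  cat(line, "\n", file = logPath, append = TRUE, sep = "")
  message(sprintf("[%s] %s", stage, status))
}

#' Run the whole pipeline on one configuration
#'
#' Executes simulate, classify-orfs, quantify-l1, enrich and compare-granules
#' in order, stopping at the first failing stage with a diagnostic naming
#' it. Per-stage seeds are derived from the master seed by fixed offsets, so
#' stages are independently reproducible; a rerun with the same config and
#' seed produces byte-identical outputs and checksums. Writes a run manifest
#' (config hash, seed, per-stage wall time, md5 checksum of every output
#' file, warnings) and a JSONL log.
#'
#' @param config an [L1SimConfig-class], or path to a YAML config.
#' @param outDir output directory.
#' @param seed optional master-seed override.
#' @return Invisibly, a list with the manifest and key in-memory results
#'   (simulation, calls, abundance estimates, enrichment table, granule
#'   comparison).
#' @export
runPipeline <- function(config = demoConfig(), outDir, seed = NULL) {
  if (is.character(config)) config <- loadConfig(config)
  if (!methods::is(config, "L1SimConfig"))
    stop("config must be an L1SimConfig or a YAML path")
  if (!is.null(seed)) config@seed <- as.integer(seed)
  validObject(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.jsonl")
  if (file.exists(logPath)) file.remove(logPath)
  warningsSeen <- character()
  times <- numeric()
  outputs <- character()

  runStage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        warningsSeen <<- c(warningsSeen,
                           sprintf("%s: %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    el <- proc.time()[["elapsed"]] - t0
    times[stage] <<- el
    .logStage(logPath, stage, "ok", el)
    res
  }

  # config hash: md5 of the canonical YAML serialization
  cfgYaml <- file.path(outDir, "config.yaml")
  cfgList <- list(
    seed = config@seed, n_l1_loci = config@nL1Loci, l1_length = config@l1Length,
    orf1_aa = config@orf1Aa, orf2_aa = config@orf2Aa,
    divergence_rate = config@divergenceRate,
    class_proportions = as.list(config@classProportions),
    host_categories = as.list(config@hostCategories),
    gene_length = config@geneLength, l1_fraction = config@l1Fraction,
    read_length = config@readLength, fragment_mean = config@fragmentMean,
    fragment_sd = config@fragmentSd, n_reads_input = config@nReadsInput,
    n_reads_ip = config@nReadsIP, error_rate = config@errorRate,
    minus_strand = config@minusStrand, stranded = config@stranded)
  yaml::write_yaml(cfgList, cfgYaml)

  sim <- runStage("simulate", function() {
    s <- simulateGenome(config)
    outputs <<- c(outputs, writeSimulation(s, outDir))
    s
  })
  rs <- runStage("simulate-reads", function() {
    r <- simulateReads(sim)
    outputs <<- c(outputs, writeReads(r, outDir))
    r
  })
  calls <- runStage("classify-orfs", function() {
    cl <- classifyLoci(sim)
    p <- file.path(outDir, "intactness_calls.tsv")
    writeTsv(cl, p)
    outputs <<- c(outputs, p)
    cl
  })
  quant <- runStage("quantify-l1", function() {
    aln <- emulateAlignment(rs, sim)
    samPath <- file.path(outDir, "alignments.sam")
    writeSAM(aln$hits, rs, sim, samPath)
    outputs <<- c(outputs, samPath)
    est <- lapply(c(input = "input", IP = "IP"), function(lib) {
      C <- buildCompatibility(aln$hits, locusIds = sim@truth$locus_id,
                              errorRate = rs@errorRate,
                              readLength = rs@readLength, library = lib)
      emQuantify(C)
    })
    tab <- data.frame(
      locus_id = sim@truth$locus_id,
      class = calls$class,
      theta_input = theta(est$input), counts_input = expectedCounts(est$input),
      theta_ip = theta(est$IP), counts_ip = expectedCounts(est$IP))
    p <- file.path(outDir, "l1_quant.tsv")
    writeTsv(tab, p)
    rep <- list(
      input = list(iterations = est$input@iterations,
                   converged = isConverged(est$input),
                   logLik = utils::tail(logLikTrace(est$input), 1)),
      IP = list(iterations = est$IP@iterations,
                converged = isConverged(est$IP),
                logLik = utils::tail(logLikTrace(est$IP), 1)),
      by_class = list(input = aggregateByClass(est$input, calls),
                      IP = aggregateByClass(est$IP, calls)))
    rp <- file.path(outDir, "l1_quant_report.json")
    jsonlite::write_json(rep, rp, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, p, rp)
    list(aln = aln, est = est, table = tab)
  })
  enr <- runStage("enrich", function() {
    hits <- as.data.frame(quant$aln$hits)
    prim <- hits[hits$primary, , drop = FALSE]
    counts <- table(factor(prim$feature_id,
                           levels = c(sim@truth$locus_id, sim@genes$gene_id)),
                    factor(prim$library, levels = c("input", "IP")))
    counts <- unclass(as.matrix(counts))
    # pooled circRNA feature from back-splice junction reads (truth-level,
    # standing in for an upstream circRNA caller)
    fr <- rs@fragments
    circ <- vapply(c("input", "IP"), function(lib)
      sum(fr$junction & fr$library == lib), 0L)
    counts <- rbind(counts, circRNA_pooled = circ)
    meta <- data.frame(
      feature_id = rownames(counts),
      category = c(paste0("L1_", sim@truth$class_true, recycle0 = TRUE),
                   sim@genes$category, "circRNA_pooled"),
      stringsAsFactors = FALSE)
    # circRNA-host linear reads stay under their gene; drop genes with no
    # counts anywhere to keep ratios meaningful
    keep <- rowSums(counts) > 0
    counts <- counts[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    # anchor size factors on the unenriched rRNA compartment (the bulk of a
    # non-depleted library), not the heavily IP-shifted LINE-1 features
    anchor <- meta$category == "rRNA"
    if (!any(anchor)) anchor <- !grepl("^L1_|^circRNA_pooled$", meta$category)
    tabEnr <- foldEnrichment(counts, ipCols = "IP", inputCols = "input",
                             normFeatures = anchor,
                             meta = meta["category"])
    p <- file.path(outDir, "enrichment.tsv")
    writeTsv(tabEnr, p)
    cats <- intersect(unique(meta$category),
                      c("mRNA", "lncRNA", "histone", "MT", "rRNA",
                        "circRNA_pooled"))
    summaries <- lapply(cats, function(cat) categorySummary(tabEnr, cat))
    names(summaries) <- cats
    fracs <- local({
      rg <- GenomicRanges::GRanges(prim$feature_id,
                                   IRanges::IRanges(prim$w1s, prim$w2s +
                                                      rs@readLength - 1L))
      g <- sim@genes
      countReadCategories(
        rg,
        rRNA = g[g$category == "rRNA"],
        exons = g[g$category != "rRNA"],
        l1 = sim@loci)
    })
    sp <- file.path(outDir, "enrichment_summary.json")
    jsonlite::write_json(list(category_summaries = summaries,
                              read_category_fractions = as.list(fracs)),
                         sp, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, p, sp)
    list(table = tabEnr, summaries = summaries, fractions = fracs)
  })
  comp <- runStage("compare-granules", function() {
    ft <- rs@featureTruth
    isGene <- ft$feature_type == "gene" & ft$category %in% c("mRNA", "lncRNA")
    ext <- simulateGranuleTables(ft$feature_id[isGene],
                                 log(ft$enrichment[isGene]),
                                 seed = config@seed)
    for (nm in names(ext))
      outputs <<- c(outputs, writeTsv(ext[[nm]],
                                      file.path(outDir, paste0(nm, "_external.tsv"))))
    gc <- joinAndCompare(enr$table, ext$pbody, external2 = ext$sg)
    cp <- file.path(outDir, "granule_comparison.json")
    jsonlite::write_json(
      list(n = gc@n, rho = gc@rho, rho_p = gc@rhoP,
           partial_rho = gc@partialRho, partial_p = gc@partialP,
           odds_ratio = gc@oddsRatio, or_corrected = gc@orCorrected,
           exact_p = gc@exactP, exact_log_p = gc@exactLogP,
           table = as.vector(gc@table)),
      cp, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, cp)
    gc
  })

  outputs <- unique(unname(c(cfgYaml, outputs)))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfgYaml)),
    seed = config@seed,
    package_version = as.character(utils::packageVersion("l1ripseq")),
    stage_seconds = as.list(round(times, 3)),
    warnings = warningsSeen,
    files = as.list(tools::md5sum(outputs)))
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  .logStage(logPath, "manifest", "ok")
  invisible(list(manifest = manifest, sim = sim, reads = rs, calls = calls,
                 quant = quant, enrichment = enr, comparison = comp))
}
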