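# Orchestration: a single configuration drives
# import -> filter -> purity QC -> EWAS -> DMR -> density -> annotation ->
# age clock -> co-methylation, with a logged, hash-manifested output
# directory. All randomness flows from one master seed.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter at its
#' documented default. Supply either `synthetic = TRUE` (the built-in
#' cohort generator provides the inputs) or `reports_dir` +
#' `sample_sheet` paths. Override any element before passing to
#' [runPipeline()]; a YAML file with the same structure is accepted too.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return a named list (`RunConfig`).
#' @export
defaultRunConfig <- function(outdir = "spermclock_run", seed = 1L) {
  list(
    outdir = outdir,
    seed = seed,
    synthetic = TRUE,
    synthetic_config = list(),       # overrides for cohortConfig()
    reports_dir = NULL,              # real-data inputs (cytosine reports)
    sample_sheet = NULL,
    exclusion_beds = list(),
    known_regions = NULL,
    genes = NULL,                    # TSV: gene_id chrom tss strand
    paternal_loci = NULL,            # BED; synthetic runs use truth loci
    maternal_loci = NULL,
    min_coverage = 20L,
    min_samples = 30L,
    covariates = c("fertility", "sperm_concentration", "smoking",
                   "testosterone", "bioavailable_T", "FSH", "HDL", "BMI",
                   "triglycerides", "chol_HDL_ratio"),
    q_threshold = 0.01,
    dmr_window = 500L,
    dmr_min_cpgs = 5L,
    density_window = 1e6,
    density_step = 1e5,
    clock_k = 5000L,
    clock_alpha = 0.5,
    clock_loocv = TRUE,
    wgcna_k = 20000L,
    wgcna_power = 8,
    wgcna_min_size = 30L,
    wgcna_cut_height = 0.4,
    traits = c("age", "fertility", "smoking", "BMI"),
    stages = c(filter = TRUE, qc = TRUE, ewas = TRUE, dmr = TRUE,
               density = TRUE, annotate = TRUE, clock = TRUE,
               comethylation = TRUE))
}

#' Validate a pipeline configuration
#'
#' Checks paths and parameter ranges; never throws — the report carries
#' the errors.
#'
#' @param config a [defaultRunConfig()]-style list or a YAML path.
#' @return list: `valid` flag, `errors` character vector, `config` (the
#'   merged configuration).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  full <- defaultRunConfig()
  for (nm in names(config)) full[[nm]] <- config[[nm]]
  errors <- character(0)
  addErr <- function(msg) errors <<- c(errors, msg)
  if (!isTRUE(full$synthetic)) {
    if (is.null(full$reports_dir) || !dir.exists(full$reports_dir))
      addErr("reports_dir missing or not a directory")
    if (is.null(full$sample_sheet) || !file.exists(full$sample_sheet))
      addErr("sample sheet missing")
  }
  for (p in full$exclusion_beds)
    if (is.character(p) && !file.exists(p))
      addErr(paste("exclusion BED not found:", p))
  for (nm in c("known_regions", "genes", "paternal_loci", "maternal_loci"))
    if (is.character(full[[nm]]) && !file.exists(full[[nm]]))
      addErr(paste(nm, "file not found:", full[[nm]]))
  chkPos <- function(nm) if (!is.numeric(full[[nm]]) || full[[nm]] <= 0)
    addErr(paste(nm, "must be a positive number"))
  for (nm in c("min_coverage", "min_samples", "dmr_window", "dmr_min_cpgs",
               "density_window", "density_step", "clock_k", "wgcna_k",
               "wgcna_min_size")) chkPos(nm)
  if (!is.numeric(full$q_threshold) || full$q_threshold <= 0 ||
      full$q_threshold >= 1)
    addErr("q_threshold must lie in (0, 1)")
  if (full$clock_alpha < 0 || full$clock_alpha > 1)
    addErr("clock_alpha must lie in [0, 1]")
  if (full$wgcna_cut_height <= 0 || full$wgcna_cut_height >= 1)
    addErr("wgcna_cut_height must lie in (0, 1)")
  list(valid = length(errors) == 0, errors = errors, config = full)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every output
#' file under `config$outdir` and finishing with `manifest.tsv` (file,
#' md5 hash) and `run_log.txt` (parameters, seed, per-stage row counts).
#' Any stage failure aborts with the stage name after preserving the
#' partial manifest. Identical configuration and inputs give
#' byte-identical output hashes.
#'
#' @param config see [validateConfig()].
#' @return invisibly, list: `manifest` (`data.frame` file/md5), `outdir`,
#'   and the in-memory stage results.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  v <- validateConfig(config)
  if (!v$valid)
    stop("invalid configuration:\n  ", paste(v$errors, collapse = "\n  "))
  cfg <- v$config
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  logfile <- file.path(cfg$outdir, "run_log.txt")
  logs <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    logs <<- c(logs, msg)
    message("[spermclock] ", msg)
  }
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  writeManifest <- function() {
    man <- data.frame(file = basename(outputs),
                      md5 = unname(tools::md5sum(outputs)),
                      stringsAsFactors = FALSE)
    write.table(man, file.path(cfg$outdir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    man
  }
  results <- list()
  stage <- function(name, enabled, fn) {
    if (!enabled) { say("stage ", name, ": skipped"); return(invisible()) }
    say("stage ", name, ": start")
    tryCatch(fn(), error = function(e) {
      writeManifest()
      writeLines(logs, logfile)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial manifest preserved)", call. = FALSE)
    })
  }
  say("seed = ", cfg$seed)
  set.seed(cfg$seed)

  ## import
  truth <- NULL
  if (isTRUE(cfg$synthetic)) {
    sc <- do.call(cohortConfig, c(cfg$synthetic_config,
                                  if (is.null(cfg$synthetic_config$seed))
                                    list(seed = cfg$seed)))
    cohort <- simulateCohort(sc)
    me <- cohort$me; sheet <- cohort$sheet; truth <- cohort$truth
    say("synthetic cohort: ", nrow(me), " CpGs x ", ncol(me), " samples")
  } else {
    files <- list.files(cfg$reports_dir,
                        pattern = "\\.cytosine_report\\.txt$",
                        full.names = TRUE)
    if (!length(files)) stop("no cytosine reports in ", cfg$reports_dir)
    counts <- lapply(files, readCytosineReport)
    names(counts) <- sub("\\.cytosine_report\\.txt$", "", basename(files))
    sheet <- readSampleSheet(cfg$sample_sheet)
    me <- assembleMatrix(counts, sampleData = sheet)
    sheet <- sampleSheet(me)
    say("imported ", nrow(me), " CpGs x ", ncol(me), " samples")
  }
  results$me_raw <- me

  ## filter
  stage("filter", cfg$stages[["filter"]], function() {
    fl <- filterSites(me, min_coverage = cfg$min_coverage,
                      min_samples = cfg$min_samples,
                      exclusion_beds = cfg$exclusion_beds)
    me <<- fl$me
    results$filter_report <<- fl$report
    say("filter: retained ", fl$report@n_retained, "/",
        fl$report@n_input_sites, " sites; masked cells ",
        fl$report@n_cells_masked_low_coverage)
    p <- file.path(cfg$outdir, "filtered_matrix.tsv")
    writeMethylationTable(me, p); emit(p)
  })

  ## purity QC
  stage("qc", cfg$stages[["qc"]], function() {
    pat <- cfg$paternal_loci; mat <- cfg$maternal_loci
    if (is.null(pat) && !is.null(truth) && length(truth$imprinted)) {
      pat <- truth$imprinted[truth$imprinted$type == "paternal"]
      mat <- truth$imprinted[truth$imprinted$type == "maternal"]
    }
    if (is.null(pat) || is.null(mat)) {
      say("qc: no imprinted loci supplied, skipped"); return()
    }
    rep_ <- qcImprinting(me, pat, mat)
    results$purity <<- rep_
    say("qc: verdict ", rep_@verdict)
    p <- file.path(cfg$outdir, "purity_report.tsv")
    write.table(rep_@loci, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  })

  ## EWAS
  stage("ewas", cfg$stages[["ewas"]], function() {
    res <- runEwas(me, outcome = "age", covariates = cfg$covariates,
                   sheet = sheet, quiet = TRUE)
    results$ewas <<- res
    infl <- genomicInflation(res$p[res$estimable])
    results$lambda_gc <<- infl$lambda_gc
    cls <- classifyDmcs(res, q_threshold = cfg$q_threshold,
                        known_regions = cfg$known_regions)
    results$dmc <<- cls
    say(sprintf("ewas: %d sites, lambda_GC = %.3f, %d significant (q < %g)",
                nrow(res), infl$lambda_gc, cls$summary$n_sig,
                cfg$q_threshold))
    p <- file.path(cfg$outdir, "ewas_results.tsv")
    write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    p <- file.path(cfg$outdir, "dmc_summary.yaml")
    yaml::write_yaml(cls$summary, p); emit(p)
  })

  ## DMR + density
  stage("dmr", cfg$stages[["dmr"]] && cfg$stages[["ewas"]], function() {
    labels <- results$dmc$labels
    sig <- labels[order(labels$chrom, labels$pos), , drop = FALSE]
    sig <- merge(sig, results$ewas[, c("id", "q", "effect")], by = "id")
    sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
    dmrs <- callDmrs(sig, all_sites = siteTable(me),
                     window = cfg$dmr_window, min_cpgs = cfg$dmr_min_cpgs)
    results$dmrs <<- dmrs
    say("dmr: ", nrow(dmrs), " DMRs (",
        sum(dmrs$direction == "hyper"), " hyper / ",
        sum(dmrs$direction == "hypo"), " hypo)")
    p <- file.path(cfg$outdir, "dmrs.tsv")
    write.table(dmrs, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    p <- file.path(cfg$outdir, "dmrs.bed")
    writeDmrBed(dmrs, p); emit(p)
  })
  stage("density", cfg$stages[["density"]] && cfg$stages[["ewas"]],
        function() {
    dens <- dmcDensity(siteTable(me), results$dmc$labels,
                       window = cfg$density_window, step = cfg$density_step)
    results$density <<- dens
    paths <- writeDensityBedGraph(dens,
                                  file.path(cfg$outdir, "dmc_density"))
    for (p in paths) emit(p)
  })

  ## annotation (needs a gene table)
  stage("annotate",
        cfg$stages[["annotate"]] && cfg$stages[["ewas"]] &&
          !is.null(cfg$genes), function() {
    genes <- read.table(cfg$genes, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    ann <- nearestTss(results$dmc$labels, genes)
    results$tss <<- ann
    p <- file.path(cfg$outdir, "dmc_nearest_tss.tsv")
    write.table(ann, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    for (dir in c("hyper", "hypo")) {
      fg <- results$dmc$labels[results$dmc$labels$direction == dir, ]
      if (nrow(fg) == 0) next
      enr <- geneDensityEnrichment(fg, siteTable(me), genes)
      p <- file.path(cfg$outdir,
                     paste0("gene_enrichment_", dir, ".tsv"))
      write.table(enr, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
    }
    say("annotate: ", sum(!is.na(ann$gene_id)), " DMCs annotated")
  })

  ## age clock
  stage("clock", cfg$stages[["clock"]] && cfg$stages[["ewas"]],
        function() {
    if (cfg$clock_loocv) {
      ev <- loocvEvaluate(me, sheet = sheet, k = cfg$clock_k,
                          alpha = cfg$clock_alpha)
      results$clock <<- ev
      say(sprintf("clock: LOOCV MAE = %.2f years (n = %d)", ev$mae, ev$n))
      p <- file.path(cfg$outdir, "clock_loocv.tsv")
      write.table(ev$evaluation, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(p)
      model <- ev$model
    } else {
      sel <- selectClockCpgs(results$ewas, me, k = cfg$clock_k)
      model <- trainAgeClock(betaValues(me)[sel, , drop = FALSE],
                             as.numeric(sheet$age),
                             alpha = cfg$clock_alpha)
      results$clock <<- list(model = model)
    }
    p <- file.path(cfg$outdir, "clock_model.tsv")
    writeClockModel(model, p); emit(p)
  })

  ## co-methylation network
  stage("comethylation", cfg$stages[["comethylation"]], function() {
    cm <- runComethylation(me, traits = cfg$traits, k = cfg$wgcna_k,
                           power = cfg$wgcna_power,
                           min_size = cfg$wgcna_min_size,
                           cut_height = cfg$wgcna_cut_height,
                           sheet = sheet)
    results$comethylation <<- cm
    n_mod <- length(setdiff(unique(cm$assignments), "grey"))
    say("comethylation: ", n_mod, " modules")
    p <- file.path(cfg$outdir, "module_assignments.tsv")
    write.table(data.frame(id = names(cm$assignments),
                           module = cm$assignments), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit(p)
    if (!is.null(cm$eigengenes)) {
      p <- file.path(cfg$outdir, "module_eigengenes.tsv")
      write.table(data.frame(sample = rownames(cm$eigengenes),
                             cm$eigengenes), p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(p)
      p <- file.path(cfg$outdir, "module_trait.tsv")
      write.table(cm$module_trait, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(p)
    }
  })

  man <- writeManifest()
  writeLines(logs, logfile)
  invisible(list(manifest = man, outdir = cfg$outdir, results = results,
                 config = cfg))
}
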