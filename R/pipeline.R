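#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for an end-to-end run:
#' either a synthetic-cohort specification or paths to on-disk inputs
#' (Bismark coverage files plus a sample table), never both, together with
#' the filter, clock, promoter and species settings and a global seed that
#' is propagated to every stochastic stage.
#'
#' @param synthetic a [cohortConfig()], or `NULL` when reading real data.
#' @param input list with `cov_files` (named by sample id) and
#'   `sample_table` path, or `NULL` when simulating.
#' @param filter a [filterSpec()].
#' @param clock a [clockConfig()].
#' @param promoter a [promoterSpec()].
#' @param lifespan species maximum lifespan in years (used for the
#'   relative-age scale).
#' @param trend_degree polynomial degree for the trajectory fits.
#' @param seed global integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(synthetic = cohortConfig(), input = NULL,
                           filter = filterSpec(), clock = clockConfig(),
                           promoter = promoterSpec(), lifespan = 31,
                           trend_degree = 1L, seed = 1L) {
  if (is.null(synthetic) == is.null(input))
    stop("exactly one of 'synthetic' and 'input' must be set")
  if (!is.null(synthetic)) synthetic$seed <- as.integer(seed)
  cfg <- list(synthetic = synthetic, input = input, filter = filter,
              clock = clock, promoter = promoter, lifespan = lifespan,
              trend_degree = as.integer(trend_degree),
              seed = as.integer(seed))
  cfg$clock$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every omitted field falls back to the package default; the fully
#' defaulted configuration is echoed into the run manifest so a run is
#' self-describing.
#'
#' @param path YAML file path.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (is.null(y$input))
    do.call(cohortConfig, y$synthetic %||% list())
  filt <- do.call(filterSpec, y$filter %||% list())
  ck <- do.call(clockConfig, y$clock %||% list())
  pm <- do.call(promoterSpec, y$promoter %||% list())
  pipelineConfig(synthetic = syn, input = y$input, filter = filt,
                 clock = ck, promoter = pm,
                 lifespan = y$lifespan %||% 31,
                 trend_degree = y$trend_degree %||% 1L,
                 seed = y$seed %||% 1L)
}

stageFile <- function(outdir, name) file.path(outdir, name)

#' Run the full analysis pipeline
#'
#' Executes the stages in order — ingest or simulate, per-sample global
#' statistics, the genome-wide age-correlation screen with Bonferroni
#' partitioning and PCA, the promoter screen, nested-CV clock training,
#' age-acceleration statistics, and the trajectory / crossover comparison —
#' writing one TSV per stage plus a YAML manifest recording the defaulted
#' configuration, seed, stage outputs and timings. Identical configuration
#' and seed give bit-identical stage outputs. A stage failure halts the run
#' naming the stage.
#'
#' @param config a [pipelineConfig()] (or a YAML path).
#' @param outdir output directory (created).
#' @return the manifest, invisibly (also written to
#'   `manifest.yml`).
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  t0 <- Sys.time()
  run_stage <- function(name, fun) {
    tic <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- list(
      outputs = out,
      seconds = round(as.numeric(difftime(Sys.time(), tic, units = "secs")),
                      3))
    out
  }

  # -- stage 1: ingest or simulate ------------------------------------
  env <- new.env()
  run_stage("ingest", function() {
    if (!is.null(config$synthetic)) {
      cohort <- simulateCohort(config$synthetic)
      env$me <- cohort$methylome
      env$truth <- cohort$truth
      env$catalog <- syntheticGeneCatalog(cohort$truth)
      tpath <- stageFile(outdir, "truth.tsv")
      data.table::fwrite(cohort$truth, tpath, sep = "\t")
    } else {
      st <- readSampleTable(config$input$sample_table)
      calls <- lapply(config$input$cov_files, readBismarkCov,
                      sample_id = "x")
      names(calls) <- names(config$input$cov_files)
      env$me <- buildMethylome(calls, config$filter, sampleData = st)
      env$catalog <- if (!is.null(config$input$gtf))
        readGeneCatalog(config$input$gtf)
    }
    mpaths <- writeMethylome(env$me, stageFile(outdir, "methylome"))
    spath <- stageFile(outdir, "samples.tsv")
    writeSampleTable(as.data.frame(colData(env$me)), spath)
    c(mpaths, spath)
  })
  ages <- sampleAges(env$me)

  # -- stage 2: global per-sample statistics --------------------------
  run_stage("global_stats", function() {
    gs <- cohortSummary(env$me)
    p <- stageFile(outdir, "global_summary.tsv")
    data.table::fwrite(gs, p, sep = "\t")
    p
  })

  # -- stage 3: age-correlation screen + partition + PCA --------------
  run_stage("screen", function() {
    screen <- ageCorrelationScreen(env$me, ages)
    env$screen <- screen
    thr <- bonferroniThreshold(0.05, nrow(screen))
    part <- partitionSignificant(screen, thr)
    env$partition <- part
    p1 <- stageFile(outdir, "screen.tsv")
    data.table::fwrite(screen, p1, sep = "\t")
    p2 <- stageFile(outdir, "partition.tsv")
    data.table::fwrite(data.frame(
      site_id = c(part$negative_sites, part$positive_sites),
      direction = rep(c("negative", "positive"),
                      c(part$n_negative, part$n_positive))), p2, sep = "\t")
    sig <- c(part$negative_sites, part$positive_sites)
    p3 <- NULL
    if (length(sig) >= 2) {
      emb <- pcaEmbed(env$me, sig, n_comp = 2)
      p3 <- stageFile(outdir, "pca.tsv")
      data.table::fwrite(data.frame(sample_id = rownames(emb$scores),
                                    emb$scores), p3, sep = "\t")
    }
    c(p1, p2, p3)
  })

  # -- stage 4: promoter screen ---------------------------------------
  run_stage("promoters", function() {
    if (is.null(env$catalog)) return(character())
    ps <- promoterAgeScreen(env$me, env$catalog, config$promoter, ages)
    p <- stageFile(outdir, "promoter_screen.tsv")
    data.table::fwrite(ps$screen, p, sep = "\t")
    p
  })

  # -- stage 5: clock nested CV ---------------------------------------
  run_stage("clock_cv", function() {
    features <- makeFeatureTable(env$me, config$filter$min_reads, 1.0)
    cv <- nestedCV(features, ages, config$clock)
    env$cv <- cv
    env$clock_model <- cv$models[[1]]
    p1 <- stageFile(outdir, "cv_predictions.tsv")
    data.table::fwrite(cv$predictions, p1, sep = "\t")
    p2 <- stageFile(outdir, "clock_model.tsv")
    writeClockModel(cv$models[[1]], p2)
    c(p1, p2)
  })

  # -- stage 6: age acceleration --------------------------------------
  run_stage("acceleration", function() {
    acc <- ageAcceleration(env$cv$predictions)
    env$acc <- acc
    p1 <- stageFile(outdir, "acceleration.tsv")
    data.table::fwrite(acc, p1, sep = "\t")
    p2 <- NULL
    if ("breeder" %in% colnames(colData(env$me))) {
      groups <- colData(env$me)[acc$sample_id, "breeder"]
      tests <- accelerationTests(acc, groups)
      if (!is.null(tests$per_group)) {
        p2 <- stageFile(outdir, "acceleration_tests.tsv")
        data.table::fwrite(tests$per_group, p2, sep = "\t")
      }
    }
    c(p1, p2)
  })

  # -- stage 7: trajectory comparison ---------------------------------
  run_stage("species_compare", function() {
    model <- env$clock_model
    sp <- list(species = metadata(env$me)$generator$species %||% "cohort",
               me = env$me, ages = ages, lifespan = config$lifespan,
               degree = config$trend_degree)
    if (length(clockSites(model)) >= 2) sp$model <- model
    else sp$sites <- list(decreasing = env$partition$negative_sites,
                          increasing = env$partition$positive_sites)
    tab <- compareSpecies(list(sp))
    p <- stageFile(outdir, "species_comparison.tsv")
    data.table::fwrite(tab, p, sep = "\t")
    p
  })

  manifest <- list(
    package = as.character(utils::packageVersion("methylaging")),
    seed = config$seed,
    config = rapply(unclass(config), unclass, how = "replace"),
    stages = stages,
    total_seconds = round(as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")), 3))
  yaml::write_yaml(manifest, stageFile(outdir, "manifest.yml"))
  invisible(manifest)
}
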