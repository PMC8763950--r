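#' Synthetic cohort configuration
#'
#' Defines an age-structured synthetic RRBS cohort. The defaults describe
#' the reference simulation used throughout the package's validation: 200
#' samples with ages uniform on 0-12 years (the well-sampled age span of a
#' naked mole-rat colony), 5,000 CpG sites of which 300 carry an age signal
#' (150 increasing, 150 decreasing, absolute slope drawn uniformly from
#' 0.01-0.03 per year), read depth from a shifted negative binomial with
#' mean 30 (minimum 1 read), and per-cell Gaussian biological noise with
#' sd 0.05 applied to the true fraction before binomial read sampling.
#'
#' @param n_samples number of animals.
#' @param age_range `(min, max)` ages in years; samples are drawn uniformly.
#' @param n_increasing,n_decreasing,n_stable,n_drift site counts per
#'   trajectory class (`drift_to_half` sites relax extreme baselines toward
#'   0.5, the entropy-increase class).
#' @param slope_range absolute per-year slope range for signal sites.
#' @param drift_rate per-year drift rate for `drift_to_half` sites.
#' @param noise_sd sd of Gaussian noise added to the true fraction
#'   (clipped to `[0, 1]`) before read sampling.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model:
#'   depth = 1 + NB(mu = depth_mean - 1, size = depth_dispersion).
#' @param juvenile when `TRUE`, baselines of samples younger than 0.1 y are
#'   pushed toward the extremes (emulating the low-entropy developmental
#'   state); off by default.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @param species,max_lifespan species label and maximum lifespan (years)
#'   recorded in the sample table / metadata.
#' @return a list of class `cohort_config`.
#' @export
cohortConfig <- function(n_samples = 200L, age_range = c(0, 12),
                         n_increasing = 150L, n_decreasing = 150L,
                         n_stable = 4700L, n_drift = 0L,
                         slope_range = c(0.01, 0.03), drift_rate = 0.02,
                         noise_sd = 0.05, depth_mean = 30,
                         depth_dispersion = 5, juvenile = FALSE,
                         seed = 1L, species = "naked mole-rat",
                         max_lifespan = 31) {
  cfg <- list(n_samples = as.integer(n_samples), age_range = age_range,
              n_increasing = as.integer(n_increasing),
              n_decreasing = as.integer(n_decreasing),
              n_stable = as.integer(n_stable), n_drift = as.integer(n_drift),
              slope_range = slope_range, drift_rate = drift_rate,
              noise_sd = noise_sd, depth_mean = depth_mean,
              depth_dispersion = depth_dispersion, juvenile = juvenile,
              seed = as.integer(seed), species = species,
              max_lifespan = max_lifespan)
  counts <- c(cfg$n_increasing, cfg$n_decreasing, cfg$n_stable, cfg$n_drift)
  if (any(counts < 0)) stop("site counts must be >= 0")
  if (cfg$n_samples < 1) stop("n_samples must be >= 1")
  if (length(age_range) != 2 || diff(age_range) < 0 || age_range[1] < 0)
    stop("age_range must be non-negative and increasing")
  if (age_range[2] > max_lifespan)
    stop("maximum age exceeds the species' maximum lifespan")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (depth_mean < 1) stop("depth_mean must be >= 1")
  structure(cfg, class = "cohort_config")
}

#' True (noise-free) methylation fraction of a site class at a given age
#'
#' Linear classes follow `clip(baseline + slope * age, 0, 1)`; stable sites
#' have slope 0. `drift_to_half` sites move from their baseline toward 0.5
#' at `|slope|` per year and saturate there without crossing, the mechanism
#' by which extreme methylation values erode and methylome entropy rises.
#'
#' @param baseline methylation fraction at age 0, in `[0, 1]`.
#' @param slope per-year change (signed for linear classes; its absolute
#'   value is the drift rate for `drift_to_half`).
#' @param age age in years (vectorised; must be >= 0).
#' @param label one of `"increasing"`, `"decreasing"`, `"stable"`,
#'   `"drift_to_half"`.
#' @return methylation fraction(s) in `[0, 1]`.
#' @examples
#' trueMethylation(0.2, 0.05, 4)                        # 0.4
#' trueMethylation(0.9, 0.05, 4)                        # clipped at 1
#' trueMethylation(1, 0.05, 20, label = "drift_to_half") # saturates at 0.5
#' @export
trueMethylation <- function(baseline, slope, age, label = "increasing") {
  if (any(age < 0)) stop("age must be >= 0")
  if (label == "drift_to_half") {
    off <- abs(baseline - 0.5)
    0.5 + sign(baseline - 0.5) * pmax(off - abs(slope) * age, 0)
  } else {
    clip01(baseline + slope * age)
  }
}

#' Ground-truth site table for a synthetic cohort
#'
#' Draws per-site class labels, baselines and slopes. Signal baselines
#' leave room for the full trajectory over the age range (increasing sites
#' start low, decreasing sites start high); `drift_to_half` baselines start
#' at the extremes. Sites are laid out 100 bp apart, 1,000 per contig.
#'
#' @param config a [cohortConfig()]. Drawn from the current RNG state
#'   (callers seed; [simulateCohort()] does).
#' @return `data.frame`: `site_id`, `contig`, `position`, `label`,
#'   `baseline`, `slope`, `noise_sd`.
#' @export
makeSiteTruth <- function(config) {
  n <- c(increasing = config$n_increasing, decreasing = config$n_decreasing,
         stable = config$n_stable, drift_to_half = config$n_drift)
  total <- sum(n)
  if (total < 1) stop("no sites requested")
  label <- rep(names(n), n)
  baseline <- numeric(total)
  slope <- numeric(total)
  i <- label == "increasing"
  baseline[i] <- runif(sum(i), 0.05, 0.35)
  slope[i] <- runif(sum(i), config$slope_range[1], config$slope_range[2])
  d <- label == "decreasing"
  baseline[d] <- runif(sum(d), 0.65, 0.95)
  slope[d] <- -runif(sum(d), config$slope_range[1], config$slope_range[2])
  s <- label == "stable"
  baseline[s] <- runif(sum(s), 0.02, 0.98)
  h <- label == "drift_to_half"
  baseline[h] <- ifelse(runif(sum(h)) < 0.5, runif(sum(h), 0, 0.05),
                        runif(sum(h), 0.95, 1))
  slope[h] <- config$drift_rate
  idx <- sample(total)   # shuffle classes along the genome
  label <- label[idx]; baseline <- baseline[idx]; slope <- slope[idx]
  contig <- paste0("ctg", (seq_len(total) - 1) %/% 1000 + 1)
  position <- ((seq_len(total) - 1) %% 1000 + 1) * 100
  data.frame(site_id = makeSiteId(contig, position), contig = contig,
             position = position, label = label, baseline = baseline,
             slope = slope, noise_sd = config$noise_sd,
             stringsAsFactors = FALSE)
}

#' Simulate observed methylation for given ages and a site truth table
#'
#' For each cell: the true fraction from [trueMethylation()], plus Gaussian
#' noise (sd from the truth table, clipped to `[0, 1]`), then a binomial
#' draw of methylated reads at a depth drawn from the shifted
#' negative-binomial model. Biological noise is applied before read
#' sampling so recovery tests can separate biological from sampling
#' variance.
#'
#' @param truth a truth table from [makeSiteTruth()] (or hand-built, which
#'   is how region-level tests plant signal at chosen coordinates).
#' @param ages per-sample ages in years.
#' @param config a [cohortConfig()] supplying the depth model and juvenile
#'   flag. Uses the current RNG state.
#' @param sample_ids optional sample names.
#' @return a [MethylomeExperiment-class] with `beta` and `coverage` assays.
#' @export
simulateMethylome <- function(truth, ages, config, sample_ids = NULL) {
  S <- nrow(truth); N <- length(ages)
  if (S < 1 || N < 1) stop("need at least one site and one sample")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(N))
  p <- matrix(0, S, N)
  for (lab in unique(truth$label)) {
    rows <- which(truth$label == lab)
    p[rows, ] <- vapply(seq_len(N), function(j)
      trueMethylation(truth$baseline[rows], truth$slope[rows], ages[j],
                      label = lab), numeric(length(rows)))
  }
  if (isTRUE(config$juvenile)) {
    young <- ages < 0.1
    if (any(young))
      p[, young] <- clip01(0.5 + (p[, young, drop = FALSE] - 0.5) * 1.3)
  }
  noise <- matrix(rnorm(S * N, 0, truth$noise_sd), S, N)
  p_obs <- clip01(p + noise)
  depth <- matrix(
    1L + rnbinom(S * N, mu = config$depth_mean - 1,
                 size = config$depth_dispersion), S, N)
  meth <- matrix(rbinom(S * N, size = depth, prob = p_obs), S, N)
  beta <- meth / depth
  dimnames(beta) <- dimnames(depth) <-
    list(truth$site_id, sample_ids)
  MethylomeExperiment(
    beta, depth,
    sites = data.frame(contig = truth$contig, position = truth$position),
    metadata = list(generator = list(seed = config$seed,
                                     species = config$species)))
}

#' Simulate a full age-structured cohort
#'
#' Draws ages uniformly on the configured range, a ground-truth site table,
#' and observed methylation with binomial read sampling. Identical seeds
#' give bit-identical output.
#'
#' @param config a [cohortConfig()].
#' @return list with elements `methylome` (a
#'   [MethylomeExperiment-class] whose `colData` holds the sample table),
#'   `samples` (the sample table: `sample_id`, `age`, `sex`, `breeder`,
#'   `species`) and `truth` (the [makeSiteTruth()] table).
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_samples = 20, n_increasing = 5,
#'                                       n_decreasing = 5, n_stable = 40,
#'                                       seed = 7))
#' cohort$methylome
#' @export
simulateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohort_config"))
  withSeed(config$seed, {
    n <- config$n_samples
    ages <- runif(n, config$age_range[1], config$age_range[2])
    sex <- sample(c("female", "male"), n, replace = TRUE)
    breeder <- sample(c("queen", "breeding_male", "non_breeder"), n,
                      replace = TRUE, prob = c(0.06, 0.06, 0.88))
    breeder[breeder == "queen" & sex == "male"] <- "breeding_male"
    breeder[breeder == "breeding_male" & sex == "female"] <- "queen"
    samples <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                          age = ages, sex = sex, breeder = breeder,
                          species = config$species,
                          stringsAsFactors = FALSE)
    truth <- makeSiteTruth(config)
    me <- simulateMethylome(truth, ages, config,
                            sample_ids = samples$sample_id)
    colData(me) <- S4Vectors::DataFrame(samples,
                                        row.names = samples$sample_id)
    metadata(me)$generator <- list(seed = config$seed,
                                   species = config$species,
                                   max_lifespan = config$max_lifespan,
                                   config = unclass(config))
    list(methylome = me, samples = samples, truth = truth)
  })
}

#' Write a synthetic cohort in the on-disk formats the reader consumes
#'
#' Emits one Bismark-style coverage file per sample plus the sample table,
#' so the ingest path can be exercised end-to-end against generated data.
#'
#' @param cohort a [simulateCohort()] result.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  me <- cohort$methylome
  b <- methLevels(me); cv <- methCoverage(me)
  sites <- splitSiteId(rownames(me))
  paths <- vapply(colnames(me), function(s) {
    meth <- ifelse(is.na(b[, s]), 0L, as.integer(round(b[, s] * cv[, s])))
    calls <- data.frame(contig = sites$contig, position = sites$position,
                        count_meth = meth,
                        count_unmeth = cv[, s] - meth)
    calls$beta <- ifelse(cv[, s] > 0, calls$count_meth / cv[, s], NA_real_)
    writeBismarkCov(calls, file.path(dir, paste0(s, ".cov")))
  }, character(1))
  st <- file.path(dir, "samples.tsv")
  writeSampleTable(cohort$samples, st)
  invisible(c(paths, st))
}

#' A toy gene catalog laid over synthetic cohort coordinates
#'
#' Builds gene models spanning blocks of consecutive synthetic CpG sites so
#' promoter and gene-body analyses can run on generated cohorts. Genes are
#' placed on alternating strands; gene spans cover `sites_per_gene`
#' adjacent sites with the whole span taken as a single exon.
#'
#' @param truth a [makeSiteTruth()] table.
#' @param sites_per_gene CpG sites per gene body.
#' @param gap_sites sites skipped between genes (left intergenic).
#' @return a [GeneCatalog-class]. Synthetic: the gene structure is
#'   generated, not taken from any real annotation.
#' @export
syntheticGeneCatalog <- function(truth, sites_per_gene = 10L,
                                 gap_sites = 5L) {
  per <- split(seq_len(nrow(truth)), truth$contig)
  genes <- list(); k <- 0L
  for (ctg in names(per)) {
    idx <- per[[ctg]][order(truth$position[per[[ctg]]])]
    i <- 1L
    while (i + sites_per_gene - 1L <= length(idx)) {
      block <- idx[i:(i + sites_per_gene - 1L)]
      k <- k + 1L
      genes[[k]] <- data.frame(
        gene_id = sprintf("SYNG%04d", k), contig = ctg,
        start = min(truth$position[block]),
        end = max(truth$position[block]),
        strand = if (k %% 2L == 1L) "+" else "-")
      i <- i + sites_per_gene + gap_sites
    }
  }
  gdf <- do.call(rbind, genes)
  gr <- GRanges(gdf$contig, IRanges(gdf$start, gdf$end),
                strand = gdf$strand)
  gr$gene_id <- gdf$gene_id
  gr$tss <- ifelse(gdf$strand == "+", gdf$start, gdf$end)
  ex <- gr
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(gene_id = gdf$gene_id)
  GeneCatalog(genes = gr, exons = ex)
}
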