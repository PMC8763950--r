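#' @import SummarizedExperiment
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames
NULL

#' MethylomeExperiment: per-CpG methylation fractions with read coverage
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with two assays:
#' `beta` (methylation fraction in `[0, 1]`, `NA` where a site has zero
#' reads in a sample) and `coverage` (non-negative integer read counts).
#' Rows are CpG sites (single-base [GenomicRanges::GRanges], names are
#' `<contig>_<position>` identifiers); columns are samples, with age / sex /
#' breeder-status / species metadata in `colData` when supplied.
#'
#' Betas are always recomputed from the methylated and unmethylated read
#' counts, never taken from a percentage column, so a `beta` cell is `NA`
#' exactly where `coverage` is zero.
#'
#' @aliases MethylomeExperiment-class
#' @export
setClass("MethylomeExperiment", contains = "RangedSummarizedExperiment")

setValidity("MethylomeExperiment", function(object) {
  an <- assayNames(object)
  if (!all(c("beta", "coverage") %in% an))
    return("assays must include 'beta' and 'coverage'")
  b <- assay(object, "beta")
  cv <- assay(object, "coverage")
  if (!identical(dim(b), dim(cv)))
    return("'beta' and 'coverage' dimensions differ")
  if (any(b < 0 | b > 1, na.rm = TRUE))
    return("beta values must lie in [0, 1]")
  if (any(cv < 0, na.rm = TRUE))
    return("coverage must be non-negative")
  if (any(is.na(b) & cv > 0))
    return("beta is NA at a covered cell")
  TRUE
})

#' Construct a MethylomeExperiment
#'
#' @param beta sites x samples numeric matrix of methylation fractions
#'   (`NA` allowed only where `coverage` is 0); rownames are site ids,
#'   colnames sample ids.
#' @param coverage matching matrix of total read counts.
#' @param sites optional `data.frame` with `contig` and `position`
#'   (1-based); derived from rownames of `beta` by [splitSiteId()] when
#'   omitted.
#' @param sampleData optional per-sample `data.frame` (e.g. a sample table
#'   with `sample_id`, `age`, `sex`, `breeder`, `species`).
#' @param metadata list stored in the object metadata (filter spec,
#'   retention report, generator seed, ...).
#' @return A [MethylomeExperiment-class] object.
#' @examples
#' b <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2,
#'             dimnames = list(c("ctg1_100", "ctg1_200"), c("s1", "s2")))
#' cv <- matrix(10L, 2, 2, dimnames = dimnames(b))
#' me <- MethylomeExperiment(b, cv)
#' methLevels(me)
#' @export
MethylomeExperiment <- function(beta, coverage, sites = NULL,
                                sampleData = NULL, metadata = list()) {
  beta <- as.matrix(beta)
  coverage <- as.matrix(coverage)
  storage.mode(coverage) <- "integer"
  if (is.null(sites)) sites <- splitSiteId(rownames(beta))
  gr <- GRanges(sites$contig, IRanges(sites$position, width = 1))
  names(gr) <- makeSiteId(sites$contig, sites$position)
  rownames(beta) <- rownames(coverage) <- names(gr)
  cd <- if (is.null(sampleData)) DataFrame(row.names = colnames(beta))
        else DataFrame(sampleData, row.names = sampleData$sample_id)
  se <- SummarizedExperiment(
    assays = list(beta = beta, coverage = coverage),
    rowRanges = gr, colData = cd, metadata = metadata)
  new("MethylomeExperiment", se)
}

#' @rdname MethylomeExperiment
#' @param x,object a `MethylomeExperiment`.
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))

#' @rdname MethylomeExperiment
#' @export
setMethod("methLevels", "MethylomeExperiment",
          function(x) assay(x, "beta"))

#' @rdname MethylomeExperiment
#' @export
setGeneric("methCoverage", function(x) standardGeneric("methCoverage"))

#' @rdname MethylomeExperiment
#' @export
setMethod("methCoverage", "MethylomeExperiment",
          function(x) assay(x, "coverage"))

#' @rdname MethylomeExperiment
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname MethylomeExperiment
#' @export
setMethod("siteIds", "MethylomeExperiment", function(x) rownames(x))

#' @rdname MethylomeExperiment
#' @export
setGeneric("sampleAges", function(x) standardGeneric("sampleAges"))

#' @rdname MethylomeExperiment
#' @export
setMethod("sampleAges", "MethylomeExperiment", function(x) {
  if (!"age" %in% colnames(colData(x)))
    stop("no 'age' column in colData; supply ages explicitly")
  setNames(as.numeric(colData(x)$age), colnames(x))
})

#' @rdname MethylomeExperiment
#' @export
setMethod("show", "MethylomeExperiment", function(object) {
  cat("MethylomeExperiment:", nrow(object), "CpG sites x",
      ncol(object), "samples\n")
  b <- assay(object, "beta")
  cat("  beta: mean", round(mean(b, na.rm = TRUE), 4),
      "| missing cells:", sum(is.na(b)), "\n")
  if ("age" %in% colnames(colData(object)))
    cat("  ages:", paste(round(range(colData(object)$age), 2),
                         collapse = " - "), "years\n")
  fs <- metadata(object)$filter
  if (!is.null(fs))
    cat("  filter: >=", fs$min_reads, "reads in >=",
        100 * fs$min_sample_fraction, "% of samples\n")
})

#' GeneCatalog: gene models distilled from a GTF annotation
#'
#' Holds one record per `gene_id` (contig, strand, the min-start / max-end
#' span over its transcripts, and the transcription start site: the span
#' start on `+`, the span end on `-`) plus the exon intervals used for
#' exon / intron feature labelling.
#'
#' @slot genes [GenomicRanges::GRanges] of gene spans with metadata columns
#'   `gene_id` and `tss`.
#' @slot exons [GenomicRanges::GRanges] of exon intervals with metadata
#'   column `gene_id` (may be empty).
#' @aliases GeneCatalog-class
#' @export
setClass("GeneCatalog",
         representation(genes = "GRanges", exons = "GRanges"))

setValidity("GeneCatalog", function(object) {
  g <- object@genes
  if (!all(c("gene_id", "tss") %in% colnames(S4Vectors::mcols(g))))
    return("genes must carry 'gene_id' and 'tss' metadata columns")
  if (anyDuplicated(g$gene_id)) return("gene_id values must be unique")
  if (length(g) && !all(g$tss == start(g) | g$tss == end(g)))
    return("TSS must coincide with the gene span start or end")
  TRUE
})

#' @rdname GeneCatalog
#' @param genes,exons see slots.
#' @export
GeneCatalog <- function(genes, exons = GRanges()) {
  new("GeneCatalog", genes = genes, exons = exons)
}

#' @rdname GeneCatalog
#' @param x,object a `GeneCatalog`.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneCatalog
#' @export
setMethod("geneRanges", "GeneCatalog", function(x) x@genes)

#' @rdname GeneCatalog
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneCatalog
#' @export
setMethod("exonRanges", "GeneCatalog", function(x) x@exons)

#' @rdname GeneCatalog
#' @export
setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog:", length(object@genes), "genes,",
      length(object@exons), "exon records\n")
})

#' ClockModel: a linear epigenetic age predictor
#'
#' The predicted age of a sample is `intercept + sum(weights * beta)` over
#' the clock sites (CpGs with non-zero elastic-net weight), in years.
#'
#' @slot intercept model intercept, years.
#' @slot weights named numeric vector, years per unit beta, one element per
#'   clock site (sites whose fitted weight is non-zero).
#' @slot mixing elastic-net mixing parameter used in training.
#' @slot lambda penalty strength selected by inner cross-validation.
#' @slot seed integer seed the training run used.
#' @slot trainSamples ids of the samples the model was fitted on.
#' @slot metadata list (training predictions, fold assignment, config).
#' @aliases ClockModel-class
#' @export
setClass("ClockModel",
         representation(intercept = "numeric", weights = "numeric",
                        mixing = "numeric", lambda = "numeric",
                        seed = "integer", trainSamples = "character",
                        metadata = "list"))

setValidity("ClockModel", function(object) {
  if (length(object@intercept) != 1 || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  if (length(object@weights) && is.null(names(object@weights)))
    return("weights must be named by site id")
  if (any(!is.finite(object@weights)))
    return("weights must be finite")
  TRUE
})

#' @rdname ClockModel
#' @param intercept,weights,mixing,lambda,seed,trainSamples,metadata see slots.
#' @export
ClockModel <- function(intercept, weights, mixing = 0.5,
                       lambda = NA_real_, seed = NA_integer_,
                       trainSamples = character(), metadata = list()) {
  new("ClockModel", intercept = as.numeric(intercept),
      weights = weights, mixing = mixing, lambda = lambda,
      seed = as.integer(seed), trainSamples = trainSamples,
      metadata = metadata)
}

#' @rdname ClockModel
#' @param x,object a `ClockModel`.
#' @export
setGeneric("clockIntercept", function(x) standardGeneric("clockIntercept"))

#' @rdname ClockModel
#' @export
setMethod("clockIntercept", "ClockModel", function(x) x@intercept)

#' @rdname ClockModel
#' @export
setGeneric("clockWeights", function(x) standardGeneric("clockWeights"))

#' @rdname ClockModel
#' @export
setMethod("clockWeights", "ClockModel", function(x) x@weights)

#' @rdname ClockModel
#' @export
setGeneric("clockSites", function(x) standardGeneric("clockSites"))

#' @rdname ClockModel
#' @export
setMethod("clockSites", "ClockModel", function(x) names(x@weights))

#' @rdname ClockModel
#' @export
setMethod("show", "ClockModel", function(object) {
  cat("ClockModel:", length(object@weights), "clock sites, intercept",
      round(object@intercept, 3), "years\n")
  cat("  mixing:", object@mixing, "| lambda:",
      signif(object@lambda, 4), "| trained on",
      length(object@trainSamples), "samples\n")
})

#' TrajectoryFit: polynomial trend of mean methylation versus age
#'
#' Least-squares polynomial (degree 1 or 2) fitted to the mean methylation
#' of a site set against chronological age, with the residual standard
#' deviation and the age range the fit is valid on.
#'
#' @slot label site-set label, e.g. `"decreasing"` or `"increasing"`.
#' @slot degree polynomial degree (1 linear, 2 quadratic).
#' @slot coefficients numeric `(intercept, linear[, quadratic])`, units
#'   methylation fraction per year^k.
#' @slot residualSd residual standard deviation of the fit.
#' @slot ageRange the fitted age range, years; fitted values are meaningful
#'   only inside it.
#' @aliases TrajectoryFit-class
#' @export
setClass("TrajectoryFit",
         representation(label = "character", degree = "integer",
                        coefficients = "numeric", residualSd = "numeric",
                        ageRange = "numeric"))

setValidity("TrajectoryFit", function(object) {
  if (!object@degree %in% c(1L, 2L)) return("degree must be 1 or 2")
  if (length(object@coefficients) != object@degree + 1)
    return("coefficient count must equal degree + 1")
  if (length(object@ageRange) != 2 || diff(object@ageRange) < 0)
    return("ageRange must be an increasing length-2 vector")
  TRUE
})

#' @rdname TrajectoryFit
#' @param object a `TrajectoryFit`.
#' @export
setMethod("show", "TrajectoryFit", function(object) {
  cat("TrajectoryFit [", object@label, "]: degree", object@degree,
      "coefficients", paste(signif(object@coefficients, 4), collapse = ", "),
      "\n  residual sd", signif(object@residualSd, 4), "on ages",
      paste(round(object@ageRange, 2), collapse = " - "), "years\n")
})

#' Evaluate a fitted methylation trajectory at given ages
#'
#' @param fit a [TrajectoryFit-class].
#' @param ages numeric vector of ages, years.
#' @param extrapolate evaluate outside the fitted age range (default
#'   `FALSE`, which errors on out-of-range ages).
#' @return numeric vector of fitted mean methylation values.
#' @export
trendValues <- function(fit, ages, extrapolate = FALSE) {
  stopifnot(is(fit, "TrajectoryFit"))
  if (!extrapolate &&
      any(ages < fit@ageRange[1] - 1e-9 | ages > fit@ageRange[2] + 1e-9))
    stop("ages outside the fitted age range; set extrapolate = TRUE")
  cf <- fit@coefficients
  v <- cf[1] + cf[2] * ages
  if (fit@degree == 2L) v <- v + cf[3] * ages^2
  v
}
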