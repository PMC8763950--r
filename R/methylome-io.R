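#' @importFrom data.table fread fwrite data.table rbindlist dcast setDF
NULL

#' Coverage filter specification
#'
#' A CpG site is retained when it is covered by at least `min_reads` reads
#' in at least `min_sample_fraction` of the samples. The defaults (5 reads,
#' 90% of samples) are the standard RRBS common-site filter; the clock
#' feature table tightens the fraction to 1 (see [makeFeatureTable()]).
#'
#' @param min_reads minimum read count for a cell to count as covered
#'   (integer >= 1).
#' @param min_sample_fraction required fraction of covered samples, in
#'   `(0, 1]`.
#' @return a list of class `filter_spec`.
#' @examples
#' filterSpec()            # >= 5 reads in >= 90% of samples
#' filterSpec(5, 1.0)      # the stricter clock-feature criterion
#' @export
filterSpec <- function(min_reads = 5L, min_sample_fraction = 0.9) {
  min_reads <- as.integer(min_reads)
  if (is.na(min_reads) || min_reads < 1L) stop("min_reads must be >= 1")
  if (!is.numeric(min_sample_fraction) || min_sample_fraction <= 0 ||
      min_sample_fraction > 1)
    stop("min_sample_fraction must lie in (0, 1]")
  structure(list(min_reads = min_reads,
                 min_sample_fraction = min_sample_fraction),
            class = "filter_spec")
}

#' Read a Bismark coverage file
#'
#' Parses the 6-column Bismark `.cov` format (contig, start, end,
#' methylation percentage, count methylated, count unmethylated). The beta
#' value is recomputed from the two integer counts; the percentage column is
#' only checked for consistency (a warning is raised when it disagrees by
#' more than one percentage point). Coordinates are taken from the start
#' column as 1-based. Plain and gzip-compressed files are accepted.
#'
#' @param path path to the coverage file.
#' @param sample_id sample identifier attached to the result.
#' @return `data.frame` of methylation calls: `contig`, `position`,
#'   `count_meth`, `count_unmeth`, `beta` (`NA` where total reads are 0)
#'   and `site_id`, with attribute `sample_id`.
#' @export
readBismarkCov <- function(path, sample_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = TRUE,
          colClasses = list(character = 1)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (ncol(dt) < 6)
    stop("expected >= 6 tab-separated columns in ", path,
         ", found ", ncol(dt))
  bad <- which(!stats::complete.cases(dt[, c(2, 3, 5, 6)]))
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path)
  calls <- data.frame(
    contig = as.character(dt[[1]]),
    position = as.integer(dt[[2]]),
    count_meth = as.integer(dt[[5]]),
    count_unmeth = as.integer(dt[[6]]),
    stringsAsFactors = FALSE)
  if (any(calls$count_meth < 0 | calls$count_unmeth < 0))
    stop("negative read counts in ", path)
  if (any(calls$position < 1))
    stop("non-positive coordinates in ", path)
  total <- calls$count_meth + calls$count_unmeth
  calls$beta <- ifelse(total > 0, calls$count_meth / total, NA_real_)
  pct <- suppressWarnings(as.numeric(dt[[4]]))
  disagree <- !is.na(calls$beta) & is.finite(pct) &
    abs(pct - 100 * calls$beta) > 1
  if (any(disagree))
    warning(sum(disagree), " line(s) in ", path,
            " have a methylation percentage inconsistent with the counts;",
            " counts were used")
  calls$site_id <- makeSiteId(calls$contig, calls$position)
  attr(calls, "sample_id") <- sample_id
  calls
}

#' Write methylation calls in Bismark coverage format
#'
#' @param calls a calls `data.frame` as returned by [readBismarkCov()].
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
writeBismarkCov <- function(calls, path) {
  total <- calls$count_meth + calls$count_unmeth
  pct <- ifelse(total > 0, 100 * calls$count_meth / total, 0)
  out <- data.table(calls$contig, calls$position, calls$position,
                    pct, calls$count_meth, calls$count_unmeth)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Build a coverage-filtered methylation matrix from per-sample calls
#'
#' Assembles per-sample Bismark-style calls into a
#' [MethylomeExperiment-class], retaining exactly the CpG sites covered by
#' at least `spec$min_reads` reads in at least `spec$min_sample_fraction`
#' of the samples. At retained sites, betas in the minority of samples
#' below the read cutoff are kept as computed from whatever reads exist
#' (they are `NA` only at zero coverage); downstream correlations therefore
#' use all samples at every retained site. Sites are ordered
#' lexicographically by contig, then by position. A retention report
#' (`sites_in`, `sites_retained`) is stored in the object metadata.
#'
#' @param calls_by_sample named list (sample id -> calls `data.frame`,
#'   see [readBismarkCov()]).
#' @param spec a [filterSpec()].
#' @param sampleData optional sample table merged into `colData`.
#' @return a [MethylomeExperiment-class]; empty (with a warning) when no
#'   site survives the filter.
#' @export
buildMethylome <- function(calls_by_sample, spec = filterSpec(),
                           sampleData = NULL) {
  if (!is.list(calls_by_sample) || length(calls_by_sample) < 2)
    stop("need calls for at least 2 samples")
  if (is.null(names(calls_by_sample)) || anyDuplicated(names(calls_by_sample)))
    stop("calls_by_sample must be uniquely named by sample id")
  if (!inherits(spec, "filter_spec")) stop("spec must be a filterSpec()")
  samples <- names(calls_by_sample)
  dt <- rbindlist(lapply(samples, function(s) {
    cc <- calls_by_sample[[s]]
    data.table(sample = s, contig = cc$contig, position = cc$position,
               total = cc$count_meth + cc$count_unmeth, beta = cc$beta)
  }))
  covW <- dcast(dt, contig + position ~ sample, value.var = "total",
                fill = 0L)
  betaW <- dcast(dt, contig + position ~ sample, value.var = "beta")
  ord <- order(covW$contig, covW$position)
  covW <- covW[ord]; betaW <- betaW[ord]
  cv <- as.matrix(covW[, samples, with = FALSE])
  b <- as.matrix(betaW[, samples, with = FALSE])
  covered_frac <- rowMeans(cv >= spec$min_reads)
  keep <- covered_frac >= spec$min_sample_fraction
  report <- list(sites_in = nrow(cv), sites_retained = sum(keep))
  message("coverage filter: ", report$sites_retained, " of ",
          report$sites_in, " sites retained")
  if (!any(keep))
    warning("no CpG site survives the coverage filter; empty matrix")
  sites <- data.frame(contig = covW$contig[keep],
                      position = covW$position[keep])
  b <- b[keep, , drop = FALSE]
  cv <- cv[keep, , drop = FALSE]
  rownames(b) <- rownames(cv) <- makeSiteId(sites$contig, sites$position)
  if (!is.null(sampleData)) {
    sampleData <- sampleData[match(samples, sampleData$sample_id), ,
                             drop = FALSE]
    if (anyNA(sampleData$sample_id))
      stop("sampleData is missing some samples present in the calls")
  }
  MethylomeExperiment(b, cv, sites = sites, sampleData = sampleData,
                      metadata = list(filter = spec, retention = report))
}

#' Read and validate a sample table
#'
#' The table is tab-separated with a header and must carry the columns
#' `sample_id`, `age` (years), `sex`, `breeder` and `species`. Sample ids
#' must be unique and ages finite and non-negative.
#'
#' @param path TSV path.
#' @return a validated `data.frame`.
#' @export
readSampleTable <- function(path) {
  df <- setDF(fread(path, sep = "\t", header = TRUE,
                    colClasses = list(character = "sample_id")))
  validateSampleTable(df)
}

validateSampleTable <- function(df) {
  required <- c("sample_id", "age", "sex", "breeder", "species")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols))
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("sample_id values must be unique")
  df$age <- as.numeric(df$age)
  if (any(!is.finite(df$age)) || any(df$age < 0))
    stop("ages must be finite and non-negative")
  df
}

#' @rdname readSampleTable
#' @param df sample table to write.
#' @param path TSV path.
#' @export
writeSampleTable <- function(df, path) {
  df <- validateSampleTable(df)
  df$age <- sprintf("%.17g", df$age)  # ages round-trip exactly
  fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write / read a methylome matrix archive
#'
#' The archive is a pair of tab-separated matrices (`<prefix>_beta.tsv`,
#' `<prefix>_coverage.tsv`): one header line of sample ids, one row per
#' site id, missing betas as `NA`. Floats are written with the shortest
#' round-trippable decimal representation, so write-then-read reproduces
#' the matrices bit-exactly. Sample metadata, when present, goes to
#' `<prefix>_samples.tsv`.
#'
#' @param me a [MethylomeExperiment-class].
#' @param prefix path prefix for the archive files.
#' @return [writeMethylome()] returns the written paths invisibly;
#'   [readMethylome()] returns a [MethylomeExperiment-class].
#' @export
writeMethylome <- function(me, prefix) {
  stopifnot(is(me, "MethylomeExperiment"))
  paths <- paste0(prefix, c("_beta.tsv", "_coverage.tsv"))
  bm <- methLevels(me)
  # 17 significant digits: every double round-trips through text exactly
  btxt <- matrix(ifelse(is.na(bm), "NA", sprintf("%.17g", bm)),
                 nrow(bm), dimnames = dimnames(bm))
  b <- data.table(site_id = rownames(me), as.data.frame(btxt))
  cv <- data.table(site_id = rownames(me), as.data.frame(methCoverage(me)))
  fwrite(b, paths[1], sep = "\t", na = "NA", quote = FALSE)
  fwrite(cv, paths[2], sep = "\t", na = "NA", quote = FALSE)
  if (ncol(colData(me)) > 0) {
    sp <- paste0(prefix, "_samples.tsv")
    cd <- as.data.frame(colData(me))
    if (all(c("sample_id", "age", "sex", "breeder", "species") %in%
            colnames(cd)))
      writeSampleTable(cd, sp)
    else fwrite(cd, sp, sep = "\t")
    paths <- c(paths, sp)
  }
  invisible(paths)
}

#' @rdname writeMethylome
#' @export
readMethylome <- function(prefix) {
  bpath <- paste0(prefix, "_beta.tsv")
  cpath <- paste0(prefix, "_coverage.tsv")
  spath <- paste0(prefix, "_samples.tsv")
  b <- fread(bpath, sep = "\t", header = TRUE, na.strings = "NA")
  cv <- fread(cpath, sep = "\t", header = TRUE)
  ids <- b$site_id
  bm <- as.matrix(b[, -1]); rownames(bm) <- ids
  cm <- as.matrix(cv[, -1]); rownames(cm) <- cv$site_id
  cm <- cm[ids, colnames(bm), drop = FALSE]
  sampleData <- if (file.exists(spath))
    setDF(fread(spath, sep = "\t", header = TRUE,
                colClasses = list(character = "sample_id")))
  MethylomeExperiment(bm, cm, sampleData = sampleData)
}

#' Distill a GTF annotation into a gene catalog
#'
#' One record per `gene_id`: contig, strand, the min-start / max-end span
#' across its transcript (or, failing that, exon) records, and the TSS
#' (span start on the `+` strand, span end on `-`). Records without a
#' `gene_id` attribute are skipped and counted; genes with unknown or
#' conflicting strand are excluded with a warning.
#'
#' @param path GTF file path.
#' @return a [GeneCatalog-class].
#' @export
readGeneCatalog <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% colnames(S4Vectors::mcols(gr)))
    stop("GTF has no gene_id attribute")
  no_id <- is.na(gr$gene_id) | gr$gene_id == ""
  if (any(no_id))
    message(sum(no_id), " GTF record(s) without gene_id skipped")
  gr <- gr[!no_id]
  use <- if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
             any(gr$type %in% c("transcript", "mRNA")))
    gr[gr$type %in% c("transcript", "mRNA")] else gr[gr$type == "exon"]
  if (!length(use)) use <- gr
  ids <- unique(use$gene_id)
  per <- S4Vectors::split(use, factor(use$gene_id, levels = ids))
  st <- vapply(per, function(g) min(start(g)), integer(1))
  en <- vapply(per, function(g) max(end(g)), integer(1))
  ctg <- vapply(per, function(g) as.character(seqnames(g)[1]), character(1))
  strands <- vapply(per, function(g) {
    s <- unique(as.character(strand(g)))
    if (length(s) == 1) s else "conflict"
  }, character(1))
  bad <- !strands %in% c("+", "-")
  if (any(bad))
    warning(sum(bad), " gene(s) with unknown or conflicting strand excluded")
  keep <- !bad
  genes <- GRanges(unname(ctg[keep]), IRanges(unname(st[keep]),
                                              unname(en[keep])),
                   strand = unname(strands[keep]))
  genes$gene_id <- ids[keep]
  genes$tss <- unname(ifelse(strands[keep] == "+", st[keep], en[keep]))
  exons <- gr[gr$type == "exon" & gr$gene_id %in% ids[keep]]
  ex <- GRanges(seqnames(exons), IRanges(start(exons), end(exons)),
                strand = strand(exons))
  ex$gene_id <- exons$gene_id
  GeneCatalog(genes = genes, exons = ex)
}
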