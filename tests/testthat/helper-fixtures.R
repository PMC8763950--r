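# Shared fixture builders. Everything is generated in code at test time.

clipv <- function(x) pmin(pmax(x, 0), 1)

# A small MethylomeExperiment straight from matrices.
tinyMethylome <- function(beta, coverage = NULL, ages = NULL,
                          contig = "ctg1") {
  beta <- as.matrix(beta)
  parses <- function(x) !is.null(x) &&
    !inherits(try(methylaging::splitSiteId(x), silent = TRUE), "try-error")
  if (!parses(rownames(beta)))
    rownames(beta) <- paste0(contig, "_", seq_len(nrow(beta)) * 100)
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("S%02d", seq_len(ncol(beta)))
  if (is.null(coverage)) {
    coverage <- matrix(10L, nrow(beta), ncol(beta), dimnames = dimnames(beta))
    coverage[is.na(beta)] <- 0L
  }
  sampleData <- if (!is.null(ages))
    data.frame(sample_id = colnames(beta), age = ages, sex = "unknown",
               breeder = "unknown", species = "synthetic")
  MethylomeExperiment(beta, coverage, sampleData = sampleData)
}

# Write a Bismark coverage file from a calls-like data.frame.
writeCovFixture <- function(df, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", df$contig, df$position,
                   df$position, format(df$pct), df$count_meth,
                   df$count_unmeth)
  writeLines(lines, path)
  path
}

# Toy GTF with one line per (type, gene) record.
writeGtfFixture <- function(records, path) {
  lines <- sprintf(
    '%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    records$contig, records$type, records$start, records$end,
    records$strand, records$gene_id, records$transcript_id)
  writeLines(lines, path)
  path
}

# A gene catalog built directly (no GTF round trip).
makeCatalog <- function(gene_id, contig, start, end, strand,
                        exons = NULL) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                               strand = strand)
  gr$gene_id <- gene_id
  gr$tss <- ifelse(strand == "+", start, end)
  ex <- if (is.null(exons)) GenomicRanges::GRanges() else {
    e <- GenomicRanges::GRanges(exons$contig,
                                IRanges::IRanges(exons$start, exons$end))
    e$gene_id <- exons$gene_id
    e
  }
  GeneCatalog(genes = gr, exons = ex)
}

# A deterministic mid-sized cohort reused across tests.
smallCohort <- function(seed = 42, n_samples = 60, n_signal = 30,
                        n_stable = 240) {
  simulateCohort(cohortConfig(
    n_samples = n_samples, n_increasing = n_signal,
    n_decreasing = n_signal, n_stable = n_stable, seed = seed))
}
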