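#' Promoter window specification
#'
#' The promoter is the window from `upstream` bp before to `downstream` bp
#' after the transcription start site, following the direction of
#' transcription. Defaults are the standard 1500 bp upstream / 500 bp
#' downstream window.
#'
#' @param upstream,downstream non-negative extents in bp.
#' @return list of class `promoter_spec`.
#' @export
promoterSpec <- function(upstream = 1500L, downstream = 500L) {
  if (upstream < 0 || downstream < 0) stop("extents must be >= 0")
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream)),
            class = "promoter_spec")
}

#' Strand-aware promoter regions of a gene catalog
#'
#' For a `+` strand gene the promoter is `[TSS - upstream, TSS +
#' downstream]`; for `-` strand, `[TSS - downstream, TSS + upstream]`
#' (1-based inclusive, clipped at position 1).
#'
#' @param catalog a [GeneCatalog-class] (or its gene [GenomicRanges::GRanges]).
#' @param spec a [promoterSpec()].
#' @return [GenomicRanges::GRanges] of promoter windows, one per gene,
#'   with `gene_id` metadata.
#' @examples
#' # + strand TSS 10000 with defaults -> [8500, 10500]
#' @export
promoterRegions <- function(catalog, spec = promoterSpec()) {
  g <- if (is(catalog, "GeneCatalog")) geneRanges(catalog) else catalog
  str <- as.character(strand(g))
  if (any(!str %in% c("+", "-")))
    stop("gene(s) with unknown strand: ",
         paste(head(g$gene_id[!str %in% c("+", "-")], 3), collapse = ", "))
  lo <- ifelse(str == "+", g$tss - spec$upstream, g$tss - spec$downstream)
  hi <- ifelse(str == "+", g$tss + spec$downstream, g$tss + spec$upstream)
  pr <- GRanges(seqnames(g), IRanges(pmax(lo, 1), hi), strand = str)
  pr$gene_id <- g$gene_id
  pr
}

siteGRanges <- function(me) {
  if (is(me, "MethylomeExperiment")) SummarizedExperiment::rowRanges(me)
  else me
}

#' Promoter-level methylation-age screen
#'
#' Per gene: the mean methylation of the CpG sites falling in its promoter
#' window, per sample (missing betas excluded), then Pearson r / two-sided
#' p against age. Genes with no covered promoter CpG are reported
#' separately, and the Bonferroni threshold uses the number of genes
#' actually scored (the divisor is reported rather than fixed silently).
#'
#' @param me a [MethylomeExperiment-class].
#' @param catalog a [GeneCatalog-class].
#' @param spec a [promoterSpec()].
#' @param ages per-sample ages; default `colData(me)$age`.
#' @return list of class `promoter_screen`: `screen` (`data.frame` with
#'   `gene_id`, `n_sites`, `r`, `p`, `n`), `unscored` (gene ids without
#'   covered promoter CpGs), `n_scored`, `bonferroni` (0.05 / n_scored),
#'   and `promoter_means` (genes x samples matrix).
#' @export
promoterAgeScreen <- function(me, catalog, spec = promoterSpec(),
                              ages = NULL) {
  if (is.null(ages)) ages <- sampleAges(me)
  pr <- promoterRegions(catalog, spec)
  hits <- findOverlaps(siteGRanges(me), pr, ignore.strand = TRUE)
  B <- methLevels(me)
  bySite <- S4Vectors::queryHits(hits)
  byGene <- pr$gene_id[S4Vectors::subjectHits(hits)]
  scored_genes <- unique(byGene)
  means <- t(vapply(scored_genes, function(g) {
    colMeans(B[bySite[byGene == g], , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(B))))
  rownames(means) <- scored_genes
  res <- rowPearson(means, ages)
  screen <- data.frame(
    gene_id = scored_genes,
    n_sites = as.integer(table(byGene)[scored_genes]),
    r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
  screen <- screen[res$usable, , drop = FALSE]
  unscored <- setdiff(pr$gene_id, scored_genes)
  structure(list(screen = screen, unscored = unscored,
                 n_scored = nrow(screen),
                 bonferroni = if (nrow(screen)) 0.05 / nrow(screen) else NA,
                 promoter_means = means),
            class = "promoter_screen")
}

#' @export
print.promoter_screen <- function(x, ...) {
  cat("Promoter screen:", x$n_scored, "genes scored,",
      length(x$unscored), "without covered promoter CpGs\n")
  cat("  Bonferroni threshold 0.05 /", x$n_scored, "=",
      signif(x$bonferroni, 3), "\n")
  invisible(x)
}

#' Assign CpG sites to genes and genomic features
#'
#' Maps each site to every gene whose span, extended by `flank` bp on both
#' sides, contains it, and labels the covered feature: `promoter` (the
#' strand-aware promoter window, which takes precedence where regions
#' overlap), then `exon`, `intron` (inside the gene body but outside
#' exons), and `flank`. Sites hitting no gene are labelled `intergenic`.
#'
#' @param me a [MethylomeExperiment-class] (or a site
#'   [GenomicRanges::GRanges]).
#' @param catalog a [GeneCatalog-class].
#' @param flank bp added on both sides of the gene span (default 1500).
#' @param spec promoter window, a [promoterSpec()].
#' @return `data.frame`: `site_id`, `gene_id` (`NA` for intergenic),
#'   `feature`.
#' @export
assignSitesToGenes <- function(me, catalog, flank = 1500L,
                               spec = promoterSpec()) {
  sites <- siteGRanges(me)
  g <- geneRanges(catalog)
  ext <- GRanges(seqnames(g), IRanges(pmax(start(g) - flank, 1),
                                      end(g) + flank))
  hits <- findOverlaps(sites, ext, ignore.strand = TRUE)
  pr <- promoterRegions(catalog, spec)
  ex <- exonRanges(catalog)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  # per-pair promoter membership: compare against the matched gene only
  prm <- pr[match(g$gene_id[si], pr$gene_id)]
  inProm <- start(sites[qi]) >= start(prm) & start(sites[qi]) <= end(prm)
  inBody <- start(sites[qi]) >= start(g[si]) &
    start(sites[qi]) <= end(g[si])
  inExon <- rep(FALSE, length(qi))
  if (length(ex)) {
    exHits <- findOverlaps(sites, ex, ignore.strand = TRUE)
    exPairs <- paste(S4Vectors::queryHits(exHits),
                     ex$gene_id[S4Vectors::subjectHits(exHits)])
    inExon <- paste(qi, g$gene_id[si]) %in% exPairs
  }
  feature <- ifelse(inProm, "promoter",
             ifelse(inBody & inExon, "exon",
             ifelse(inBody, "intron", "flank")))
  assigned <- data.frame(site_id = names(sites)[qi],
                         gene_id = g$gene_id[si],
                         feature = feature, stringsAsFactors = FALSE)
  orphan <- setdiff(names(sites), assigned$site_id)
  if (length(orphan))
    assigned <- rbind(assigned,
                      data.frame(site_id = orphan, gene_id = NA_character_,
                                 feature = "intergenic",
                                 stringsAsFactors = FALSE))
  assigned[order(match(assigned$site_id, names(sites))), ]
}

#' Per-CpG age-correlation profile along a gene
#'
#' All covered CpG sites within the gene span plus `flank` bp on both
#' sides, ordered by genomic position, each with Pearson r / two-sided p
#' against age. The significance flag uses unadjusted `p < 0.05` (the
#' per-gene visual convention), distinct from the Bonferroni threshold the
#' promoter screen applies.
#'
#' @param me a [MethylomeExperiment-class].
#' @param catalog a [GeneCatalog-class].
#' @param gene_id the gene to profile.
#' @param ages per-sample ages; default `colData(me)$age`.
#' @param flank bp on each side of the gene span (default 1500).
#' @param clock_sites optional site ids flagged as clock sites.
#' @return `data.frame` of class `gene_profile` (`site_id`, `position`,
#'   `r`, `p`, `n`, `significant`, `is_clock`) with attributes `gene_id`,
#'   `strand`, `tss`, `gene_start`, `gene_end`.
#' @export
geneProfile <- function(me, catalog, gene_id, ages = NULL, flank = 1500L,
                        clock_sites = character()) {
  g <- geneRanges(catalog)
  gi <- which(g$gene_id == gene_id)
  if (!length(gi)) stop("gene not in catalog: ", gene_id)
  if (is.null(ages)) ages <- sampleAges(me)
  g <- g[gi]
  sites <- siteGRanges(me)
  inReg <- as.logical(seqnames(sites) == as.character(seqnames(g))) &
    start(sites) >= start(g) - flank & start(sites) <= end(g) + flank
  if (!any(inReg))
    stop("no covered CpG sites in region of gene ", gene_id)
  idx <- which(inReg)[order(start(sites)[inReg])]
  B <- methLevels(me)[idx, , drop = FALSE]
  res <- rowPearson(B, ages)
  prof <- data.frame(site_id = rownames(B), position = start(sites)[idx],
                     r = res$r, p = res$p, n = res$n,
                     significant = !is.na(res$p) & res$p < 0.05,
                     is_clock = rownames(B) %in% clock_sites,
                     stringsAsFactors = FALSE)
  prof <- prof[res$usable, , drop = FALSE]
  structure(prof, gene_id = gene_id,
            strand = as.character(strand(g)), tss = g$tss,
            gene_start = start(g), gene_end = end(g),
            class = c("gene_profile", "data.frame"))
}

profileSummary <- function(prof) {
  gs <- attr(prof, "gene_start"); ge <- attr(prof, "gene_end")
  i <- which.max(abs(prof$r))
  list(gene_id = attr(prof, "gene_id"),
       n_sites = nrow(prof),
       n_significant = sum(prof$significant),
       max_abs_r = abs(prof$r[i]),
       max_r_position = prof$position[i],
       max_r_fraction = (prof$position[i] - gs) / max(ge - gs, 1))
}

#' Age-correlation profiles of a gene and its ortholog in a second cohort
#'
#' Profiles the same gene (matched by exact gene symbol, or through an
#' explicit two-column ortholog table) in two cohorts on their own
#' coordinate systems, and summarises each profile (number of significant
#' sites, location of the max-|r| site as a fraction of gene length) so
#' cross-species patterns can be compared. A gene absent from either
#' catalog yields a `NULL` profile on that side, reported, not fatal.
#'
#' @param gene_id gene symbol in cohort A.
#' @param catalog_a,me_a,ages_a catalog, methylome and ages of cohort A.
#' @param catalog_b,me_b,ages_b the same for cohort B.
#' @param ortholog_table optional `data.frame` with columns `from` (A ids)
#'   and `to` (B ids); exact-name matching when omitted.
#' @param flank bp flank for both profiles.
#' @return list: `gene_id`, `gene_id_b`, `a` and `b` each a list with
#'   `profile` ([geneProfile()] output or `NULL`) and `summary`.
#' @export
orthologProfiles <- function(gene_id, catalog_a, me_a, catalog_b, me_b,
                             ages_a = NULL, ages_b = NULL,
                             ortholog_table = NULL, flank = 1500L) {
  id_b <- gene_id
  if (!is.null(ortholog_table)) {
    stopifnot(all(c("from", "to") %in% colnames(ortholog_table)))
    j <- match(gene_id, ortholog_table$from)
    id_b <- if (is.na(j)) NA_character_ else ortholog_table$to[j]
  }
  side <- function(catalog, me, ages, id) {
    if (is.na(id) || !id %in% geneRanges(catalog)$gene_id) {
      message("gene ", id, " absent from catalog; profile omitted")
      return(list(profile = NULL, summary = NULL))
    }
    prof <- geneProfile(me, catalog, id, ages = ages, flank = flank)
    list(profile = prof, summary = profileSummary(prof))
  }
  list(gene_id = gene_id, gene_id_b = id_b,
       a = side(catalog_a, me_a, ages_a, gene_id),
       b = side(catalog_b, me_b, ages_b, id_b))
}
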