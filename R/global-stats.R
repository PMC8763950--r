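#' Binary Shannon entropy of a methylation level
#'
#' `-m * log2(m) - (1 - m) * log2(1 - m)` in bits, with the convention
#' `0 * log2(0) = 0`: the information content of a CpG's methylation state,
#' maximal (1 bit) at `m = 0.5` and zero at the fully (un)methylated
#' extremes. Rising mean entropy with age is the methylome
#' information-loss signature.
#'
#' @param m methylation fraction(s) in `[0, 1]` (vectorised; `NA` passes
#'   through).
#' @return entropy in bits.
#' @examples
#' siteEntropy(0.5)   # 1 bit
#' siteEntropy(c(0, 1))  # 0 bits
#' @export
siteEntropy <- function(m) {
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("methylation level must lie in [0, 1]")
  term <- function(x) ifelse(x > 0, -x * log2(x), 0)
  term(m) + term(1 - m)
}

#' Per-sample global methylome summary
#'
#' For each sample: the global mean methylation over non-missing sites, the
#' mean Shannon entropy (the methylome entropy of the sample), and the
#' proportions of sites with beta exactly 0, exactly 1, and in the
#' mid-range `[0.45, 0.55]` (closed band). Exact 0/1 comparisons are
#' intentional: count-derived betas hit the extremes exactly.
#'
#' @param me a [MethylomeExperiment-class].
#' @param sample_id one sample id ([sampleSummary()]) or all samples
#'   ([cohortSummary()]).
#' @return one-row (or per-sample) `data.frame` with columns `sample_id`,
#'   `n_sites`, `n_missing`, `mean_beta`, `mean_entropy`, `prop_zero`,
#'   `prop_one`, `prop_mid`.
#' @export
sampleSummary <- function(me, sample_id) {
  stopifnot(is(me, "MethylomeExperiment"))
  if (!sample_id %in% colnames(me)) stop("unknown sample: ", sample_id)
  b <- methLevels(me)[, sample_id]
  summariseBetas(b, sample_id)
}

summariseBetas <- function(b, sample_id) {
  miss <- sum(is.na(b))
  b <- b[!is.na(b)]
  if (!length(b)) stop("no non-missing sites for sample ", sample_id)
  data.frame(sample_id = sample_id, n_sites = length(b), n_missing = miss,
             mean_beta = mean(b), mean_entropy = mean(siteEntropy(b)),
             prop_zero = mean(b == 0), prop_one = mean(b == 1),
             prop_mid = mean(b >= 0.45 & b <= 0.55),
             stringsAsFactors = FALSE)
}

#' @rdname sampleSummary
#' @export
cohortSummary <- function(me) {
  do.call(rbind, lapply(colnames(me), function(s) sampleSummary(me, s)))
}

#' Kernel density profile of a sample's methylation levels
#'
#' Gaussian-kernel density on a fixed grid over `[0, 1]`, bandwidth by
#' Scott's rule of thumb. The trapezoid integral over the grid is ~1 up to
#' boundary leakage (mass the kernel places outside `[0, 1]`).
#'
#' @param betas numeric vector of methylation fractions (>= 2 finite,
#'   non-constant values).
#' @param n_grid grid resolution (default 512).
#' @param bw bandwidth; defaults to Scott's rule.
#' @return `data.frame` with columns `x` (grid) and `density`.
#' @export
densityProfile <- function(betas, n_grid = 512L, bw = NULL) {
  x <- betas[is.finite(betas)]
  if (length(x) < 2) stop("need at least 2 finite values")
  if (var(x) == 0)
    stop("constant input: kernel bandwidth would be zero")
  if (is.null(bw)) bw <- bw.nrd(x)
  d <- density(x, bw = bw, n = n_grid, from = 0, to = 1)
  data.frame(x = d$x, density = d$y)
}

#' Genome-wide CpG-age correlation screen
#'
#' Pearson correlation of each site's methylation levels with chronological
#' age, with the two-sided p-value from the t-distribution transform of
#' `r`. Missing betas are dropped pairwise per site. Sites with fewer than
#' 3 usable pairs or zero variance are skipped (no `r` assigned) and
#' reported in the `"skipped"` attribute.
#'
#' @param me a [MethylomeExperiment-class] (or a sites x samples matrix).
#' @param ages per-sample ages; defaults to `colData(me)$age`.
#' @return `data.frame` (`site_id`, `r`, `p`, `n`), one row per scored
#'   site, with attribute `skipped` naming unscored sites.
#' @export
ageCorrelationScreen <- function(me, ages = NULL) {
  B <- if (is(me, "MethylomeExperiment")) methLevels(me) else as.matrix(me)
  if (is.null(ages)) ages <- sampleAges(me)
  ok <- is.finite(ages)
  if (sum(ok) < 3) stop("need at least 3 samples with finite age")
  B <- B[, ok, drop = FALSE]; ages <- ages[ok]
  res <- rowPearson(B, ages)
  skipped <- rownames(B)[!res$usable]
  if (length(skipped))
    message(length(skipped),
            " site(s) skipped (undefined correlation or < 3 pairs)")
  out <- data.frame(site_id = rownames(B)[res$usable],
                    r = res$r[res$usable], p = res$p[res$usable],
                    n = res$n[res$usable], stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`: the genome-wide per-test p-value cutoff controlling
#' the family-wise error rate over `n_tests` CpG sites.
#'
#' @param alpha family-wise error rate, in `(0, 1)`.
#' @param n_tests number of tests (>= 1).
#' @return the per-test p-value threshold.
#' @examples
#' bonferroniThreshold(0.05, 3089098)   # ~1.62e-08
#' @export
bonferroniThreshold <- function(alpha = 0.05, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  n_tests <- as.numeric(n_tests)
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count")
  alpha / n_tests
}

#' Partition Bonferroni-significant sites by correlation sign
#'
#' Splits screen records with `p < threshold` into negatively and
#' positively age-correlated site sets.
#'
#' @param records screen output from [ageCorrelationScreen()].
#' @param threshold p-value cutoff (typically [bonferroniThreshold()]).
#' @return list of class `significant_partition`: `threshold`,
#'   `negative_sites`, `positive_sites`, and their counts.
#' @export
partitionSignificant <- function(records, threshold) {
  stopifnot(all(c("site_id", "r", "p") %in% colnames(records)))
  sig <- records[records$p < threshold, , drop = FALSE]
  if (any(sig$r == 0))
    stop("site significant with r exactly 0; screen output is inconsistent")
  structure(list(threshold = threshold,
                 negative_sites = sig$site_id[sig$r < 0],
                 positive_sites = sig$site_id[sig$r > 0],
                 n_negative = sum(sig$r < 0),
                 n_positive = sum(sig$r > 0)),
            class = "significant_partition")
}

#' @export
print.significant_partition <- function(x, ...) {
  cat("Significant partition at p <", signif(x$threshold, 3), ":",
      x$n_negative, "negative,", x$n_positive, "positive sites\n")
  invisible(x)
}

#' PCA embedding of samples on a site set
#'
#' Site-centred (not variance-scaled) principal component analysis of the
#' samples restricted to a site set — typically the Bonferroni-significant
#' sites, where the leading component tracks age-related methylome
#' remodelling. Betas share the common `[0, 1]` scale, so no per-site
#' scaling is applied. Component signs are fixed by making each
#' component's largest-magnitude site loading positive, so coordinates are
#' deterministic.
#'
#' @param me a [MethylomeExperiment-class] or sites x samples matrix.
#' @param sites site ids to restrict to (default: all rows).
#' @param n_comp number of components (must not exceed the rank).
#' @return list: `scores` (samples x components), `loadings` (sites x
#'   components), `explained` (variance fractions, non-increasing).
#' @export
pcaEmbed <- function(me, sites = NULL, n_comp = 2L) {
  B <- if (is(me, "MethylomeExperiment")) methLevels(me) else as.matrix(me)
  if (!is.null(sites)) {
    missing_sites <- setdiff(sites, rownames(B))
    if (length(missing_sites))
      stop("sites not in the matrix: ",
           paste(head(missing_sites, 3), collapse = ", "))
    B <- B[sites, , drop = FALSE]
  }
  if (ncol(B) < 3 || nrow(B) < 2)
    stop("need at least 3 samples and 2 sites")
  if (anyNA(B)) {
    message("missing betas mean-imputed per site for PCA")
    rm <- rowMeans(B, na.rm = TRUE)
    idx <- which(is.na(B), arr.ind = TRUE)
    B[idx] <- rm[idx[, 1]]
  }
  X <- scale(t(B), center = TRUE, scale = FALSE)  # samples x sites
  sv <- svd(X)
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_comp > pos) stop("requested ", n_comp,
                         " components but rank is ", pos)
  scores <- sv$u[, seq_len(n_comp), drop = FALSE] %*%
    diag(sv$d[seq_len(n_comp)], n_comp)
  loadings <- sv$v[, seq_len(n_comp), drop = FALSE]
  for (k in seq_len(n_comp)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- colnames(B)
  rownames(loadings) <- rownames(B)
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(n_comp))
  list(scores = scores, loadings = loadings,
       explained = sv$d[seq_len(n_comp)]^2 / sum(sv$d^2))
}

#' Per-sample mean methylation of a site set
#'
#' Arithmetic mean beta across the set for each sample, missing betas
#' excluded per sample — the mean-trajectory statistic tracked against age
#' for, e.g., the Bonferroni-negative and -positive site sets or the clock
#' sites.
#'
#' @param me a [MethylomeExperiment-class] or sites x samples matrix.
#' @param sites non-empty character vector of site ids.
#' @return named numeric vector, one mean per sample.
#' @export
meanTrajectory <- function(me, sites) {
  if (!length(sites)) stop("site set is empty")
  B <- if (is(me, "MethylomeExperiment")) methLevels(me) else as.matrix(me)
  missing_sites <- setdiff(sites, rownames(B))
  if (length(missing_sites))
    stop("sites not in the matrix: ",
         paste(head(missing_sites, 3), collapse = ", "))
  colMeans(B[sites, , drop = FALSE], na.rm = TRUE)
}
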