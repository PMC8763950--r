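#' @importFrom methods new validObject is slot
#' @importFrom stats coef cor density lm median pt residuals rnorm runif
#'   rbinom rnbinom sd t.test var bw.nrd setNames
#' @importFrom utils head
NULL

# clip to the unit interval
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Compose and split CpG site identifiers
#'
#' Site identifiers are the genomic contig accession and the 1-based position
#' of the cytosine joined by an underscore (`"ctg1_100"`). Because contig
#' accessions may themselves contain underscores, [splitSiteId()] splits on
#' the final underscore only.
#'
#' @param contig character vector of contig names.
#' @param position integer vector of 1-based cytosine positions.
#' @param site_id character vector of identifiers to split.
#' @return [makeSiteId()] returns a character vector; [splitSiteId()] a
#'   `data.frame` with columns `contig` and `position`.
#' @examples
#' makeSiteId("NW_004624735.1", 12045)
#' splitSiteId("NW_004624735.1_12045")
#' @export
makeSiteId <- function(contig, position) {
  stopifnot(all(position >= 1))
  paste(contig, position, sep = "_")
}

#' @rdname makeSiteId
#' @export
splitSiteId <- function(site_id) {
  pos <- sub(".*_", "", site_id)
  contig <- sub("_[^_]*$", "", site_id)
  position <- suppressWarnings(as.integer(pos))
  if (anyNA(position))
    stop("site_id not of the form <contig>_<position>: ",
         paste(head(site_id[is.na(position)], 3), collapse = ", "))
  data.frame(contig = contig, position = position,
             stringsAsFactors = FALSE)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Pearson r with the two-sided p-value from the t transform, for one pair
# of vectors. Complete pairs only.
pearsonTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n))
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x, y)
  p <- pearsonP(r, n)
  list(r = r, p = p, n = n)
}

# two-sided p for Pearson r at sample size n (t distribution, df = n - 2)
pearsonP <- function(r, n) {
  r2 <- pmin(r * r, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  pmin(p, 1)
}

# Row-wise Pearson correlation of a sites x samples matrix against a vector
# of ages, dropping missing cells pairwise. Returns r, p, n per row; rows
# with < 3 usable pairs or zero variance get NA.
rowPearson <- function(B, ages) {
  stopifnot(ncol(B) == length(ages))
  M <- !is.na(B)
  Bz <- B; Bz[!M] <- 0
  A <- matrix(ages, nrow(B), ncol(B), byrow = TRUE)
  Az <- A * M
  n <- rowSums(M)
  Sx <- rowSums(Bz)
  Sy <- rowSums(Az)
  Sxx <- rowSums(Bz * Bz)
  Syy <- rowSums(Az * Az)
  Sxy <- rowSums(Bz * A)
  vx <- Sxx - Sx^2 / pmax(n, 1)
  vy <- Syy - Sy^2 / pmax(n, 1)
  cxy <- Sxy - Sx * Sy / pmax(n, 1)
  usable <- n >= 3 & vx > 1e-12 & vy > 1e-12
  r <- rep(NA_real_, nrow(B))
  r[usable] <- cxy[usable] / sqrt(vx[usable] * vy[usable])
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, nrow(B))
  p[usable] <- pearsonP(r[usable], n[usable])
  list(r = r, p = p, n = n, usable = usable)
}
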