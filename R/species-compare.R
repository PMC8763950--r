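#' Species maximum-lifespan record
#'
#' @param species species label.
#' @param max_lifespan maximum lifespan in years (> 0), e.g. 31 for the
#'   naked mole-rat, 4 for the mouse and 122.5 for the human (AnAge).
#' @return list of class `species_lifespan`.
#' @export
speciesLifespan <- function(species, max_lifespan) {
  if (!is.numeric(max_lifespan) || max_lifespan <= 0)
    stop("max_lifespan must be > 0")
  structure(list(species = species, max_lifespan = max_lifespan),
            class = "species_lifespan")
}

#' Relative age: chronological age as a fraction of maximum lifespan
#'
#' @param age age in years (>= 0, vectorised).
#' @param lifespan a [speciesLifespan()] (or a bare positive number).
#' @return `age / max_lifespan`.
#' @examples
#' relativeAge(11.87, speciesLifespan("naked mole-rat", 31))  # ~0.383
#' @export
relativeAge <- function(age, lifespan) {
  if (any(age < 0)) stop("age must be >= 0")
  ml <- if (inherits(lifespan, "species_lifespan"))
    lifespan$max_lifespan else lifespan
  if (!is.numeric(ml) || ml <= 0) stop("max_lifespan must be > 0")
  age / ml
}

#' Split clock sites into decreasing and increasing sets
#'
#' Clock sites are divided by the sign of their Pearson correlation with
#' age — not by the sign of their model weight. Decreasing sites tend to
#' start highly methylated and lose methylation; increasing sites start low
#' and gain.
#'
#' @param model a [ClockModel-class] (or a character vector of site ids).
#' @param me a [MethylomeExperiment-class] (or sites x samples matrix)
#'   containing every clock site.
#' @param ages per-sample ages; default `colData(me)$age`.
#' @return list of class `clock_split`: `decreasing`, `increasing`
#'   (site-id vectors) and their counts.
#' @export
splitClockSites <- function(model, me, ages = NULL) {
  sites <- if (is(model, "ClockModel")) clockSites(model) else model
  B <- if (is(me, "MethylomeExperiment")) methLevels(me) else as.matrix(me)
  if (is.null(ages)) ages <- sampleAges(me)
  absent <- setdiff(sites, rownames(B))
  if (length(absent))
    stop("clock site(s) missing from the matrix: ",
         paste(head(absent, 5), collapse = ", "))
  res <- rowPearson(B[sites, , drop = FALSE], ages)
  if (any(!res$usable))
    stop("undefined age correlation at clock site(s): ",
         paste(head(sites[!res$usable], 5), collapse = ", "))
  dec <- sites[res$r < 0]
  inc <- sites[res$r > 0]
  if (!length(dec)) warning("no decreasing clock sites")
  if (!length(inc)) warning("no increasing clock sites")
  structure(list(decreasing = dec, increasing = inc,
                 n_decreasing = length(dec), n_increasing = length(inc)),
            class = "clock_split")
}

#' @export
print.clock_split <- function(x, ...) {
  cat("Clock split:", x$n_decreasing, "decreasing,",
      x$n_increasing, "increasing sites\n")
  invisible(x)
}

#' Fit a polynomial trend of mean methylation versus age
#'
#' Least-squares polynomial (degree 1 or 2) of the mean methylation of a
#' site set against age, with the residual standard deviation. Linear fits
#' suit species with near-linear adult trends; the quadratic option covers
#' curved trajectories.
#'
#' @param mean_traj per-sample mean methylation (e.g. [meanTrajectory()]).
#' @param ages matching ages, years.
#' @param degree 1 (linear) or 2 (quadratic).
#' @param label site-set label stored in the fit.
#' @return a [TrajectoryFit-class].
#' @export
fitTrend <- function(mean_traj, ages, degree = 1L, label = "") {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  ok <- is.finite(mean_traj) & is.finite(ages)
  y <- mean_traj[ok]; x <- ages[ok]
  if (length(y) <= degree + 1)
    stop("need more than degree + 1 points")
  X <- stats::poly(x, degree, raw = TRUE)
  fit <- lm(y ~ X)
  cf <- coef(fit)
  if (anyNA(cf)) stop("rank-deficient fit (degenerate ages)")
  rsd <- sqrt(sum(residuals(fit)^2) / fit$df.residual)
  new("TrajectoryFit", label = label, degree = degree,
      coefficients = unname(cf), residualSd = rsd,
      ageRange = range(x))
}

#' Crossover of decreasing and increasing methylation trends
#'
#' Solves for the age at which the fitted decreasing and increasing trends
#' intersect, within the given age range (by default the overlap of the two
#' fitted ranges — extrapolated intersections are not reported). The
#' difference polynomial has degree at most 2 and is solved analytically:
#' linear-linear in closed form, any quadratic case by the quadratic
#' formula. With several in-range roots the smallest is chosen with a
#' warning; no in-range real root yields a "no crossover" result, not an
#' error.
#'
#' @param fit_dec,fit_inc [TrajectoryFit-class] objects for the decreasing
#'   and increasing site sets.
#' @param age_range length-2 numeric search interval, years.
#' @return list of class `crossover_result`: `found`, `crossover_age`,
#'   `methylation_at_cross` (evaluated on the decreasing fit at the root),
#'   `age_range`.
#' @export
findCrossover <- function(fit_dec, fit_inc, age_range = NULL) {
  stopifnot(is(fit_dec, "TrajectoryFit"), is(fit_inc, "TrajectoryFit"))
  if (is.null(age_range))
    age_range <- c(max(fit_dec@ageRange[1], fit_inc@ageRange[1]),
                   min(fit_dec@ageRange[2], fit_inc@ageRange[2]))
  if (diff(age_range) < 0)
    stop("fitted age ranges do not overlap")
  pad <- function(f) c(f@coefficients, rep(0, 3 - length(f@coefficients)))
  d <- pad(fit_dec) - pad(fit_inc)   # c0 + c1 x + c2 x^2
  roots <- if (abs(d[3]) < 1e-14) {
    if (abs(d[2]) < 1e-14) numeric(0) else -d[1] / d[2]
  } else {
    disc <- d[2]^2 - 4 * d[3] * d[1]
    if (disc < 0) numeric(0)
    else (-d[2] + c(-1, 1) * sqrt(disc)) / (2 * d[3])
  }
  inside <- roots[roots >= age_range[1] - 1e-12 &
                  roots <= age_range[2] + 1e-12]
  if (!length(inside))
    return(structure(list(found = FALSE, crossover_age = NA_real_,
                          methylation_at_cross = NA_real_,
                          age_range = age_range),
                     class = "crossover_result"))
  if (length(unique(round(inside, 12))) > 1)
    warning("multiple crossover roots in range; smallest chosen")
  root <- min(inside)
  structure(list(found = TRUE, crossover_age = root,
                 methylation_at_cross =
                   trendValues(fit_dec, root, extrapolate = TRUE),
                 age_range = age_range),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  if (x$found)
    cat("Crossover at", round(x$crossover_age, 3), "years, methylation",
        round(x$methylation_at_cross, 3), "\n")
  else cat("No crossover within", paste(round(x$age_range, 2),
                                        collapse = " - "), "years\n")
  invisible(x)
}

#' Cross-species clock-site trajectory comparison
#'
#' For each species: split its clock sites into decreasing and increasing
#' sets (or accept provided sets), compute the mean methylation trajectory
#' of each set, fit the trend at the species' polynomial degree, locate the
#' crossover of the two trends, and express the crossover age on the
#' relative-age scale (age / maximum lifespan).
#'
#' @param species_list list of per-species specifications; each a list with
#'   `species` (label), `me` (a [MethylomeExperiment-class] or matrix),
#'   `lifespan` (years), and either `model` (a [ClockModel-class]) or
#'   `sites` (list with `decreasing` and `increasing` id vectors);
#'   optional `ages` (default `colData` ages) and `degree` (default 1).
#' @return `data.frame` of class `species_comparison`, one row per
#'   species: site counts, crossover age (years), relative crossover age,
#'   methylation at the crossover, fit degree and whether a crossover was
#'   found in range.
#' @export
compareSpecies <- function(species_list) {
  stopifnot(length(species_list) >= 1)
  rows <- lapply(species_list, function(sp) {
    ages <- sp$ages
    if (is.null(ages)) ages <- sampleAges(sp$me)
    degree <- sp$degree %||% 1L
    sets <- if (!is.null(sp$model))
      splitClockSites(sp$model, sp$me, ages)
    else list(decreasing = sp$sites$decreasing,
              increasing = sp$sites$increasing)
    fit_dec <- fitTrend(meanTrajectory(sp$me, sets$decreasing), ages,
                        degree, label = "decreasing")
    fit_inc <- fitTrend(meanTrajectory(sp$me, sets$increasing), ages,
                        degree, label = "increasing")
    cross <- findCrossover(fit_dec, fit_inc)
    data.frame(
      species = sp$species,
      n_decreasing = length(sets$decreasing),
      n_increasing = length(sets$increasing),
      degree = degree,
      found = cross$found,
      crossover_age = cross$crossover_age,
      relative_age = if (cross$found)
        relativeAge(cross$crossover_age, sp$lifespan) else NA_real_,
      methylation_at_cross = cross$methylation_at_cross,
      stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("species_comparison", "data.frame"))
}
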