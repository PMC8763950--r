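#' @importFrom glmnet cv.glmnet glmnet
NULL

#' Clock training configuration
#'
#' Elastic-net training scheme for the epigenetic clock: mixing parameter
#' 0.5 (equal L1/L2 blend), penalty strength chosen by 10-fold inner
#' cross-validation on the training set, and 5-fold outer cross-validation
#' so every sample receives exactly one out-of-sample prediction (each
#' outer model trains on the complementary 80% of samples).
#'
#' @param mixing elastic-net mixing parameter in `[0, 1]`.
#' @param inner_folds folds for the inner lambda search (>= 2).
#' @param outer_folds outer CV folds (>= 2).
#' @param holdout_fraction training holdout fraction for a single
#'   train/test split (`1 - 1/outer_folds` by construction in nested CV).
#' @param seed integer seed; folds are drawn by seeded uniform shuffling,
#'   without age stratification.
#' @param lambda_rule `"1se"` (default): the largest lambda whose CV error
#'   is within one standard error of the minimum, the cut-point default of
#'   the glmnet family of tools and the choice that yields sparse clocks;
#'   `"min"`: the lambda minimising CV error.
#' @return list of class `clock_config`.
#' @export
clockConfig <- function(mixing = 0.5, inner_folds = 10L, outer_folds = 5L,
                        holdout_fraction = 0.2, seed = 1L,
                        lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  if (mixing < 0 || mixing > 1) stop("mixing must lie in [0, 1]")
  if (inner_folds < 2 || outer_folds < 2) stop("folds must be >= 2")
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("holdout_fraction must lie in (0, 1)")
  structure(list(mixing = mixing, inner_folds = as.integer(inner_folds),
                 outer_folds = as.integer(outer_folds),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed), lambda_rule = lambda_rule),
            class = "clock_config")
}

#' Clock feature table: fully covered, gap-free beta matrix
#'
#' Re-filters a methylome at the stricter clock criterion — coverage of at
#' least `min_reads` reads in at least `fraction` of the samples (default
#' all of them) — and returns the sites x samples beta matrix with no
#' missing values, the input the elastic net trains on.
#'
#' @param me a [MethylomeExperiment-class].
#' @param min_reads read cutoff (default 5).
#' @param fraction required covered-sample fraction (default 1.0).
#' @return numeric sites x samples matrix (possibly 0-row, with a warning).
#' @export
makeFeatureTable <- function(me, min_reads = 5L, fraction = 1.0) {
  stopifnot(is(me, "MethylomeExperiment"))
  cv <- methCoverage(me)
  keep <- rowMeans(cv >= min_reads) >= fraction
  if (!any(keep)) {
    warning("no site passes the clock coverage criterion")
    return(methLevels(me)[keep, , drop = FALSE])
  }
  B <- methLevels(me)[keep, , drop = FALSE]
  if (anyNA(B))
    stop("internal error: missing beta at a site passing the clock filter")
  B
}

# deterministic fold assignment by seeded shuffling
makeFolds <- function(n, k, seed) {
  withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Train an elastic-net epigenetic clock
#'
#' Fits `age ~ beta` by elastic net at the configured mixing parameter.
#' The penalty strength is chosen by inner cross-validation: by default the
#' one-standard-error rule (the largest lambda whose CV error is within one
#' SE of the minimum, giving sparse clocks), optionally the CV-error
#' minimum (`lambda_rule = "min"`). When the optimum lands on the smallest
#' lambda of the early-stopped path, the grid is extended downward so the
#' selection is interior. The fold assignment is drawn from the configured
#' seed, so training is reproducible. Features are standardised internally for fitting and the
#' coefficients are reported back on the raw beta scale, giving the
#' published-clock form: predicted age = intercept + sum(weight * beta).
#'
#' @param features sites x samples beta matrix (e.g. from
#'   [makeFeatureTable()]); no missing values.
#' @param ages per-sample chronological ages, years.
#' @param config a [clockConfig()].
#' @return a [ClockModel-class]; its metadata records the selected lambda,
#'   fold assignment and the model's training-set predictions. A warning is
#'   raised if no feature receives a non-zero weight (an intercept-only
#'   model, the expected outcome on age-shuffled data).
#' @export
trainClock <- function(features, ages, config = clockConfig()) {
  features <- as.matrix(features)
  n <- ncol(features)
  if (length(ages) != n) stop("ages length must match the sample count")
  if (any(!is.finite(ages))) stop("ages must be finite")
  if (n < config$inner_folds)
    stop("fewer samples (", n, ") than inner folds (",
         config$inner_folds, ")")
  if (anyNA(features)) stop("feature table contains missing values")
  sds <- apply(features, 1, sd)
  if (all(sds == 0)) stop("all features have zero variance")
  x <- t(features)
  if (ncol(x) == 1) {
    # the fitter requires >= 2 columns; pad with an inert constant feature
    x <- cbind(x, `..pad..` = 0)
  }
  foldid <- makeFolds(n, config$inner_folds, config$seed)
  cvfit <- cv.glmnet(x, ages, alpha = config$mixing, foldid = foldid,
                     standardize = TRUE)
  # if CV selects the smallest lambda of the (early-stopped) path, extend
  # the grid downward so the optimum is interior
  for (i in 1:2) {
    if (cvfit$lambda.min > min(cvfit$lambda) + 1e-15) break
    lam <- exp(seq(log(max(cvfit$lambda)),
                   log(min(cvfit$lambda) * 1e-2), length.out = 120))
    cvfit <- cv.glmnet(x, ages, alpha = config$mixing, foldid = foldid,
                       standardize = TRUE, lambda = lam)
  }
  lambda <- if (identical(config$lambda_rule, "min")) cvfit$lambda.min
            else cvfit$lambda.1se
  cf <- as.matrix(coef(cvfit, s = lambda))
  w <- cf[-1, 1]
  w <- w[names(w) != "..pad.."]
  nz <- w != 0
  if (!any(nz))
    warning("intercept-only clock: no feature received a non-zero weight")
  model <- ClockModel(
    intercept = cf[1, 1], weights = w[nz], mixing = config$mixing,
    lambda = lambda, seed = config$seed,
    trainSamples = colnames(features),
    metadata = list(config = unclass(config), foldid = foldid,
                    n_features = nrow(features)))
  model@metadata$train_predictions <- predictAge(model, features)
  model
}

#' Predict epigenetic age from a clock model
#'
#' `intercept + sum(weight_i * beta_i)` over the model's clock sites, in
#' years. Negative predictions are reported as-is (and flagged with a
#' message), never clamped.
#'
#' @param model a [ClockModel-class].
#' @param features sites x samples beta matrix containing every clock site.
#' @return named numeric vector of predicted ages (DNAm ages), years.
#' @export
setGeneric("predictAge",
           function(model, features) standardGeneric("predictAge"))

#' @rdname predictAge
#' @export
setMethod("predictAge", "ClockModel", function(model, features) {
  features <- as.matrix(features)
  w <- clockWeights(model)
  if (length(w)) {
    absent <- setdiff(names(w), rownames(features))
    if (length(absent))
      stop("clock site(s) missing from features: ",
           paste(head(absent, 5), collapse = ", "))
    pred <- clockIntercept(model) +
      as.numeric(crossprod(features[names(w), , drop = FALSE], w))
  } else {
    pred <- rep(clockIntercept(model), ncol(features))
  }
  names(pred) <- colnames(features)
  if (any(pred < 0))
    message(sum(pred < 0), " negative age prediction(s) reported as-is")
  pred
})

#' Nested cross-validated clock predictions
#'
#' Splits the cohort into `outer_folds` disjoint folds by seeded shuffling
#' (fold sizes differ by at most one). Each fold's clock is trained only on
#' the complementary samples — with its own inner lambda search — and
#' predicts the held-out fold, so the unified prediction set is strictly
#' out-of-sample and covers every sample exactly once. The overall Pearson
#' r and median absolute error (MedAE) of the unified test predictions are
#' the headline clock metrics.
#'
#' @param features sites x samples beta matrix.
#' @param ages per-sample ages, years.
#' @param config a [clockConfig()].
#' @return list of class `clock_cv`: `predictions` (`data.frame` with
#'   `sample_id`, `age`, `predicted`, `fold`), `models` (one
#'   [ClockModel-class] per fold), `r`, `medae` (`r` is `NA` when the
#'   unified predictions are constant).
#' @export
nestedCV <- function(features, ages, config = clockConfig()) {
  features <- as.matrix(features)
  n <- ncol(features)
  if (n < config$outer_folds)
    stop("cannot stratify ", n, " samples into ",
         config$outer_folds, " folds")
  fold <- makeFolds(n, config$outer_folds, config$seed)
  sample_ids <- colnames(features)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  preds <- rep(NA_real_, n)
  models <- vector("list", config$outer_folds)
  for (k in seq_len(config$outer_folds)) {
    test <- which(fold == k)
    train <- which(fold != k)
    sub <- clockConfig(mixing = config$mixing,
                       inner_folds = config$inner_folds,
                       outer_folds = config$outer_folds,
                       holdout_fraction = config$holdout_fraction,
                       seed = config$seed + k,
                       lambda_rule = config$lambda_rule %||% "1se")
    m <- trainClock(features[, train, drop = FALSE], ages[train], sub)
    stopifnot(!any(sample_ids[test] %in% m@trainSamples))
    preds[test] <- predictAge(m, features[, test, drop = FALSE])
    models[[k]] <- m
  }
  stopifnot(!anyNA(preds))
  r <- if (sd(preds) > 0) cor(preds, ages) else NA_real_
  structure(list(
    predictions = data.frame(sample_id = sample_ids, age = ages,
                             predicted = preds, fold = fold,
                             stringsAsFactors = FALSE),
    models = models, r = r, medae = median(abs(preds - ages))),
    class = "clock_cv")
}

#' @export
print.clock_cv <- function(x, ...) {
  cat("Nested CV clock:", nrow(x$predictions), "unified test predictions",
      "over", length(x$models), "folds\n")
  cat("  Pearson r =", round(x$r, 4), "| MedAE =",
      round(x$medae, 3), "years\n")
  invisible(x)
}

#' Epigenetic age acceleration
#'
#' Fits ordinary least squares of predicted age on chronological age over
#' all samples; a sample's acceleration is its predicted age minus the
#' regression-line value at its chronological age (years). Accelerations
#' sum to zero by construction when the line is fitted on the same set.
#'
#' @param predictions `data.frame` with columns `sample_id`, `age`,
#'   `predicted` (e.g. `nestedCV(...)$predictions`).
#' @return `data.frame`: `sample_id`, `age`, `predicted`, `acceleration`.
#' @export
ageAcceleration <- function(predictions) {
  stopifnot(all(c("sample_id", "age", "predicted") %in%
                colnames(predictions)))
  if (nrow(predictions) < 3) stop("need at least 3 predictions")
  if (var(predictions$age) == 0)
    stop("all chronological ages identical; regression is degenerate")
  fit <- lm(predicted ~ age, data = predictions)
  data.frame(sample_id = predictions$sample_id, age = predictions$age,
             predicted = predictions$predicted,
             acceleration = as.numeric(residuals(fit)),
             stringsAsFactors = FALSE)
}

#' Group tests on age acceleration
#'
#' Per group, a two-sided one-sample t-test of mean acceleration against
#' zero; optionally a Welch two-sample t-test between two named groups
#' (unequal variances not assumed equal).
#'
#' @param records [ageAcceleration()] output.
#' @param groups per-sample group labels (character/factor, aligned with
#'   `records`), e.g. breeder status.
#' @param compare optional length-2 character vector of group names to
#'   contrast with Welch's t-test.
#' @return list: `per_group` (`data.frame` with `group`, `n`, `mean`,
#'   `t`, `p`), `between` (`NULL` or `data.frame` with the Welch result).
#' @export
accelerationTests <- function(records, groups, compare = NULL) {
  stopifnot(length(groups) == nrow(records))
  groups <- as.character(groups)
  lev <- unique(groups)
  rows <- lapply(lev, function(g) {
    x <- records$acceleration[groups == g]
    if (length(x) < 2) return(NULL)
    if (var(x) == 0)
      stop("zero within-group variance in group '", g, "'")
    tt <- t.test(x, mu = 0)
    data.frame(group = g, n = length(x), mean = mean(x),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, rows)
  between <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2, all(compare %in% groups))
    x <- records$acceleration[groups == compare[1]]
    y <- records$acceleration[groups == compare[2]]
    tt <- t.test(x, y)   # Welch by default
    between <- data.frame(group1 = compare[1], group2 = compare[2],
                          n1 = length(x), n2 = length(y),
                          mean_diff = mean(x) - mean(y),
                          t = unname(tt$statistic), p = tt$p.value,
                          stringsAsFactors = FALSE)
  }
  list(per_group = per_group, between = between)
}

#' Serialize / load a clock model as TSV
#'
#' One row per term: `intercept` first, then one row per clock site with
#' its weight. A YAML sidecar (`<path>.meta.yml`) records mixing, lambda,
#' seed and training sample ids.
#'
#' @param model a [ClockModel-class].
#' @param path TSV path.
#' @return [writeClockModel()] the path invisibly; [readClockModel()] a
#'   [ClockModel-class].
#' @export
writeClockModel <- function(model, path) {
  df <- data.frame(term = c("intercept", clockSites(model)),
                   weight = c(clockIntercept(model),
                              unname(clockWeights(model))))
  data.table::fwrite(df, path, sep = "\t")
  yaml::write_yaml(list(mixing = model@mixing, lambda = model@lambda,
                        seed = model@seed,
                        train_samples = model@trainSamples),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname writeClockModel
#' @export
readClockModel <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE)
  stopifnot(df$term[1] == "intercept")
  w <- df$weight[-1]
  names(w) <- df$term[-1]
  meta_path <- paste0(path, ".meta.yml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  ClockModel(intercept = df$weight[1], weights = w,
             mixing = meta$mixing %||% 0.5,
             lambda = meta$lambda %||% NA_real_,
             seed = meta$seed %||% NA_integer_,
             trainSamples = as.character(meta$train_samples %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
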