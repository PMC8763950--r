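test_that("binary entropy matches the closed form and its symmetries", {
  expect_equal(siteEntropy(0.5), 1)
  expect_equal(siteEntropy(c(0, 1)), c(0, 0))
  # independent high-precision evaluation of -m log2 m - (1-m) log2(1-m)
  expect_equal(siteEntropy(0.25), 0.811278124459133, tolerance = 1e-12)
  m <- seq(0, 1, by = 0.01)
  expect_equal(siteEntropy(m), siteEntropy(1 - m))
  expect_error(siteEntropy(1.2), "\\[0, 1\\]")
  expect_error(siteEntropy(-0.1), "\\[0, 1\\]")
})

test_that("per-sample summaries agree with hand arithmetic and brute force", {
  me <- tinyMethylome(cbind(s1 = c(0, 0.5, 1, 0.5)))
  s <- sampleSummary(me, "s1")
  expect_equal(s$mean_beta, 0.5)
  expect_equal(s$mean_entropy, 0.5)
  expect_equal(c(s$prop_zero, s$prop_one, s$prop_mid), c(0.25, 0.25, 0.5))
  all_mid <- sampleSummary(tinyMethylome(cbind(s1 = rep(0.5, 8))), "s1")
  expect_equal(all_mid$mean_entropy, 1)
  expect_equal(all_mid$prop_mid, 1)
  # 1,000-site random fixture against a brute-force loop
  set.seed(4)
  b <- cbind(s1 = round(runif(1000), 2))
  s <- sampleSummary(tinyMethylome(b), "s1")
  ent <- 0; nz <- 0; no <- 0; nm <- 0
  for (x in b[, 1]) {
    e <- 0
    if (x > 0) e <- e - x * log2(x)
    if (x < 1) e <- e - (1 - x) * log2(1 - x)
    ent <- ent + e
    nz <- nz + (x == 0); no <- no + (x == 1)
    nm <- nm + (x >= 0.45 && x <= 0.55)
  }
  expect_equal(s$mean_entropy, ent / 1000)
  expect_equal(s$mean_beta, mean(b))
  expect_equal(c(s$prop_zero, s$prop_one, s$prop_mid),
               c(nz, no, nm) / 1000)
  # missing betas are excluded and counted
  b2 <- cbind(s1 = c(0.2, NA, 0.8))
  cv <- cbind(s1 = c(5L, 0L, 5L))
  s2 <- sampleSummary(tinyMethylome(b2, cv), "s1")
  expect_equal(s2$n_sites, 2)
  expect_equal(s2$n_missing, 1)
  expect_equal(s2$mean_beta, 0.5)
})

test_that("density profiles behave like a Gaussian KDE on [0,1]", {
  set.seed(8)
  bimodal <- c(rnorm(300, 0.08, 0.03), rnorm(300, 0.92, 0.03))
  bimodal <- bimodal[bimodal >= 0 & bimodal <= 1]
  d <- densityProfile(bimodal)
  expect_equal(nrow(d), 512)
  # two local maxima, one near each mode
  peaks <- which(diff(sign(diff(d$density))) == -2) + 1
  expect_gte(length(peaks), 2)
  expect_lt(min(d$x[peaks]), 0.2)
  expect_gt(max(d$x[peaks]), 0.8)
  # trapezoid integral ~ 1 up to boundary leakage (checked away from the
  # boundaries, where a Scott-rule kernel keeps its mass inside [0, 1])
  central <- pmin(pmax(rnorm(400, 0.5, 0.1), 0), 1)
  dc <- densityProfile(central)
  integ <- sum(diff(dc$x) * (head(dc$density, -1) + dc$density[-1]) / 2)
  expect_lt(abs(integ - 1), 0.05)
  # narrower bandwidth sharpens the peak
  d_narrow <- densityProfile(bimodal, bw = 0.01)
  expect_gt(max(d_narrow$density), max(d$density))
  expect_error(densityProfile(rep(0.3, 50)), "constant")
  expect_error(densityProfile(0.5), "2 finite")
})

test_that("age screen reproduces the textbook Pearson r and p", {
  ages <- c(1, 2, 3, 5, 8)
  me <- tinyMethylome(rbind(lin = 0.1 + 0.01 * ages,
                            anti = 0.9 - 0.02 * ages,
                            flat = rep(0.4, 5)), ages = ages)
  scr <- suppressMessages(ageCorrelationScreen(me))
  expect_equal(nrow(scr), 2)           # constant site skipped, no record
  expect_equal(attr(scr, "skipped"), "ctg1_300")
  expect_equal(scr$r[scr$site_id == "ctg1_100"], 1)   # exact linearity
  expect_equal(scr$r[scr$site_id == "ctg1_200"], -1)
  # 20-sample fixture against the direct formula, to 1e-12
  set.seed(12)
  ages20 <- runif(20, 0, 12)
  b <- rbind(a = pmin(pmax(0.3 + 0.02 * ages20 + rnorm(20, 0, 0.05), 0), 1),
             b = runif(20))
  scr20 <- ageCorrelationScreen(tinyMethylome(b, ages = ages20))
  for (i in 1:2) {
    x <- b[i, ]; y <- ages20; n <- 20
    r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
    p_hand <- 2 * stats::pt(-abs(t_hand), n - 2)
    expect_equal(scr20$r[i], r_hand, tolerance = 1e-12)
    expect_equal(scr20$p[i], p_hand, tolerance = 1e-12)
  }
  # cross-check against stats::cor.test as an independent implementation
  ct <- cor.test(b[1, ], ages20)
  expect_equal(scr20$r[1], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(scr20$p[1], ct$p.value, tolerance = 1e-12)
})

test_that("screen p-values decrease monotonically in |r| at fixed n", {
  set.seed(3)
  ages <- seq(0, 12, length.out = 30)
  slopes <- seq(0.001, 0.03, length.out = 10)
  b <- t(vapply(slopes, function(s)
    pmin(pmax(0.3 + s * ages + rnorm(30, 0, 0.03), 0), 1), numeric(30)))
  scr <- ageCorrelationScreen(tinyMethylome(b, ages = ages))
  ord <- order(abs(scr$r))
  expect_false(is.unsorted(rev(scr$p[ord])))
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 20), 0.0025)
  expect_equal(signif(bonferroniThreshold(0.05, 3089098), 3), 1.62e-08)
  expect_error(bonferroniThreshold(0.05, 0), "positive")
  expect_error(bonferroniThreshold(1.5, 10), "alpha")
})

test_that("significant partition equals a brute-force recount", {
  set.seed(19)
  ages <- runif(40, 0, 12)
  # 5 strong positive, 3 strong negative, 92 null sites
  b <- rbind(
    t(vapply(1:5, function(i) clipv(0.1 + 0.05 * ages + rnorm(40, 0, 0.02)),
             numeric(40))),
    t(vapply(1:3, function(i) clipv(0.9 - 0.05 * ages + rnorm(40, 0, 0.02)),
             numeric(40))),
    matrix(runif(92 * 40), 92, 40))
  scr <- ageCorrelationScreen(tinyMethylome(b, ages = ages))
  thr <- bonferroniThreshold(0.05, nrow(scr))
  part <- partitionSignificant(scr, thr)
  expect_equal(part$n_negative, 3)
  expect_equal(part$n_positive, 5)
  # brute-force recount on the records
  expect_equal(part$n_negative, sum(scr$p < thr & scr$r < 0))
  expect_equal(part$n_positive, sum(scr$p < thr & scr$r > 0))
  expect_length(intersect(part$negative_sites, part$positive_sites), 0)
  expect_equal(partitionSignificant(scr, 0)$n_positive +
                 partitionSignificant(scr, 0)$n_negative, 0)
  all_in <- partitionSignificant(scr, 1)
  expect_equal(all_in$n_negative + all_in$n_positive, nrow(scr))
})

test_that("PCA embedding matches an eigendecomposition oracle", {
  # two perfectly correlated sites: PC1 explains all variance
  ages <- 1:6
  twin <- rbind(a = 0.2 + 0.05 * ages, b = 0.4 + 0.025 * ages)
  emb <- pcaEmbed(tinyMethylome(twin), n_comp = 1)
  expect_equal(emb$explained[1], 1)
  # 10 x 6 fixture against eigen() of the sample covariance
  set.seed(25)
  B <- matrix(runif(60), 10, 6,
              dimnames = list(paste0("c_", 1:10), paste0("S", 1:6)))
  emb <- pcaEmbed(B, n_comp = 2)
  expect_true(all(diff(emb$explained) <= 1e-12))
  expect_lte(sum(emb$explained), 1 + 1e-12)
  X <- scale(t(B), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(X))
  for (k in 1:2) {
    sc_oracle <- as.numeric(X %*% eig$vectors[, k])
    # agree up to sign
    agree <- min(max(abs(emb$scores[, k] - sc_oracle)),
                 max(abs(emb$scores[, k] + sc_oracle)))
    expect_lt(agree, 1e-8)
    expect_equal(emb$explained[k],
                 eig$values[k] / sum(eig$values), tolerance = 1e-10)
  }
  expect_error(pcaEmbed(twin[, 1:3, drop = FALSE] * 0 + 0.5, n_comp = 2),
               "rank|variance|samples")
})

test_that("PC1 of the Bonferroni set tracks age on a signal cohort", {
  ch <- smallCohort(61)
  scr <- ageCorrelationScreen(ch$methylome)
  part <- partitionSignificant(scr, bonferroniThreshold(0.05, nrow(scr)))
  sig <- c(part$negative_sites, part$positive_sites)
  expect_gt(length(sig), 5)
  emb <- pcaEmbed(ch$methylome, sig)
  expect_gte(abs(cor(emb$scores[, 1], sampleAges(ch$methylome))), 0.9)
})

test_that("mean trajectories average the site set per sample", {
  b <- rbind(a = c(0.2, 0.6), b = c(0.4, 0.8), c = c(1, 0))
  rownames(b) <- c("c_1", "c_2", "c_3"); colnames(b) <- c("s1", "s2")
  expect_equal(unname(meanTrajectory(b, "c_1")), c(0.2, 0.6))  # singleton
  expect_equal(unname(meanTrajectory(b, c("c_1", "c_2"))), c(0.3, 0.7))
  # 50-site random set against a brute-force loop
  set.seed(33)
  B <- matrix(runif(50 * 7), 50, 7,
              dimnames = list(paste0("c_", 1:50), paste0("S", 1:7)))
  mt <- meanTrajectory(B, rownames(B))
  loop <- numeric(7)
  for (j in 1:7) loop[j] <- mean(B[, j])
  expect_equal(unname(mt), loop)
  expect_error(meanTrajectory(B, character()), "empty")
})
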