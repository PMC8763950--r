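test_that("promoter windows follow the transcription direction", {
  catg <- makeCatalog(c("plus", "minus", "edge"), "c1",
                      start = c(10000L, 5000L, 800L),
                      end = c(20000L, 10000L, 2000L),
                      strand = c("+", "-", "+"))
  pr <- promoterRegions(catg)
  expect_equal(start(pr[1]), 8500)    # + strand: [TSS-1500, TSS+500]
  expect_equal(end(pr[1]), 10500)
  expect_equal(start(pr[2]), 9500)    # - strand mirrored: [TSS-500, TSS+1500]
  expect_equal(end(pr[2]), 11500)
  expect_equal(start(pr[3]), 1)       # clipped at position 1
  expect_equal(end(pr[3]), 1300)
  # unclipped width = upstream + downstream + 1 on either strand
  expect_equal(width(pr[1]), 1500 + 500 + 1)
  expect_equal(width(pr[2]), 1500 + 500 + 1)
})

test_that("sites are assigned to genes with promoter precedence", {
  # + strand gene 10000-20000, TSS 10000; exon 10000-12000
  catg <- makeCatalog("gA", "c1", 10000L, 20000L, "+",
                      exons = data.frame(contig = "c1", start = 10000L,
                                         end = 12000L, gene_id = "gA"))
  pos <- c(10200L,  # in exon AND promoter window -> promoter wins
           11900L,  # exon, outside promoter ([8500,10500])
           15000L,  # gene body, no exon -> intron
           20900L,  # within 1500 bp downstream flank
           8399L,   # 1601 bp upstream of TSS -> outside flank, intergenic
           30000L)  # far away -> intergenic
  b <- matrix(0.5, length(pos), 3,
              dimnames = list(makeSiteId("c1", pos), paste0("S", 1:3)))
  me <- MethylomeExperiment(b, matrix(10L, length(pos), 3,
                                      dimnames = dimnames(b)),
                            sites = data.frame(contig = "c1",
                                               position = pos))
  asg <- assignSitesToGenes(me, catg)
  expect_equal(asg$feature,
               c("promoter", "exon", "intron", "flank",
                 "intergenic", "intergenic"))
  expect_equal(asg$gene_id[1:4], rep("gA", 4))
  expect_true(all(is.na(asg$gene_id[5:6])))
  # promoter-flagged sites really lie inside the promoter window
  pr <- promoterRegions(catg)
  prom_pos <- splitSiteId(asg$site_id[asg$feature == "promoter"])$position
  expect_true(all(prom_pos >= start(pr) & prom_pos <= end(pr)))
})

# cohort with one gene whose promoter CpGs all carry a planted slope
promoterCohort <- function(seed, slope = 0.02, n = 100) {
  pos <- c(seq(8600, 10400, by = 200),   # promoter sites of gA (TSS 10000)
           seq(12000, 19000, by = 1000)) # gene-body sites
  truth <- data.frame(
    site_id = makeSiteId("c1", pos), contig = "c1", position = pos,
    label = c(rep("increasing", 10), rep("stable", 8)),
    baseline = c(runif(10, 0.1, 0.3), runif(8, 0.3, 0.7)),
    slope = c(rep(slope, 10), rep(0, 8)), noise_sd = 0.02)
  cfg <- cohortConfig(n_samples = n, depth_mean = 50, noise_sd = 0.02,
                      seed = seed)
  withr::with_seed(seed, {
    ages <- runif(n, 0, 12)
    me <- simulateMethylome(truth, ages, cfg)
    list(me = me, ages = ages, truth = truth)
  })
}

test_that("promoter screen recovers a planted promoter age signal", {
  fx <- promoterCohort(91)
  catg <- makeCatalog("gA", "c1", 10000L, 20000L, "+")
  ps <- promoterAgeScreen(fx$me, catg, ages = fx$ages)
  expect_equal(ps$n_scored, 1)
  expect_equal(ps$screen$n_sites, 10)
  expect_gt(ps$screen$r, 0.9)
  expect_equal(ps$bonferroni, 0.05)
})

test_that("genes without covered promoter CpGs are reported, not scored", {
  fx <- promoterCohort(92)
  catg <- makeCatalog(c("gA", "gNone"), "c1",
                      start = c(10000L, 500000L), end = c(20000L, 510000L),
                      strand = c("+", "+"))
  ps <- promoterAgeScreen(fx$me, catg, ages = fx$ages)
  expect_equal(ps$screen$gene_id, "gA")
  expect_equal(ps$unscored, "gNone")
})

test_that("a single-CpG promoter reproduces the site-level correlation", {
  fx <- promoterCohort(93)
  # gene whose promoter covers exactly one CpG: TSS at 12050 on + strand
  # window [10550, 12550] contains only the site at 12000
  catg <- makeCatalog("g1", "c1", 12050L, 13000L, "+")
  ps <- promoterAgeScreen(fx$me, catg, ages = fx$ages)
  expect_equal(ps$screen$n_sites, 1)
  scr <- ageCorrelationScreen(fx$me, fx$ages)
  site_r <- scr$r[scr$site_id == "c1_12000"]
  expect_equal(ps$screen$r, site_r, tolerance = 1e-12)
})

test_that("gene profiles locate a planted age-signal cluster", {
  fx <- promoterCohort(94)
  catg <- makeCatalog("gA", "c1", 10000L, 20000L, "+")
  prof <- geneProfile(fx$me, catg, "gA", ages = fx$ages,
                      clock_sites = "c1_9000")
  expect_equal(nrow(prof), 18)
  expect_false(is.unsorted(prof$position))
  # max |r| lies inside the planted promoter cluster (positions <= 10400)
  expect_lte(prof$position[which.max(abs(prof$r))], 10400)
  expect_true(all(prof$significant[prof$position <= 10400]))
  expect_equal(sum(prof$is_clock), 1)
  # single-site region: profile of length 1 with that site's r
  catg1 <- makeCatalog("tiny", "c1", 14950L, 15050L, "+")
  p1 <- geneProfile(fx$me, catg1, "tiny", ages = fx$ages, flank = 100)
  expect_equal(nrow(p1), 1)
  scr <- ageCorrelationScreen(fx$me, fx$ages)
  expect_equal(p1$r, scr$r[scr$site_id == p1$site_id], tolerance = 1e-12)
  expect_error(geneProfile(fx$me, catg, "nope"), "not in catalog")
})

test_that("null single-CpG genes are flagged at roughly the nominal rate", {
  # one stable site; the p < 0.05 flag should fire in ~5% of seeds
  flagged <- vapply(1:40, function(s) {
    truth <- data.frame(site_id = "c1_5000", contig = "c1",
                        position = 5000L, label = "stable",
                        baseline = 0.5, slope = 0, noise_sd = 0.05)
    cfg <- cohortConfig(n_samples = 100, depth_mean = 30, seed = s)
    withr::with_seed(1000 + s, {
      ages <- runif(100, 0, 12)
      me <- simulateMethylome(truth, ages, cfg)
      prof <- geneProfile(me, makeCatalog("g", "c1", 4900L, 5100L, "+"),
                          "g", ages = ages)
      prof$significant[1]
    })
  }, logical(1))
  expect_lte(mean(flagged), 0.15)   # 0.05 nominal + binomial slack at 40 seeds
})

test_that("ortholog profiles compare planted clusters across cohorts", {
  fxa <- promoterCohort(95)
  fxb <- promoterCohort(96)
  catg <- makeCatalog("gA", "c1", 10000L, 20000L, "+")
  # self-comparison: duplicated cohort gives identical summaries
  self <- orthologProfiles("gA", catg, fxa$me, catg, fxa$me,
                           ages_a = fxa$ages, ages_b = fxa$ages)
  expect_identical(self$a$summary, self$b$summary)
  # independent cohorts with the same construction: cluster position agrees
  pair <- orthologProfiles("gA", catg, fxa$me, catg, fxb$me,
                           ages_a = fxa$ages, ages_b = fxb$ages)
  expect_lt(abs(pair$a$summary$max_r_fraction -
                pair$b$summary$max_r_fraction), 0.1)
  # explicit ortholog table and a gene missing from the second catalog
  catg_b <- makeCatalog("Mm_gA", "c7", 1000L, 9000L, "+")
  tbl <- data.frame(from = "gA", to = "Mm_other")
  expect_message(
    miss <- orthologProfiles("gA", catg, fxa$me, catg_b, fxb$me,
                             ages_a = fxa$ages, ages_b = fxb$ages,
                             ortholog_table = tbl),
    "absent")
  expect_null(miss$b$profile)
  expect_false(is.null(miss$a$profile))
})

test_that("a planted mid-gene cluster is located at mid-gene in both cohorts", {
  mk <- function(seed) {
    pos <- seq(1000, 21000, by = 1000)   # gene 1000-21000, cluster at center
    center <- abs(pos - 11000) <= 2000
    truth <- data.frame(site_id = makeSiteId("c1", pos), contig = "c1",
                        position = pos,
                        label = ifelse(center, "increasing", "stable"),
                        baseline = ifelse(center, 0.2, 0.5),
                        slope = ifelse(center, 0.025, 0), noise_sd = 0.02)
    cfg <- cohortConfig(n_samples = 80, depth_mean = 50, seed = seed)
    withr::with_seed(seed, {
      ages <- runif(80, 0, 12)
      list(me = simulateMethylome(truth, ages, cfg), ages = ages)
    })
  }
  a <- mk(7); b <- mk(8)
  catg <- makeCatalog("gC", "c1", 1000L, 21000L, "+")
  pair <- orthologProfiles("gC", catg, a$me, catg, b$me,
                           ages_a = a$ages, ages_b = b$ages)
  expect_lt(abs(pair$a$summary$max_r_fraction - 0.5), 0.1)
  expect_lt(abs(pair$b$summary$max_r_fraction - 0.5), 0.1)
})
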