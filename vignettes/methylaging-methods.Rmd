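---
title: "Models and methods behind methylaging"
author: "methylaging authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaging)
```

# Scope and data model

`methylaging` analyses per-CpG methylation calls from reduced
representation bisulfite sequencing (RRBS). The central container is the
`MethylomeExperiment`, a `RangedSummarizedExperiment` with two assays: the
`beta` matrix of methylation fractions and the `coverage` matrix of read
counts, rows being single-base CpG sites and columns samples with age,
sex, breeder-status and species metadata. Betas are always recomputed from
the methylated/unmethylated read counts — the percentage column of a
Bismark coverage file is only checked for consistency — so rounding
conventions of upstream extractors cannot drift into the analysis, and a
beta is missing exactly where a cell has zero reads.

Coordinates are stored 1-based inclusive (the Bismark convention). All
interval logic runs through `GenomicRanges`, which keeps the arithmetic in
one place; the only interval constructions in package code are the
strand-aware promoter window and the symmetric gene flank.

## Coverage filtering

A site enters the matrix when covered by at least `min_reads` reads
(default 5) in at least `min_sample_fraction` of the samples (default
0.9), the standard RRBS common-site filter. At a retained site, the
minority of samples below the read cutoff keep their beta computed from
whatever reads exist; a beta is missing only at zero coverage. The
alternative — masking low-coverage cells — would silently change the
sample set of every downstream correlation; keeping the observed fractions
makes the correlation sample sets explicit (they are reported per site as
`n`). The clock feature table re-filters at the stricter criterion of
coverage in *all* samples (`fraction = 1.0`), which guarantees a gap-free
matrix for the elastic net without imputation.

# Global statistics

Per-sample descriptors are the global mean beta, the mean binary Shannon
entropy
$-m\log_2 m - (1-m)\log_2(1-m)$ (bits, with $0\log 0 = 0$), and the
proportions of sites at beta exactly 0, exactly 1, and inside
$[0.45, 0.55]$. Exact equality for the extreme proportions is deliberate:
count-derived betas hit 0 and 1 exactly, so no epsilon band is needed. The
mid band is closed on both ends; with typical read depths the boundary
atoms are negligible, but the choice is pinned rather than implicit. Mean
entropy is averaged over all matrix sites, not only sites passing any
downstream screen.

The age screen computes, per site, the Pearson correlation of betas with
age and the two-sided p-value from the t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$, dropping missing cells pairwise. Sites with
fewer than 3 usable pairs or zero variance are skipped and reported, never
assigned an `r`. Significance is Bonferroni-controlled ($p < \alpha/N$
with $N$ the number of scored sites); the significant set splits by the
sign of `r`. PCA of the significant set is site-centred but not
variance-scaled — betas already share the [0, 1] scale, and per-site
scaling would inflate near-constant sites. Component signs are fixed by
making each component's largest-magnitude loading positive, so embeddings
are reproducible across platforms.

Density profiles use a Gaussian kernel on a fixed 512-point grid over
[0, 1] with Scott's-rule bandwidth. On strongly bimodal methylomes the
rule produces a wide kernel whose mass leaks past the boundaries; the
profile is a descriptive display, and the package neither renormalises nor
reflects at the boundaries. Constant input is an error (zero bandwidth).

# Promoter and gene profiling

The promoter is the window from 1500 bp upstream to 500 bp downstream of
the transcription start site, following the direction of transcription,
clipped at position 1. The gene catalog is distilled from a GTF: one
record per `gene_id` spanning the min start / max end of its transcripts,
TSS at the span start (`+`) or end (`-`); genes with unknown or
conflicting strand are excluded with a warning.

The promoter screen averages the betas of promoter CpGs per gene and
sample, then correlates with age. Its Bonferroni divisor is the number of
genes actually scored (genes with at least one covered promoter CpG) and
is reported next to the results, because the alternative divisor — all
annotated genes — is defensible too and silent divisor choices are a
classic irreproducibility source.

Site-to-gene assignment maps each site to every gene whose span ± 1500 bp
contains it, labelling the feature with precedence promoter > exon >
intron > flank; a single label per site-gene pair keeps downstream tables
unambiguous where the promoter window overlaps the first exon. Gene
profiles flag sites at unadjusted $p < 0.05$ — the per-gene display
convention — which is intentionally distinct from the Bonferroni threshold
of the promoter screen; both thresholds are exposed. Ortholog comparison
matches gene symbols exactly by default, or through an explicit two-column
table, and summarises each profile by its count of significant sites and
the position of the max-|r| site as a fraction of gene length.

# The epigenetic clock

Training fits `age ~ beta` by elastic net at mixing parameter 0.5. The
penalty $\lambda$ is selected by 10-fold inner cross-validation with a
seeded fold assignment. The selection rule is the **one-standard-error
cut point**: the largest $\lambda$ whose CV error is within one SE of the
minimum. This is the long-standing default of the glmnet family of tools,
and it is the rule that makes clocks sparse: at the reference simulation
the 1-SE rule selects ~90–120 sites of which 91–100% are planted signal
sites, whereas the CV-minimum rule selects 120–190 sites with as little as
56% on signal. The CV-minimum rule remains available
(`clockConfig(lambda_rule = "min")`). If the selection lands on the
smallest $\lambda$ of glmnet's early-stopped path, the grid is extended
downward (twice at most, each by a factor of 100) so the optimum is
interior — without this, near-noiseless inputs are visibly over-shrunk.

Features are standardised internally by the fitter and coefficients
reported back on the raw beta scale, so a trained clock has the published
form `intercept + Σ w · beta` and serialises as a two-column TSV. Nested
cross-validation draws 5 outer folds by seeded uniform shuffling without
age stratification (fold sizes differ by at most one), trains each fold's
clock — including its own inner $\lambda$ search — on the complementary
80%, and predicts the held-out fold, giving every sample exactly one
strictly out-of-sample DNAm age. Unified-prediction Pearson r and median
absolute error are the headline metrics. Negative predictions are reported
as-is. On age-shuffled data the 1-SE rule routinely returns an
intercept-only model; this is allowed (with a warning) because it is the
correct null behaviour.

Age acceleration is the residual of DNAm age from the OLS line of DNAm
age on chronological age over all samples, so accelerations sum to zero by
construction. Group deviations from zero use two-sided one-sample t-tests;
the between-group contrast uses Welch's t-test, chosen over the pooled
test because group sizes and variances (queens vs non-breeders, say) are
typically unequal.

# Cross-species trajectory comparison

Clock sites split by the **sign of their age correlation** — not the sign
of their model weight, which can differ — into decreasing and increasing
sets. Each set's mean methylation versus age is fitted by least squares at
degree 1 or 2 per species (published blood-clock trends are near-linear
for the naked mole-rat and human and curved for the mouse), with the
residual SD and the fitted age range attached to the fit. The crossover of
the two trends is the root of the difference polynomial, solved
analytically (closed form for linear–linear, quadratic formula otherwise);
roots are only accepted inside the observed age range, since extrapolated
intersections are not meaningful, and with several in-range roots the
smallest is chosen with a warning. Relative age divides by the species'
maximum lifespan; reported relative ages are rounded to 3 decimals, full
precision retained internally. One known wrinkle: published values of
crossover age 1.66 y at lifespan 4 y imply 0.415 at 3 decimals, while
0.414 has been printed — an upstream rounding artefact the package does
not attempt to resolve.

# The synthetic cohort generator

`simulateCohort()` is first-class, tested code, not a fixture. Site
classes are `increasing`, `decreasing`, `stable` and `drift_to_half`;
linear classes follow `clip(baseline + slope · age, 0, 1)` and drift sites
move from extreme baselines toward 0.5 at a fixed rate, saturating there —
the mechanism that raises methylome entropy with age. Linear (clipped)
trajectories are the default because adult mean-methylation trends of
age-correlated site sets are near-linear; curvature can be emulated by the
drift class. Per cell, the observed count is binomial at the true fraction
plus Gaussian biological noise (clipped), at a read depth drawn from a
shifted negative binomial (minimum 1 read) capturing RRBS depth
over-dispersion. Noise precedes read sampling so recovery tests can
separate biological from sampling variance.

Reference conditions, used for validation throughout: 200 samples, ages
uniform on 0–12 years (the densely sampled span of a naked mole-rat
colony), 5,000 sites of which 150 increase and 150 decrease with absolute
slope 0.01–0.03 per year (baselines leave room for the full trajectory),
4,700 stable sites, depth mean 30 with dispersion 5, noise SD 0.05. At
these conditions the nested-CV clock reaches r ≈ 0.98 and MedAE ≈ 0.4
years over seeds; the acceptance thresholds (r ≥ 0.85, MedAE ≤ 1.2 y) sit
well below the achieved values so that they test the machinery, not the
seed. An optional `juvenile` flag widens baseline extremity below 0.1
years to emulate the low-entropy developmental state; it is off by
default.

What the generator does **not** emulate: sequence context and CpG
density, strand effects, SNP-confounded CpGs, batch structure, and
correlated methylation of neighbouring sites. Passing tests therefore
demonstrate the statistical machinery on cohorts with the assumed
age-signal structure; they do not certify performance on real RRBS data,
where neighbour correlation and technical covariates matter.

# Problem sizes and determinism

Validation runs at deliberately modest sizes: the reference cohort
(200 × 5,000) for clock acceptance over 5 seeds, 10-seed null batteries at
40–80 samples and 400–500 sites for calibration (uniform screen p-values;
no clock signal after age shuffling), and ≤ 50-sample fixtures for
closed-form oracle comparisons (entropy, Pearson r/p, OLS residuals, PCA
against an eigendecomposition, crossover roots against the quadratic
formula). Every stochastic step — cohort generation, fold assignment, age
shuffling — consumes an explicit integer seed, and the generator restores
the caller's RNG state, so identical configurations are bit-identical.

# Known limitations

* Correlation screens assume approximately linear beta–age relationships;
  strongly non-monotone sites are under-called by design.
* The clock is a linear model on betas; no interaction or tissue terms.
* Promoter definitions come from transcript spans only (no CAGE-refined
  TSS), and ortholog matching is by symbol, not sequence homology.
* The pipeline accepts processed coverage files; alignment, methylation
  extraction and contig preprocessing are upstream of this package.
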