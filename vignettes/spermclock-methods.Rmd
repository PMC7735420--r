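---
title: "Modelling sperm methylome aging: methods and design choices"
author: "spermclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sperm methylome aging: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermclock)
```

## The scientific problem

Sperm DNA methylation changes systematically with a man's age: thousands of
CpG sites gain or lose methylation per year of life, more of them gaining
(roughly a 62:38 hyper:hypo split in targeted capture data), with
hypomethylation concentrated near transcription start sites and
hypermethylation in gene-distal, heterochromatin-like territory. These
changes are strong enough to support an epigenetic "clock" — a penalized
linear predictor of chronological age from methylation proportions — and
coordinated enough that co-methylation network analysis finds large
age-linked modules.

`spermclock` implements the full analysis chain for this kind of study:
from per-CpG bisulfite read counts and a clinical sample sheet, through
covariate-adjusted per-CpG age EWAS with Storey q-values and
genomic-control diagnostics, direction-specific DMR calling, genomic
annotation and enrichment, an elastic-net age clock with leave-one-out
cross-validation (LOOCV), and weighted co-methylation modules with
eigengene–trait correlation. Because cohorts of this kind are
controlled-access, the package ships a fully specified synthetic cohort
generator that emulates the statistical structure such a study produces,
so every stage is testable end to end.

## Data model and coordinates

The central container is `MethylationExperiment`, a
`RangedSummarizedExperiment` with integer assays `meth` and `total`
(sites × samples). Methylation is always analysed on the proportion scale
`beta = meth / total`, in [0, 1], with `beta` missing wherever a cell has
no usable reads. The sample sheet (age in years, fertility status, semen
parameters, hormones, lipids, smoking) lives in `colData`.

Coordinates follow two conventions deliberately: site identifiers
(`"chr1:100"`) and all on-disk BED/report output use 0-based (half-open)
positions, while the in-memory `GRanges` use the 1-based Bioconductor
convention. Cytosine reports are 1-based on disk, as the aligners emit
them; `readCytosineReport()` shifts on input and, by default, merges each
CpG dyad's G-strand record into the forward-strand C one base upstream —
CpG-level methylation is strand-symmetric, and merging doubles effective
coverage. A `merge_strands = FALSE` escape hatch preserves strands for
debugging.

## Site filtering and purity QC

`filterSites()` applies three rules in a fixed order:

1. **coverage mask** — any (site, sample) cell with fewer than 20 reads is
   set missing (the cell, not the site: a site poorly covered in one donor
   is still informative in the others);
2. **exclusion regions** — sites overlapping supplied BED intervals
   (SNPs, blacklisted regions) are removed;
3. **minimum informative samples** — sites observed in fewer than 30
   donors are removed. The boundary is inclusive: exactly 30 passes.

The `FilterReport` carries the counts so that
`input − excluded − few_samples = retained` always holds; the coverage
mask is reported as masked cells, since it removes no site by itself.

Sperm purity is checked the way the field does it: germline imprinted
differentially methylated regions have parent-of-origin methylation that
is essentially binary in pure sperm (paternally methylated loci such as
H19 near 1, maternally methylated loci such as MEST near 0), and somatic
contamination mixes both linearly toward ~0.5. `qcImprinting()` passes a
paternal locus at mean beta ≥ 0.80 and a maternal locus at ≤ 0.20.
The thresholds are a package choice — sperm studies typically report this QC
only qualitatively — set so that roughly ≥ 30% somatic admixture fails
under the linear mixture model (a 50:50 mixture puts a paternal locus at
(0.95 + 0.5)/2 ≈ 0.73). Loci with no assayed CpG are reported
not-assessable and fail the overall verdict rather than passing silently.

## Per-CpG EWAS

Each retained CpG is fit by ordinary least squares:
`beta ~ intercept + age + covariates`, complete-case on the methylation
values per site. The age coefficient is the effect (Δ proportion / year);
its two-sided t test uses `n_used − rank` degrees of freedom. Degenerate
fits — rank-deficient designs, constant responses, too few cases — are
flagged non-estimable with missing p, never silently zero.

Covariate coding: fertility and smoking enter as indicator columns
(`never`/`fertile` as reference); continuous covariates are untransformed.
Missing covariate values are median-imputed (mode for smoking) with one
message per variable: complete-case deletion would drop donors
non-uniformly per CpG, and the cohort's per-variable n < 94 pattern is
exactly the situation the imputation addresses. The response stays on the
proportion scale; a logit transform was considered and rejected because
sperm EWAS conventionally model proportions directly, and effects are then
interpretable in percentage points per year.

**Multiple testing** uses Storey q-values, implemented in the package
(`qvalues()`): π₀ is estimated by a cubic smoothing spline (df = 3) on
π₀(λ) = mean(p > λ)/(1 − λ) over λ = 0.05 … 0.95, evaluated at λ = 0.95,
with a fallback to π₀ = 1 whenever the estimate leaves (0, 1] or fewer
than 100 tests are available. With π₀ = 1 the procedure is exactly
Benjamini–Hochberg, which the tests assert on a worked example.
Genome-wide significance is fixed at q < 0.01.

**Inflation diagnostics**: `genomicInflation()` reports
λ_GC = median(χ²₁ quantiles of the p-values)/0.4549. On null synthetic
cohorts λ_GC is 1.00 within sampling noise; on confounded cohorts the
covariate-adjusted EWAS moves λ_GC strictly toward 1 relative to the
unadjusted fit — the qualitative pattern reported for sperm age EWAS
(≈1.7 unadjusted dropping to ≈1.44 adjusted).

## DMR calling and density

A DMR is a cluster of same-direction significant CpGs: any window
`[p, p + 500)` anchored at a significant CpG containing ≥ 5 of them
qualifies, qualifying windows that overlap are merged, and the merged
member set becomes one DMR spanning first to last member CpG (half-open).
Direction purity is strict — hyper and hypo regions are called
independently, and mixed clusters yield nothing. Windows are anchored at
CpGs rather than tiled, because fixed tiles miss clusters straddling tile
boundaries; an exhaustive window-enumeration oracle in the test suite
checks equality on hundreds of random instances.

Two properties worth knowing: the *number* of merged DMRs is not monotone
in `min_cpgs` (removing a bridging window can split one region into two),
so the monotonicity the caller guarantees — and the tests assert — is on
the total number of member CpGs; and reported counts are merged regions,
not qualifying windows, because only merged regions have a well-defined
count.

`dmcDensity()` tiles each chromosome with 1 Mb windows stepped every
100 kb (the step is a package choice; sliding-window density analyses
rarely state one) and reports the per-direction ratio of DMCs to
assayed CpGs, missing where a window holds no CpG.

## Annotation and enrichment

`nearestTss()` assigns each CpG the gene with the minimum absolute
TSS distance, sign made orientation-aware (positive = downstream of the
TSS in the gene's reading direction), ties broken by lexicographically
smallest gene id for determinism. Distance profiles default to
GREAT-style signed bins (0–5 kb, 5–50 kb, 50–500 kb, > 500 kb each side).

Gene-level enrichment of foreground CpGs (e.g. hyper-DMCs) within
TSS ± 1 Mb uses a one-sided hypergeometric test against the assayed panel
as background. This is a deliberate simplification of GREAT's
regulatory-domain binomial test, whose domain construction is not
parameterized here; counts of CpGs (not base-pair-normalized rates)
are used, and that choice is documented here precisely because the
alternative is defensible too. Genes with no background CpG in the window
are flagged and skipped, not scored. Constrained-element analysis is
consumed as a precomputed score BED (`constrainedFraction()`, threshold
1.7): computing conservation scores is out of scope.

## The methylation age clock

Feature selection takes the top 5,000 sites by ascending p (ties broken
by |effect| then position), then drops every site not measured in all
donors — the clock must never depend on imputation at training time.
`trainAgeClock()` fits an elastic net (α = 0.5) of age on the selected
beta values, with λ minimizing LOOCV mean squared error over 100
log-spaced values from the data-driven maximal λ down to 10⁻⁴ of it; the
grid is built explicitly (glmnet's own path can stop early once the
deviance plateaus) and recorded in the model for reproducibility.
Coefficients are reported on the original proportion scale.

`loocvEvaluate()` runs the honest outer loop: for each held-out donor,
the EWAS ranking, the top-k selection, and the inner λ tuning are all
refit on the remaining n − 1 donors, so no selection information leaks
into the evaluation. Reported sperm clock errors (≈2.7 years at n = 94) do not always say
whether selection was refit per fold or fixed once, so both variants are
implemented; the leaky variant sits
behind `fixed_selection = TRUE` and is labelled as such. The deployable
model is trained once on all donors with λ from full-data LOOCV.
Predictions are the plain affine map with no clamping — negative
predictions are reported as-is.

On synthetic cohorts with 200 informative CpGs at n = 94 and ~30×
coverage, selection-inside-fold LOOCV reaches ~1.5–2.5 years MAE, and a
12-donor replication cohort drawn from the same panel biology
(`simulateReplication()`: same baselines, effects and capture
efficiencies; new donors, depths and reads) lands near 3 years —
the discovery-better-than-replication ordering reported for sperm
clocks (≈2.7 y discovery vs ≈4.4 y in a 12-donor replication). Under permuted age labels the LOOCV error
collapses onto the no-information bound (the mean absolute deviation
from the mean age), which the acceptance suite checks within 15%.

## Co-methylation modules

The network stage follows WGCNA conventions in a deliberately small,
deterministic implementation: top 20,000 most variable complete-coverage
CpGs; unsigned adjacency `|r|⁸`; topological overlap
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`;
average-linkage clustering on 1 − TOM cut at the *static* height 0.4,
clusters under 30 CpGs pooled as `"grey"`. The static cut (rather than the
dynamic hybrid cut common in practice) is intentional and is a divergence
from common practice worth flagging: a plain static cut height is the
convention this package follows.

A numerical fact shapes everything downstream: at power 8 with a 0.4 cut,
average linkage only isolates blocks whose pairwise correlations are
roughly ≥ 0.95. Modules that survive these settings are therefore
*tightly* co-methylated — locus-level blocks in which CpGs track a shared
methylation state almost perfectly, like the reported chromosome-8
infertility-linked sperm module in which nearly all module CpGs track
one 9 kb locus. The synthetic generator models exactly that (next section).

Module eigengenes are the unit-variance leading principal component of
the per-CpG standardized module submatrix, sign-anchored to correlate
positively with the module's mean standardized methylation (PC sign is
otherwise arbitrary and would make trait correlations irreproducible).
Trait correlation is plain Pearson with two-sided p, complete-case per
trait; categorical traits are coded fertile/infertile → 0/1 and smoking
never/past/current → 0/1/2, a package choice, since no standard coding exists.

## The synthetic cohort generator

The generator is the package's testing instrument and defines the study
conditions; its defaults are fixed, not tuned:

- **Design**: 48 young donors (ages 18–38, truncated normal with mean
  29.4, SD 6.3) and 46 old (46–71, mean 53.2, SD 6.7), fertile/infertile
  matched within age groups; smoking 61/27/12% never/past/current.
- **Covariates**: generated with target Pearson correlations to age
  (FSH +0.45, testosterone −0.35, motility −0.25, BMI +0.20, …) and
  pooled cross-sectional moments in adult male reference ranges;
  covariate values go missing completely at random at 3%.
- **Baselines**: the bimodal sperm methylome — 45% low (Beta(2,18)),
  45% high (Beta(18,2)), 10% intermediate.
- **Age effects**: a configurable fraction of CpGs (default 10%) gets a
  signed per-year effect, |effect| ~ N(0.004, 0.0015) proportion/year,
  62% positive; effects are additive in age on the proportion scale,
  centred at the cohort mean age, clamped to [0, 1]. Ten DMR clusters of
  7 same-direction CpGs within 500 bp are planted.
- **Coverage**: negative-binomial at the cell level (size 30) with
  lognormal per-site capture-efficiency (meanlog 0.25, sdlog 0.30) and
  per-sample depth (sdlog 0.15) factors. The profile is calibrated once
  against the assay's stated detection behaviour — ~80% of panel CpGs at
  ≥ 20× in ≥ 90% of donors — which also leaves a realistic minority of
  sites covered ≥ 20× in *every* donor, the subset the clock and network
  stages require. Planted modules and imprinted QC loci sit in
  well-captured regions, as network input and QC targets do on a real
  capture panel. An i.i.d. coverage model cannot reproduce this: with
  independent cells, the probability of a site being complete across 94
  donors is essentially zero, which would contradict the existence of
  the study's 20,000 complete-coverage network sites.
- **Modules**: epiallele-like bimodal states. Each module has a latent
  per-donor factor (optionally correlated with age; defaults ±0.6 for two
  modules, mirroring the two large opposite-signed age modules);
  module CpGs sit at baseline ~0.5 and flip by ±0.4 × loading
  (loadings U(0.8, 1)) with the factor's sign. This is the only generative
  shape that produces the ≥ 0.95 within-module correlations the power-8 /
  0.4-cut clustering can detect through binomial read noise at 30×; a
  Gaussian factor of realistic amplitude cannot. One consequence to keep
  in mind: thresholding the latent factor attenuates the configured
  module–age correlation by ≈ 0.8 (point-biserial), so a configured 0.6
  recovers ≈ 0.45–0.5.
- **Imprinted loci**: two paternal-type (0.95) and two maternal-type
  (0.03) five-CpG loci; a somatic contamination fraction mixes both
  toward 0.5 linearly.
- **Counts**: methylated reads are Binomial(coverage, true proportion) —
  identical seeds give bit-identical cohorts.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: sequence-context effects, meQTL/SNP structure,
between-donor biological variance at non-module sites (non-planted sites
are flat apart from read sampling), spatial correlation of methylation
outside planted clusters, batch effects, and cell-composition artifacts
beyond the linear imprinting mixture. Effect recovery and calibration
results transfer to real data only insofar as the linear-model
assumptions hold there.

## Problem sizes and numerical choices

Demonstration and test runs use panels of 300–6,000 CpGs and the full
94-donor design — the package's chosen demonstration scale; the analysis
code is the same at 2.65 million sites, only slower. Other numerical
choices: per-site OLS uses a QR rank check plus Cholesky solve;
`qvalues()` falls back to π₀ = 1 below 100 tests; p = 0 inputs to
λ_GC are mapped to the smallest positive double with a warning; DMR
calling refuses unsorted input rather than resorting (surfacing upstream
bugs); all tie-breaks (clock ranking, TSS ties, module labels) are
specified exactly so reruns are byte-identical, which the pipeline
manifest hashes verify.

## A minimal run

```{r example, eval = FALSE}
cohort <- simulateCohort(cohortConfig(n_cpgs = 2000L, seed = 1L))
fl <- filterSites(cohort$me)
res <- runEwas(fl$me, outcome = "age",
               covariates = c("fertility", "smoking", "FSH"))
genomicInflation(res$p[res$estimable])$lambda_gc
cls <- classifyDmcs(res, q_threshold = 0.01)
sig <- merge(cls$labels, res[, c("id", "q", "effect")], by = "id")
sig <- sig[order(sig$chrom, sig$pos), ]
callDmrs(sig, all_sites = siteTable(fl$me))
```

The orchestrated equivalent is `runPipeline(defaultRunConfig())`, which
writes every stage output plus an md5 manifest and run log; the
`spermclock` functions themselves are the package's interface, and the
pipeline configuration (one list or YAML file, one master seed) is how a
full study is reproduced.

## Known limitations

The static tree cut makes module detection conservative; loosely
co-methylated modules that dynamic tree cutting would find are reported
as unassigned. The hypergeometric enrichment ignores GREAT's
regulatory-domain geometry. The purity thresholds are calibrated to a
linear mixture model, not to pyrosequencing variance. The q-value π₀
smoother is evaluated at λ = 0.95 without bootstrap smoothing of the
tuning parameter. And the clock's replication design assumes the
replication cohort shares the discovery panel's capture chemistry —
cross-platform transfer (e.g. to array data) is out of scope.
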