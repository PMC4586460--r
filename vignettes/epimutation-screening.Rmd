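---
title: "Screening cohorts for individual-specific methylation outliers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cohorts for individual-specific methylation outliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcan)
library(dplyr)
```

## Why an outlier scan

Per-probe group tests compare a phenotype group's methylation against a
control group's, probe by probe. They have power only when the *same*
CpG sites shift in most affected individuals. Many real exposures do not
behave this way: each affected individual accumulates alterations at
*different* loci, so group means barely move and a rank-sum test with
multiple-testing control finds nothing. `episcan` keeps the group test
(`compare_groups()`) as the first, usually negative, step, and then asks
the complementary question: at each probe, does exactly one sample
deviate from the rest of the cohort? Counting those single-sample
deviations per subject yields an epimutation *burden*, a per-individual
quantity that can be compared across exposure categories even when the
affected loci never replicate between individuals.

## The statistical core

At a probe with cohort values $x_1 \dots x_N$ the Smirnov-Grubbs
statistic is $G = \max_i |x_i - \bar x| / s$ with sample SD $s$. The
two-sided p-value uses the classical t-inversion

$$t = \sqrt{\frac{N(N-2)G^2}{(N-1)^2 - NG^2}}, \qquad
  p = \min\!\left(1,\; 2N\,P(T_{N-2} \ge t)\right).$$

Three properties matter for its use at genome scale:

* **It is a union (Bonferroni-type) bound over which sample is extreme.**
  It is conservative for moderate $G$ (at $N = 33$, $G = 2.5$ it returns
  $\approx 0.29$ where the true null exceedance is $\approx 0.27$) and
  tight in the small-p regime where genome-wide calling happens
  (corrected cut-off 0.1 over $\sim 4.5\times10^5$ probes means raw
  $p \sim 10^{-7}$). The test suite checks both conservativeness and
  small-p tightness against a $10^6$-draw Monte-Carlo null rather than
  asserting exact agreement, which the bound cannot deliver at large p.
* **$G$ is algebraically capped at $(N-1)/\sqrt N$.** The implementation
  treats numerical overshoot as the cap (p $\to$ 0) rather than
  producing NaN.
* **One call per probe.** The single-outlier test is not iterated after
  removing the outlier; calls are therefore individual-specific by
  construction, and ties in $|x_i - \bar x|$ resolve deterministically to
  the lowest sample index.

The Bonferroni denominator defaults to the number of probes actually
tested (not probes × samples): the correction is applied across the
per-probe tests, and each probe's single test is then attributed to its
most deviant sample. The cut-off (corrected $p < 0.1$, strict) and the
denominator are both exposed in `scan_params()`. $\Delta\beta$ is the
outlier's $\beta$ minus the mean $\beta$ of the other $N-1$ samples; its
sign classifies calls as hyper- or hypomethylated after the two-sided
test.

A probe is skipped (and counted in the scan provenance) when it has a
missing value, fewer than 3 samples, or SD at or below `min_sd`
($10^{-8}$): a zero-variance probe carries no outlier information and
would divide by zero.

## Pipeline around the core

**β values and filters.** $\beta = M/(U+M+100)$; the +100 offset
regularises low-intensity probes, so $\beta < 1$ always. Probe QC removes,
in order: sex-chromosome probes (X-inactivation and sex composition make
cohort-level outlier tests meaningless there), rs-prefixed SNP genotyping
controls, probes with detection $p > 0.01$ in one or more samples, and
probes with any missing β. The order only affects the attribution in the
filter report, not the retained set; the report reconciles exactly with
the input probe count. Whether a detection failure should also be treated
as a missing value is left to the caller (pass the detection table or
not); by default the two rules are separate, as listed.

**Batch correction.** The empirical-Bayes location/scale model
(ComBat-class): probes standardised by grand mean and pooled variance;
per-(batch, probe) locations shrunk towards a normal prior and scales
towards an inverse-gamma prior, hyperparameters by method of moments
across probes, solved by the standard conditional-posterior fixed-point
iteration (relative tolerance $10^{-4}$, the reference implementation's
conventional value; up to 500 iterations). No covariates are protected
during correction. Correction acts directly on β, clipping to [0, 1]
afterwards and counting clipped cells. Degenerate probes are handled
explicitly: overall-constant probes pass through unchanged; probes whose
variance is *purely* between-batch (zero within-batch residual) collapse
to their grand mean — the batch effect is their entire signal. The test
suite cross-checks the implementation against the reference
implementation in `sva` on random data, and verifies exact removal of a
planted shift and exact identity for a single batch.

Note a side effect relevant to effect sizes: because an outlier inflates
its probe's variance estimate, the EB scale shrinkage slightly compresses
outlier deviations. Recovered $|\Delta\beta|$ are therefore a little
smaller than injected ones. The published analysis ran the same
correction before scanning, so this compression is part of the procedure
being reproduced, not an artifact to remove.

**Group tests.** `wilcox.test` with the exact distribution when the
smaller group has ≤ 10 samples and no ties — cohort categories here have
4–19 samples, where the normal approximation alone is unreliable — and
the tie-corrected normal approximation otherwise; BH adjustment via
`p.adjust`; threshold 0.05. `group_presets()` names the standard eight
comparisons for the FGR-by-weight-gain design (overall phenotype
contrast, phenotype within each weight-gain stratum, and
insufficient/excessive vs adequate within each phenotype).

**Annotation.** When a probe maps to several genes or feature groups
(semicolon-joined manifest fields), only the lead-off entry is used.
pTSS (promoter-proximal) means lead feature in TSS1500, TSS200, 5'UTR or
1stExon. Shores and shelves collapse to "Shore"/"Shelf" groups for
reporting while the raw category is retained. Two calls are *adjacent*
when their probes occupy consecutive rows of the retained-probe manifest
on the same chromosome; connected runs form clusters, and members of
clusters of ≥ 2 are "clustered". This definition is deterministic and
filter-aware; no base-pair cap is applied by default because island
probes are dense, but `max_gap` provides one. Clusters are
direction-homogeneous and, by default, single-sample — burden reporting
is per subject, and cross-sample clusters would conflate individuals
(`same_sample = FALSE` is available). Gene subgroups use strict
$\Delta\beta > 0.2$. Enrichment is a one-sided hypergeometric upper tail
against user-supplied GMT gene sets, with the universe defaulting to the
genes assayable after filtering (array-composition control), BH across
terms.

**Reporting.** Burden tables order samples by category and gestational
weight gain, so inadequate gain at either end of the axis appears as a
U-shaped profile. Tukey HSD on the one-way category layout treats counts
as approximately normal (as the original analysis did); a Kruskal-Wallis
p-value rides along as a distribution-free cross-check, and the
degenerate all-identical case returns p = 1 rather than NaN. Coordinates
are 1-based points in the manifest; BED export converts to 0-based
half-open intervals and ignores strand (CpG methylation is
strand-symmetric on this array).

## The synthetic cohort generator

The generator exists so that every stage above is testable against known
truth. Its defaults emulate the study conditions end to end:

* 33 samples in six categories (FGR/normal × insufficient/adequate/
  excessive weight gain; 5/5/4/9/5/5), with category-typical weight-gain
  draws truncated to the guideline bands (< 7 kg, 7–12 kg, > 12 kg);
* a 485,577-probe manifest (473,864 autosomal cg probes in island/shore/
  shelf/open-sea blocks, 11,648 sex-chromosome probes, 65 rs controls),
  with 89,678/485,577 of probes SNP-flagged;
* bimodal baselines keyed on probe class — promoter-island probes from a
  low-methylation Beta distribution, open sea high — with per-probe noise
  applied on the **logit** scale (SD uniform on 0.05–0.3) so β stays in
  (0, 1) without clipping dominating and variance shrinks near the
  boundaries, as on real arrays;
* two batches with symmetric location shifts (±0.2 logits) and a 15%
  scale difference — the ComBat model class;
* trimodal (genotype-like) values at rs controls, and allele-specific
  methylation artifacts at 2% of SNP-flagged probes (one sample pulled
  halfway to 0.5), which seed exactly the spurious hypomethylated calls
  the SNP filter exists to remove;
* per-subject injected burdens drawn uniformly from 46–74
  (normal_adequate) or 44–421 (other categories) — the ranges are all the
  published record states, so uniform is the least-informative choice and
  both are configurable;
* hypermethylation shifts $N(0.18, 0.11)$ truncated positive, targeting
  promoter-island probes with baseline mean < 0.15, with 56% of each
  subject's hyper burden laid down as runs of ≥ 2 adjacent probes
  (geometric length tail); hypomethylation shifts $N(-0.27, 0.12)$
  truncated negative at isolated non-island probes with baseline mean in
  (0.70, 0.86). The baseline windows are calibrated so the *detected*
  outlier β means land near their observed values (≈ 0.24 hyper, ≈ 0.56
  hypo); at most one injection per (probe, sample), recorded in a truth
  table for recovery scoring.

What the generator does **not** model: mosaic cell mixtures (intermediate
$\Delta\beta$ magnitudes stand in for them — the array only sees the
aggregate), probe cross-hybridisation, spatial correlation of noise along
the array, chip-position effects beyond the two-batch model, and any
genotype structure beyond the single-probe artifacts. Passing recovery
tests therefore demonstrates that the pipeline's statistics behave as
specified under the assumed noise model, not that real placental data
meet those assumptions. Two visible consequences: recovered
$|\Delta\beta|$ SDs are narrower than the published ones (real biological
heterogeneity exceeds the truncated-normal injection model after EB
compression), and the *detected* clustered fraction of hyper calls
(~40%) is below the injected 56%, because per-probe detection attrition
and SNP filtering break clusters apart; the published 56% is itself a
detected fraction from data whose underlying injected fraction is
unknowable, and we chose not to tune the injected fraction against the
realised detection rate.

## Problem sizes and numerical choices

The test suite runs the generator at reduced scale (2,000–12,000 probes)
for speed, plus one full default-scale cohort (485,577 probes × 33
samples, ~1 minute) in the end-to-end recovery test; the acceptance
script repeats the full-scale run. The Monte-Carlo null for the Grubbs
p-value uses $10^6$ draws in 20,000-row chunks; the family-wise error
check uses 500 null scans of 10,000 probes. Random seeds are fixed in
every stochastic test; stochastic assertions use bands set in advance
from binomial standard errors (e.g. FWER ≤ 0.10 + 2·SE over the
replicates).

Numerical edge cases and their resolutions: Grubbs at $N = 3$ caps at
p = 1; statistics above the algebraic maximum are treated as the maximum;
zero-variance probes are skipped (scan) or passed through (batch
correction); pure-batch probes collapse to the grand mean; the
truncated-normal injection sampler collapses to its mean when the SD is
0; BED export caps scores at 1000; Tukey on identical counts returns
p = 1; β = 1 cells make the intensity decomposition put all signal on the
methylated channel.

## Known limitations

* The published genome-wide counts derive from scanner-normalised
  intensity data (GenomeStudio background subtraction and control
  normalisation); those upstream steps are out of scope here, so exact
  call-count reproduction on the deposited data is not expected —
  composition-level quantities (retention and genic fractions, effect
  sizes, burden structure) are the reproducible targets.
* Only the parametric EB batch model is provided (no nonparametric mode,
  reference batch, or surrogate variables), and no covariate protection —
  matching the original analysis.
* The scan is strictly single-outlier: two genuine epimutations at the
  same probe in different samples mask each other. At the observed burden
  rates this is rare, but it is a structural blind spot.
* Enrichment is generic: users supply gene sets (GMT); no ontology
  database ships with the package, and curated-term results are not
  reproduced.
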