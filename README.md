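# episcan

Individual-specific DNA methylation outlier (epimutation) screening for
Illumina HumanMethylation450 cohort data.

## The problem

In small human cohorts, adverse exposures often do not shift DNA
methylation at the *same* CpG sites in every affected individual: group
tests (e.g. Wilcoxon rank-sum per probe with Benjamini-Hochberg control)
find nothing, even when each individual's methylome carries real
alterations at *different* loci. `episcan` implements the complementary
analysis: a per-probe **Smirnov-Grubbs single-outlier test** that asks, at
every CpG probe, whether exactly one sample deviates significantly from
the rest of the cohort. Counting such outlier calls per subject turns
scattered, individual-specific epimutations into a per-subject **burden**
that can be compared across phenotype or exposure categories.

At each probe with cohort values x₁…x_N the test statistic is

    G = max_i |x_i − x̄| / s

with sample mean x̄ and SD s. Its two-sided p-value follows the standard
t-inversion

    t = √( N(N−2)G² / ((N−1)² − N G²) ),   p = min(1, 2N · P(T_{N−2} ≥ t))

and is Bonferroni-corrected across all tested probes (cut-off: corrected
p < 0.1). Each call records Δβ = (outlier's β) − (mean β of the other
samples); the sign classifies the call as hyper- or hypomethylated. Calls
at probes annotated to contain SNPs (`Probe_SNPs` / `Probe_SNPs_10`) are
filtered, since sequence-dependent allele-specific methylation mimics
epimutations.

Around this core the package provides the full pipeline: β computation
from signal intensities (β = M/(U+M+100)), probe QC filters (sex
chromosomes, rs control probes, detection p, missing values), an
empirical-Bayes location/scale batch correction (ComBat model), per-probe
group testing, CpG-island / gene-feature / promoter-proximal (pTSS)
annotation with clustered-vs-isolated classification, gene subgroup
selection, generic hypergeometric gene-set enrichment, per-subject burden
tables with Tukey HSD category comparisons — and a **synthetic 450K cohort
generator** that injects ground-truth epimutations so every stage is
verifiable end to end without external data.

## Worked example

```r
library(episcan)

cfg <- sim_config(n_probes = 20000, n_sex_chrom_probes = 400, seed = 5,
                  burden_range = list(normal_adequate = c(10, 20),
                                      default = c(20, 60)),
                  hypo_per_subject = c(5, 15))
man    <- generate_manifest(cfg)
cohort <- generate_cohort(cfg, man)

filt      <- filter_probes(cohort$beta, man, detection = cohort$detection)
corrected <- correct_batch(filt$beta, cohort$sheet)
scan      <- scan_outliers(corrected)
scan
#> <epi_scan> 854 outlier calls ( 671 hyper, 183 hypo ) from 19581 tested
#>   probes x 33 samples
#>   Bonferroni n_tests = 19581 ; corrected p < 0.1

kept <- snp_filter(scan, man)$kept
summarize_deltas(kept)
#> # A tibble: 2 x 6
#>   direction     n beta_mean beta_sd delta_mean delta_sd
#> 1 hyper       528     0.220  0.0750      0.170   0.0674
#> 2 hypo        132     0.544  0.0901     -0.270   0.0797

score_recovery(scan, cohort$truth)
#> <epi_recovery> 818 / 1081 injections recovered (sensitivity 0.757 );
#>   36 false calls; attribution 1.000
```

The filter report (`filt$report`) accounts for every removed probe; the
hyper calls sit at low-baseline CpG-island promoters (mean outlier β near
0.22, Δβ near +0.17) and the hypo calls at high-baseline open-sea probes
(β near 0.54, Δβ near −0.27); most injected shifts of that size are
recovered and every strong call names the correct sample. Downstream:

```r
ann    <- annotate_calls(kept, man[man$IlmnID %in% filt$beta$probe_id, ])
cl     <- cluster_calls(ann, man[man$IlmnID %in% filt$beta$probe_id, ])
burden <- burden_by_subject(kept, cohort$sheet)
tukey_hsd(burden)          # all-pairs category comparison
plot_burden(burden)        # per-subject stacked bar chart
```

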