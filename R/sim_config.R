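#' Simulation configuration for a synthetic 450K cohort
#'
#' Defines the study conditions emulated by the generator: a 33-placenta
#' cohort in six phenotype-by-weight-gain categories (FGR / normal crossed
#' with insufficient / adequate / excessive gestational weight gain), a
#' 450K-scale probe manifest, bimodal baseline methylation, array-batch
#' effects, SNP-driven allele-specific-methylation artifacts, and injected
#' individual-specific epimutations with known effect sizes.
#'
#' Defaults reproduce the published study conditions: category sizes
#' 5/5/4/9/5/5; per-subject injected burden drawn uniformly from 46-74 in
#' the normal_adequate category and 44-421 elsewhere; hypermethylation
#' shifts N(0.18, 0.11) targeting low-baseline CpG-island promoter probes
#' (56% of them in runs of two or more adjacent probes); hypomethylation
#' shifts N(-0.27, 0.12) targeting isolated high-baseline open-sea probes;
#' 89,678/485,577 of probes carry SNP annotation flags.
#'
#' @param n_probes Number of autosomal cg probes in the manifest.
#' @param n_sex_chrom_probes Number of chrX/chrY probes (removed by QC).
#' @param n_rs_control_probes Number of rs-prefixed SNP genotyping control
#'   probes (65 on the real array).
#' @param fraction_cgi_promoter Fraction of simulated CpG islands that are
#'   promoter islands (probes annotated TSS1500/TSS200/5'UTR/1stExon).
#' @param fraction_snp_flagged Fraction of cg probes flagged in the
#'   `Probe_SNPs` / `Probe_SNPs_10` manifest columns.
#' @param category_sizes Named integer vector of samples per category; names
#'   are the six category labels.
#' @param burden_range Named list of `c(min, max)` injected-outlier counts
#'   per subject; must contain an entry per category or a `default`.
#' @param hypo_per_subject `c(min, max)` of the hypomethylated share of each
#'   subject's burden (the remainder is hypermethylated).
#' @param hyper_delta `c(mean, sd)` of injected hypermethylation beta shifts
#'   (truncated to be > `delta_floor`).
#' @param hypo_delta `c(mean, sd)` of injected hypomethylation shifts
#'   (negative; truncated to be < `-delta_floor`).
#' @param delta_floor Minimum absolute injected shift.
#' @param hyper_baseline_max Hypermethylation injections target
#'   promoter-island probes with baseline mean below this value, so the
#'   hyper outlier beta mean lands near its observed ~0.24.
#' @param hypo_baseline_range Hypomethylation injections target non-island
#'   probes with baseline mean in this band; the band is placed so the
#'   hypo outlier beta mean lands near its observed ~0.56.
#' @param hyper_clustered_frac Fraction of each subject's hypermethylation
#'   burden placed as runs of >= 2 adjacent promoter-island probes.
#' @param cluster_geom_p Success probability of the geometric tail of
#'   cluster lengths (length = 2 + rgeom).
#' @param noise_sd_logit `c(min, max)` of the per-probe noise SD on the
#'   logit scale (biological + measurement variation).
#' @param batch_shift_logit Additive per-batch location shift (logit scale);
#'   length = number of batches.
#' @param batch_scale Multiplicative per-batch noise scale; same length.
#' @param asm_fraction Fraction of SNP-flagged probes given an
#'   allele-specific-methylation artifact (one sample pulled toward 0.5).
#' @param detection_fail_rate Per-cell probability of a failed detection
#'   p-value (> 0.01).
#' @param missing_rate Per-cell probability of a missing beta value.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A `sim_config` list, validated.
#' @examples
#' cfg <- sim_config(n_probes = 5000, seed = 7)
#' cfg$category_sizes
#' @export
sim_config <- function(n_probes = 473864,
                       n_sex_chrom_probes = 11648,
                       n_rs_control_probes = 65,
                       fraction_cgi_promoter = 0.55,
                       fraction_snp_flagged = 89678 / 485577,
                       category_sizes = c(FGR_adequate = 5L,
                                          FGR_insufficient = 5L,
                                          FGR_excessive = 4L,
                                          normal_adequate = 9L,
                                          normal_insufficient = 5L,
                                          normal_excessive = 5L),
                       burden_range = list(normal_adequate = c(46, 74),
                                           default = c(44, 421)),
                       hypo_per_subject = c(25, 55),
                       hyper_delta = c(mean = 0.18, sd = 0.11),
                       hypo_delta = c(mean = -0.27, sd = 0.12),
                       delta_floor = 0.02,
                       hyper_baseline_max = 0.15,
                       hypo_baseline_range = c(0.70, 0.86),
                       hyper_clustered_frac = 0.56,
                       cluster_geom_p = 0.55,
                       noise_sd_logit = c(0.05, 0.3),
                       batch_shift_logit = c(-0.2, 0.2),
                       batch_scale = c(1, 1.15),
                       asm_fraction = 0.02,
                       detection_fail_rate = 5e-4,
                       missing_rate = 1e-4,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_sex_chrom_probes = as.integer(n_sex_chrom_probes),
              n_rs_control_probes = as.integer(n_rs_control_probes),
              fraction_cgi_promoter = fraction_cgi_promoter,
              fraction_snp_flagged = fraction_snp_flagged,
              category_sizes = category_sizes,
              burden_range = burden_range,
              hypo_per_subject = hypo_per_subject,
              hyper_delta = hyper_delta,
              hypo_delta = hypo_delta,
              delta_floor = delta_floor,
              hyper_baseline_max = hyper_baseline_max,
              hypo_baseline_range = hypo_baseline_range,
              hyper_clustered_frac = hyper_clustered_frac,
              cluster_geom_p = cluster_geom_p,
              noise_sd_logit = noise_sd_logit,
              batch_shift_logit = batch_shift_logit,
              batch_scale = batch_scale,
              asm_fraction = asm_fraction,
              detection_fail_rate = detection_fail_rate,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$fraction_cgi_promoter, cfg$fraction_snp_flagged,
             cfg$hyper_clustered_frac, cfg$asm_fraction,
             cfg$detection_fail_rate, cfg$missing_rate)
  if (any(props < 0 | props > 1)) abort("all proportions must lie in [0, 1]")
  counts <- c(cfg$n_probes, cfg$n_sex_chrom_probes, cfg$n_rs_control_probes)
  if (any(counts < 0)) abort("all probe counts must be >= 0")
  if (cfg$n_probes == 0) abort("n_probes must be positive: a zero-probe manifest is not allowed")
  if (any(cfg$category_sizes < 0) || is.null(names(cfg$category_sizes))) {
    abort("category_sizes must be a named vector of non-negative counts")
  }
  if (length(cfg$batch_shift_logit) != length(cfg$batch_scale)) {
    abort("batch_shift_logit and batch_scale must have one entry per batch")
  }
  bad <- vapply(cfg$burden_range, function(r) length(r) != 2 || r[1] > r[2] || any(r < 0),
                logical(1))
  if (any(bad)) abort("burden_range entries must be c(min, max) with 0 <= min <= max")
  miss <- setdiff(names(cfg$category_sizes), names(cfg$burden_range))
  if (length(miss) > 0 && !"default" %in% names(cfg$burden_range)) {
    abort(paste0("burden_range missing for categories (and no default): ",
                 paste(miss, collapse = ", ")))
  }
  if (cfg$hyper_delta[["sd"]] < 0 || cfg$hypo_delta[["sd"]] < 0) {
    abort("delta SDs must be >= 0")
  }
  invisible(cfg)
}

burden_range_for <- function(cfg, category) {
  cfg$burden_range[[category]] %||% cfg$burden_range[["default"]]
}
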