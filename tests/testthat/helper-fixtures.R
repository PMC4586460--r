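# Small simulation configuration for fast tests: array structure preserved,
# probe count and burdens scaled down.
tiny_config <- function(seed = 42, n_probes = 6000,
                        n_sex_chrom_probes = 150,
                        burden_range = list(normal_adequate = c(4, 8),
                                            default = c(6, 14)),
                        hypo_per_subject = c(2, 5), ...) {
  sim_config(n_probes = n_probes,
             n_sex_chrom_probes = n_sex_chrom_probes,
             burden_range = burden_range,
             hypo_per_subject = hypo_per_subject,
             seed = seed, ...)
}

# Deterministic, effect-free configuration: no noise, no batch effects, no
# artifacts; injections (if any) are the only signal.
clean_config <- function(seed = 1, n_probes = 3000, ...) {
  sim_config(n_probes = n_probes, n_sex_chrom_probes = 0,
             noise_sd_logit = c(0, 0),
             batch_shift_logit = c(0, 0), batch_scale = c(1, 1),
             asm_fraction = 0, detection_fail_rate = 0, missing_rate = 0,
             seed = seed, ...)
}

# Beta tibble from a bare matrix, probes cg01, cg02, ... and samples s1...
toy_beta <- function(m, probes = sprintf("cg%02d", seq_len(nrow(m))),
                     samples = paste0("s", seq_len(ncol(m)))) {
  rownames(m) <- probes
  colnames(m) <- samples
  beta_tibble(m)
}

# Hand-written manifest; defaults give autosomal unflagged probes.
toy_manifest <- function(probe_id, chr = "1",
                         pos = seq_along(probe_id) * 1000L,
                         gene = "", feature = "", relation = "",
                         snps = "", snps10 = "") {
  n <- length(probe_id)
  tibble::tibble(
    IlmnID = probe_id,
    CHR = rep_len(chr, n),
    MAPINFO = as.integer(rep_len(pos, n)),
    UCSC_RefGene_Name = rep_len(gene, n),
    UCSC_RefGene_Group = rep_len(feature, n),
    Relation_to_UCSC_CpG_Island = rep_len(relation, n),
    Probe_SNPs = rep_len(snps, n),
    Probe_SNPs_10 = rep_len(snps10, n)
  )
}

# Minimal epi_scan wrapper around a hand-built calls tibble.
as_scan_result <- function(calls, n_samples = 33) {
  structure(list(calls = calls,
                 provenance = list(n_probes = NA_integer_,
                                   n_tested = NA_integer_,
                                   n_samples = n_samples,
                                   n_tests = NA_integer_,
                                   alpha_corrected = 0.1)),
            class = "epi_scan")
}

# Calls tibble skeleton with sensible defaults for annotation tests.
make_calls <- function(probe_id, sample_id = "s1", delta_beta = 0.3,
                       direction = ifelse(delta_beta > 0, "hyper", "hypo"),
                       beta = 0.4) {
  n <- length(probe_id)
  tibble::tibble(
    probe_id = probe_id,
    sample_id = rep_len(sample_id, n),
    beta = rep_len(beta, n),
    delta_beta = rep_len(delta_beta, n),
    direction = rep_len(direction, n),
    statistic = 5, p_value = 1e-9, p_bonferroni = 1e-4,
    snp_flagged = NA
  )
}
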