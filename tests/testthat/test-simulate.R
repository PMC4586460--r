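test_that("generator is deterministic given config and seed", {
  cfg <- tiny_config(seed = 7)
  m1 <- generate_manifest(cfg)
  m2 <- generate_manifest(cfg)
  expect_identical(m1, m2)
  c1 <- generate_cohort(cfg, m1)
  c2 <- generate_cohort(cfg, m2)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$sheet, c2$sheet)
  expect_identical(c1$truth, c2$truth)
})

test_that("manifest schema, sorting and SNP-flag sampling behave", {
  cfg <- tiny_config(seed = 3, n_probes = 100000,
                     n_sex_chrom_probes = 0, fraction_snp_flagged = 0.185)
  man <- generate_manifest(cfg)
  expect_true(manifest_is_sorted(man))
  expect_setequal(setdiff(unique(man$Relation_to_UCSC_CpG_Island), ""),
                  c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf"))
  expect_equal(sum(startsWith(man$IlmnID, "rs")), 65)
  expect_false(anyDuplicated(man$IlmnID) > 0)

  # flagged count within the binomial 99% interval around n * p
  n_cg <- sum(startsWith(man$IlmnID, "cg"))
  flagged <- sum(man$Probe_SNPs != "" | man$Probe_SNPs_10 != "")
  ci <- qbinom(c(0.005, 0.995), n_cg, 0.185)
  expect_gte(flagged, ci[1])
  expect_lte(flagged, ci[2])

  # degenerate fraction: no probe flagged
  man0 <- generate_manifest(tiny_config(seed = 3, n_probes = 2000,
                                        fraction_snp_flagged = 0))
  expect_true(all(man0$Probe_SNPs == "" & man0$Probe_SNPs_10 == ""))

  expect_error(sim_config(n_probes = 0), "zero-probe")
})

test_that("baseline marginal beta distribution is bimodal by probe class", {
  cfg <- tiny_config(seed = 9, n_probes = 12000,
                     burden_range = list(default = c(0, 0)),
                     hypo_per_subject = c(0, 0))
  man <- generate_manifest(cfg)
  cohort <- generate_cohort(cfg, man)
  X <- beta_matrix(cohort$beta)
  mu <- rowMeans(X, na.rm = TRUE)
  lead_feat <- lead_off(man$UCSC_RefGene_Group)
  promoter <- man$Relation_to_UCSC_CpG_Island == "Island" &
    lead_feat %in% c("TSS1500", "TSS200", "5'UTR", "1stExon")
  open_sea <- man$Relation_to_UCSC_CpG_Island == "" &
    startsWith(man$IlmnID, "cg") & !man$CHR %in% c("X", "Y")
  expect_gte(mean(mu[promoter] < 0.10), 0.9)
  expect_gte(mean(mu[open_sea] > 0.85), 0.9)
})

test_that("truth table is consistent with its labels and the manifest", {
  cfg <- tiny_config(seed = 5)
  man <- generate_manifest(cfg)
  cohort <- generate_cohort(cfg, man)
  tr <- cohort$truth
  expect_true(all(tr$delta[tr$direction == "hyper"] > 0))
  expect_true(all(tr$delta[tr$direction == "hypo"] < 0))
  expect_true(all(tr$probe_id %in% man$IlmnID))
  expect_false(anyDuplicated(paste(tr$probe_id, tr$sample_id)) > 0)
  # hyper clusters span >= 2 probes; hypo injections are isolated
  clu <- dplyr::count(tr[!is.na(tr$cluster_id), ], cluster_id)
  expect_true(all(clu$n >= 2))
  expect_true(all(is.na(tr$cluster_id[tr$direction == "hypo"])))
})

test_that("per-subject injected burdens respect the configured ranges", {
  cfg <- tiny_config(seed = 13)
  man <- generate_manifest(cfg)
  cohort <- generate_cohort(cfg, man)
  per <- dplyr::count(cohort$truth, sample_id)
  per <- dplyr::left_join(per, cohort$sheet, by = "sample_id")
  lims <- t(vapply(per$category,
                   function(ct) episcan:::burden_range_for(cfg, ct),
                   numeric(2)))
  expect_true(all(per$n >= lims[, 1] & per$n <= lims[, 2]))
  # every sample got its draw recorded
  expect_setequal(per$sample_id, cohort$sheet$sample_id)
})

test_that("zero burden produces an empty truth table", {
  cfg <- tiny_config(seed = 2, n_probes = 2000,
                     burden_range = list(default = c(0, 0)),
                     hypo_per_subject = c(0, 0))
  man <- generate_manifest(cfg)
  cohort <- generate_cohort(cfg, man)
  expect_equal(nrow(cohort$truth), 0)
})

test_that("zero-noise, fixed-delta injections shift beta by exactly delta", {
  cfg <- clean_config(seed = 4, n_probes = 4000,
                      burden_range = list(default = c(4, 8)),
                      hypo_per_subject = c(1, 3),
                      hyper_delta = c(mean = 0.3, sd = 0),
                      hypo_delta = c(mean = -0.3, sd = 0))
  man <- generate_manifest(cfg)
  cohort <- generate_cohort(cfg, man)
  X <- beta_matrix(cohort$beta)
  sheet <- cohort$sheet
  for (i in seq_len(nrow(cohort$truth))) {
    tr <- cohort$truth[i, ]
    row <- match(tr$probe_id, rownames(X))
    col <- match(tr$sample_id, colnames(X))
    others <- mean(X[row, -col])
    expect_equal(X[row, col] - others, tr$delta, tolerance = 1e-10)
  }
})

test_that("burden exceeding the eligible probe pool errors with the category", {
  cfg <- tiny_config(seed = 6, n_probes = 400,
                     burden_range = list(default = c(5000, 5000)))
  man <- generate_manifest(cfg)
  expect_error(generate_cohort(cfg, man), "category")
})

test_that("intensity tables round-trip through the beta formula", {
  cfg <- clean_config(seed = 8, n_probes = 500,
                      burden_range = list(default = c(0, 0)),
                      hypo_per_subject = c(0, 0))
  man <- generate_manifest(cfg)
  cohort <- generate_cohort(cfg, man)
  ints <- sim_intensities(cohort$beta, seed = 8)
  back <- beta_from_intensities(ints)
  back <- back[match(cohort$beta$probe_id, back$probe_id),
               names(cohort$beta)]
  expect_equal(as.data.frame(back), as.data.frame(cohort$beta),
               tolerance = 1e-12)
})
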