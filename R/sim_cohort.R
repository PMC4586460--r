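#' Generate a synthetic methylation cohort with injected epimutations
#'
#' Draws a bimodal baseline methylation profile keyed on probe class
#' (promoter CpG islands low, open sea high), adds per-probe noise on the
#' logit scale (so beta stays inside (0,1) without hard clipping dominating),
#' applies per-batch location/scale effects on the logit scale, simulates
#' trimodal genotype patterns at rs control probes and allele-specific
#' methylation artifacts at a fraction of SNP-flagged probes, and finally
#' injects individual-specific epimutations: hypermethylation as runs of
#' adjacent low-baseline promoter-island probes (plus isolated probes) and
#' hypomethylation as isolated high-baseline open-sea probes. Every
#' injection is recorded in a ground-truth table for recovery scoring.
#'
#' @param config A [sim_config()].
#' @param manifest Manifest from [generate_manifest()] (or the same schema).
#' @return A list with elements
#'   \describe{
#'     \item{beta}{beta tibble (`probe_id` + one column per sample)}
#'     \item{sheet}{sample sheet tibble (`sample_id`, `phenotype`,
#'       `gwg_category`, `category`, `gwg_kg`, `batch`)}
#'     \item{truth}{injection ground truth (`sample_id`, `probe_id`,
#'       `delta`, `direction`, `cluster_id`; `NA` cluster = isolated)}
#'     \item{detection}{sparse long tibble of failed detection p-values}
#'     \item{probe_params}{per-probe baseline mean and noise SDs}
#'   }
#' @examples
#' cfg <- sim_config(n_probes = 4000, n_sex_chrom_probes = 100,
#'                   burden_range = list(default = c(5, 10)), seed = 3)
#' man <- generate_manifest(cfg)
#' cohort <- generate_cohort(cfg, man)
#' dplyr::count(cohort$truth, direction)
#' @export
generate_cohort <- function(config, manifest) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  cls <- manifest_classes(manifest)
  p <- nrow(manifest)
  sheet <- make_sample_sheet(config)
  n <- nrow(sheet)

  # ---- baseline means by probe class (bimodal marginal distribution)
  m <- numeric(p)
  rel <- cls$rel
  pi_ <- cls$promoter_island
  isl_np <- rel == "Island" & !pi_
  m[pi_] <- rbeta(sum(pi_), 5, 95)
  lowish <- runif(sum(isl_np)) < 0.8
  m[isl_np] <- ifelse(lowish, rbeta(sum(isl_np), 2, 18), rbeta(sum(isl_np), 10, 4))
  m[cls$shore] <- rbeta(sum(cls$shore), 3, 7)
  m[cls$shelf] <- rbeta(sum(cls$shelf), 7, 3)
  sea <- rel == "" & cls$is_cg
  m[sea] <- rbeta(sum(sea), 90, 10)
  m[!cls$is_cg] <- 0.5 # rs controls, overwritten below

  sd_logit <- runif(p, config$noise_sd_logit[1], config$noise_sd_logit[2])
  mu_logit <- qlogis(pmin(pmax(m, 1e-4), 1 - 1e-4))

  beta <- matrix(rnorm(p * n), p, n)
  shift <- config$batch_shift_logit[sheet$batch]
  scale <- config$batch_scale[sheet$batch]
  for (j in seq_len(n)) {
    beta[, j] <- plogis(mu_logit + scale[j] * sd_logit * beta[, j] + shift[j])
  }

  # ---- rs genotyping controls: trimodal across samples
  rs_rows <- which(!cls$is_cg)
  if (length(rs_rows) > 0) {
    maf <- runif(length(rs_rows), 0.2, 0.5)
    geno <- matrix(rbinom(length(rs_rows) * n, 2, rep(maf, n)),
                   length(rs_rows), n)
    noise <- matrix(rnorm(length(rs_rows) * n, 0, 0.02), length(rs_rows), n)
    beta[rs_rows, ] <- pmin(pmax(geno / 2 * 0.9 + 0.05 + noise, 0), 1)
  }

  # ---- allele-specific methylation artifacts at SNP-flagged probes:
  # one sample's beta pulled halfway toward 0.5 (heterozygous-like)
  asm_pool <- which(cls$snp_flagged & cls$autosomal & cls$is_cg)
  n_asm <- round(config$asm_fraction * length(asm_pool))
  if (n_asm > 0) {
    ai <- sample(asm_pool, n_asm)
    aj <- sample.int(n, n_asm, replace = TRUE)
    beta[cbind(ai, aj)] <- (beta[cbind(ai, aj)] + 0.5) / 2
  }

  # ---- epimutation injections
  inj <- inject_epimutations(config, cls, m, beta, sheet)
  beta <- inj$beta
  truth <- inj$truth

  # ---- missing cells and detection failures
  n_cells <- p * n
  k_miss <- rbinom(1, n_cells, config$missing_rate)
  if (k_miss > 0) beta[sample.int(n_cells, k_miss)] <- NA_real_
  k_fail <- rbinom(1, n_cells, config$detection_fail_rate)
  detection <- tibble::tibble(probe_id = character(), sample_id = character(),
                              detection_p = numeric())
  if (k_fail > 0) {
    cell <- sample.int(n_cells, k_fail)
    detection <- tibble::tibble(
      probe_id = manifest$IlmnID[(cell - 1L) %% p + 1L],
      sample_id = sheet$sample_id[(cell - 1L) %/% p + 1L],
      detection_p = runif(k_fail, 0.011, 0.2)
    )
  }

  rownames(beta) <- manifest$IlmnID
  colnames(beta) <- sheet$sample_id
  list(beta = beta_tibble(beta),
       sheet = sheet,
       truth = truth,
       detection = detection,
       probe_params = tibble::tibble(
         probe_id = manifest$IlmnID,
         base_mean = m,
         sd_logit = sd_logit,
         sd_beta = m * (1 - m) * sd_logit))
}

make_sample_sheet <- function(config) {
  sizes <- config$category_sizes
  category <- rep(names(sizes), sizes)
  idx <- sequence(unname(sizes))
  gwg_cat <- sub(".*_", "", category)
  # gestational weight gain draws: category-typical mean/SD, truncated to
  # the guideline bands (insufficient < 7 kg, adequate 7-12, excessive > 12)
  gwg_mean <- c(FGR_adequate = 8.2, FGR_insufficient = 4.5,
                FGR_excessive = 13.5, normal_adequate = 8.7,
                normal_insufficient = 6.3, normal_excessive = 14.7)
  gwg_sd <- c(FGR_adequate = 1.2, FGR_insufficient = 1.8,
              FGR_excessive = 0.9, normal_adequate = 1.1,
              normal_insufficient = 0.7, normal_excessive = 1.0)
  lo <- c(insufficient = 0.5, adequate = 7, excessive = 12.1)
  hi <- c(insufficient = 6.9, adequate = 12, excessive = 25)
  mu <- ifelse(category %in% names(gwg_mean), gwg_mean[category],
               (lo[gwg_cat] + hi[gwg_cat]) / 2)
  s <- ifelse(category %in% names(gwg_sd), gwg_sd[category], 1)
  gwg <- pmin(pmax(rnorm(length(category), mu, s), lo[gwg_cat]), hi[gwg_cat])
  n_batch <- length(config$batch_shift_logit)
  tibble::tibble(
    sample_id = paste0(category, "_", idx),
    phenotype = sub("_.*", "", category),
    gwg_category = gwg_cat,
    category = category,
    gwg_kg = round(gwg, 1),
    batch = sample(rep(seq_len(n_batch), length.out = length(category)))
  )
}

# Truncated-normal draws by rejection; sd = 0 collapses to the mean.
draw_trunc <- function(k, mean, sd, lower, upper) {
  if (k == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, k))
  out <- rnorm(k, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

inject_epimutations <- function(config, cls, m, beta, sheet) {
  p <- nrow(beta)
  hyper_ok <- cls$promoter_island & cls$autosomal & cls$is_cg &
    m < config$hyper_baseline_max
  hypo_ok <- (cls$open_sea | cls$shelf) & cls$autosomal & cls$is_cg &
    m > config$hypo_baseline_range[1] & m < config$hypo_baseline_range[2]

  # maximal runs of consecutive hyper-eligible manifest rows, never
  # spanning a chromosome boundary
  idx <- which(hyper_ok)
  if (length(idx) > 0) {
    brk <- c(TRUE, diff(idx) != 1L |
               cls$chr[idx[-1]] != cls$chr[idx[-length(idx)]])
    seg_id <- cumsum(brk)
    seg <- tibble::tibble(
      start = idx[match(unique(seg_id), seg_id)],
      len = as.integer(table(seg_id))
    )
  } else {
    seg <- tibble::tibble(start = integer(0), len = integer(0))
  }
  seg_avail <- rep(TRUE, nrow(seg))
  hypo_avail <- hypo_ok

  truth <- list()
  for (s in seq_len(nrow(sheet))) {
    cat_s <- sheet$category[s]
    rng <- burden_range_for(config, cat_s)
    total <- round(runif(1, rng[1], rng[2]))
    hypo_n <- min(round(runif(1, config$hypo_per_subject[1],
                              config$hypo_per_subject[2])), total)
    hyper_n <- total - hypo_n

    # cluster length plan: geometric tail, each run >= 2 probes
    target <- round(config$hyper_clustered_frac * hyper_n)
    lens <- integer(0)
    while (sum(lens) < target - 1) {
      lens <- c(lens, 2L + rgeom(1, config$cluster_geom_p))
    }
    if (length(lens) > 0 && sum(lens) > target) {
      lens[length(lens)] <- max(2L, lens[length(lens)] - (sum(lens) - target))
    }
    if (length(lens) > 0 && sum(lens) > hyper_n) lens <- lens[-length(lens)]
    iso_n <- hyper_n - sum(lens)

    rows_clu <- integer(0); clu_id <- character(0)
    for (k in seq_along(lens)) {
      cand <- which(seg_avail & seg$len >= lens[k])
      if (length(cand) == 0) {
        abort(paste0("injected burden exceeds eligible promoter-island runs ",
                     "for category '", cat_s, "'"))
      }
      pick <- cand[sample.int(length(cand), 1)]
      off <- sample.int(seg$len[pick] - lens[k] + 1L, 1) - 1L
      rows_clu <- c(rows_clu, seg$start[pick] + off + seq_len(lens[k]) - 1L)
      clu_id <- c(clu_id, rep(paste0(sheet$sample_id[s], "_c", k), lens[k]))
      seg_avail[pick] <- FALSE
    }
    cand_iso <- which(seg_avail)
    if (iso_n > length(cand_iso)) {
      abort(paste0("injected burden exceeds eligible promoter-island probes ",
                   "for category '", cat_s, "'"))
    }
    segs_iso <- if (iso_n > 0) sample(cand_iso, iso_n) else integer(0)
    rows_iso <- seg$start[segs_iso] +
      vapply(seg$len[segs_iso], function(l) sample.int(l, 1) - 1L, integer(1))
    seg_avail[segs_iso] <- FALSE

    # hypomethylation: isolated open-sea probes, kept non-adjacent
    rows_hypo <- integer(0)
    need <- hypo_n
    while (need > 0) {
      pool <- which(hypo_avail)
      if (length(pool) < need) {
        abort(paste0("injected burden exceeds eligible open-sea probes ",
                     "for category '", cat_s, "'"))
      }
      pick <- sort(sample(pool, need))
      pick <- pick[c(TRUE, diff(pick) > 1)] # drop same-draw adjacencies
      nb <- unique(c(pick - 1L, pick, pick + 1L))
      hypo_avail[nb[nb >= 1L & nb <= p]] <- FALSE
      rows_hypo <- c(rows_hypo, pick)
      need <- hypo_n - length(rows_hypo)
    }

    hyper_rows <- c(rows_clu, rows_iso)
    d_hyper <- draw_trunc(length(hyper_rows), config$hyper_delta[["mean"]],
                          config$hyper_delta[["sd"]], config$delta_floor, 1)
    d_hypo <- draw_trunc(length(rows_hypo), config$hypo_delta[["mean"]],
                         config$hypo_delta[["sd"]], -1, -config$delta_floor)
    rows_all <- c(hyper_rows, rows_hypo)
    d_all <- c(d_hyper, d_hypo)
    if (length(rows_all) > 0) {
      beta[cbind(rows_all, s)] <-
        pmin(pmax(beta[cbind(rows_all, s)] + d_all, 0), 1)
    }
    truth[[s]] <- tibble::tibble(
      sample_id = sheet$sample_id[s],
      row = rows_all,
      delta = d_all,
      direction = rep(c("hyper", "hypo"), c(length(hyper_rows), length(rows_hypo))),
      cluster_id = c(clu_id, rep(NA_character_, iso_n + length(rows_hypo)))
    )
  }
  truth <- dplyr::bind_rows(truth)
  truth <- tibble::tibble(sample_id = truth$sample_id,
                          probe_id = cls$probe_id[truth$row],
                          delta = truth$delta,
                          direction = truth$direction,
                          cluster_id = truth$cluster_id)
  list(beta = beta, truth = truth)
}

#' Derive a signal-intensity table from a beta table
#'
#' Produces a long intensity table (methylated signal `M`, unmethylated
#' signal `U`, `detection_p`) consistent with the beta-value definition
#' beta = M / (U + M + 100): per-cell total signal is drawn from a gamma
#' distribution and split so that recomputing beta recovers the input.
#' Cells listed in `detection` keep their failed detection p-values.
#'
#' @param beta Beta tibble (`probe_id` + sample columns).
#' @param detection Optional sparse tibble of failed cells
#'   (`probe_id`, `sample_id`, `detection_p`), as returned by
#'   [generate_cohort()].
#' @param mean_signal Mean total signal intensity per cell.
#' @param seed Integer seed.
#' @return Long tibble: `probe_id`, `sample_id`, `M`, `U`, `detection_p`.
#' @export
sim_intensities <- function(beta, detection = NULL, mean_signal = 5000,
                            seed = 1L) {
  set.seed(seed)
  long <- tidyr::pivot_longer(beta, -"probe_id", names_to = "sample_id",
                              values_to = "beta")
  total <- rgamma(nrow(long), shape = 20, scale = mean_signal / 20)
  b <- ifelse(is.na(long$beta), 0, long$beta)
  # total signal must reach 100*b/(1-b) for the +100 offset formula to be
  # exactly invertible; floor it there (beta = 1 maps to U = 0)
  floor_sig <- ifelse(b >= 1, total, 100 * b / (1 - b))
  total <- pmax(total, floor_sig)
  M <- pmin(b * (total + 100), total)
  out <- tibble::tibble(
    probe_id = long$probe_id,
    sample_id = long$sample_id,
    M = M,
    U = total - M,
    detection_p = runif(nrow(long), 0, 0.005)
  )
  if (!is.null(detection) && nrow(detection) > 0) {
    key <- paste(out$probe_id, out$sample_id)
    fkey <- paste(detection$probe_id, detection$sample_id)
    hit <- match(fkey, key)
    out$detection_p[hit[!is.na(hit)]] <- detection$detection_p[!is.na(hit)]
  }
  out
}
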