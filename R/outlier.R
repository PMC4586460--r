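#' Parameters for the epimutation outlier scan
#'
#' @param alpha_corrected Cutoff on the Bonferroni-corrected p-value
#'   (default 0.1; calls require corrected p strictly below this).
#' @param n_tests Bonferroni denominator; `NULL` (default) uses the number
#'   of probes actually tested in the scan.
#' @param min_sd Numerical floor for the per-probe SD; probes at or below
#'   it are skipped.
#' @return A `scan_params` list.
#' @export
scan_params <- function(alpha_corrected = 0.1, n_tests = NULL,
                        min_sd = 1e-8) {
  if (alpha_corrected <= 0 || alpha_corrected > 1) {
    abort("alpha_corrected must lie in (0, 1]")
  }
  if (!is.null(n_tests) && n_tests < 1) abort("n_tests must be >= 1")
  structure(list(alpha_corrected = alpha_corrected, n_tests = n_tests,
                 min_sd = min_sd), class = "scan_params")
}

#' Grubbs statistic for a single probe
#'
#' The maximum absolute standardised deviation of one observation from the
#' sample mean, G = max_i |x_i - mean(x)| / sd(x), together with the index
#' of the achieving sample (ties broken towards the lowest index).
#'
#' @param x Numeric vector of beta values across samples (length >= 3).
#' @param min_sd SD floor below which no test is performed.
#' @return List with `statistic` (G) and `index`, or `NULL` when the probe
#'   cannot be tested (n < 3 or SD at/below the floor).
#' @examples
#' grubbs_statistic(c(0, 0, 0, 0, 1))$statistic  # 4/sqrt(5)
#' @export
grubbs_statistic <- function(x, min_sd = 1e-8) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(NULL)
  s <- sd(x)
  if (!is.finite(s) || s <= min_sd) return(NULL)
  dev <- abs(x - mean(x))
  i <- which.max(dev) # ties resolve to the lowest index
  list(statistic = dev[i] / s, index = i)
}

#' Two-sided p-value of the single-outlier Grubbs test
#'
#' Standard t-inversion: t = sqrt(N (N-2) G^2 / ((N-1)^2 - N G^2)) and
#' p = min(1, 2 N P(T_{N-2} >= t)). Statistics at or above the algebraic
#' maximum (N-1)/sqrt(N) are treated as the maximum (p -> 0). The p-value
#' is monotone decreasing in G for fixed N.
#'
#' @param G Grubbs statistic (vectorised).
#' @param N Number of samples (>= 3).
#' @return Raw two-sided p-values in [0, 1].
#' @export
grubbs_pvalue <- function(G, N) {
  if (N < 3) abort("Grubbs test requires N >= 3")
  gmax <- (N - 1) / sqrt(N)
  G <- pmin(G, gmax)
  denom <- (N - 1)^2 - N * G^2
  t_stat <- ifelse(denom <= 0, Inf,
                   sqrt(pmax(N * (N - 2) * G^2, 0) / denom))
  pmin(1, 2 * N * pt(t_stat, df = N - 2, lower.tail = FALSE))
}

#' Genome-wide epimutation scan
#'
#' Applies the two-sided single-outlier Grubbs test at every probe of a
#' (filtered, batch-corrected) beta table, corrects the per-probe p-values
#' by Bonferroni across all tested probes, and emits one call per probe
#' whose corrected p falls strictly below the cutoff. Each call is
#' attributed to the single most-deviant sample; delta-beta is the
#' outlier's beta minus the mean beta of the other samples, and its sign
#' classifies the call as hyper- or hypomethylated.
#'
#' @param beta Beta tibble.
#' @param params A [scan_params()].
#' @return An `epi_scan`: list with `calls` (tibble: `probe_id`,
#'   `sample_id`, `beta`, `delta_beta`, `direction`, `statistic`,
#'   `p_value`, `p_bonferroni`, `snp_flagged`) and `provenance`.
#' @examples
#' b <- beta_tibble(matrix(c(rep(0.1, 9), 0.9), nrow = 1,
#'                  dimnames = list("cg1", paste0("s", 1:10))))
#' scan_outliers(b)$calls
#' @export
scan_outliers <- function(beta, params = scan_params()) {
  X <- beta_matrix(beta)
  N <- ncol(X)
  if (N < 3) abort("outlier scan requires a cohort of >= 3 samples")

  ok_na <- complete.cases(X)
  mu <- rowMeans(X)
  s <- row_sds(X)
  testable <- ok_na & is.finite(s) & s > params$min_sd

  dev <- abs(X - mu)
  dev[!testable, ] <- -Inf
  idx <- max.col(dev, ties.method = "first")
  pick <- cbind(seq_len(nrow(X)), idx)
  G <- ifelse(testable, dev[pick] / s, NA_real_)

  n_tests <- params$n_tests %||% sum(testable)
  p_raw <- rep(NA_real_, nrow(X))
  p_raw[testable] <- grubbs_pvalue(G[testable], N)
  p_bonf <- pmin(1, p_raw * n_tests)

  is_call <- testable & p_bonf < params$alpha_corrected
  b_out <- unname(X[pick][is_call])
  delta <- unname((X[pick][is_call] - mu[is_call]) * N / (N - 1))

  calls <- tibble::tibble(
    probe_id = rownames(X)[is_call],
    sample_id = colnames(X)[idx[is_call]],
    beta = b_out,
    delta_beta = delta,
    direction = ifelse(delta > 0, "hyper", "hypo"),
    statistic = unname(G[is_call]),
    p_value = unname(p_raw[is_call]),
    p_bonferroni = unname(p_bonf[is_call]),
    snp_flagged = NA
  )
  structure(list(
    calls = calls,
    provenance = list(n_probes = nrow(X),
                      n_tested = sum(testable),
                      n_skipped_na = sum(!ok_na),
                      n_skipped_low_sd = sum(ok_na & !testable),
                      n_samples = N,
                      n_tests = n_tests,
                      alpha_corrected = params$alpha_corrected)
  ), class = "epi_scan")
}

#' Split scan calls by SNP-probe annotation
#'
#' Calls on probes with a non-empty `Probe_SNPs` or `Probe_SNPs_10`
#' manifest entry - probes whose signal can reflect sequence-dependent
#' allele-specific methylation rather than an epimutation - are moved to
#' the removed set. Retention fractions are reported per direction.
#'
#' @param result An `epi_scan`.
#' @param manifest Manifest covering every called probe.
#' @return List with `kept` and `removed` (`epi_scan` objects) and
#'   `retention` (per-direction call counts and retained fractions).
#' @export
snp_filter <- function(result, manifest) {
  stopifnot(inherits(result, "epi_scan"))
  calls <- result$calls
  missing_probes <- setdiff(calls$probe_id, manifest$IlmnID)
  if (length(missing_probes) > 0) {
    abort(paste0("called probes absent from manifest: ",
                 paste(utils::head(missing_probes, 5), collapse = ", ")))
  }
  flagged_ids <- manifest$IlmnID[is_snp_flagged(manifest)]
  calls$snp_flagged <- calls$probe_id %in% flagged_ids
  keep <- calls[!calls$snp_flagged, , drop = FALSE]
  drop <- calls[calls$snp_flagged, , drop = FALSE]
  retention <- calls |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(n_calls = dplyr::n(),
                     n_flagged = sum(.data$snp_flagged),
                     n_kept = sum(!.data$snp_flagged),
                     retention = n_kept / n_calls,
                     flag_coincidence = n_flagged / n_calls,
                     .groups = "drop")
  as_scan <- function(cl) {
    structure(list(calls = cl, provenance = result$provenance),
              class = "epi_scan")
  }
  list(kept = as_scan(keep), removed = as_scan(drop), retention = retention)
}

#' Per-direction summary of outlier betas and delta-betas
#'
#' Mean and sample SD (n-1 denominator) of the outlier beta values and of
#' delta-beta, per direction. Directions with no calls are absent from the
#' output; a single call yields an `NA` SD.
#'
#' @param result An `epi_scan` (or its `calls` tibble).
#' @return Tibble: `direction`, `n`, `beta_mean`, `beta_sd`, `delta_mean`,
#'   `delta_sd`.
#' @export
summarize_deltas <- function(result) {
  calls <- if (inherits(result, "epi_scan")) result$calls else result
  calls |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(n = dplyr::n(),
                     beta_mean = mean(.data$beta),
                     beta_sd = sd(.data$beta),
                     delta_mean = mean(.data$delta_beta),
                     delta_sd = sd(.data$delta_beta),
                     .groups = "drop")
}

#' @export
print.epi_scan <- function(x, ...) {
  pv <- x$provenance
  nd <- table(factor(x$calls$direction, levels = c("hyper", "hypo")))
  cat("<epi_scan>", nrow(x$calls), "outlier calls (",
      nd[["hyper"]], "hyper,", nd[["hypo"]], "hypo ) from",
      pv$n_tested, "tested probes x", pv$n_samples, "samples\n")
  cat("  Bonferroni n_tests =", pv$n_tests, "; corrected p <",
      pv$alpha_corrected, "\n")
  invisible(x)
}

#' @rdname scan_outliers
#' @param x An `epi_scan` object.
#' @param ... Unused.
#' @method tidy epi_scan
#' @export
tidy.epi_scan <- function(x, ...) x$calls

#' @rdname scan_outliers
#' @method glance epi_scan
#' @export
glance.epi_scan <- function(x, ...) {
  pv <- x$provenance
  tibble::tibble(n_calls = nrow(x$calls),
                 n_hyper = sum(x$calls$direction == "hyper"),
                 n_hypo = sum(x$calls$direction == "hypo"),
                 n_probes = pv$n_probes, n_tested = pv$n_tested,
                 n_samples = pv$n_samples, n_tests = pv$n_tests,
                 alpha_corrected = pv$alpha_corrected)
}
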