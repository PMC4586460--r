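#' Per-subject epimutation burden table
#'
#' Counts outlier calls per sample (total, hyper, hypo), joined to the
#' sample sheet and ordered by category then gestational weight gain, the
#' ordering used for burden profiles across the weight-gain axis. Samples
#' without calls appear with zero counts.
#'
#' @param result An `epi_scan` or calls tibble.
#' @param sheet Sample sheet (`sample_id`, `category`, `gwg_kg`, ...).
#' @return Tibble: one row per sample with `n_total`, `n_hyper`, `n_hypo`
#'   and the sheet's metadata columns.
#' @export
burden_by_subject <- function(result, sheet) {
  calls <- if (inherits(result, "epi_scan")) result$calls else result
  unknown <- setdiff(calls$sample_id, sheet$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("calls reference samples absent from the sample sheet: ",
                 paste(unknown, collapse = ", ")))
  }
  counts <- calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_hyper = sum(.data$direction == "hyper"),
                     n_hypo = sum(.data$direction == "hypo"),
                     .groups = "drop")
  out <- dplyr::left_join(sheet, counts, by = "sample_id")
  out <- dplyr::mutate(out, dplyr::across(c("n_total", "n_hyper", "n_hypo"),
                                          ~ tidyr::replace_na(.x, 0L)))
  if ("gwg_kg" %in% names(out)) {
    dplyr::arrange(out, .data$category, .data$gwg_kg)
  } else {
    dplyr::arrange(out, .data$category)
  }
}

#' Per-category burden summary
#'
#' @param burden A burden table from [burden_by_subject()].
#' @param value Which count to summarise (`"n_total"`, `"n_hyper"`,
#'   `"n_hypo"`).
#' @return Tibble: `category`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
burden_by_category <- function(burden, value = "n_total") {
  burden |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[value]]),
                     sd = sd(.data[[value]]),
                     min = min(.data[[value]]),
                     max = max(.data[[value]]),
                     .groups = "drop")
}

#' Tukey honest-significant-difference comparison of category burdens
#'
#' All-pairs comparison of per-sample outlier counts across categories on
#' a one-way layout, using the studentised-range distribution
#' (`TukeyHSD`). Counts are treated as approximately normal; a
#' Kruskal-Wallis omnibus p-value is attached for a distribution-free
#' cross-check. Categories with fewer than two samples are excluded with
#' a warning.
#'
#' @param burden Burden table from [burden_by_subject()].
#' @param value Count column to compare (default `"n_total"`).
#' @return Tibble: `comparison`, `estimate`, `conf_low`, `conf_high`,
#'   `p_adjusted`, `stars` (significance at 0.001 / 0.01 / 0.05);
#'   attribute `kruskal_p`.
#' @export
tukey_hsd <- function(burden, value = "n_total") {
  sizes <- table(burden$category)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("categories with < 2 samples excluded: ",
                paste(small, collapse = ", ")))
    burden <- burden[!burden$category %in% small, , drop = FALSE]
  }
  if (length(unique(burden$category)) < 2) {
    abort("need >= 2 categories with >= 2 samples each")
  }
  df <- data.frame(y = burden[[value]],
                   category = factor(burden$category))
  fit <- aov(y ~ category, data = df)
  tk <- TukeyHSD(fit)$category
  # zero residual variance with zero differences: no evidence against the null
  rss <- sum(stats::residuals(fit)^2)
  if (rss <= 1e-16 * max(1, sum(df$y^2))) {
    tk[abs(tk[, "diff"]) < 1e-8, "p adj"] <- 1
  }
  tk[!is.finite(tk[, "p adj"]) & tk[, "diff"] == 0, "p adj"] <- 1
  kw <- kruskal.test(y ~ category, data = df)$p.value
  out <- tibble::tibble(
    comparison = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adjusted = tk[, "p adj"],
    stars = dplyr::case_when(
      tk[, "p adj"] < 0.001 ~ "***",
      tk[, "p adj"] < 0.01 ~ "**",
      tk[, "p adj"] < 0.05 ~ "*",
      TRUE ~ ""
    )
  )
  attr(out, "kruskal_p") <- kw
  out
}

#' Score scan calls against simulation ground truth
#'
#' A truth record is recovered when a call exists at the same
#' (probe, sample) with the same direction. Sensitivity is
#' recovered / injected; a false call matches no truth record at its
#' probe+sample; attribution accuracy is, among calls whose probe carries
#' an injection of the same direction in some sample, the fraction
#' attributed to the correct sample.
#'
#' @param result An `epi_scan` or calls tibble.
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @return An `epi_recovery`: list with `records` (truth + `recovered`)
#'   and `metrics` (per-direction and overall rates).
#' @export
score_recovery <- function(result, truth) {
  calls <- if (inherits(result, "epi_scan")) result$calls else result
  call_key <- paste(calls$probe_id, calls$sample_id, calls$direction)
  truth_key <- paste(truth$probe_id, truth$sample_id, truth$direction)
  records <- dplyr::mutate(truth, recovered = truth_key %in% call_key)

  probe_dir_truth <- unique(paste(truth$probe_id, truth$direction))
  at_injected <- paste(calls$probe_id, calls$direction) %in% probe_dir_truth
  attributed <- call_key %in% truth_key
  false_calls <- calls[!attributed, , drop = FALSE]

  per_dir <- records |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(injected = dplyr::n(),
                     recovered = sum(.data$recovered),
                     sensitivity = recovered / injected,
                     .groups = "drop")
  metrics <- dplyr::bind_rows(
    per_dir,
    tibble::tibble(direction = "overall",
                   injected = nrow(records),
                   recovered = sum(records$recovered),
                   sensitivity = ifelse(nrow(records) > 0,
                                        sum(records$recovered) / nrow(records),
                                        NA_real_))
  )
  metrics$attribution <- NA_real_
  metrics$attribution[metrics$direction == "overall"] <-
    ifelse(sum(at_injected) > 0,
           sum(attributed & at_injected) / sum(at_injected), NA_real_)
  metrics$false_calls <- NA_integer_
  metrics$false_calls[metrics$direction == "overall"] <- nrow(false_calls)

  structure(list(records = records, metrics = metrics,
                 false_calls = false_calls),
            class = "epi_recovery")
}

#' @export
print.epi_recovery <- function(x, ...) {
  ov <- x$metrics[x$metrics$direction == "overall", ]
  cat("<epi_recovery>", ov$recovered, "/", ov$injected,
      "injections recovered (sensitivity",
      sprintf("%.3f", ov$sensitivity), ");",
      ov$false_calls, "false calls; attribution",
      sprintf("%.3f", ov$attribution), "\n")
  invisible(x)
}

#' @rdname score_recovery
#' @param x An `epi_recovery` object.
#' @param ... Unused.
#' @method tidy epi_recovery
#' @export
tidy.epi_recovery <- function(x, ...) x$records

#' @rdname score_recovery
#' @method glance epi_recovery
#' @export
glance.epi_recovery <- function(x, ...) {
  x$metrics[x$metrics$direction == "overall", ]
}

#' Heatmap-ready matrix of called probes
#'
#' Beta values of every called probe across all samples, one row per
#' (direction, probe), for heatmap visualisation of outlier profiles.
#'
#' @param result An `epi_scan` or calls tibble.
#' @param beta Beta tibble the calls were made from.
#' @return Long tibble: `probe_id`, `direction`, `sample_id`, `beta`,
#'   `is_outlier_sample`.
#' @export
call_heatmap_data <- function(result, beta) {
  calls <- if (inherits(result, "epi_scan")) result$calls else result
  sub <- beta[beta$probe_id %in% calls$probe_id, , drop = FALSE]
  long <- tidyr::pivot_longer(sub, -"probe_id", names_to = "sample_id",
                              values_to = "beta")
  key <- paste(calls$probe_id, calls$sample_id)
  dplyr::left_join(long,
                   dplyr::select(calls, "probe_id", "direction"),
                   by = "probe_id") |>
    dplyr::mutate(is_outlier_sample =
                    paste(.data$probe_id, .data$sample_id) %in% key)
}
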