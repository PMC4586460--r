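#' Two-sided Wilcoxon rank-sum test for one probe
#'
#' Exact-distribution p-value when the smaller group has <= 10 samples and
#' there are no ties; normal approximation with tie correction (and
#' continuity correction) otherwise. Group sizes in cohort studies of this
#' kind are 4-19, where the normal approximation alone is unreliable.
#'
#' @param x,y Beta values for the two groups (each >= 2 samples).
#' @return A list with `statistic` (rank-sum W) and `p_value`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 exact
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("both groups need >= 2 samples")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 10 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper around `p.adjust(method = "BH")`; output order
#' matches input order.
#'
#' @param p Vector of raw p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Named presets for the study's group comparisons
#'
#' Phenotype contrasts (growth-restricted vs normal, overall and within
#' each weight-gain stratum) and weight-gain contrasts (insufficient or
#' excessive vs adequate within each phenotype).
#'
#' @return A tibble with columns `name`, `column`, `a`, `b`, `within_column`,
#'   `within`.
#' @export
group_presets <- function() {
  tibble::tibble(
    name = c("FGR_vs_normal",
             paste0("FGR_vs_normal_within_",
                    c("insufficient", "adequate", "excessive")),
             "insufficient_vs_adequate_within_FGR",
             "excessive_vs_adequate_within_FGR",
             "insufficient_vs_adequate_within_normal",
             "excessive_vs_adequate_within_normal"),
    column = c(rep("phenotype", 4), rep("gwg_category", 4)),
    a = c(rep("FGR", 4), "insufficient", "excessive", "insufficient",
          "excessive"),
    b = c(rep("normal", 4), rep("adequate", 4)),
    within_column = c(NA, rep("gwg_category", 3), rep("phenotype", 4)),
    within = c(NA, "insufficient", "adequate", "excessive",
               "FGR", "FGR", "normal", "normal")
  )
}

#' Per-probe two-group differential methylation testing
#'
#' Runs a Wilcoxon rank-sum test at every probe between two sample groups
#' defined by a sample-sheet column, adjusts the p-values by
#' Benjamini-Hochberg, and counts probes significant at the adjusted
#' threshold.
#'
#' @param beta Beta tibble.
#' @param sheet Sample sheet.
#' @param a,b Labels of the two groups being compared (a vs b).
#' @param column Sample-sheet column holding the group labels.
#' @param within_column,within Optional stratum restriction: only samples
#'   with `sheet[[within_column]] == within` are used.
#' @param threshold Adjusted-p significance cutoff (default 0.05).
#' @return An `epi_grouptest`: list with `table` (per-probe tibble:
#'   group means, rank-sum statistic, raw and adjusted p) and `summary`.
#' @export
compare_groups <- function(beta, sheet, a, b, column = "phenotype",
                           within_column = NULL, within = NULL,
                           threshold = 0.05) {
  sh <- sheet
  if (!is.null(within_column) && !is.null(within) && !is.na(within)) {
    sh <- sh[sh[[within_column]] %in% within, , drop = FALSE]
  }
  labels <- sh[[column]]
  if (!all(c(a, b) %in% labels)) {
    abort(paste0("grouping labels not present in sample sheet: ",
                 paste(setdiff(c(a, b), labels), collapse = ", ")))
  }
  ids_a <- sh$sample_id[labels == a]
  ids_b <- sh$sample_id[labels == b]
  ids_a <- intersect(ids_a, names(beta))
  ids_b <- intersect(ids_b, names(beta))
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort("each group must select at least 2 samples")
  }
  Xa <- beta_matrix(beta[c("probe_id", ids_a)])
  Xb <- beta_matrix(beta[c("probe_id", ids_b)])
  res <- purrr::map(seq_len(nrow(Xa)), function(i) {
    xa <- Xa[i, ]; xb <- Xb[i, ]
    if (anyNA(xa) || anyNA(xb)) return(list(statistic = NA_real_,
                                            p_value = NA_real_))
    wilcoxon_rank_sum(xa, xb)
  })
  tab <- tibble::tibble(
    probe_id = rownames(Xa),
    mean_a = rowMeans(Xa),
    mean_b = rowMeans(Xb),
    statistic = purrr::map_dbl(res, "statistic"),
    p_value = purrr::map_dbl(res, "p_value")
  )
  tab$p_adjusted <- bh_adjust(tab$p_value)
  n_sig <- sum(tab$p_adjusted < threshold, na.rm = TRUE)
  structure(list(
    table = tab,
    summary = tibble::tibble(group_a = a, group_b = b,
                             n_a = length(ids_a), n_b = length(ids_b),
                             within = within %||% NA_character_,
                             threshold = threshold,
                             n_significant = n_sig)
  ), class = "epi_grouptest")
}

#' @export
print.epi_grouptest <- function(x, ...) {
  s <- x$summary
  cat("<epi_grouptest>", s$group_a, "vs", s$group_b,
      if (!is.na(s$within)) paste0("(within ", s$within, ")") else "",
      "\n  n =", s$n_a, "vs", s$n_b, "over", nrow(x$table), "probes;",
      s$n_significant, "significant at adjusted p <", s$threshold, "\n")
  invisible(x)
}

#' @rdname compare_groups
#' @param x An `epi_grouptest` object.
#' @param ... Unused.
#' @method tidy epi_grouptest
#' @export
tidy.epi_grouptest <- function(x, ...) x$table

#' @rdname compare_groups
#' @method glance epi_grouptest
#' @export
glance.epi_grouptest <- function(x, ...) x$summary
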