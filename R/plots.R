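#' Per-subject burden bar plot
#'
#' Bars of outlier counts per sample, faceted by phenotype and ordered by
#' gestational weight gain within each facet, so inadequate weight gain at
#' either end of the axis shows up as a U-shaped profile. Hyper- and
#' hypomethylated counts are stacked.
#'
#' @param burden Burden table from [burden_by_subject()].
#' @return A ggplot object.
#' @export
plot_burden <- function(burden) {
  long <- burden |>
    tidyr::pivot_longer(c("n_hyper", "n_hypo"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(direction = sub("n_", "", .data$direction))
  long$sample_id <- factor(long$sample_id,
                           levels = burden$sample_id[order(burden$phenotype,
                                                           burden$gwg_kg)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ phenotype, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(hyper = "#c0392b",
                                          hypo = "#27ae60")) +
    ggplot2::labs(x = "sample (ordered by gestational weight gain)",
                  y = "outlier calls", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Genomic-feature composition plot for a call set
#'
#' Stacked fractions of calls per CpG-island group and per gene-feature
#' group, split by direction.
#'
#' @param calls Annotated calls tibble (see [annotate_calls()]).
#' @return A ggplot object.
#' @export
plot_call_features <- function(calls) {
  rep_ <- feature_report(calls)
  df <- dplyr::bind_rows(
    dplyr::mutate(rep_$cgi, panel = "CpG-island relation"),
    dplyr::mutate(rep_$feature, panel = "gene feature")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction,
                                   y = .data$fraction,
                                   fill = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = "fraction of calls", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot epi_scan
#' @export
autoplot.epi_scan <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$delta_beta,
                                      fill = .data$direction)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8, position = "identity") +
    ggplot2::scale_fill_manual(values = c(hyper = "#c0392b",
                                          hypo = "#27ae60")) +
    ggplot2::labs(x = expression(Delta * beta), y = "calls", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Outlier heatmap (calls x samples)
#'
#' Tile plot of beta values at called probes across all samples, split by
#' direction; the per-probe outlier sample stands out against the cohort.
#'
#' @param result An `epi_scan` or calls tibble.
#' @param beta Beta tibble.
#' @return A ggplot object.
#' @export
plot_outlier_heatmap <- function(result, beta) {
  df <- call_heatmap_data(result, beta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$probe_id,
                                   fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(direction ~ ., scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient(low = "#ffffcc", high = "#800026",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(beta)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
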