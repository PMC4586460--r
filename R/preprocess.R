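#' Compute methylation beta values from signal intensities
#'
#' beta = M / (U + M + 100), where M and U are the methylated and
#' unmethylated signal intensities and the +100 offset regularises
#' low-intensity probes. Values lie in [0, 1).
#'
#' @param M Methylated intensity (vector, >= 0).
#' @param U Unmethylated intensity (vector, >= 0).
#' @return Numeric vector of beta values.
#' @examples
#' compute_beta(100, 0)  # 0.5
#' compute_beta(900, 0)  # 0.9
#' @export
compute_beta <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative")
  }
  M / (U + M + 100)
}

#' Build a beta table from a long intensity table
#'
#' @param intensities Long tibble with `probe_id`, `sample_id`, `M`, `U`
#'   (and optionally `detection_p`).
#' @return A wide beta tibble (`probe_id` + one column per sample).
#' @export
beta_from_intensities <- function(intensities) {
  stopifnot(all(c("probe_id", "sample_id", "M", "U") %in% names(intensities)))
  out <- dplyr::mutate(intensities, beta = compute_beta(.data$M, .data$U))
  tidyr::pivot_wider(dplyr::select(out, "probe_id", "sample_id", "beta"),
                     names_from = "sample_id", values_from = "beta")
}

#' Probe-level quality filtering of a beta table
#'
#' Removes, in this order: probes on sex chromosomes; rs-prefixed SNP
#' genotyping control probes; probes whose detection p-value exceeds the
#' threshold in one or more samples; probes with a missing beta value in
#' one or more samples. A probe failing several rules is attributed to the
#' first rule in this order; totals reconcile with the input probe count.
#'
#' @param beta Beta tibble.
#' @param manifest Manifest covering every probe in `beta`.
#' @param detection Optional long tibble (`probe_id`, `sample_id`,
#'   `detection_p`); may be sparse (failed cells only) or complete.
#' @param detection_p_threshold Detection p-value cutoff (default 0.01).
#' @return A list with `beta` (the filtered table, manifest probe order)
#'   and `report` (a tibble of per-rule removal counts plus the retained
#'   count).
#' @export
filter_probes <- function(beta, manifest, detection = NULL,
                          detection_p_threshold = 0.01) {
  missing_probes <- setdiff(beta$probe_id, manifest$IlmnID)
  if (length(missing_probes) > 0) {
    abort(paste0("probes absent from manifest: ",
                 paste(utils::head(missing_probes, 5), collapse = ", ")))
  }
  man <- manifest[match(beta$probe_id, manifest$IlmnID), ]

  sex <- man$CHR %in% c("X", "Y", "chrX", "chrY")
  rs <- startsWith(beta$probe_id, "rs")
  det <- rep(FALSE, nrow(beta))
  if (!is.null(detection) && nrow(detection) > 0) {
    fail <- detection$probe_id[detection$detection_p > detection_p_threshold]
    det <- beta$probe_id %in% fail
  }
  miss <- !complete.cases(beta[setdiff(names(beta), "probe_id")])

  rule <- dplyr::case_when(
    sex ~ "sex_chromosome",
    rs ~ "rs_control",
    det ~ "detection_p",
    miss ~ "missing_beta",
    TRUE ~ "retained"
  )
  counts <- table(factor(rule, levels = c("sex_chromosome", "rs_control",
                                          "detection_p", "missing_beta",
                                          "retained")))
  report <- tibble::tibble(rule = names(counts), n = as.integer(counts))
  kept <- beta[rule == "retained", , drop = FALSE]
  # preserve manifest order among retained probes
  kept <- kept[order(match(kept$probe_id, manifest$IlmnID)), , drop = FALSE]
  list(beta = kept, report = report)
}
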