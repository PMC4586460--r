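#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric test of a query gene list against
#' each annotation term, with Benjamini-Hochberg adjustment across terms.
#' Fold enrichment is (k/n) / (K/N) for overlap k, query size n, term size
#' K (within the universe) and universe size N. The universe should be the
#' genes assayable by the platform (e.g. all genes with at least one
#' retained probe), not the whole genome, to control array-composition
#' bias.
#'
#' @param genes Character vector: the query gene set (must be a subset of
#'   `universe`).
#' @param universe Character vector: the background gene universe.
#' @param annotation_sets Named list of character vectors (term -> genes),
#'   e.g. from [read_gmt()].
#' @return Tibble: `term`, `term_size` (within universe), `overlap`,
#'   `fold_enrichment`, `p_value`, `p_adjusted`.
#' @examples
#' test_enrichment(c("A", "B"), LETTERS[1:10],
#'                 list(t1 = c("A", "B", "C")))
#' @export
test_enrichment <- function(genes, universe, annotation_sets) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (length(genes) == 0 || length(annotation_sets) == 0) {
    abort("query genes and annotation sets must be non-empty")
  }
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    abort(paste0("query genes outside the universe: ",
                 paste(utils::head(outside, 5), collapse = ", ")))
  }
  N <- length(universe)
  n <- length(genes)
  res <- purrr::imap_dfr(annotation_sets, function(set, term) {
    set <- intersect(unique(set), universe)
    K <- length(set)
    k <- length(intersect(genes, set))
    tibble::tibble(
      term = term,
      term_size = K,
      overlap = k,
      fold_enrichment = if (K > 0) (k / n) / (K / N) else NA_real_,
      p_value = if (K > 0) phyper(k - 1, K, N - K, n, lower.tail = FALSE)
                else NA_real_
    )
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res
}
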