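# Shared helpers for moving between the tibble interface (probe_id + one
# column per sample) and the numeric probe x sample matrix used internally.

#' Convert a beta tibble to a numeric matrix
#'
#' Beta tables throughout the package are tibbles with a `probe_id` column
#' followed by one numeric column per sample. This converts to a probes x
#' samples matrix with probe ids as rownames.
#'
#' @param beta A beta tibble (`probe_id` + sample columns).
#' @return A numeric matrix, probes in rows, samples in columns.
#' @export
beta_matrix <- function(beta) {
  stopifnot(is.data.frame(beta), "probe_id" %in% names(beta))
  m <- as.matrix(beta[setdiff(names(beta), "probe_id")])
  if (!is.numeric(m)) abort("beta columns must be numeric")
  rownames(m) <- beta$probe_id
  m
}

#' Convert a probes x samples matrix back to a beta tibble
#'
#' @param m Numeric matrix with probe ids as rownames.
#' @return A tibble with `probe_id` plus one column per sample.
#' @export
beta_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# Row SDs without matrixStats; NA cells propagate to NA.
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

# Chromosome sort order used by all manifest operations: 1..22, X, Y.
chrom_levels <- function() c(as.character(1:22), "X", "Y")

manifest_is_sorted <- function(manifest) {
  chr <- factor(manifest$CHR, levels = chrom_levels())
  if (anyNA(chr)) return(FALSE)
  o <- order(chr, manifest$MAPINFO)
  identical(o, seq_len(nrow(manifest)))
}

check_sorted_manifest <- function(manifest) {
  if (!manifest_is_sorted(manifest)) {
    abort("manifest must be sorted by (chromosome, position); see `sort_manifest()`")
  }
  invisible(manifest)
}

#' Sort a probe manifest by genomic coordinates
#'
#' Orders probes by chromosome (1-22, X, Y) then position, the order assumed
#' by all adjacency-based operations.
#'
#' @param manifest Manifest tibble with `CHR` and `MAPINFO` columns.
#' @return The manifest, sorted.
#' @export
sort_manifest <- function(manifest) {
  chr <- factor(manifest$CHR, levels = chrom_levels())
  manifest[order(chr, manifest$MAPINFO), , drop = FALSE]
}

# First entry of a ";"-separated annotation list ("" stays "").
lead_off <- function(x) {
  x <- ifelse(is.na(x), "", x)
  vapply(strsplit(x, ";", fixed = TRUE),
         function(p) if (length(p) == 0) "" else p[[1]], character(1))
}

is_snp_flagged <- function(manifest) {
  flag <- function(x) !is.na(x) & x != ""
  flag(manifest$Probe_SNPs) | flag(manifest$Probe_SNPs_10)
}

ptss_features <- function() c("TSS1500", "TSS200", "5'UTR", "1stExon")
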