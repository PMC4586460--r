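#' Read and write pipeline tables
#'
#' Thin readr wrappers fixing the on-disk conventions: manifest as CSV with
#' the standard 450K annotation columns, beta matrices as TSV with
#' `probe_id` first, sample sheets as CSV, calls and burden tables as TSV.
#'
#' @param path File path.
#' @name episcan-io
NULL

#' @rdname episcan-io
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    IlmnID = "c", CHR = "c", MAPINFO = "i", UCSC_RefGene_Name = "c",
    UCSC_RefGene_Group = "c", Relation_to_UCSC_CpG_Island = "c",
    Probe_SNPs = "c", Probe_SNPs_10 = "c"
  )) |>
    dplyr::mutate(dplyr::across(
      c("UCSC_RefGene_Name", "UCSC_RefGene_Group",
        "Relation_to_UCSC_CpG_Island", "Probe_SNPs", "Probe_SNPs_10"),
      ~ tidyr::replace_na(.x, "")))
}

#' @rdname episcan-io
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname episcan-io
#' @export
read_beta <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()))
  out
}

#' @rdname episcan-io
#' @param beta Beta tibble.
#' @export
write_beta <- function(beta, path) {
  readr::write_tsv(beta, path)
  invisible(path)
}

#' @rdname episcan-io
#' @export
read_sample_sheet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname episcan-io
#' @param sheet Sample sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet, path)
  invisible(path)
}

#' Export outlier calls as a BED track
#'
#' One interval per called CpG, converted from the manifest's 1-based
#' point coordinate to BED's 0-based half-open convention
#' (start = position - 1, end = position). The name field carries the
#' outlier sample id and the score is round(1000 * |delta-beta|), capped
#' at 1000.
#'
#' @param result An `epi_scan` or calls tibble.
#' @param manifest Manifest with probe coordinates.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_bed <- function(result, manifest, path) {
  calls <- if (inherits(result, "epi_scan")) result$calls else result
  hit <- match(calls$probe_id, manifest$IlmnID)
  if (anyNA(hit)) abort("calls reference probes absent from the manifest")
  bed <- tibble::tibble(
    chrom = paste0("chr", manifest$CHR[hit]),
    start = manifest$MAPINFO[hit] - 1L,
    end = manifest$MAPINFO[hit],
    name = calls$sample_id,
    score = pmin(round(1000 * abs(calls$delta_beta)), 1000),
    strand = "."
  )
  bed <- bed[order(bed$chrom, bed$start), ]
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' GMT format: one set per line, tab-separated: term, description, then
#' member genes.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- purrr::map(parts, ~ unique(.x[-(1:2)]))
  names(sets) <- purrr::map_chr(parts, 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (term -> genes).
#' @param descriptions Optional character vector of term descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  lines <- purrr::imap_chr(sets, function(g, term) {
    paste(c(term, desc[[match(term, names(sets))]], g), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}
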