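#' Annotate outlier calls with genomic features
#'
#' Joins each call to the probe manifest and derives: the CpG-island
#' relation (raw category plus a collapsed Island / Shore / Shelf /
#' OpenSea group), the lead-off gene symbol and feature group (the first
#' entry of the semicolon-joined manifest lists; probes with empty gene
#' fields are intergenic), and the promoter-proximal (pTSS) flag - lead
#' feature in TSS1500, TSS200, 5'UTR, or 1stExon.
#'
#' @param result An `epi_scan` or a calls tibble with `probe_id`.
#' @param manifest Manifest sorted by (chromosome, position).
#' @return The calls tibble with added columns `chr`, `pos`,
#'   `cgi_relation`, `cgi_group`, `gene`, `feature`, `genic`, `ptss`.
#' @export
annotate_calls <- function(result, manifest) {
  check_sorted_manifest(manifest)
  calls <- if (inherits(result, "epi_scan")) result$calls else result
  hit <- match(calls$probe_id, manifest$IlmnID)
  if (anyNA(hit)) abort("calls reference probes absent from the manifest")
  man <- manifest[hit, ]
  rel <- man$Relation_to_UCSC_CpG_Island
  rel <- ifelse(is.na(rel), "", rel)
  grp <- dplyr::case_when(
    rel == "Island" ~ "Island",
    rel %in% c("N_Shore", "S_Shore") ~ "Shore",
    rel %in% c("N_Shelf", "S_Shelf") ~ "Shelf",
    TRUE ~ "OpenSea"
  )
  gene <- lead_off(man$UCSC_RefGene_Name)
  feature <- lead_off(man$UCSC_RefGene_Group)
  dplyr::mutate(calls,
                chr = man$CHR,
                pos = man$MAPINFO,
                cgi_relation = rel,
                cgi_group = grp,
                gene = dplyr::if_else(gene == "", "intergenic", gene),
                feature = dplyr::if_else(feature == "", "intergenic", feature),
                genic = .data$feature != "intergenic",
                ptss = .data$feature %in% ptss_features())
}

#' Group adjacent outlier calls into clusters
#'
#' Two calls are adjacent when their probes occupy consecutive rows of the
#' retained-probe manifest on the same chromosome (optionally within a
#' base-pair gap cap). Connected runs of adjacent calls form clusters;
#' calls in clusters of two or more probes are `clustered`, the rest
#' `isolated`. Clusters never mix hyper- and hypomethylated calls, and by
#' default never mix samples (per-subject epimutation reporting).
#'
#' @param calls Annotated calls tibble (from [annotate_calls()]).
#' @param manifest The retained-probe manifest (post-filter), sorted; its
#'   row order defines probe adjacency.
#' @param same_sample Cluster only calls from the same sample
#'   (default TRUE).
#' @param max_gap Optional maximum base-pair distance between adjacent
#'   probes (default `Inf`: manifest adjacency alone decides).
#' @return `calls` with `cluster_id` (NA for isolated calls), `clustered`,
#'   and `cluster_size` columns; input row order preserved.
#' @export
cluster_calls <- function(calls, manifest, same_sample = TRUE,
                          max_gap = Inf) {
  check_sorted_manifest(manifest)
  row_i <- match(calls$probe_id, manifest$IlmnID)
  if (anyNA(row_i)) abort("calls reference probes absent from the manifest")
  key_sample <- if (same_sample) calls$sample_id else ""
  grp <- paste(key_sample, calls$direction, manifest$CHR[row_i], sep = "\r")

  ord <- order(grp, row_i)
  g <- grp[ord]; r <- row_i[ord]
  pos <- manifest$MAPINFO[r]
  new_run <- c(TRUE, g[-1] != g[-length(g)] | diff(r) != 1L |
                 diff(pos) > max_gap)
  run_id <- cumsum(new_run)
  size <- as.integer(table(run_id))[run_id]
  cluster_id <- ifelse(size >= 2, paste0("cluster_", run_id), NA_character_)

  out <- calls
  out$cluster_id <- NA_character_
  out$cluster_size <- NA_integer_
  out$cluster_id[ord] <- cluster_id
  out$cluster_size[ord] <- size
  out$clustered <- !is.na(out$cluster_id)
  out
}

#' Select gene subgroups hosting outlier calls
#'
#' Aggregates calls to genes via the lead-off symbol and emits, per
#' direction: all host genes; genes hosting highly deviated calls
#' (|delta-beta| > 0.2, strict); genes hosting promoter-proximal (pTSS)
#' calls; genes hosting clustered calls (two or more adjacent probes); and
#' the intersection subgroup (highly deviated AND clustered AND pTSS,
#' required of a single call). Intergenic calls are excluded; each gene is
#' listed once per subgroup.
#'
#' @param calls Annotated, clustered calls tibble.
#' @param delta_threshold Strict |delta-beta| threshold (default 0.2).
#' @return Tibble: `direction`, `subgroup`, `gene`.
#' @export
select_gene_subgroups <- function(calls, delta_threshold = 0.2) {
  genic <- calls[calls$gene != "intergenic", , drop = FALSE]
  high <- abs(genic$delta_beta) > delta_threshold
  sub <- list(
    hosts = rep(TRUE, nrow(genic)),
    high_delta = high,
    ptss = genic$ptss,
    clustered = genic$clustered,
    high_delta_clustered_ptss = high & genic$clustered & genic$ptss
  )
  purrr::map_dfr(names(sub), function(s) {
    g <- genic[sub[[s]], c("direction", "gene")]
    dplyr::distinct(dplyr::mutate(g, subgroup = s),
                    .data$direction, .data$subgroup, .data$gene)
  }) |>
    dplyr::select("direction", "subgroup", "gene") |>
    dplyr::arrange(.data$direction, .data$subgroup, .data$gene)
}

#' Feature-composition report for a call set
#'
#' Fractions of calls per CpG-island group, per lead gene-feature group,
#' genic fraction, pTSS fraction, and clustered/isolated split, computed
#' per direction.
#'
#' @param calls Annotated (optionally clustered) calls tibble.
#' @return A named list of tibbles: `cgi`, `feature`, `summary`.
#' @export
feature_report <- function(calls) {
  frac_by <- function(col) {
    calls |>
      dplyr::count(.data$direction, value = .data[[col]]) |>
      dplyr::group_by(.data$direction) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  summary <- calls |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      n = dplyr::n(),
      genic_fraction = mean(.data$genic),
      ptss_fraction = mean(.data$ptss),
      clustered_fraction = if ("clustered" %in% names(calls))
        mean(.data$clustered) else NA_real_,
      .groups = "drop")
  list(cgi = frac_by("cgi_group"), feature = frac_by("feature"),
       summary = summary)
}
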