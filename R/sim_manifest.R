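#' Generate a synthetic 450K-style probe manifest
#'
#' Emulates the schema of the Illumina HumanMethylation450 annotation table:
#' probes organised into CpG-island blocks (shelf / shore / island core /
#' shore / shelf runs) interleaved with open-sea stretches, gene symbol and
#' gene-feature-group columns (semicolon-joined, lead-off entry first),
#' `Probe_SNPs` / `Probe_SNPs_10` SNP flags, sex-chromosome probes, and
#' rs-prefixed SNP genotyping control probes. Probes are sorted by
#' (chromosome, position).
#'
#' @param config A [sim_config()].
#' @return A manifest tibble with columns `IlmnID`, `CHR`, `MAPINFO`,
#'   `UCSC_RefGene_Name`, `UCSC_RefGene_Group`,
#'   `Relation_to_UCSC_CpG_Island`, `Probe_SNPs`, `Probe_SNPs_10`.
#' @examples
#' man <- generate_manifest(sim_config(n_probes = 2000, seed = 1))
#' dplyr::count(man, Relation_to_UCSC_CpG_Island)
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  n <- config$n_probes
  n_blocks <- ceiling(n / 4) + 25L
  is_island <- runif(n_blocks) < 0.45

  # --- island blocks: shelf/shore/core/shore/shelf part lengths
  isl_idx <- which(is_island)
  n_isl <- length(isl_idx)
  L <- cbind(n_shelf = rbinom(n_isl, 1, 0.5),
             n_shore = sample(1:2, n_isl, replace = TRUE),
             core    = 2L + rpois(n_isl, 3),
             s_shore = sample(1:2, n_isl, replace = TRUE),
             s_shelf = rbinom(n_isl, 1, 0.5))
  part_rel <- c("N_Shelf", "N_Shore", "Island", "S_Shore", "S_Shelf")
  lens <- as.vector(t(L))
  isl <- tibble::tibble(
    block = rep(rep(isl_idx, each = 5L), lens),
    part  = rep(rep(part_rel, n_isl), lens)
  )
  # index within the island core, for promoter feature assignment
  isl$core_idx <- NA_integer_
  core_rows <- isl$part == "Island"
  isl$core_idx[core_rows] <- sequence(L[, "core"])
  isl$core_len <- NA_integer_
  isl$core_len[core_rows] <- rep(L[, "core"], L[, "core"])

  # --- open-sea blocks
  sea_idx <- which(!is_island)
  sea_len <- 1L + rpois(length(sea_idx), 2)
  sea <- tibble::tibble(
    block = rep(sea_idx, sea_len),
    part = "", core_idx = NA_integer_, core_len = NA_integer_
  )

  probes <- dplyr::arrange(dplyr::bind_rows(isl, sea), .data$block)
  # truncate to the requested probe count in block order (blocks carry
  # random chromosome assignments, so this keeps chromosomes balanced)
  probes <- utils::head(probes, n)

  # --- block-level gene assignment
  promoter <- is_island & runif(n_blocks) < config$fraction_cgi_promoter
  body_island <- is_island & !promoter & runif(n_blocks) < 0.6
  genic_sea <- !is_island & runif(n_blocks) < 0.55
  gene_name <- paste0("GENE", seq_len(n_blocks))

  b <- probes$block
  feat <- character(nrow(probes))
  gene <- character(nrow(probes))
  prom_core <- promoter[b] & probes$part == "Island"
  quarter <- ceiling(4 * probes$core_idx / probes$core_len)
  feat[prom_core] <- ptss_features()[quarter[prom_core]]
  prom_shore <- promoter[b] & probes$part %in% c("N_Shore", "S_Shore")
  feat[prom_shore] <- "TSS1500"
  body_rows <- body_island[b] & probes$part != ""
  feat[body_rows] <- "Body"
  sea_rows <- genic_sea[b]
  feat[sea_rows] <- sample(c("Body", "3'UTR"), sum(sea_rows),
                           replace = TRUE, prob = c(0.85, 0.15))
  genic <- feat != ""
  gene[genic] <- gene_name[b[genic]]

  # occasional second overlapping gene to exercise the lead-off rule
  second <- genic & runif(nrow(probes)) < 0.05
  gene[second] <- paste0(gene[second], ";", gene_name[b[second]], "B")
  feat[second] <- paste0(feat[second], ";Body")

  # --- chromosome assignment and positions
  chr_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 133,
              115, 107, 102, 90, 81, 78, 59, 63, 48, 51)
  block_chr <- sample(1:22, n_blocks, replace = TRUE, prob = chr_mb)
  probes$chr <- as.character(block_chr[b])
  probes$gene <- gene
  probes$feat <- feat
  probes <- probes[order(factor(probes$chr, levels = chrom_levels()),
                         probes$block), ]
  # first probe of each block opens a large inter-block gap
  fob <- c(TRUE, diff(probes$block) != 0)
  gap <- ifelse(fob, round(runif(nrow(probes), 500, 50000)),
                round(runif(nrow(probes), 20, 300)))
  probes$pos <- as.integer(stats::ave(gap, probes$chr, FUN = cumsum) + 15000)

  auto <- tibble::tibble(
    CHR = probes$chr, MAPINFO = probes$pos,
    UCSC_RefGene_Name = probes$gene, UCSC_RefGene_Group = probes$feat,
    Relation_to_UCSC_CpG_Island = probes$part
  )

  # --- sex-chromosome probes
  ns <- config$n_sex_chrom_probes
  sex <- tibble::tibble(
    CHR = sample(c("X", "Y"), ns, replace = TRUE, prob = c(0.96, 0.04)),
    MAPINFO = NA_integer_,
    UCSC_RefGene_Name = "",
    UCSC_RefGene_Group = "",
    Relation_to_UCSC_CpG_Island = sample(c("Island", ""), ns,
                                         replace = TRUE, prob = c(0.3, 0.7))
  )
  if (ns > 0) {
    sex$MAPINFO <- as.integer(stats::ave(
      round(runif(ns, 100, 5000)), sex$CHR, FUN = cumsum) + 10000)
  }

  cg <- dplyr::bind_rows(auto, sex)
  cg$IlmnID <- sprintf("cg%08d", sample.int(99999999L, nrow(cg)))

  # SNP-containing probe flags (dbSNP-style annotation)
  flagged <- runif(nrow(cg)) < config$fraction_snp_flagged
  rs_ids <- sprintf("rs%d", sample.int(99999999L, nrow(cg)))
  u <- runif(nrow(cg))
  cg$Probe_SNPs <- ifelse(flagged & u < 0.8, rs_ids, "")
  cg$Probe_SNPs_10 <- ifelse(flagged & u >= 0.7, rs_ids, "")

  # rs genotyping control probes
  nr <- config$n_rs_control_probes
  rs <- tibble::tibble(
    IlmnID = sprintf("rs%07d", sample.int(9999999L, nr)),
    CHR = sample(as.character(1:22), nr, replace = TRUE),
    MAPINFO = as.integer(round(runif(nr, 1e4, 5e7))),
    UCSC_RefGene_Name = "", UCSC_RefGene_Group = "",
    Relation_to_UCSC_CpG_Island = "", Probe_SNPs = "", Probe_SNPs_10 = ""
  )

  out <- sort_manifest(dplyr::bind_rows(cg, rs))
  out <- dplyr::select(out, "IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
                       "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island",
                       "Probe_SNPs", "Probe_SNPs_10")
  if (anyDuplicated(out$IlmnID)) abort("duplicate probe ids in generated manifest")
  out
}

# Probe classes driving baseline methylation and injection eligibility.
manifest_classes <- function(manifest) {
  rel <- manifest$Relation_to_UCSC_CpG_Island
  lead_feat <- lead_off(manifest$UCSC_RefGene_Group)
  is_cg <- startsWith(manifest$IlmnID, "cg")
  autosomal <- !manifest$CHR %in% c("X", "Y")
  tibble::tibble(
    probe_id = manifest$IlmnID,
    chr = manifest$CHR,
    rel = rel,
    lead_feature = lead_feat,
    promoter_island = rel == "Island" & lead_feat %in% ptss_features(),
    shore = rel %in% c("N_Shore", "S_Shore"),
    shelf = rel %in% c("N_Shelf", "S_Shelf"),
    open_sea = rel == "" & is_cg,
    is_cg = is_cg,
    autosomal = autosomal,
    snp_flagged = is_snp_flagged(manifest)
  )
}
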