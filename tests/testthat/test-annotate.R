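annot_manifest <- function() {
  toy_manifest(
    sprintf("cg%02d", 1:8),
    chr = c("1", "1", "1", "1", "1", "2", "2", "2"),
    pos = c(100, 200, 300, 5000, 5100, 120, 240, 9000),
    gene = c("GENEA;GENEB", "", "GENEC", "GENEC", "GENEC", "GENED",
             "GENED", ""),
    feature = c("TSS200;Body", "", "Body", "1stExon", "TSS200", "5'UTR",
                "TSS1500", ""),
    relation = c("Island", "", "", "Island", "Island", "Island",
                 "N_Shore", "")
  )
}

test_that("annotation applies the lead-off rule and the pTSS definition", {
  man <- annot_manifest()
  calls <- make_calls(c("cg01", "cg02", "cg03"))
  ann <- annotate_calls(as_scan_result(calls), man)
  expect_equal(ann$gene, c("GENEA", "intergenic", "GENEC"))
  expect_equal(ann$feature, c("TSS200", "intergenic", "Body"))
  expect_equal(ann$ptss, c(TRUE, FALSE, FALSE))
  expect_equal(ann$cgi_group, c("Island", "OpenSea", "OpenSea"))
  expect_equal(ann$genic, c(TRUE, FALSE, TRUE))

  shuffled <- man[c(3, 1, 2, 5, 4, 8, 7, 6), ]
  expect_error(annotate_calls(calls, shuffled), "sorted")
  expect_error(annotate_calls(make_calls("cgNO"), man), "absent")
})

test_that("clustering follows retained-manifest adjacency", {
  man <- annot_manifest()
  # cg03..cg05 are consecutive manifest rows on chr1; cg05 -> cg06 crosses
  # a chromosome boundary and must not chain
  calls <- make_calls(c("cg03", "cg04", "cg05", "cg06", "cg08"),
                      sample_id = "s1")
  cl <- cluster_calls(annotate_calls(calls, man), man)
  expect_equal(cl$clustered, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(length(unique(cl$cluster_id[1:3])), 1)
  expect_equal(cl$cluster_size[1:3], rep(3L, 3))
  # clustered + isolated partitions the calls
  expect_equal(sum(cl$clustered) + sum(!cl$clustered), nrow(cl))
})

test_that("clustering respects direction, sample and the gap cap", {
  man <- annot_manifest()
  calls <- make_calls(c("cg03", "cg04"), sample_id = c("s1", "s2"))
  ann <- annotate_calls(calls, man)
  expect_false(any(cluster_calls(ann, man, same_sample = TRUE)$clustered))
  expect_true(all(cluster_calls(ann, man, same_sample = FALSE)$clustered))

  mixed <- make_calls(c("cg04", "cg05"), sample_id = "s1",
                      delta_beta = c(0.3, -0.3))
  expect_false(any(cluster_calls(annotate_calls(mixed, man), man)$clustered))

  # cg03 (pos 300) and cg04 (pos 5000): adjacent rows but 4.7 kb apart
  far <- make_calls(c("cg03", "cg04"), sample_id = "s1")
  expect_false(any(cluster_calls(annotate_calls(far, man), man,
                                 max_gap = 1000)$clustered))
  expect_true(all(cluster_calls(annotate_calls(far, man), man,
                                max_gap = Inf)$clustered))
})

test_that("cluster assignment is invariant to call order", {
  man <- annot_manifest()
  calls <- make_calls(c("cg03", "cg04", "cg05", "cg08"))
  ann <- annotate_calls(calls, man)
  c1 <- cluster_calls(ann, man)
  c2 <- cluster_calls(ann[c(4, 2, 1, 3), ], man)
  key <- function(x) x[order(x$probe_id), c("probe_id", "clustered",
                                            "cluster_size")]
  expect_equal(key(c1), key(c2))
})

test_that("gene subgroups follow their strict definitions", {
  man <- toy_manifest(
    sprintf("cg%02d", 1:6),
    gene = paste0("G", 1:6),
    feature = c("TSS200", "TSS200", "Body", "TSS200", "Body", "TSS1500"),
    relation = "Island"
  )
  calls <- make_calls(sprintf("cg%02d", 1:6), sample_id = "s1",
                      delta_beta = c(0.25, 0.2, 0.5, 0.15, 0.21, 0.3))
  ann <- annotate_calls(calls, man)
  ann$clustered <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  ann$cluster_id <- ifelse(ann$clustered, "c1", NA)
  sub <- select_gene_subgroups(ann)
  pick <- function(s) sort(sub$gene[sub$subgroup == s])
  expect_equal(pick("hosts"), paste0("G", 1:6))
  # delta = 0.2 exactly is excluded (strict inequality)
  expect_equal(pick("high_delta"), c("G1", "G3", "G5", "G6"))
  expect_equal(pick("ptss"), c("G1", "G2", "G4", "G6"))
  expect_equal(pick("clustered"), c("G1", "G3", "G4", "G6"))
  expect_equal(pick("high_delta_clustered_ptss"), c("G1", "G6"))
})

test_that("single qualifying call puts its gene in all hyper subgroups", {
  man <- toy_manifest(c("cg01", "cg02"), gene = "GENEA",
                      feature = "TSS200", relation = "Island")
  calls <- make_calls(c("cg01", "cg02"), sample_id = "s1",
                      delta_beta = 0.25)
  ann <- cluster_calls(annotate_calls(calls, man), man)
  sub <- select_gene_subgroups(ann)
  expect_equal(sort(unique(sub$subgroup)),
               sort(c("hosts", "high_delta", "ptss", "clustered",
                      "high_delta_clustered_ptss")))
  expect_true(all(sub$gene == "GENEA"))
})

test_that("hypergeometric enrichment matches exact tail probabilities", {
  # all five query genes inside a five-gene term of a ten-gene universe
  uni <- paste0("g", 1:10)
  res <- test_enrichment(paste0("g", 1:5), uni,
                         list(term = paste0("g", 1:5)))
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_equal(res$fold_enrichment, 2)

  # query = universe: fold 1, p 1 for any term
  res2 <- test_enrichment(uni, uni, list(a = paste0("g", 1:3),
                                         b = paste0("g", 2:9)))
  expect_equal(res2$fold_enrichment, c(1, 1))
  expect_equal(res2$p_value, c(1, 1))

  # fold-enrichment arithmetic on a constructed contingency
  res3 <- test_enrichment(paste0("g", 1:4), uni, list(t = paste0("g", 1:5)))
  expect_equal(res3$fold_enrichment, (4 / 4) / (5 / 10))

  expect_error(test_enrichment(c("g1", "zz"), uni, list(t = "g1")),
               "outside the universe")
})

test_that("feature-report fractions sum to one per direction", {
  man <- annot_manifest()
  calls <- make_calls(sprintf("cg%02d", c(1, 2, 3, 4, 6)),
                      delta_beta = c(0.3, 0.3, -0.3, 0.3, -0.3))
  rep_ <- feature_report(annotate_calls(calls, man))
  sums <- tapply(rep_$cgi$fraction, rep_$cgi$direction, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  sums2 <- tapply(rep_$feature$fraction, rep_$feature$direction, sum)
  expect_equal(as.numeric(sums2), c(1, 1))
})
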