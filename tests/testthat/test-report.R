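mini_sheet <- function() {
  tibble::tibble(
    sample_id = c("A", "B", "C"),
    phenotype = c("FGR", "normal", "normal"),
    gwg_category = c("adequate", "adequate", "excessive"),
    category = c("FGR_adequate", "normal_adequate", "normal_excessive"),
    gwg_kg = c(8, 9, 14),
    batch = c(1, 2, 1)
  )
}

test_that("burden table counts calls per subject and keeps zero rows", {
  calls <- make_calls(c("cg1", "cg2", "cg3"),
                      sample_id = c("A", "A", "A"),
                      delta_beta = c(0.3, 0.4, -0.3))
  bt <- burden_by_subject(as_scan_result(calls), mini_sheet())
  rowA <- bt[bt$sample_id == "A", ]
  expect_equal(c(rowA$n_total, rowA$n_hyper, rowA$n_hypo), c(3, 2, 1))
  expect_equal(bt$n_total[bt$sample_id == "B"], 0)
  expect_equal(sum(bt$n_total), nrow(calls))

  empty <- burden_by_subject(make_calls(character(0)), mini_sheet())
  expect_true(all(empty$n_total == 0))

  bad <- make_calls("cg1", sample_id = "ZZZ")
  expect_error(burden_by_subject(bad, mini_sheet()), "absent from the sample")
})

test_that("burden rows are ordered by category then weight gain", {
  sheet <- tibble::tibble(
    sample_id = c("x1", "x2", "x3", "x4"),
    phenotype = "normal",
    gwg_category = c("adequate", "adequate", "insufficient", "insufficient"),
    category = c("normal_adequate", "normal_adequate",
                 "normal_insufficient", "normal_insufficient"),
    gwg_kg = c(11, 8, 3, 6), batch = 1
  )
  bt <- burden_by_subject(make_calls(character(0)), sheet)
  expect_equal(bt$sample_id, c("x2", "x1", "x3", "x4"))
})

test_that("identical category burdens give Tukey p of one", {
  burden <- tibble::tibble(
    sample_id = paste0("s", 1:9),
    category = rep(c("a", "b", "c"), each = 3),
    n_total = 50
  )
  tk <- tukey_hsd(burden)
  expect_equal(unname(tk$p_adjusted), rep(1, 3))
})

test_that("two-category Tukey equals the pooled t-test and a permutation null", {
  set.seed(55)
  y1 <- rnorm(15, 100, 20); y2 <- rnorm(15, 112, 20)
  burden <- tibble::tibble(sample_id = paste0("s", 1:30),
                           category = rep(c("a", "b"), each = 15),
                           n_total = c(y1, y2))
  tk <- tukey_hsd(burden)
  tt <- t.test(y2, y1, var.equal = TRUE)
  expect_equal(unname(tk$p_adjusted), tt$p.value, tolerance = 1e-8)

  # permutation oracle for the same two-sample comparison
  obs <- abs(mean(y2) - mean(y1))
  pooled <- c(y1, y2)
  perm <- vapply(1:20000, function(i) {
    idx <- sample(30, 15)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  }, numeric(1))
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - unname(tk$p_adjusted)), 0.01)
})

test_that("planted category separation is declared at the 0.001 level", {
  set.seed(56)
  cats <- rep(c("normal_adequate", "FGR_adequate", "FGR_insufficient",
                "FGR_excessive", "normal_insufficient", "normal_excessive"),
              c(9, 5, 5, 4, 5, 5))
  y <- ifelse(cats == "normal_adequate", rnorm(33, 50, 8),
              rnorm(33, 300, 60))
  burden <- tibble::tibble(sample_id = paste0("s", 1:33),
                           category = cats, n_total = y)
  tk <- tukey_hsd(burden)
  vs_ref <- grepl("normal_adequate", tk$comparison)
  expect_equal(sum(vs_ref), 5)
  expect_true(all(tk$p_adjusted[vs_ref] < 0.001))
  expect_true(all(tk$stars[vs_ref] == "***"))
})

test_that("Tukey p-values are invariant to category relabelling", {
  set.seed(57)
  burden <- tibble::tibble(sample_id = paste0("s", 1:20),
                           category = rep(c("a", "b", "c", "d"), each = 5),
                           n_total = rnorm(20, 100, 30))
  tk1 <- tukey_hsd(burden)
  relab <- c(a = "w", b = "x", c = "y", d = "z")
  burden2 <- dplyr::mutate(burden, category = unname(relab[category]))
  tk2 <- tukey_hsd(burden2)
  expect_equal(unname(sort(tk1$p_adjusted)), unname(sort(tk2$p_adjusted)),
               tolerance = 1e-12)
})

test_that("undersized categories are dropped with a warning", {
  burden <- tibble::tibble(sample_id = paste0("s", 1:7),
                           category = c(rep("a", 3), rep("b", 3), "tiny"),
                           n_total = c(1, 2, 3, 7, 8, 9, 100))
  expect_warning(tk <- tukey_hsd(burden), "tiny")
  expect_false(any(grepl("tiny", tk$comparison)))
})

test_that("recovery scoring handles the degenerate extremes", {
  truth <- tibble::tibble(sample_id = c("A", "B"),
                          probe_id = c("cg1", "cg2"),
                          delta = c(0.3, -0.3),
                          direction = c("hyper", "hypo"),
                          cluster_id = NA_character_)
  none <- score_recovery(make_calls(character(0)), truth)
  expect_equal(glance(none)$sensitivity, 0)

  exact <- make_calls(c("cg1", "cg2"), sample_id = c("A", "B"),
                      delta_beta = c(0.3, -0.3))
  all_found <- score_recovery(exact, truth)
  expect_equal(glance(all_found)$sensitivity, 1)
  expect_equal(glance(all_found)$false_calls, 0)
  expect_equal(glance(all_found)$attribution, 1)

  # wrong sample at an injected probe counts against attribution
  wrong <- make_calls("cg1", sample_id = "B", delta_beta = 0.3)
  sc <- score_recovery(wrong, truth)
  expect_equal(glance(sc)$attribution, 0)
  expect_equal(glance(sc)$sensitivity, 0)
})

test_that("scan, truth and burden accounting reconcile on a simulation", {
  cfg <- tiny_config(seed = 77, n_probes = 8000)
  man <- generate_manifest(cfg)
  cohort <- generate_cohort(cfg, man)
  filt <- filter_probes(cohort$beta, man, detection = cohort$detection)
  sc <- scan_outliers(filt$beta)
  rec <- score_recovery(sc, cohort$truth)
  ov <- glance(rec)
  expect_equal(nrow(sc$calls), ov$recovered + ov$false_calls)
  bt <- burden_by_subject(sc, cohort$sheet)
  expect_equal(sum(bt$n_total), nrow(sc$calls))
  expect_equal(sum(bt$n_hyper) + sum(bt$n_hypo), sum(bt$n_total))
})
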