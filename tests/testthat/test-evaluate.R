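test_that("roc_auc equals exhaustive pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(55)
  for (i in 1:10) {
    scores <- sample(seq(0, 1, by = 0.05), 30, replace = TRUE)  # many ties
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("roc_auc matches an independent implementation and is rank-invariant", {
  set.seed(56)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  auc <- roc_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc, ref, tolerance = 1e-10)
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(scores), labels), auc)
  expect_equal(roc_auc(rank(scores), labels), auc)
  expect_equal(roc_auc(plogis(scores), labels), auc)
})

test_that("sensitivity and specificity count the confusion matrix", {
  perfect <- sens_spec_at_threshold(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  # threshold 0 calls everything positive
  all_pos <- sens_spec_at_threshold(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0), 0)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  half <- sens_spec_at_threshold(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(half$sensitivity, 0.5)
  expect_equal(half$specificity, 0.5)
  # threshold is inclusive for positives
  edge <- sens_spec_at_threshold(c(0.5, 0.4), c(1, 0), 0.5)
  expect_equal(edge$sensitivity, 1)
  expect_equal(edge$specificity, 1)
})

test_that("rank-sum p agrees with split enumeration and handles the null", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)),
               oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(60)
  for (sizes in list(c(3, 3), c(4, 6), c(5, 5), c(6, 7))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2])
    expect_equal(wilcoxon_rank_sum(x, y), oracle_ranksum_p(x, y),
                 info = paste(sizes, collapse = "x"))
  }
  # identical samples: no evidence of a shift
  x <- c(0.1, 0.4, 0.8, 0.2)
  expect_gte(wilcoxon_rank_sum(x, x), 0.8)
  expect_error(wilcoxon_rank_sum(1:2, 1:5), ">= 3")
})

test_that("rank-sum detects a one-SD shift in moderate samples", {
  hits <- vapply(1:20, function(s) {
    set.seed(600 + s)
    wilcoxon_rank_sum(rnorm(40), rnorm(40, 1)) < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("signed-rank p matches sign-pattern enumeration", {
  d8 <- c(0.11, 0.23, 0.34, 0.41, 0.52, 0.66, 0.71, 0.85)
  expect_equal(wilcoxon_signed_rank(d8), 2 / 256)
  expect_equal(wilcoxon_signed_rank(d8), 0.0078125)
  # three positive differences can never reach 0.05
  expect_equal(wilcoxon_signed_rank(c(0.2, 0.5, 0.9)), 0.25)
  set.seed(61)
  for (n in c(4, 6, 8, 10)) {
    d <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(d), oracle_signedrank_p(d), info = n)
  }
  # exactly sign-balanced differences carry no evidence
  expect_equal(wilcoxon_signed_rank(c(1, -1.5, 2, -2.5, 3, -3.5)),
               oracle_signedrank_p(c(1, -1.5, 2, -2.5, 3, -3.5)))
  expect_gte(wilcoxon_signed_rank(c(1, -1.5, 2, -2.5, 3, -3.5)), 0.8)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
})

test_that("signed-rank zero handling: drop by default, Pratt on request", {
  d <- c(0, 0.2, 0.5, -0.1, 0.7, 0.4, 0.3, 0.6, 0.8)
  expect_equal(wilcoxon_signed_rank(d), wilcoxon_signed_rank(d[d != 0]))
  p_pratt <- wilcoxon_signed_rank(d, zeros = "pratt")
  expect_true(p_pratt > 0 && p_pratt < 1)
})

test_that("compare_sample_types applies the right test per pair", {
  ch <- simulate_cohort(quick_config(), seed = 71)
  panel <- ch$truth$diff_probe_ids[1:5]
  spec <- tibble::tibble(
    type_a = c("bronchial_biopsy", "bronchial_biopsy"),
    type_b = c("tumor_tissue", "bronchial_washing"),
    paired = c(FALSE, TRUE)
  )
  cmp <- compare_sample_types(ch$beta, ch$samples, panel, spec)
  expect_s3_class(cmp, "surrogate_comparison")
  expect_equal(nrow(cmp), 10)
  expect_setequal(unique(cmp$test), c("rank_sum", "signed_rank"))
  # washing is strongly diluted relative to biopsy: positive median difference
  sr <- cmp[cmp$test == "signed_rank", ]
  expect_true(all(sr$median_diff > 0))
  expect_true(all(sr$p_value < 0.05))
  summ <- concordance_summary(cmp)
  expect_equal(nrow(summ), 2)
  expect_false(summ$concordant[summ$test == "signed_rank"])
  # paired comparison requires shared patients
  expect_error(
    compare_sample_types(ch$beta, ch$samples, panel,
                         tibble::tibble(type_a = "tumor_tissue",
                                        type_b = "control_washing",
                                        paired = TRUE)),
    "shared patients"
  )
  expect_error(
    compare_sample_types(ch$beta, ch$samples, panel,
                         tibble::tibble(type_a = "tumor_tissue",
                                        type_b = "saliva", paired = FALSE)),
    "missing"
  )
})

test_that("identical specimen distributions yield p = 1 everywhere", {
  m <- matrix(runif(40), 4, 10,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  m[, 6:10] <- m[, 1:5]  # second type duplicates the first
  samples <- tibble::tibble(
    sample_id = colnames(m),
    patient_id = rep(paste0("P", 1:5), 2),
    specimen_type = rep(c("tumor_tissue", "bronchial_biopsy"), each = 5),
    disease_label = "cancer", age = 60, sex = "M", histology = NA
  )
  cmp <- compare_sample_types(
    matrix_to_beta(m), samples, paste0("p", 1:4),
    tibble::tibble(type_a = "tumor_tissue", type_b = "bronchial_biopsy",
                   paired = FALSE)
  )
  expect_true(all(cmp$p_value == 1))
  expect_true(all(cmp$concordant_pair))
})

test_that("region_profile averages by region class and specimen type", {
  ann <- tibble::tibble(
    probe_id = paste0("p", 1:5), gene = "GENE1",
    region = c("TSS1500", "TSS200", "5UTR", "1stExon", "Body")
  )
  m <- matrix(0.5, 5, 4, dimnames = list(ann$probe_id, paste0("s", 1:4)))
  samples <- tibble::tibble(
    sample_id = colnames(m), patient_id = paste0("P", 1:4),
    specimen_type = rep(c("tumor_tissue", "sputum"), 2),
    disease_label = "cancer", age = 55, sex = "F", histology = NA
  )
  prof <- region_profile("GENE1", ann, matrix_to_beta(m), samples)
  expect_true(all(prof$mean_beta == 0.5))
  expect_equal(levels(prof$region),
               c("TSS1500", "TSS200", "5UTR", "1stExon", "Body"))
  # absent specimen types are omitted, not zero-filled
  expect_setequal(unique(prof$specimen_type), c("tumor_tissue", "sputum"))
  expect_error(region_profile("NOPE", ann, matrix_to_beta(m), samples),
               "unknown gene")
})

test_that("promoter-planted probes profile above the gene body in tumors", {
  ch <- simulate_cohort(quick_config(noise_sd = 0), seed = 81)
  diff_gene <- ch$annotation$gene[match(ch$truth$diff_probe_ids[1],
                                        ch$annotation$probe_id)]
  prof <- region_profile(diff_gene, ch$annotation, ch$beta, ch$samples)
  tum <- prof[prof$specimen_type == "tumor_tissue", ]
  promoter <- mean(tum$mean_beta[tum$region != "Body"])
  body <- tum$mean_beta[tum$region == "Body"]
  if (length(body)) expect_gt(promoter, body)
  # normal tissue stays at background everywhere
  nor <- prof[prof$specimen_type == "normal_tissue", ]
  expect_true(all(nor$mean_beta < 0.35))
})

test_that("plot constructors return ggplot objects", {
  ch <- simulate_cohort(quick_config(), seed = 91)
  bin <- dichotomize(ch$beta)
  dmr <- detect_dmrs(bin, ch$samples)
  expect_s3_class(ggplot2::autoplot(dmr), "ggplot")
  qc <- qc_control_curve(list("0" = c(0.1, 0.2), "1" = 0.97))
  expect_s3_class(ggplot2::autoplot(qc), "ggplot")
  cmp <- compare_sample_types(
    ch$beta, ch$samples, ch$truth$diff_probe_ids[1:3],
    tibble::tibble(type_a = "bronchial_biopsy", type_b = "tumor_tissue",
                   paired = FALSE)
  )
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
  gene <- ch$annotation$gene[match(ch$truth$diff_probe_ids[1],
                                   ch$annotation$probe_id)]
  prof <- region_profile(gene, ch$annotation, ch$beta, ch$samples)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  expect_s3_class(plot_roc(runif(20), rep(c(0, 1), 10)), "ggplot")
})
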