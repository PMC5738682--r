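#' Run the full panel-derivation pipeline
#'
#' Chains the five selection stages on a cohort: (i) probe filtering and
#' dichotomization, (ii) tumor-vs-normal differential methylation with
#' Bonferroni family-wise error control, (iii) removal of age-correlated
#' CpGs using normal-tissue samples, (iv) gene-set enrichment followed by
#' per-gene probe collapse and within-term correlation pruning, and (v)
#' logistic-regression fits of the candidate feature sets, ranked by
#' likelihood. The top-ranked model's roster is the derived panel.
#'
#' @param beta Beta tibble for the whole cohort.
#' @param samples Sample sheet matching `beta`; training uses
#'   `tumor_tissue` vs `normal_tissue` samples.
#' @param annotation Probe annotation (probe_id, gene, region).
#' @param gene_sets Gene-set tibble (term_id, term_label, genes).
#' @param max_missing_fraction Probe-filter cutoff (default 0.05).
#' @param beta_threshold Dichotomization threshold (default 0.3).
#' @param family_alpha Family-wise error rate for differential testing
#'   (default 0.05).
#' @param age_p_cutoff Age-correlation removal cutoff (default 1.1e-5).
#' @param age_scan_all Scan every retained probe for age correlation instead
#'   of only the differential hits (default FALSE).
#' @param go_cutoff Bonferroni cutoff for term selection (default 1e-5).
#' @param n_terms_keep Number of enriched terms carried into model building
#'   (default 3, by ascending raw p among selected terms).
#' @param corr_alpha Within-term correlation flagging level (default 0.05).
#' @param probes_per_term Integer vector, recycled over the selected terms
#'   (ordered by enrichment): how many CpGs each term contributes to the
#'   panel, keeping the smallest differential p per gene first. The default
#'   `c(4, 3, 3)` yields a 10-CpG panel from three terms.
#' @param max_sets,top See [enumerate_candidate_sets()] and [rank_models()].
#' @return A list of class `panel_pipeline` with each stage's result,
#'   `panel` (the selected CpG panel across terms) and `models` (candidate
#'   rosters drawn from the panel, ranked by likelihood).
#' @export
run_panel_pipeline <- function(beta, samples, annotation, gene_sets,
                               max_missing_fraction = 0.05,
                               beta_threshold = 0.3,
                               family_alpha = 0.05,
                               age_p_cutoff = 1.1e-5,
                               age_scan_all = FALSE,
                               go_cutoff = 1e-5,
                               n_terms_keep = 3,
                               corr_alpha = 0.05,
                               probes_per_term = c(4, 3, 3),
                               max_sets = 50,
                               top = 3) {
  check_sample_sheet(samples, beta)

  filt <- filter_probes(beta, max_missing_fraction)
  binary <- dichotomize(filt$beta, beta_threshold)
  dmr <- detect_dmrs(binary, samples, family_alpha, "hyper")
  dmr_hits <- dmr$probe_id[dmr$passes]
  if (!length(dmr_hits)) abort("no differentially methylated CpGs detected.")

  normals <- samples[samples$specimen_type == "normal_tissue", ]
  beta_normal <- filt$beta[, c("probe_id", normals$sample_id)]
  age_input <- if (age_scan_all) filt$beta$probe_id else dmr_hits
  age <- remove_age_related(age_input, beta_normal, normals$age, age_p_cutoff)
  kept <- setdiff(dmr_hits, age$removed$probe_id)

  collapsed <- best_probe_per_gene(dmr[dmr$probe_id %in% kept, ], annotation)
  enrichment <- go_enrichment(
    gene_sets, query_genes = collapsed$gene,
    background_genes = unique(annotation$gene),
    bonferroni_cutoff = go_cutoff
  )
  selected <- enrichment[enrichment$selected, ]
  if (!nrow(selected)) abort("no gene-set term passed the enrichment cutoff.")
  selected <- utils::head(selected, n_terms_keep)

  term_probes <- purrr::map(
    stats::setNames(selected$term_id, selected$term_id),
    function(tid) {
      genes <- gene_sets$genes[[match(tid, gene_sets$term_id)]]
      collapsed$probe_id[collapsed$gene %in% genes]
    }
  )
  term_probes <- term_probes[lengths(term_probes) > 0]
  if (!length(term_probes)) abort("selected terms contain no candidate probes.")

  # per-term panel contribution: best probes by differential p
  probe_order <- collapsed$probe_id[order(collapsed$p_value, collapsed$probe_id)]
  caps <- rep_len(probes_per_term, length(term_probes))
  term_probes <- purrr::imap(term_probes, function(probes, tid) {
    k <- caps[match(tid, names(term_probes))]
    sort(utils::head(probes[order(match(probes, probe_order))], k))
  })
  panel <- sort(unlist(term_probes, use.names = FALSE))

  tumors <- samples[samples$specimen_type == "tumor_tissue", ]
  beta_tumor <- filt$beta[, c("probe_id", tumors$sample_id)]
  correlations <- within_term_correlations(beta_tumor, term_probes, corr_alpha)

  candidates <- enumerate_candidate_sets(
    names(term_probes), term_probes, correlations,
    max_sets = max_sets, max_probes_per_term = max(caps),
    probe_order = probe_order
  )

  tissue <- samples[samples$specimen_type %in% c("tumor_tissue", "normal_tissue"), ]
  beta_train <- filt$beta[, c("probe_id", tissue$sample_id)]
  labels <- as.integer(tissue$specimen_type == "tumor_tissue")
  models <- rank_models(candidates, beta_train, labels, top = top)

  structure(
    list(
      filtered = filt, dmr = dmr, dmr_hits = dmr_hits, age = age,
      kept_probes = kept, collapsed = collapsed, enrichment = enrichment,
      selected_terms = selected$term_id, term_probes = term_probes,
      correlations = correlations, candidates = candidates,
      models = models, panel = panel, top_model = models$model[[1]],
      train_samples = tissue$sample_id, train_labels = labels
    ),
    class = "panel_pipeline"
  )
}

#' @export
print.panel_pipeline <- function(x, ...) {
  cat("<panel_pipeline>\n")
  cat("  differential CpGs:", length(x$dmr_hits),
      "(threshold", format(attr(x$dmr, "per_test_threshold"), digits = 2), ")\n")
  cat("  age-correlated removed:", nrow(x$age$removed), "\n")
  cat("  enriched terms used:", paste(x$selected_terms, collapse = ", "), "\n")
  cat("  candidate sets:", nrow(x$candidates),
      "| top panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a fitted panel on one specimen-type contrast
#'
#' Scores every sample of the case and control specimen types with the
#' model's predicted probability and reports AUC plus sensitivity and
#' specificity at the probability threshold.
#'
#' @param model A `panel_logit`.
#' @param beta Beta tibble holding the evaluation samples.
#' @param samples Sample sheet matching `beta`.
#' @param case_type,control_type Specimen types defining cases and controls.
#' @param threshold Positive-call probability threshold (default 0.5).
#' @return One-row tibble: case_type, control_type, auc, sensitivity,
#'   specificity, n_cases, n_controls.
#' @export
evaluate_model_on <- function(model, beta, samples, case_type, control_type,
                              threshold = 0.5) {
  sel <- samples[samples$specimen_type %in% c(case_type, control_type), ]
  if (!nrow(sel)) abort("no samples of the requested specimen types.")
  X <- t(beta_to_matrix(beta))[sel$sample_id, , drop = FALSE]
  scores <- predict_prob(model, X)
  y <- as.integer(sel$specimen_type == case_type)
  ss <- sens_spec_at_threshold(scores, y, threshold)
  tibble(
    case_type = case_type, control_type = control_type,
    auc = roc_auc(scores, y),
    sensitivity = ss$sensitivity, specificity = ss$specificity,
    n_cases = sum(y == 1), n_controls = sum(y == 0)
  )
}
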