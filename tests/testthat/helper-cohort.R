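# Small cohorts keep unit tests fast; acceptance tests use the full-size
# default configuration.
quick_config <- function(...) {
  defaults <- list(
    n_probes = 400, n_diff_probes = 12, n_age_probes = 3,
    n_samples = c(
      tumor_tissue = 20, normal_tissue = 20, bronchial_biopsy = 6,
      bronchial_washing = 20, control_washing = 20, sputum = 4
    ),
    n_genes = 120, genes_per_term = 5, n_background_terms = 8
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# clip to [0, 1] without dropping matrix dimensions
clip01 <- function(m) {
  m[] <- pmin(1, pmax(0, m))
  m
}

normal_beta_of <- function(cohort) {
  ids <- cohort$samples$sample_id[cohort$samples$specimen_type == "normal_tissue"]
  list(
    beta = cohort$beta[, c("probe_id", ids)],
    ages = cohort$samples$age[match(ids, cohort$samples$sample_id)]
  )
}
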