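#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

#' Convert a beta-value tibble to a numeric matrix
#'
#' Beta-value tables in this package are wide tibbles: a `probe_id` column
#' followed by one numeric column per sample. This helper converts to a
#' probes-by-samples matrix with probe ids as row names.
#'
#' @param beta A beta-value tibble (`probe_id` + sample columns).
#' @return Numeric matrix, rows = probes, columns = samples.
#' @export
beta_to_matrix <- function(beta) {
  check_beta_tbl(beta)
  m <- as.matrix(beta[setdiff(names(beta), "probe_id")])
  rownames(m) <- beta$probe_id
  storage.mode(m) <- "double"
  m
}

#' Convert a probes-by-samples matrix to a beta-value tibble
#'
#' @param m Numeric matrix with probe ids as row names.
#' @return Tibble with `probe_id` first, then sample columns.
#' @export
matrix_to_beta <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble(probe_id = rownames(m)), as_tibble(m))
}

# Validate the wide beta tibble contract: probe_id column, unique ids,
# numeric sample columns, values in [0,1] or NA.
check_beta_tbl <- function(beta, check_range = TRUE) {
  if (!is.data.frame(beta) || !"probe_id" %in% names(beta)) {
    abort("`beta` must be a data frame with a `probe_id` column.")
  }
  if (anyDuplicated(beta$probe_id)) abort("probe ids must be unique.")
  vals <- beta[setdiff(names(beta), "probe_id")]
  if (ncol(vals) == 0L) abort("`beta` has no sample columns.")
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("all sample columns of `beta` must be numeric.")
  }
  if (check_range) {
    rng <- range(as.matrix(vals), na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
      abort("beta values must lie in [0, 1] (or be missing).")
    }
  }
  invisible(beta)
}

check_sample_sheet <- function(samples, beta = NULL) {
  req <- c("sample_id", "specimen_type", "disease_label")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    abort(paste0("`samples` must contain columns: ", paste(req, collapse = ", "), "."))
  }
  if (anyDuplicated(samples$sample_id)) abort("sample ids must be unique.")
  if ("age" %in% names(samples) && any(samples$age <= 0, na.rm = TRUE)) {
    abort("ages must be positive where present.")
  }
  if (!is.null(beta)) {
    cols <- setdiff(names(beta), "probe_id")
    if (!setequal(cols, samples$sample_id)) {
      abort("sample ids in `samples` must match the sample columns of `beta`.")
    }
  }
  invisible(samples)
}

check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(!is.na(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    abort(sprintf(
      "`%s` must lie in %s.", name, if (open) "(0, 1)" else "[0, 1]"
    ))
  }
  invisible(x)
}

#' Per-test Bonferroni threshold
#'
#' The family-wise error rate is controlled by dividing the family-level
#' alpha by the number of tests performed; with the ~480,912 CpGs retained on
#' a 450K array and alpha = 0.05 this gives a per-test cutoff of 1.0E-07.
#'
#' @param family_alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests in the family.
#' @return The per-test p-value cutoff `family_alpha / n_tests`.
#' @export
bonferroni_threshold <- function(family_alpha, n_tests) {
  check_fraction(family_alpha, "family_alpha", open = TRUE)
  stopifnot(is.numeric(n_tests), n_tests >= 1)
  family_alpha / n_tests
}
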