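#' Compute beta values from methylated/unmethylated intensities
#'
#' The methylation level of a CpG is the ratio of methylated signal to total
#' signal, `M / (M + U + offset)`, ranging from 0 (unmethylated) to 1 (fully
#' methylated). Vectorised; returns `NA` where the denominator is zero.
#'
#' @param methylated,unmethylated Non-negative signal intensities.
#' @param offset Non-negative stabilising offset added to the denominator
#'   (default 0, a plain ratio; some array pipelines use 100).
#' @return Numeric vector of beta values in \[0, 1\] (or `NA`).
#' @examples
#' compute_beta(300, 100)  # 0.75
#' @export
compute_beta <- function(methylated, unmethylated, offset = 0) {
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE) ||
      any(offset < 0)) {
    abort("intensities and offset must be non-negative.")
  }
  denom <- methylated + unmethylated + offset
  ifelse(denom == 0, NA_real_, methylated / denom)
}

#' QC against methylation-standard control DNA
#'
#' Assay quality is checked by measuring control DNA mixed to predefined
#' methylation levels (e.g. 0, 33, 66 and 100%) and comparing observed mean
#' beta to the expected level. A positive bias above `tolerance` flags the
#' level as inflated (background signal typically inflates the low end).
#'
#' @param observed A data frame with columns `expected` (the nominal
#'   methylation fraction) and `beta` (observed values), or a named list
#'   mapping expected level to a numeric vector of observed betas.
#' @param tolerance Positive bias above which a level is flagged inflated
#'   (default 0.05).
#' @return A tibble of class `qc_report`: `expected`, `n`, `observed_mean`,
#'   `bias`, `inflated`.
#' @export
qc_control_curve <- function(observed, tolerance = 0.05) {
  if (!is.data.frame(observed)) {
    if (is.null(names(observed)) || !length(observed)) {
      abort("`observed` must be a data frame or a named list of beta vectors.")
    }
    observed <- purrr::imap_dfr(observed, function(v, nm) {
      tibble(expected = as.numeric(nm), beta = as.numeric(v))
    })
  }
  stopifnot(all(c("expected", "beta") %in% names(observed)))
  check_fraction(tolerance, "tolerance")
  if (!nrow(observed)) abort("no control observations supplied.")
  rep <- observed |>
    dplyr::group_by(expected = .data$expected) |>
    dplyr::summarise(
      n = dplyr::n(),
      observed_mean = mean(.data$beta, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bias = .data$observed_mean - .data$expected,
      inflated = .data$bias > tolerance
    )
  if (any(is.nan(rep$observed_mean))) abort("a standard level has no observations.")
  structure(rep, class = c("qc_report", class(rep)))
}

#' Remove probes with too many missing values
#'
#' Probe filtering uses a missing-fraction criterion: probes whose fraction
#' of missing beta values across samples exceeds `max_missing_fraction` are
#' dropped. When a `detection_p` data frame is supplied (probe_id, sample
#' columns of detection p-values), values failing `detection_p_cutoff` are
#' first set missing and the same fraction rule applies.
#'
#' @param beta Beta-value tibble.
#' @param max_missing_fraction Probes with a larger missing fraction are
#'   removed (default 0.05). A cutoff of 1 removes nothing.
#' @param detection_p Optional detection p-value table shaped like `beta`.
#' @param detection_p_cutoff Detection p-values at or above this are treated
#'   as failed measurements (default 0.01).
#' @return List with `beta` (filtered, input probe order preserved) and
#'   `removed` (probe ids, in input order).
#' @export
filter_probes <- function(beta, max_missing_fraction = 0.05,
                          detection_p = NULL, detection_p_cutoff = 0.01) {
  check_fraction(max_missing_fraction, "max_missing_fraction")
  m <- beta_to_matrix(beta)
  if (!is.null(detection_p)) {
    dp <- beta_to_matrix(check_beta_tbl(detection_p, check_range = FALSE))
    stopifnot(identical(dim(dp), dim(m)))
    m[dp >= detection_p_cutoff] <- NA_real_
  }
  miss_frac <- rowMeans(is.na(m))
  drop <- miss_frac > max_missing_fraction
  out <- beta[!drop, , drop = FALSE]
  if (!is.null(detection_p)) {
    out <- matrix_to_beta(m[!drop, , drop = FALSE])
  }
  list(beta = out, removed = beta$probe_id[drop])
}

#' Dichotomize beta values at a methylation threshold
#'
#' Calls a CpG methylated (1) when beta strictly exceeds the threshold and
#' unmethylated (0) otherwise; missing values stay missing. The default
#' threshold of 0.3 reflects array background signal in unmethylated DNA,
#' which sits almost entirely below beta = 0.3.
#'
#' @param beta Beta-value tibble.
#' @param threshold Dichotomization threshold in (0, 1); default 0.3.
#'   The comparison is strict (`beta > threshold`).
#' @return A tibble shaped like `beta` with 0/1/NA entries.
#' @export
dichotomize <- function(beta, threshold = 0.3) {
  check_fraction(threshold, "threshold", open = TRUE)
  m <- beta_to_matrix(beta)
  matrix_to_beta((m > threshold) + 0)
}
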