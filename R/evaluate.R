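#' ROC area under the curve (Mann-Whitney concordance)
#'
#' The AUC equals the probability that a randomly chosen case scores above a
#' randomly chosen control, with ties counted 0.5; computed from mid-ranks,
#' which is identical to exhaustive pairwise concordance.
#'
#' @param scores Numeric score per sample (higher = more case-like).
#' @param labels 0/1 (control/case) per sample; both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  keep <- !is.na(scores)
  scores <- scores[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present.")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a score threshold
#'
#' A sample is called positive when its score is at least `threshold`
#' (inclusive). Sensitivity is the fraction of cases called positive,
#' specificity the fraction of controls called negative.
#'
#' @param scores Numeric score per sample.
#' @param labels 0/1 per sample.
#' @param threshold Positive-call threshold (default 0.5, suited to
#'   predicted probabilities).
#' @return One-row tibble: sensitivity, specificity, threshold, n_cases,
#'   n_controls.
#' @export
sens_spec_at_threshold <- function(scores, labels, threshold = 0.5) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  if (!any(y == 1) || !any(y == 0)) abort("both classes must be present.")
  pos <- scores >= threshold
  tibble(
    sensitivity = mean(pos[y == 1]),
    specificity = mean(!pos[y == 0]),
    threshold = threshold,
    n_cases = sum(y == 1), n_controls = sum(y == 0)
  )
}

#' Wilcoxon rank-sum test (two independent samples, two-sided)
#'
#' Exact when the smaller group has at most 10 observations and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is used. Delegates to [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors (each >= 3 non-missing values).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) abort("each group needs >= 3 values.")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && min(length(x), length(y)) <= 10
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Wilcoxon signed-rank test (paired differences, two-sided)
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' treatment); with `zeros = "pratt"` they instead participate in the
#' ranking and are then discarded, handled by the normal approximation.
#' The null distribution is enumerated exactly over all `2^n` sign
#' assignments when at most 20 non-zero differences remain and their
#' absolute values are untied; otherwise the normal approximation with
#' corrections is used.
#'
#' @param differences Numeric vector of paired differences.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(differences, zeros = c("drop", "pratt")) {
  zeros <- match.arg(zeros)
  d <- differences[!is.na(differences)]
  if (!length(d) || all(d == 0)) abort("all differences are zero or missing.")
  if (zeros == "pratt") {
    # rank with zeros included, then discard their contribution; normal approx
    r <- rank(abs(d))
    nz <- d != 0
    V <- sum(r[nz & d > 0])
    n <- length(d)
    ev <- (n * (n + 1) / 2 - sum(r[!nz])) / 2
    sigma2 <- sum(r[nz]^2) / 4
    z <- (V - ev) / sqrt(sigma2)
    return(min(1, 2 * stats::pnorm(-abs(z))))
  }
  d <- d[d != 0]
  if (length(d) < 3) abort("need >= 3 non-zero differences.")
  exact <- length(d) <= 20 && anyDuplicated(abs(d)) == 0
  suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value
  )
}

#' Compare panel methylation across specimen types
#'
#' For each panel probe and each requested specimen-type pair, tests whether
#' beta values differ between the two types: unpaired pairs use the Wilcoxon
#' rank-sum test, paired pairs use the Wilcoxon signed-rank test on
#' patient-matched differences (type A minus type B). A pair of types is
#' summarised as concordant when every panel probe has p above `alpha`.
#'
#' @param beta Beta tibble.
#' @param samples Sample sheet matching `beta`.
#' @param probes Character vector of panel probe ids.
#' @param pairs_spec Tibble with columns `type_a`, `type_b`, `paired`
#'   (logical).
#' @param alpha Per-probe significance level for the concordance summary
#'   (default 0.05; per-CpG reporting, no multiplicity correction).
#' @return Tibble of class `surrogate_comparison`: type_a, type_b, test,
#'   probe_id, n_a, n_b, median_diff, p_value, concordant_pair.
#' @export
compare_sample_types <- function(beta, samples, probes, pairs_spec,
                                 alpha = 0.05) {
  check_sample_sheet(samples)
  stopifnot(all(c("type_a", "type_b", "paired") %in% names(pairs_spec)))
  m <- beta_to_matrix(beta)
  probes <- intersect(probes, rownames(m))
  if (!length(probes)) abort("none of the requested probes are in `beta`.")

  res <- purrr::map_dfr(seq_len(nrow(pairs_spec)), function(i) {
    ta <- pairs_spec$type_a[i]; tb <- pairs_spec$type_b[i]
    paired <- isTRUE(pairs_spec$paired[i])
    sa <- samples[samples$specimen_type == ta, ]
    sb <- samples[samples$specimen_type == tb, ]
    if (!nrow(sa) || !nrow(sb)) {
      abort(sprintf("specimen type missing from cohort: %s / %s", ta, tb))
    }
    if (paired) {
      shared <- intersect(sa$patient_id, sb$patient_id)
      if (!length(shared)) abort(sprintf("no shared patients for %s vs %s.", ta, tb))
      ia <- sa$sample_id[match(shared, sa$patient_id)]
      ib <- sb$sample_id[match(shared, sb$patient_id)]
    }
    purrr::map_dfr(probes, function(pr) {
      if (paired) {
        dvec <- m[pr, ia] - m[pr, ib]
        p <- wilcoxon_signed_rank(dvec)
        md <- stats::median(dvec, na.rm = TRUE)
        na <- nb <- length(dvec)
      } else {
        xa <- m[pr, sa$sample_id]; xb <- m[pr, sb$sample_id]
        p <- if (isTRUE(all.equal(sort(xa), sort(xb)))) 1 else wilcoxon_rank_sum(xa, xb)
        md <- stats::median(xa, na.rm = TRUE) - stats::median(xb, na.rm = TRUE)
        na <- sum(!is.na(xa)); nb <- sum(!is.na(xb))
      }
      tibble(type_a = ta, type_b = tb,
             test = if (paired) "signed_rank" else "rank_sum",
             probe_id = pr, n_a = na, n_b = nb,
             median_diff = md, p_value = p)
    })
  })
  res <- res |>
    dplyr::group_by(.data$type_a, .data$type_b) |>
    dplyr::mutate(concordant_pair = all(.data$p_value > alpha)) |>
    dplyr::ungroup()
  class(res) <- c("surrogate_comparison", class(res))
  res
}

#' Per-pair concordance summary of a surrogate comparison
#'
#' @param comparison Result of [compare_sample_types()].
#' @param alpha Per-probe significance level (default 0.05).
#' @return Tibble: type_a, type_b, test, n_probes, n_significant, concordant.
#' @export
concordance_summary <- function(comparison, alpha = 0.05) {
  comparison |>
    dplyr::group_by(.data$type_a, .data$type_b, .data$test) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      n_significant = sum(.data$p_value <= alpha),
      concordant = all(.data$p_value > alpha),
      .groups = "drop"
    )
}

#' Mean methylation per gene region class and specimen type
#'
#' Averages beta values (missing-aware) of a gene's probes within each
#' region class (TSS1500, TSS200, 5'UTR, first exon, gene body) for each
#' specimen type present in the cohort. Tumor-specific promoter
#' hypermethylation appears as high promoter-class means in high-purity
#' specimens with a quiet gene body.
#'
#' @param gene Gene symbol.
#' @param annotation Probe annotation (probe_id, gene, region).
#' @param beta Beta tibble.
#' @param samples Sample sheet matching `beta`.
#' @return Tibble of class `region_profile`: region (ordered factor),
#'   specimen_type, n_probes, mean_beta. Specimen types absent from the
#'   cohort are omitted.
#' @export
region_profile <- function(gene, annotation, beta, samples) {
  probes <- annotation$probe_id[annotation$gene == gene]
  if (!length(probes)) abort(sprintf("unknown gene: %s", gene))
  region_levels <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body")
  long <- beta[beta$probe_id %in% probes, , drop = FALSE] |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id", values_to = "beta") |>
    dplyr::inner_join(annotation[, c("probe_id", "region")], by = "probe_id") |>
    dplyr::inner_join(samples[, c("sample_id", "specimen_type")], by = "sample_id")
  out <- long |>
    dplyr::group_by(
      region = factor(.data$region, levels = region_levels),
      specimen_type = .data$specimen_type
    ) |>
    dplyr::summarise(
      n_probes = dplyr::n_distinct(.data$probe_id),
      mean_beta = mean(.data$beta, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$region, .data$specimen_type)
  class(out) <- c("region_profile", class(out))
  out
}
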