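#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_tile
#'   geom_line geom_hline facet_wrap labs scale_fill_gradientn theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Volcano-style view of a differential-methylation scan
#'
#' Plots each probe's tumor-minus-normal difference in methylated proportion
#' against -log10 p, highlighting probes that pass the Bonferroni threshold.
#'
#' @param object A `dmr_result` from [detect_dmrs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmr_result
#' @export
autoplot.dmr_result <- function(object, ...) {
  df <- dplyr::mutate(
    as_tibble(object),
    prop_diff = .data$a / pmax(.data$a + .data$b, 1) -
      .data$c / pmax(.data$c + .data$d, 1),
    neglog_p = -log10(pmax(.data$p_value, 1e-300))
  )
  thr <- attr(object, "per_test_threshold")
  ggplot(df, aes(.data$prop_diff, .data$neglog_p, colour = .data$passes)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    labs(x = "methylated proportion difference (tumor - normal)",
         y = expression(-log[10]~italic(p)),
         colour = "passes threshold") +
    theme_minimal()
}

#' Control-standard QC curve
#'
#' Observed mean beta against the nominal methylation level of each control
#' standard; points above the identity line indicate background inflation.
#'
#' @param object A `qc_report` from [qc_control_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(.data$expected, .data$observed_mean, colour = .data$inflated)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    geom_point(size = 3) +
    labs(x = "nominal methylation level", y = "observed mean beta",
         colour = "inflated") +
    theme_minimal()
}

#' Per-probe surrogate comparison plot
#'
#' -log10 p per panel probe, one facet per specimen-type contrast, with the
#' per-probe alpha marked.
#'
#' @param object A `surrogate_comparison` from [compare_sample_types()].
#' @param alpha Reference significance level (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot surrogate_comparison
#' @export
autoplot.surrogate_comparison <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(
    as_tibble(object),
    contrast = paste(.data$type_a, "vs", .data$type_b),
    neglog_p = -log10(pmax(.data$p_value, 1e-300))
  )
  ggplot(df, aes(.data$probe_id, .data$neglog_p)) +
    geom_point() +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    facet_wrap(~contrast, scales = "free_y") +
    labs(x = NULL, y = expression(-log[10]~italic(p))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Region-by-specimen methylation heatmap for one gene
#'
#' Mean beta per gene region class and specimen type as a tile map, using
#' the conventional green (unmethylated) to red (methylated) spectrum.
#'
#' @param object A `region_profile` from [region_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot region_profile
#' @export
autoplot.region_profile <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(.data$region, .data$specimen_type, fill = .data$mean_beta)) +
    geom_tile(colour = "grey90") +
    scale_fill_gradientn(colours = c("#1a9850", "#fee08b", "#d73027"),
                         limits = c(0, 1), name = "mean beta") +
    labs(x = "region class", y = NULL) +
    theme_minimal()
}

#' Empirical ROC curve
#'
#' @param scores Numeric score per sample.
#' @param labels 0/1 per sample.
#' @return A ggplot object with the ROC curve and its AUC in the subtitle.
#' @export
plot_roc <- function(scores, labels) {
  y <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y[ord] == 0) / sum(y == 0))
  ggplot(tibble(fpr = fpr, tpr = tpr), aes(.data$fpr, .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "1 - specificity", y = "sensitivity",
         subtitle = sprintf("AUC = %.3f", roc_auc(scores, y))) +
    theme_minimal()
}
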