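#' Tally a 2x2 methylation contingency table for one probe
#'
#' Counts samples by group (tumor / normal) and methylation call (1 / 0),
#' dropping missing calls pairwise.
#'
#' @param binary_row 0/1/NA methylation calls, one per sample.
#' @param labels Group label per sample; values in `c("tumor", "normal")`.
#' @return Named numeric vector `c(a, b, c, d)`: a = tumor & methylated,
#'   b = tumor & unmethylated, c = normal & methylated, d = normal &
#'   unmethylated.
#' @export
contingency_from_groups <- function(binary_row, labels) {
  stopifnot(length(binary_row) == length(labels))
  if (!all(labels %in% c("tumor", "normal"))) {
    abort('`labels` must be "tumor" or "normal".')
  }
  keep <- !is.na(binary_row)
  if (!any(keep)) abort("all methylation calls are missing for this probe.")
  x <- binary_row[keep]
  g <- labels[keep]
  if (!all(x %in% c(0, 1))) abort("`binary_row` must be 0/1/NA.")
  c(
    a = sum(g == "tumor" & x == 1), b = sum(g == "tumor" & x == 0),
    c = sum(g == "normal" & x == 1), d = sum(g == "normal" & x == 0)
  )
}

#' Pearson chi-square test for a 2x2 table
#'
#' The canonical Pearson statistic `sum((O - E)^2 / E)` on 1 degree of
#' freedom, without continuity correction, with an upper-tail chi-square
#' p-value. Callers should route tables with small expected counts to
#' [fisher_exact_test()] (as [detect_dmrs()] does).
#'
#' @param table Numeric vector `c(a, b, c, d)` (row-major 2x2 counts).
#' @return Two-sided (upper-tail) p-value.
#' @export
chi_square_test <- function(table) {
  tab <- check_table2x2(table)
  n <- sum(tab)
  rs <- c(tab[1] + tab[2], tab[3] + tab[4])
  cs <- c(tab[1] + tab[3], tab[2] + tab[4])
  if (any(rs == 0) || any(cs == 0)) {
    abort("degenerate table: a row or column margin is zero.")
  }
  e <- outer(rs, cs) / n
  o <- matrix(tab, 2, byrow = TRUE)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Exact conditional test: with margins fixed, the two-sided p-value is the
#' sum of hypergeometric probabilities of all tables whose probability does
#' not exceed that of the observed table.
#'
#' @param table Numeric vector `c(a, b, c, d)`.
#' @return Two-sided exact p-value.
#' @export
fisher_exact_test <- function(table) {
  tab <- check_table2x2(table)
  fisher_p_counts(tab[1], tab[2], tab[3], tab[4])
}

# scalar two-sided Fisher p from counts; relative tolerance guards ties in
# floating point, matching stats::fisher.test's treatment
fisher_p_counts <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

check_table2x2 <- function(table) {
  tab <- as.numeric(table)
  if (length(tab) != 4 || any(is.na(tab)) || any(tab < 0) ||
      any(tab != round(tab))) {
    abort("`table` must be four non-negative integer counts c(a, b, c, d).")
  }
  if (sum(tab) == 0) abort("`table` must have a positive total.")
  tab
}

#' Detect tumor-hypermethylated CpGs with family-wise error control
#'
#' Tests each probe's dichotomized calls for association with group via a
#' 2x2 contingency table: Pearson chi-square when all expected cell counts
#' are at least 5, otherwise Fisher's exact test (Cochran's rule). The
#' per-test threshold is `family_alpha / n probes tested` (Bonferroni), and
#' a probe passes when `p <= threshold` and its direction matches
#' `direction_filter` (default hypermethylated in tumor, i.e. a larger
#' methylated proportion in the tumor row).
#'
#' @param binary Dichotomized beta tibble (from [dichotomize()]).
#' @param labels Either a character vector ("tumor"/"normal") aligned with
#'   the sample columns of `binary`, or a sample sheet from which tissue
#'   labels are derived (`tumor_tissue` -> tumor, `normal_tissue` -> normal;
#'   other specimen types are dropped).
#' @param family_alpha Family-wise error rate in (0, 1); default 0.05.
#' @param direction_filter `"hyper"` (default) or `"both"`.
#' @return Tibble of class `dmr_result`: probe_id, a, b, c, d, method,
#'   p_value, direction, passes, with the per-test threshold as attribute
#'   `per_test_threshold`.
#' @export
detect_dmrs <- function(binary, labels, family_alpha = 0.05,
                        direction_filter = c("hyper", "both")) {
  direction_filter <- match.arg(direction_filter)
  check_fraction(family_alpha, "family_alpha", open = TRUE)
  m <- beta_to_matrix(binary)
  if (is.data.frame(labels)) {
    sheet <- check_sample_sheet(labels)
    keep <- sheet$specimen_type %in% c("tumor_tissue", "normal_tissue")
    sheet <- sheet[keep, ]
    m <- m[, sheet$sample_id, drop = FALSE]
    labels <- ifelse(sheet$specimen_type == "tumor_tissue", "tumor", "normal")
  }
  stopifnot(length(labels) == ncol(m))
  if (!all(labels %in% c("tumor", "normal"))) {
    abort('`labels` must be "tumor" or "normal".')
  }
  if (sum(labels == "tumor") < 2 || sum(labels == "normal") < 2) {
    abort("need at least 2 samples per group.")
  }

  is_t <- labels == "tumor"
  a <- rowSums(m[, is_t, drop = FALSE] == 1, na.rm = TRUE)
  b <- rowSums(m[, is_t, drop = FALSE] == 0, na.rm = TRUE)
  cc <- rowSums(m[, !is_t, drop = FALSE] == 1, na.rm = TRUE)
  d <- rowSums(m[, !is_t, drop = FALSE] == 0, na.rm = TRUE)
  a <- unname(a); b <- unname(b); cc <- unname(cc); d <- unname(d)
  n <- a + b + cc + d
  if (any(n == 0)) abort("a probe has no non-missing calls.")

  # expected counts from margins; Fisher whenever any expected count < 5
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  min_expected <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  use_fisher <- min_expected < 5

  p <- numeric(length(a))
  flat <- c1 == 0 | c2 == 0            # constant call across all samples
  p[flat] <- 1
  chi_idx <- which(!use_fisher & !flat)
  if (length(chi_idx)) {
    e11 <- r1[chi_idx] * c1[chi_idx] / n[chi_idx]
    e12 <- r1[chi_idx] * c2[chi_idx] / n[chi_idx]
    e21 <- r2[chi_idx] * c1[chi_idx] / n[chi_idx]
    e22 <- r2[chi_idx] * c2[chi_idx] / n[chi_idx]
    stat <- (a[chi_idx] - e11)^2 / e11 + (b[chi_idx] - e12)^2 / e12 +
      (cc[chi_idx] - e21)^2 / e21 + (d[chi_idx] - e22)^2 / e22
    p[chi_idx] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  fis_idx <- which(use_fisher & !flat)
  for (i in fis_idx) p[i] <- fisher_p_counts(a[i], b[i], cc[i], d[i])

  prop_t <- ifelse(r1 > 0, a / r1, NA_real_)
  prop_n <- ifelse(r2 > 0, cc / r2, NA_real_)
  direction <- ifelse(!is.na(prop_t) & !is.na(prop_n) & prop_t > prop_n,
                      "hyper", "hypo")
  threshold <- bonferroni_threshold(family_alpha, length(a))
  passes <- p <= threshold &
    (direction_filter == "both" | direction == "hyper")

  out <- tibble(
    probe_id = rownames(m), a = a, b = b, c = cc, d = d,
    method = ifelse(use_fisher, "fisher_exact", "chi_square"),
    p_value = p, direction = direction, passes = passes
  )
  attr(out, "per_test_threshold") <- threshold
  class(out) <- c("dmr_result", class(out))
  out
}
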