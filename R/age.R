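#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Pairs with a
#' missing value in either vector are removed first.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return The rank correlation rho in \[-1, 1\], or `NA` when either vector
#'   is constant after missing removal.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Two-sided p-value for a Spearman correlation
#'
#' For n < 10 the p-value is exact, enumerating all n! permutations of one
#' rank vector (ties kept as mid-ranks). For n >= 10 it uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom. At `|rho| = 1` the approximate branch underflows to 0.
#'
#' @param rho Observed rank correlation.
#' @param n Number of pairs (>= 3).
#' @param x,y Optional original vectors; supplying them lets the exact
#'   branch respect the tie structure (otherwise untied ranks are assumed).
#' @return Two-sided p-value.
#' @export
spearman_p <- function(rho, n, x = NULL, y = NULL) {
  stopifnot(n >= 3)
  if (is.na(rho)) return(NA_real_)
  if (n < 10) {
    rx <- if (is.null(x)) seq_len(n) else rank(x)
    ry <- if (is.null(y)) seq_len(n) else rank(y)
    perms <- all_permutations(n)
    rx_c <- as.numeric(scale(rx))
    ry_c <- as.numeric(scale(ry))
    # rho under each permutation of the y ranks
    rho_perm <- (matrix(ry_c[perms], nrow = nrow(perms)) %*% rx_c) / (n - 1)
    return(mean(abs(rho_perm) >= abs(rho) - 1e-12))
  }
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.xmin))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# all n! permutations of 1..n as an n! x n integer matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Age correlation of each probe in normal tissue
#'
#' Computes the Spearman correlation and p-value between each probe's beta
#' values and patient age across the supplied (normal-tissue) samples.
#'
#' @param beta_normal Beta tibble restricted to normal-tissue samples.
#' @param ages Age (years) per sample, aligned with the sample columns.
#' @return Tibble: probe_id, rho, p_value, n.
#' @export
age_correlations <- function(beta_normal, ages) {
  m <- beta_to_matrix(beta_normal)
  stopifnot(length(ages) == ncol(m))
  if (any(is.na(ages))) abort("ages must be available for all normal samples.")
  res <- apply(m, 1, function(v) {
    keep <- !is.na(v)
    nn <- sum(keep)
    if (nn < 3) return(c(NA_real_, NA_real_, nn))
    r <- spearman_rho(v[keep], ages[keep])
    p <- if (is.na(r)) NA_real_ else spearman_p(r, nn, v[keep], ages[keep])
    c(r, p, nn)
  })
  tibble(
    probe_id = rownames(m),
    rho = res[1, ], p_value = res[2, ], n = as.integer(res[3, ])
  )
}

#' Remove age-correlated CpGs from a probe list
#'
#' Drops probes whose methylation in normal tissue shows a significant
#' positive Spearman correlation with patient age (`rho > 0` and
#' `p < p_cutoff`). The default cutoff 1.1E-05 reproduces the printed
#' screening threshold; numerically it equals 0.05 / 4,726 to two
#' significant figures, consistent with (but not stated as) a Bonferroni
#' correction over a differential set of that size.
#'
#' @param dmr_probes Character vector of candidate probe ids (kept order is
#'   preserved).
#' @param beta_normal Beta tibble restricted to normal-tissue samples.
#' @param ages Age per sample, aligned with the columns of `beta_normal`.
#' @param p_cutoff Significance cutoff in (0, 1); default 1.1e-5.
#' @param positive_only Remove only positively correlated probes (default
#'   TRUE); with FALSE, significant correlations of either sign are removed.
#' @return List with `kept` (probe ids, input order) and `removed` (tibble
#'   of age correlations for the removed probes).
#' @export
remove_age_related <- function(dmr_probes, beta_normal, ages,
                               p_cutoff = 1.1e-5, positive_only = TRUE) {
  check_fraction(p_cutoff, "p_cutoff", open = TRUE)
  beta_sub <- beta_normal[beta_normal$probe_id %in% dmr_probes, , drop = FALSE]
  corr <- age_correlations(beta_sub, ages)
  corr$removed <- !is.na(corr$p_value) & corr$p_value < p_cutoff &
    (if (positive_only) corr$rho > 0 else TRUE)
  removed_ids <- corr$probe_id[corr$removed]
  list(
    kept = dmr_probes[!dmr_probes %in% removed_ids],
    removed = corr[corr$removed, c("probe_id", "rho", "p_value", "n")],
    correlations = corr
  )
}
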