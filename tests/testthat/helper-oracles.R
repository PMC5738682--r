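# Independent brute-force oracles used to validate the package's statistical
# primitives. These deliberately avoid the code paths they check.

# two-sided Fisher p by summing manually computed hypergeometric
# probabilities of every table sharing the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lp <- function(x) {
    lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  }
  support <- max(0, k - n2):min(k, m)
  probs <- exp(vapply(support, lp, numeric(1)))
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Pearson chi-square p for a 2x2 from the definitional formula
oracle_chisq_p <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

# exact two-sided rank-sum p by enumerating every assignment of ranks to
# the first group: p = min(1, 2 * min(P(W <= w), P(W >= w)))
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  splits <- utils::combn(n + m, n)
  w_all <- colSums(matrix(r[splits], nrow = n))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# AUC by exhaustive case/control pair concordance
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (s in cases) for (t in ctrls) {
    tot <- tot + if (s > t) 1 else if (s == t) 0.5 else 0
  }
  tot / (length(cases) * length(ctrls))
}

# Spearman rho from the classic tie-free rank-difference formula
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# upper-tail hypergeometric enrichment p from binomial coefficients
oracle_hyper_p <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# all maximal independent sets of a conflict graph by brute-force subset
# enumeration (vertices as character ids, edges as a 2-column matrix)
oracle_mis <- function(vertices, edges) {
  nv <- length(vertices)
  is_independent <- function(sub) {
    if (nrow(edges) == 0) return(TRUE)
    !any(edges[, 1] %in% sub & edges[, 2] %in% sub)
  }
  subsets <- lapply(seq_len(2^nv) - 1, function(mask) {
    vertices[bitwAnd(mask, 2^(seq_len(nv) - 1)) > 0]
  })
  ind <- Filter(is_independent, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(vertices, s), function(v) {
      is_independent(c(s, v))
    }, logical(1)))
  }, ind)
  lapply(maximal, sort)
}
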