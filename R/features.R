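#' Hypergeometric gene-set over-representation test
#'
#' For each term, tests whether the query genes are over-represented using
#' the upper-tail hypergeometric probability `P(X >= k)` of drawing `k`
#' term genes when sampling `n` query genes from a background of `N` genes
#' of which `K` belong to the term, with Bonferroni correction over the
#' number of terms tested. This is a transparent single-test-per-term
#' replacement for fuzzy annotation clustering.
#'
#' @param gene_sets Tibble with `term_id`, `term_label` and a `genes`
#'   list-column (see [read_gene_sets()]).
#' @param query_genes Character vector of query gene symbols (must be a
#'   subset of `background_genes`).
#' @param background_genes Character vector defining the gene universe.
#' @param bonferroni_cutoff Terms with Bonferroni-corrected p below this are
#'   marked selected (default 1e-5).
#' @return Tibble: term_id, term_label, k, K, n, N, p_raw, p_bonferroni,
#'   selected, ordered by p_raw.
#' @export
go_enrichment <- function(gene_sets, query_genes, background_genes,
                          bonferroni_cutoff = 1e-5) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  if (!length(query_genes) || !length(background_genes)) {
    abort("query and background gene sets must be non-empty.")
  }
  if (!all(query_genes %in% background_genes)) {
    abort("`query_genes` must be a subset of `background_genes`.")
  }
  N <- length(background_genes)
  n <- length(query_genes)
  n_terms <- nrow(gene_sets)
  res <- purrr::map_dfr(seq_len(n_terms), function(i) {
    members <- intersect(gene_sets$genes[[i]], background_genes)
    K <- length(members)
    k <- length(intersect(members, query_genes))
    p_raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term_id = gene_sets$term_id[i], term_label = gene_sets$term_label[i],
           k = k, K = K, n = n, N = N, p_raw = p_raw)
  })
  res |>
    dplyr::mutate(
      p_bonferroni = pmin(1, .data$p_raw * n_terms),
      selected = .data$p_bonferroni < bonferroni_cutoff
    ) |>
    dplyr::arrange(.data$p_raw)
}

#' Keep one CpG per gene
#'
#' When a gene carries several candidate CpGs, retains the one with the
#' smallest differential-methylation p-value (ties broken by probe id).
#'
#' @param dmr A [detect_dmrs()] result (or any tibble with probe_id and
#'   p_value) restricted to the candidate probes.
#' @param annotation Probe annotation tibble (probe_id, gene).
#' @return Tibble probe_id, gene, p_value with one row per gene.
#' @export
best_probe_per_gene <- function(dmr, annotation) {
  dmr |>
    dplyr::select("probe_id", "p_value") |>
    dplyr::inner_join(annotation[, c("probe_id", "gene")], by = "probe_id") |>
    dplyr::arrange(.data$p_value, .data$probe_id) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
}

#' Within-term Spearman correlations of panel candidates
#'
#' For every unordered probe pair within a term, computes the Spearman
#' correlation of their beta values across tumor samples; a pair is flagged
#' when its p-value is below `alpha`. Flagged pairs are later forbidden from
#' entering the same model together.
#'
#' @param beta_tumor Beta tibble restricted to tumor samples (>= 3).
#' @param term_probes Named list mapping term id to its candidate probe ids.
#' @param alpha Per-pair significance level (default 0.05).
#' @return Tibble: term_id, probe_a, probe_b, rho, p_value, flagged.
#' @export
within_term_correlations <- function(beta_tumor, term_probes, alpha = 0.05) {
  check_fraction(alpha, "alpha", open = TRUE)
  m <- beta_to_matrix(beta_tumor)
  if (ncol(m) < 3) abort("need at least 3 tumor samples.")
  purrr::imap_dfr(term_probes, function(probes, term) {
    probes <- intersect(probes, rownames(m))
    if (length(probes) < 2) return(tibble())
    pairs <- utils::combn(sort(probes), 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      va <- m[pairs[1, j], ]; vb <- m[pairs[2, j], ]
      keep <- !is.na(va) & !is.na(vb)
      if (sum(keep) < 3 || stats::sd(va[keep]) == 0 || stats::sd(vb[keep]) == 0) {
        warn(sprintf("skipping constant/short pair %s-%s in %s",
                     pairs[1, j], pairs[2, j], term))
        return(tibble())
      }
      r <- spearman_rho(va[keep], vb[keep])
      p <- spearman_p(r, sum(keep), va[keep], vb[keep])
      tibble(term_id = term, probe_a = pairs[1, j], probe_b = pairs[2, j],
             rho = r, p_value = p, flagged = p < alpha)
    })
  })
}

#' Enumerate correlation-pruned candidate feature sets
#'
#' Within each selected term, builds a conflict graph (vertices = candidate
#' probes, edges = flagged correlated pairs) and enumerates its maximal
#' independent sets, so that no two significantly correlated CpGs from the
#' same term enter a model together. Candidate feature sets are all
#' cross-term combinations of these within-term sets, truncated per term at
#' `max_probes_per_term`, ordered lexicographically by roster and capped at
#' `max_sets`. Enumeration is exact for conflict graphs of up to
#' `exact_limit` vertices; beyond that a single greedy independent set is
#' built, admitting probes in `probe_order` (best first).
#'
#' @param selected_terms Character vector of term ids to use.
#' @param term_probes Named list: term id -> candidate probe ids.
#' @param correlated_pairs Tibble from [within_term_correlations()] (only
#'   rows with `flagged = TRUE` are used).
#' @param max_sets Maximum number of candidate sets returned (default 50).
#' @param max_probes_per_term Per-term roster cap (default 4).
#' @param exact_limit Exact-enumeration size limit (default 20 vertices).
#' @param probe_order Optional character vector giving the preference order
#'   of probes (e.g. by ascending differential p); defaults to lexicographic.
#' @return Tibble of class `candidate_sets`: set_id, probes (list-column),
#'   provenance (list-column of the term each probe came from), size.
#' @export
enumerate_candidate_sets <- function(selected_terms, term_probes,
                                     correlated_pairs, max_sets = 50,
                                     max_probes_per_term = 4,
                                     exact_limit = 20, probe_order = NULL) {
  if (max_sets < 1) abort("`max_sets` must be at least 1.")
  if (!length(selected_terms)) abort("need at least one selected term.")
  flagged <- correlated_pairs[correlated_pairs$flagged %in% TRUE, , drop = FALSE]

  pref_rank <- function(p) {
    if (is.null(probe_order)) rank(p) else match(p, probe_order)
  }

  per_term <- lapply(selected_terms, function(term) {
    probes <- sort(term_probes[[term]])
    if (is.null(probes) || !length(probes)) abort(sprintf("term %s has no probes.", term))
    edges <- flagged[flagged$term_id == term &
                       flagged$probe_a %in% probes &
                       flagged$probe_b %in% probes, , drop = FALSE]
    sets <- maximal_independent_sets(probes, edges, exact_limit, pref_rank)
    # per-term truncation: keep the preferred max_probes_per_term members
    sets <- lapply(sets, function(s) {
      s <- s[order(pref_rank(s), s)]
      sort(utils::head(s, max_probes_per_term))
    })
    unique(sets)
  })

  combos <- purrr::reduce(per_term, function(acc, sets) {
    purrr::map(acc, function(a) purrr::map(sets, function(s) c(a, list(s)))) |>
      purrr::flatten()
  }, .init = list(list()))

  rosters <- purrr::map(combos, function(parts) {
    probes <- unlist(parts)
    prov <- rep(selected_terms, lengths(parts))
    ord <- order(probes)
    list(probes = probes[ord], provenance = prov[ord])
  })
  keys <- vapply(rosters, function(r) paste(r$probes, collapse = "|"), character(1))
  rosters <- rosters[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  rosters <- rosters[order(keys)]
  rosters <- utils::head(rosters, max_sets)

  out <- tibble(
    set_id = sprintf("set%03d", seq_along(rosters)),
    probes = purrr::map(rosters, "probes"),
    provenance = purrr::map(rosters, "provenance"),
    size = lengths(purrr::map(rosters, "probes"))
  )
  class(out) <- c("candidate_sets", class(out))
  out
}

# maximal independent sets of the conflict graph over `probes` with edge
# list `edges` (probe_a, probe_b); exact via the complement-graph cliques
# for small graphs, greedy otherwise
maximal_independent_sets <- function(probes, edges, exact_limit, pref_rank) {
  if (!nrow(edges)) return(list(probes))
  g <- igraph::graph_from_data_frame(
    edges[, c("probe_a", "probe_b")], directed = FALSE,
    vertices = data.frame(name = probes)
  )
  if (length(probes) <= exact_limit) {
    sets <- igraph::max_ivs(g)
    return(lapply(sets, function(s) sort(names(s))))
  }
  # greedy: admit probes best-first, skipping neighbours of admitted ones
  adj <- igraph::as_adj_list(g)
  names(adj) <- igraph::V(g)$name
  chosen <- character(0)
  for (p in probes[order(pref_rank(probes), probes)]) {
    nbrs <- names(adj[[p]])
    if (!any(nbrs %in% chosen)) chosen <- c(chosen, p)
  }
  list(sort(chosen))
}
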