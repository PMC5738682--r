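#' Write a simulated cohort to plain-text files
#'
#' Emits the beta matrix as TSV (probes as rows, header of sample ids), the
#' sample sheet as CSV, the probe annotation as TSV, the gene sets as GMT and
#' the planted truth as JSON.
#'
#' @param cohort A `meth_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, "beta.tsv"),
    samples = file.path(dir, "samples.csv"),
    annotation = file.path(dir, "annotation.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(cohort$beta, paths[["beta"]])
  readr::write_csv(cohort$samples, paths[["samples"]])
  readr::write_tsv(cohort$annotation, paths[["annotation"]])
  write_gene_sets(cohort$gene_sets, paths[["gene_sets"]])
  truth <- cohort$truth
  truth$config <- truth$config[!vapply(truth$config, is.null, logical(1))]
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a beta-value matrix from TSV
#'
#' Expects the dialect written by [write_cohort()]: a `probe_id` column and
#' one numeric column per sample.
#'
#' @param path Path to a TSV file.
#' @return A beta-value tibble.
#' @export
read_beta_matrix <- function(path) {
  beta <- readr::read_tsv(path, show_col_types = FALSE)
  check_beta_tbl(beta)
  beta
}

#' Read a sample sheet from CSV
#' @param path Path to a CSV file with at least sample_id, specimen_type,
#'   disease_label columns.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  samples <- readr::read_csv(path, show_col_types = FALSE)
  check_sample_sheet(samples)
  samples
}

#' Read a probe annotation table from TSV
#' @param path Path to a TSV with probe_id, gene, region columns.
#' @return A tibble.
#' @export
read_probe_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("probe_id", "gene", "region") %in% names(ann)))
  ann
}

#' Read a gene-set collection from a GMT file
#'
#' Parsing is delegated to [fgsea::gmtPathways()]; the GMT description field
#' is not retained, so `term_label` equals `term_id` on read.
#'
#' @param path Path to a GMT file.
#' @return Tibble with `term_id`, `term_label` and a `genes` list-column.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  tibble(term_id = names(sets), term_label = names(sets),
         genes = unname(sets))
}

#' Write a gene-set collection to GMT
#' @param gene_sets Tibble with term_id, term_label, genes (list-column).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(c(gene_sets$term_id[i], gene_sets$term_label[i],
            gene_sets$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
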