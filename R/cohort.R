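#' Configuration for the synthetic bronchoscopy cohort generator
#'
#' Builds the parameter list consumed by [simulate_cohort()]. The defaults
#' emulate a 450K-style lung-cancer methylation study: six specimen types
#' (resected tumor and matched normal tissue, bronchial biopsy, bronchial
#' washing from cases and from hospital controls, sputum), background signal
#' concentrated below beta = 0.3, negatively skewed tumor methylation at a
#' set of planted tumor-hypermethylated CpGs, linear tumor-purity dilution,
#' and a handful of CpGs whose methylation in normal tissue drifts with age.
#'
#' @param n_probes Total number of CpG probes.
#' @param n_diff_probes Number of planted tumor-hypermethylated probes.
#' @param n_age_probes Number of planted age-correlated probes (disjoint from
#'   the differential set).
#' @param n_samples Named integer vector: samples per specimen type. Biopsies
#'   are paired with the first `n_samples["bronchial_biopsy"]` washing-case
#'   patients; tumor and normal tissue are patient-matched.
#' @param purity Named numeric vector mapping specimen type to tumor-cell
#'   fraction pi in \[0, 1\]. The biopsy default of 0.60 reflects the
#'   empirical observation that biopsy methylation tracks resected tumor
#'   tissue closely; the histologically reported mean tumor area of about a
#'   third is available as a documented alternative (`purity_biopsy_low`).
#' @param background_shape Beta-distribution shape pair for per-probe
#'   background methylation (default mean 0.10, >95% of mass below 0.3).
#' @param tumor_shape Beta shape pair for tumor-cell methylation at planted
#'   probes (default mean 0.65, negatively skewed).
#' @param age_slope Beta increase per year at age probes (per-year units),
#'   applied in the normal-cell compartment of normal tissue samples.
#' @param noise_sd Standard deviation of additive measurement noise applied
#'   after mixing, on the clipped linear beta scale.
#' @param age_range Two-element numeric vector of patient ages (years),
#'   sampled uniformly.
#' @param n_genes Number of synthetic gene symbols in the annotation scaffold.
#' @param genes_per_term Genes per gene-set term.
#' @param n_background_terms Number of unenriched gene-set terms emitted in
#'   addition to the three terms that partition the planted differential
#'   genes (mirroring transcription / cell-signaling / adhesion categories).
#' @param seed Optional integer seed; may also be supplied to
#'   [simulate_cohort()] directly.
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_probes = 5000,
                          n_diff_probes = 50,
                          n_age_probes = 5,
                          n_samples = c(
                            tumor_tissue = 42, normal_tissue = 42,
                            bronchial_biopsy = 8, bronchial_washing = 76,
                            control_washing = 60, sputum = 12
                          ),
                          purity = c(
                            tumor_tissue = 0.70, normal_tissue = 0,
                            bronchial_biopsy = 0.60, bronchial_washing = 0.10,
                            control_washing = 0, sputum = 0.05
                          ),
                          background_shape = c(2, 18),
                          tumor_shape = c(6.5, 3.5),
                          age_slope = 0.004,
                          noise_sd = 0.03,
                          age_range = c(40, 75),
                          n_genes = 1200,
                          genes_per_term = 40,
                          n_background_terms = 30,
                          seed = NULL) {
  cfg <- list(
    n_probes = n_probes, n_diff_probes = n_diff_probes,
    n_age_probes = n_age_probes, n_samples = n_samples, purity = purity,
    background_shape = background_shape, tumor_shape = tumor_shape,
    age_slope = age_slope, noise_sd = noise_sd, age_range = age_range,
    n_genes = n_genes, genes_per_term = genes_per_term,
    n_background_terms = n_background_terms, seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

# Documented low-purity biopsy preset: mean tumor area reported
# histologically in forceps biopsies is about one third.
#' @rdname cohort_config
#' @export
purity_biopsy_low <- 0.334

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_probes >= 1,
    cfg$n_diff_probes >= 0, cfg$n_age_probes >= 0,
    cfg$n_diff_probes + cfg$n_age_probes <= cfg$n_probes,
    all(cfg$background_shape > 0), length(cfg$background_shape) == 2,
    all(cfg$tumor_shape > 0), length(cfg$tumor_shape) == 2,
    cfg$noise_sd >= 0, cfg$age_slope >= 0,
    length(cfg$age_range) == 2, cfg$age_range[1] > 0,
    cfg$age_range[2] >= cfg$age_range[1],
    cfg$n_genes >= cfg$n_diff_probes + 3,
    cfg$genes_per_term >= 1, cfg$n_background_terms >= 0
  )
  if (is.null(names(cfg$n_samples)) || any(cfg$n_samples < 0)) {
    abort("`n_samples` must be a named, non-negative vector.")
  }
  missing_purity <- setdiff(names(cfg$n_samples), names(cfg$purity))
  if (length(missing_purity)) {
    abort(paste0("`purity` missing specimen types: ",
                 paste(missing_purity, collapse = ", ")))
  }
  check_fraction(unname(cfg$purity), "purity")
  if (all(c("tumor_tissue", "normal_tissue") %in% names(cfg$n_samples)) &&
      cfg$n_samples[["tumor_tissue"]] != cfg$n_samples[["normal_tissue"]]) {
    abort("tumor and matched normal tissue counts must be equal.")
  }
  if ("bronchial_biopsy" %in% names(cfg$n_samples) &&
      "bronchial_washing" %in% names(cfg$n_samples) &&
      cfg$n_samples[["bronchial_biopsy"]] > cfg$n_samples[["bronchial_washing"]]) {
    abort("biopsies are paired with washing-case patients; need n biopsies <= n washings.")
  }
  invisible(cfg)
}

#' Mix tumor and background methylation for one measurement
#'
#' The measured beta value of a specimen is modelled as a cell-population
#' average: a fraction `purity` of tumor cells carrying `true_tumor_beta` and
#' the remainder carrying `true_background_beta`, plus additive measurement
#' noise, clipped to \[0, 1\]. Arguments are vectorised and recycled.
#'
#' @param true_tumor_beta Methylation fraction in tumor cells, in \[0, 1\].
#' @param true_background_beta Methylation fraction in non-tumor cells.
#' @param purity Tumor-cell fraction pi in \[0, 1\].
#' @param noise_sd Standard deviation of additive Gaussian noise (default 0).
#' @return Numeric vector of simulated beta values in \[0, 1\].
#' @examples
#' sample_beta(0.8, 0.1, 1.0)  # pure tumor: 0.8
#' sample_beta(0.8, 0.1, 0.5)  # linear mixture midpoint: 0.45
#' @export
sample_beta <- function(true_tumor_beta, true_background_beta, purity,
                        noise_sd = 0) {
  check_fraction(true_tumor_beta, "true_tumor_beta")
  check_fraction(true_background_beta, "true_background_beta")
  check_fraction(purity, "purity")
  stopifnot(noise_sd >= 0)
  mixed <- purity * true_tumor_beta + (1 - purity) * true_background_beta
  if (any(noise_sd > 0)) {
    mixed <- mixed + stats::rnorm(length(mixed), 0, noise_sd)
  }
  pmin(1, pmax(0, mixed))
}

#' Simulate a full bronchoscopy methylation cohort
#'
#' Generates a beta-value matrix, sample sheet, probe annotation, gene-set
#' collection and the planted ground truth, deterministically for a given
#' seed (one global RNG stream, no per-module reseeding). Matched tumor and
#' normal tissue share a patient id, as do paired biopsy/washing specimens.
#' Non-differential probes have the same generating distribution in every
#' group; planted differential probes mix a per-patient tumor-cell draw with
#' the probe's background level according to the specimen's purity; planted
#' age probes drift linearly with patient age in the normal-cell compartment
#' of normal tissue.
#'
#' @param config A [cohort_config()] list.
#' @param seed Integer seed; overrides `config$seed` when given.
#' @return A list of class `meth_cohort` with elements `beta` (wide tibble),
#'   `samples`, `annotation`, `gene_sets` (tibble with a `genes`
#'   list-column) and `truth` (planted differential / age probe ids,
#'   per-sample purity, config echo).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) abort("a seed is required (in `config` or as `seed`).")
  set.seed(as.integer(seed))

  P <- config$n_probes
  probe_ids <- sprintf("cg%06d", seq_len(P))
  diff_idx <- seq_len(config$n_diff_probes)
  age_idx <- config$n_diff_probes + seq_len(config$n_age_probes)

  samples <- build_sample_sheet(config)
  S <- nrow(samples)

  # --- annotation scaffold --------------------------------------------------
  # Planted differential probes each anchor their own gene; remaining probes
  # are spread round-robin over the whole gene list, so differential genes
  # also carry null (mostly gene-body) probes for region profiling.
  genes <- c(
    sprintf("DGENE%03d", seq_len(config$n_diff_probes)),
    sprintf("GENE%04d", seq_len(config$n_genes - config$n_diff_probes))
  )
  gene_of <- character(P)
  gene_of[diff_idx] <- genes[diff_idx]
  rest <- setdiff(seq_len(P), diff_idx)
  gene_of[rest] <- rep_len(genes, length(rest))
  regions <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body")
  region_of <- rep_len(regions, P)
  # promoter-biased planting for differential probes
  region_of[diff_idx] <- rep_len(regions[1:4], length(diff_idx))
  annotation <- tibble(probe_id = probe_ids, gene = gene_of, region = region_of)

  gene_sets <- build_gene_sets(config, genes, diff_genes = genes[diff_idx])

  # --- latent levels --------------------------------------------------------
  mu_bg <- stats::rbeta(P, config$background_shape[1], config$background_shape[2])
  ages <- samples$age
  B <- matrix(mu_bg, nrow = P, ncol = S)
  if (length(age_idx)) {
    norm_cols <- which(samples$specimen_type == "normal_tissue")
    if (length(norm_cols)) {
      drift <- config$age_slope * (ages[norm_cols] - config$age_range[1])
      B[age_idx, norm_cols] <- pmin(1, B[age_idx, norm_cols] +
                                      matrix(drift, nrow = length(age_idx),
                                             ncol = length(norm_cols), byrow = TRUE))
    }
  }

  purity_per_sample <- unname(config$purity[samples$specimen_type])
  cancer_patients <- unique(samples$patient_id[purity_per_sample > 0])
  V <- B
  if (length(diff_idx) && length(cancer_patients)) {
    Tm <- matrix(
      stats::rbeta(length(diff_idx) * length(cancer_patients),
                   config$tumor_shape[1], config$tumor_shape[2]),
      nrow = length(diff_idx), ncol = length(cancer_patients),
      dimnames = list(NULL, cancer_patients)
    )
    for (j in which(purity_per_sample > 0)) {
      pi_j <- purity_per_sample[j]
      t_j <- Tm[, samples$patient_id[j]]
      V[diff_idx, j] <- pi_j * t_j + (1 - pi_j) * B[diff_idx, j]
    }
  }
  if (config$noise_sd > 0) {
    V <- V + matrix(stats::rnorm(P * S, 0, config$noise_sd), P, S)
  }
  V[] <- pmin(1, pmax(0, V))
  dimnames(V) <- list(probe_ids, samples$sample_id)

  truth <- list(
    diff_probe_ids = probe_ids[diff_idx],
    age_probe_ids = probe_ids[age_idx],
    purity_per_sample = stats::setNames(purity_per_sample, samples$sample_id),
    config = config
  )
  stopifnot(length(intersect(truth$diff_probe_ids, truth$age_probe_ids)) == 0)

  structure(
    list(beta = matrix_to_beta(V), samples = samples,
         annotation = annotation, gene_sets = gene_sets, truth = truth),
    class = "meth_cohort"
  )
}

build_sample_sheet <- function(config) {
  ns <- function(type) if (type %in% names(config$n_samples)) config$n_samples[[type]] else 0L
  n_tt <- ns("tumor_tissue"); n_nt <- ns("normal_tissue")
  n_bb <- ns("bronchial_biopsy"); n_bw <- ns("bronchial_washing")
  n_cw <- ns("control_washing"); n_sp <- ns("sputum")
  if (n_nt != n_tt) abort("tumor and matched normal tissue counts must be equal.")

  pat_tt <- sprintf("PT%03d", seq_len(n_tt))
  pat_bw <- sprintf("PW%03d", seq_len(n_bw))
  pat_cw <- sprintf("PC%03d", seq_len(n_cw))
  pat_sp <- sprintf("PS%03d", seq_len(n_sp))

  rows <- dplyr::bind_rows(
    tibble(sample_id = sprintf("TT%03d", seq_len(n_tt)), patient_id = pat_tt,
           specimen_type = "tumor_tissue", disease_label = "cancer"),
    tibble(sample_id = sprintf("NT%03d", seq_len(n_nt)), patient_id = pat_tt,
           specimen_type = "normal_tissue", disease_label = "control"),
    tibble(sample_id = sprintf("BB%03d", seq_len(n_bb)),
           patient_id = pat_bw[seq_len(n_bb)],
           specimen_type = "bronchial_biopsy", disease_label = "cancer"),
    tibble(sample_id = sprintf("BW%03d", seq_len(n_bw)), patient_id = pat_bw,
           specimen_type = "bronchial_washing", disease_label = "cancer"),
    tibble(sample_id = sprintf("CW%03d", seq_len(n_cw)), patient_id = pat_cw,
           specimen_type = "control_washing", disease_label = "control"),
    tibble(sample_id = sprintf("SP%03d", seq_len(n_sp)), patient_id = pat_sp,
           specimen_type = "sputum", disease_label = "cancer")
  )
  patients <- unique(rows$patient_id)
  age_of <- stats::setNames(
    round(stats::runif(length(patients), config$age_range[1], config$age_range[2]), 1),
    patients
  )
  sex_of <- stats::setNames(
    sample(c("M", "F"), length(patients), replace = TRUE, prob = c(0.75, 0.25)),
    patients
  )
  rows$age <- unname(age_of[rows$patient_id])
  rows$sex <- unname(sex_of[rows$patient_id])
  rows$histology <- ifelse(
    rows$disease_label == "cancer",
    sample(c("adenocarcinoma", "squamous", "other"), nrow(rows),
           replace = TRUE, prob = c(0.6, 0.2, 0.2)),
    NA_character_
  )
  # one histology per patient
  rows <- rows |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(histology = .data$histology[1]) |>
    dplyr::ungroup()
  rows
}

build_gene_sets <- function(config, genes, diff_genes) {
  labels <- c("transcription regulation", "cell-cell signaling", "cell-cell adhesion")
  background_genes <- setdiff(genes, diff_genes)
  sets <- list()
  if (length(diff_genes)) {
    split_idx <- rep_len(1:3, length(diff_genes))
    for (i in 1:3) {
      members <- diff_genes[split_idx == i]
      pad <- max(0, config$genes_per_term - length(members))
      members <- c(members, sample(background_genes, min(pad, length(background_genes))))
      sets[[sprintf("GO:%07d", i)]] <- list(label = labels[i], genes = members)
    }
  }
  for (i in seq_len(config$n_background_terms)) {
    sets[[sprintf("GO:%07d", 100 + i)]] <- list(
      label = sprintf("background process %d", i),
      genes = sample(background_genes,
                     min(config$genes_per_term, length(background_genes)))
    )
  }
  tibble(
    term_id = names(sets),
    term_label = vapply(sets, `[[`, "", "label"),
    genes = unname(lapply(sets, `[[`, "genes"))
  )
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("<meth_cohort>", nrow(x$beta), "probes x", nrow(x$samples), "samples\n")
  print(dplyr::count(x$samples, .data$specimen_type, .data$disease_label))
  cat("planted differential probes:", length(x$truth$diff_probe_ids),
      "| age probes:", length(x$truth$age_probe_ids), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
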