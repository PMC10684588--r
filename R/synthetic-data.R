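#' Configuration for the synthetic FFPE-DIA cohort generator
#'
#' Bundles and validates all generator parameters. Defaults emulate a
#' matched primary/metastasis lung-adenocarcinoma cohort profiled by
#' label-free DIA from FFPE blocks: 14 patients contributing one primary
#' each plus 24 metastases (38 samples), 1405 proteins, log-normal
#' abundances, per-sample depth offsets, and a mixture of
#' intensity-dependent (MNAR) and random (MAR) dropout calibrated so that a
#' typical sample quantifies roughly 1000 of the 1405 proteins and about
#' three quarters of proteins survive a 50% valid-value filter.
#'
#' @param n_patients Number of patients; each contributes one primary tumor.
#' @param metastases_per_patient Integer range `c(min, max)` of metastases
#'   drawn per patient.
#' @param total_metastases Optional exact total; after drawing, counts are
#'   nudged within the range until the total matches. `NULL` disables.
#' @param n_proteins Number of proteins in the matrix.
#' @param n_de_proteins Number of proteins carrying a planted
#'   primary-vs-metastasis effect.
#' @param de_effect Absolute log2 shift applied to metastasis samples of a
#'   planted DE protein; each planted protein gets a random sign (positive =
#'   higher in metastases).
#' @param n_cluster_proteins Number of proteins (disjoint from the DE set)
#'   carrying planted sample-cluster structure.
#' @param n_clusters Number of planted sample clusters.
#' @param cluster_effect Log2 separation: samples of cluster `c` are shifted
#'   by `+cluster_effect` on cluster block `c`.
#' @param base_mean,base_sd Location/scale (log2) of per-protein baseline
#'   abundances.
#' @param noise_sd Within-protein residual scatter across samples (log2).
#' @param sample_offset_sd Scale of per-sample depth offsets (log2).
#' @param mnar_midpoint Log2 intensity at which intensity-dependent dropout
#'   probability is one half.
#' @param mnar_slope Logistic steepness of MNAR dropout per log2 unit
#'   (0 disables).
#' @param mar_rate Additional completely-random dropout probability.
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   bit for bit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 14,
                       metastases_per_patient = c(1, 4),
                       total_metastases = 24,
                       n_proteins = 1405,
                       n_de_proteins = 100,
                       de_effect = 1.0,
                       n_cluster_proteins = 30,
                       n_clusters = 3,
                       cluster_effect = 2.0,
                       base_mean = 20,
                       base_sd = 2,
                       noise_sd = 0.8,
                       sample_offset_sd = 0.3,
                       mnar_midpoint = 18.65,
                       mnar_slope = 2.1,
                       mar_rate = 0.005,
                       seed = 1L) {
  cfg <- list(n_patients = n_patients, metastases_per_patient = metastases_per_patient,
              total_metastases = total_metastases, n_proteins = n_proteins,
              n_de_proteins = n_de_proteins, de_effect = de_effect,
              n_cluster_proteins = n_cluster_proteins, n_clusters = n_clusters,
              cluster_effect = cluster_effect, base_mean = base_mean, base_sd = base_sd,
              noise_sd = noise_sd, sample_offset_sd = sample_offset_sd,
              mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
              mar_rate = mar_rate, seed = seed)
  bad <- function(field, why) {
    rlang::abort(paste0("invalid sim_config field `", field, "`: ", why),
                 class = "proteopipe_config_error")
  }
  for (f in c("n_patients", "n_proteins", "n_de_proteins", "n_cluster_proteins", "n_clusters")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]])) {
      bad(f, "must be a single nonnegative integer")
    }
  }
  if (cfg$n_patients < 1) bad("n_patients", "need at least one patient")
  if (length(cfg$metastases_per_patient) != 2L || any(cfg$metastases_per_patient < 0) ||
      cfg$metastases_per_patient[1] > cfg$metastases_per_patient[2]) {
    bad("metastases_per_patient", "must be c(min, max) with 0 <= min <= max")
  }
  if (!is.null(cfg$total_metastases)) {
    rng <- cfg$metastases_per_patient * cfg$n_patients
    if (cfg$total_metastases < rng[1] || cfg$total_metastases > rng[2]) {
      bad("total_metastases", sprintf("unreachable from range [%d, %d] over %d patients",
                                      rng[1], rng[2], cfg$n_patients))
    }
  }
  if (cfg$n_de_proteins + cfg$n_cluster_proteins > cfg$n_proteins) {
    bad("n_de_proteins", "n_de_proteins + n_cluster_proteins exceeds n_proteins")
  }
  if (cfg$mar_rate < 0 || cfg$mar_rate > 1) bad("mar_rate", "must lie in [0, 1]")
  if (cfg$mnar_slope < 0) bad("mnar_slope", "must be >= 0")
  for (f in c("base_sd", "noise_sd", "sample_offset_sd")) {
    if (cfg[[f]] < 0) bad(f, "must be >= 0")
  }
  if (cfg$n_clusters > 0 && cfg$n_cluster_proteins > 0 &&
      cfg$n_cluster_proteins < cfg$n_clusters) {
    bad("n_cluster_proteins", "fewer cluster proteins than clusters")
  }
  structure(cfg, class = "sim_config")
}

# draw per-patient metastasis counts, optionally nudged to an exact total
draw_metastasis_counts <- function(cfg) {
  rng <- cfg$metastases_per_patient
  vals <- seq(rng[1], rng[2])
  m <- vals[sample.int(length(vals), cfg$n_patients, replace = TRUE)]
  pick <- function(idx) idx[sample.int(length(idx), 1L)]
  if (!is.null(cfg$total_metastases)) {
    while (sum(m) > cfg$total_metastases) {
      i <- pick(which(m > rng[1]))
      m[i] <- m[i] - 1L
    }
    while (sum(m) < cfg$total_metastases) {
      i <- pick(which(m < rng[2]))
      m[i] <- m[i] + 1L
    }
  }
  m
}

#' Simulate a matched primary/metastasis cohort with known ground truth
#'
#' Generates a raw-scale intensity matrix, a sample sheet, and the planted
#' truth. Log2 abundances are Gaussian: per-protein baseline plus per-sample
#' depth offset plus residual noise, with a signed log2 effect added to
#' metastasis samples for the planted DE proteins and a block-structured
#' shift encoding the planted sample clusters. With
#' `with_missingness = TRUE` (default) the MNAR/MAR dropout of
#' [inject_missingness()] is applied and the realized mask recorded in the
#' truth.
#'
#' @param config A [sim_config()].
#' @param with_missingness Apply the dropout model after effect planting?
#' @return A list of class `sim_cohort` with elements `matrix` (raw-scale
#'   intensity table), `samples` (sample sheet), and `truth` (list with
#'   `de_proteins` — tibble of `protein_id`, `effect` —, `cluster_proteins`,
#'   `cluster_labels`, `sample_offsets`, and `missing_mask`, a logical
#'   protein-by-sample matrix, `TRUE` where a value was dropped).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_proteins = 50, seed = 1))
#' nrow(cohort$samples)  # 38 = 14 primaries + 24 metastases
#' @export
simulate_cohort <- function(config = sim_config(), with_missingness = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    m_counts <- draw_metastasis_counts(config)
    patient <- sprintf("PAT%02d", seq_len(config$n_patients))
    sheet <- dplyr::bind_rows(
      tibble::tibble(sample_id = paste0(patient, "_P"), patient_id = patient,
                     tissue_type = "primary", localization = NA_character_),
      purrr::map2_dfr(patient, m_counts, function(p, k) {
        if (k == 0L) return(NULL)
        tibble::tibble(sample_id = paste0(p, "_M", seq_len(k)), patient_id = p,
                       tissue_type = "metastasis",
                       localization = sample(c("ADR", "HEP", "KID", "OSS", "OTH"), k, replace = TRUE))
      })
    )
    n_s <- nrow(sheet)
    prot <- sprintf("PROT%04d", seq_len(config$n_proteins))

    base <- stats::rnorm(config$n_proteins, config$base_mean, config$base_sd)
    offsets <- stats::rnorm(n_s, 0, config$sample_offset_sd)
    log2v <- matrix(base, config$n_proteins, n_s) +
      matrix(offsets, config$n_proteins, n_s, byrow = TRUE) +
      matrix(stats::rnorm(config$n_proteins * n_s, 0, config$noise_sd), config$n_proteins, n_s)
    dimnames(log2v) <- list(prot, sheet$sample_id)

    special <- sample(prot, config$n_de_proteins + config$n_cluster_proteins)
    de_ids <- special[seq_len(config$n_de_proteins)]
    cl_ids <- setdiff(special, de_ids)
    de_sign <- if (config$n_de_proteins) sample(c(-1, 1), config$n_de_proteins, replace = TRUE) else numeric()
    de_effects <- de_sign * config$de_effect
    is_met <- sheet$tissue_type == "metastasis"
    if (config$n_de_proteins && any(is_met)) {
      log2v[de_ids, is_met] <- log2v[de_ids, is_met] + de_effects
    }

    if (config$n_clusters > 0) {
      cl_lab <- sample(rep_len(seq_len(config$n_clusters), n_s))
    } else {
      cl_lab <- rep(1L, n_s)
    }
    if (config$n_clusters > 1 && config$n_cluster_proteins > 0) {
      block <- rep_len(seq_len(config$n_clusters), config$n_cluster_proteins)
      for (c in seq_len(config$n_clusters)) {
        rows <- cl_ids[block == c]
        cols <- cl_lab == c
        log2v[rows, cols] <- log2v[rows, cols] + config$cluster_effect
      }
    }

    mat <- as_intensity_tbl(
      tibble::add_column(tibble::as_tibble(2^log2v, .name_repair = "minimal"),
                         protein_id = prot, .before = 1),
      scale = "raw")
    truth <- list(
      de_proteins = tibble::tibble(protein_id = de_ids, effect = de_effects),
      cluster_proteins = cl_ids,
      cluster_labels = tibble::tibble(sample_id = sheet$sample_id, cluster = cl_lab),
      sample_offsets = tibble::tibble(sample_id = sheet$sample_id, offset = offsets),
      missing_mask = NULL
    )
    if (with_missingness) {
      mat <- inject_missingness(mat, config, seed = NULL)
      truth$missing_mask <- is.na(im_values(mat))
    }
    structure(list(matrix = mat, samples = sheet, truth = truth), class = "sim_cohort")
  })
}

#' Apply MNAR + MAR dropout to a complete raw-scale matrix
#'
#' Each entry with raw value `x` is set missing independently with
#' probability `mar_rate + (1 - mar_rate) * plogis(-mnar_slope *
#' (log2(x) - mnar_midpoint))`: a floor of completely-random dropout plus a
#' logistic intensity-dependent component that removes faint signals
#' preferentially, as FFPE DIA data do.
#'
#' @param x A complete (no missing values) raw-scale intensity table.
#' @param config A [sim_config()] supplying `mar_rate`, `mnar_slope`,
#'   `mnar_midpoint`, and the default seed.
#' @param seed Seed for the dropout draws; `NULL` uses the current RNG state
#'   (as inside [simulate_cohort()]), the default uses `config$seed`.
#' @return The intensity table with missing entries.
#' @export
inject_missingness <- function(x, config, seed = config$seed) {
  stopifnot(inherits(x, "intensity_tbl"), inherits(config, "sim_config"))
  v <- im_values(x)
  if (anyNA(v)) rlang::abort("matrix already contains missing values")
  run <- function() {
    p <- dropout_probability(log2(v), config)
    v[matrix(stats::runif(length(v)), nrow(v)) < p] <- NA_real_
    v
  }
  v <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  im_rebuild(v, x)
}

# analytic per-entry dropout probability on the log2 scale
dropout_probability <- function(log2_values, config) {
  mnar <- if (config$mnar_slope > 0 && is.finite(config$mnar_midpoint)) {
    stats::plogis(-config$mnar_slope * (log2_values - config$mnar_midpoint))
  } else {
    0
  }
  config$mar_rate + (1 - config$mar_rate) * mnar
}
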