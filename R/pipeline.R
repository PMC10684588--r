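#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the study-style
#' defaults: 50% valid-value filter, top-100 invariant-protein median
#' normalization, unadjusted p <= 0.05 with |log2FC| >= 0.5 volcano
#' thresholds, consensus NMF over ranks 2..10, relevance selection above the
#' 90th percentile, 100 phenotype permutations for GSEA, and root seed 7.
#'
#' @param min_valid_fraction Valid-value filter fraction (default 0.5).
#' @param n_invariant Invariant proteins for normalization (default 100).
#' @param p_threshold Unadjusted DE significance threshold (default 0.05).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 0.5).
#' @param k_range NMF rank sweep (default `2:10`).
#' @param n_runs NMF restarts per rank (default 50).
#' @param relevance_percentile Relevance selection percentile (default 90).
#' @param n_perm GSEA phenotype permutations (default 100).
#' @param seed Root seed (default 7); stage seeds are derived by fixed
#'   offsets so stages are independently reproducible.
#' @param impute_method Imputation variant for PCA/clustering (default
#'   `"protein_mean"`).
#' @param require_lfc_for_candidates Gate the candidate DE side on the
#'   fold-change classes (default `FALSE`: the full significant set).
#' @param gsea_min_size,gsea_max_size,gsea_weight GSEA set-size bounds and
#'   hit weight.
#' @param nmf_max_iter,nmf_tol NMF stopping rule.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_valid_fraction = 0.5, n_invariant = 100,
                            p_threshold = 0.05, lfc_threshold = 0.5,
                            k_range = 2:10, n_runs = 50L,
                            relevance_percentile = 90, n_perm = 100L, seed = 7L,
                            impute_method = c("protein_mean", "global_mean"),
                            require_lfc_for_candidates = FALSE,
                            gsea_min_size = 5L, gsea_max_size = 500L, gsea_weight = 1,
                            nmf_max_iter = 3000L, nmf_tol = 1e-9) {
  cfg <- list(min_valid_fraction = min_valid_fraction, n_invariant = n_invariant,
              p_threshold = p_threshold, lfc_threshold = lfc_threshold,
              k_range = as.integer(k_range), n_runs = as.integer(n_runs),
              relevance_percentile = relevance_percentile, n_perm = as.integer(n_perm),
              seed = as.integer(seed), impute_method = match.arg(impute_method),
              require_lfc_for_candidates = isTRUE(require_lfc_for_candidates),
              gsea_min_size = as.integer(gsea_min_size),
              gsea_max_size = as.integer(gsea_max_size), gsea_weight = gsea_weight,
              nmf_max_iter = as.integer(nmf_max_iter), nmf_tol = nmf_tol)
  if (cfg$min_valid_fraction <= 0 || cfg$min_valid_fraction > 1) {
    rlang::abort("min_valid_fraction must lie in (0, 1]")
  }
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr, log) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    rlang::abort(paste0("stage '", name, "' failed: ", conditionMessage(e)), parent = e)
  })
  log(sprintf("stage %-12s ok (%.2fs)", name, as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the full matched-cohort analysis
#'
#' Executes, in order: coverage summary, valid-value filter, log2 transform,
#' invariant-protein median normalization, then — on the unimputed
#' normalized matrix — Mann-Whitney differential expression and (when a
#' gene-set collection is supplied) phenotype-permutation GSEA, and — on the
#' mean-imputed matrix — PCA (also computed unimputed on complete proteins)
#' and the consensus NMF rank sweep with rank selection and relevance
#' scoring, finishing with the DE-by-relevance candidate intersection.
#' Imputed values never reach a statistical test. The same matrix, sheet,
#' config and seed reproduce every numeric table byte for byte.
#'
#' @param x A raw- or log2-scale intensity table, or a path to a wide TSV
#'   matrix (assumed raw scale).
#' @param sheet A sample sheet tibble or path to a sample-sheet TSV.
#' @param collection Optional gene-set tibble from [read_gmt()] or a GMT
#'   path; `NULL` skips GSEA.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV together with `manifest.json` and `log.txt`. Created if absent.
#' @return A list of class `pipeline_run` with elements `coverage`,
#'   `filtered`, `normalization`, `de`, `gsea`, `pca_imputed`,
#'   `pca_complete`, `sweep`, `selected_k`, `consensus`, `relevance`,
#'   `candidates`, `config`, `manifest`.
#' @export
run_pipeline <- function(x, sheet, collection = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  log <- function(msg) log_lines <<- c(log_lines, msg)
  if (is.character(x)) x <- read_intensity_matrix(x, scale = "raw")
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  sheet <- validate_sample_sheet(sheet)
  if (is.character(collection)) collection <- read_gmt(collection)

  coverage <- stage("coverage", coverage_summary(x), log)
  filtered <- stage("filter", filter_valid(x, config$min_valid_fraction), log)
  log(sprintf("  %d of %d proteins pass the %.0f%% filter",
              nrow(filtered), nrow(x), 100 * config$min_valid_fraction))
  l2 <- if (intensity_scale(filtered) == "raw") {
    stage("log2", log2_transform(filtered), log)
  } else filtered
  norm <- stage("normalize", {
    inv <- select_invariant(l2, config$n_invariant)
    normalize_median(l2, inv)
  }, log)
  normalized <- norm$normalized

  de <- stage("diffexp", run_diffexp(normalized, sheet,
                                     p_threshold = config$p_threshold,
                                     lfc_threshold = config$lfc_threshold), log)
  gsea <- if (!is.null(collection)) {
    stage("gsea", run_gsea(normalized, sheet, collection, n_perm = config$n_perm,
                           seed = config$seed, min_size = config$gsea_min_size,
                           max_size = config$gsea_max_size,
                           weight = config$gsea_weight), log)
  } else NULL

  imputed <- stage("impute", impute_mean(normalized, method = config$impute_method), log)
  pca_imputed <- stage("pca", pca_embed(imputed, impute = FALSE), log)
  pca_complete <- tryCatch(pca_embed(normalized, impute = FALSE),
                           error = function(e) NULL)
  n_complete <- sum(rowSums(is.na(im_values(normalized))) == 0L)
  log(sprintf("  complete-protein PCA uses %d proteins", n_complete))

  nmf_V <- nmf_input(imputed)
  sweep_res <- stage("nmf_sweep",
                     nmf_rank_sweep(nmf_V, k_range = config$k_range,
                                    n_runs = config$n_runs,
                                    seed = config$seed + 211L,
                                    max_iter = config$nmf_max_iter,
                                    tol = config$nmf_tol), log)
  selected_k <- stage("rank_select", select_rank(sweep_res), log)
  consensus <- sweep_res$results[[as.character(selected_k)]]
  relevance <- stage("relevance",
                     relevance_scores(consensus$best_W,
                                      percentile = config$relevance_percentile), log)
  candidates <- stage("candidates",
                      intersect_candidates(de, relevance,
                                           p_threshold = config$p_threshold,
                                           require_lfc = config$require_lfc_for_candidates),
                      log)

  manifest <- list(
    config = unclass(config),
    stages = c("coverage", "filter", "normalize", "diffexp",
               if (!is.null(gsea)) "gsea", "impute_pca", "consensus_nmf", "candidates"),
    n_proteins_input = nrow(x), n_proteins_filtered = nrow(filtered),
    n_samples = length(sample_ids(x)),
    n_complete_proteins = n_complete,
    nmf_shift = attr(nmf_V, "shift"),
    selected_k = selected_k,
    n_candidates = nrow(candidates)
  )
  run <- structure(list(coverage = coverage, filtered = filtered, normalization = norm,
                        de = de, gsea = gsea, pca_imputed = pca_imputed,
                        pca_complete = pca_complete, sweep = sweep_res,
                        selected_k = selected_k, consensus = consensus,
                        relevance = relevance, candidates = candidates,
                        config = config, manifest = manifest, log = log_lines),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' Write a pipeline run to disk
#'
#' @param run A `pipeline_run`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(run$coverage, p("coverage.tsv"))
  write_intensity_matrix(run$filtered, p("filtered_matrix.tsv"))
  write_intensity_matrix(run$normalization$normalized, p("normalized_matrix.tsv"))
  readr::write_tsv(run$normalization$offsets, p("sample_offsets.tsv"))
  readr::write_tsv(tibble::tibble(protein_id = run$normalization$invariant_proteins),
                   p("invariant_proteins.tsv"))
  readr::write_tsv(tibble::as_tibble(run$de), p("de_table.tsv"))
  if (!is.null(run$gsea)) {
    g <- tibble::as_tibble(run$gsea)
    g$leading_edge <- purrr::map_chr(g$leading_edge, paste, collapse = ";")
    readr::write_tsv(g, p("gsea_table.tsv"))
  }
  readr::write_tsv(run$sweep$table, p("sweep_table.tsv"))
  cm <- tibble::as_tibble(run$consensus$consensus, .name_repair = "minimal")
  readr::write_tsv(tibble::add_column(cm, sample_id = run$consensus$labels$sample_id,
                                      .before = 1),
                   p(sprintf("consensus_k%d.tsv", run$selected_k)))
  readr::write_tsv(run$consensus$labels, p("cluster_labels.tsv"))
  readr::write_tsv(tibble::as_tibble(run$relevance), p("relevance_scores.tsv"))
  readr::write_tsv(tibble::as_tibble(run$candidates), p("candidates.tsv"))
  readr::write_tsv(run$pca_imputed$scores, p("pca_scores_imputed.tsv"))
  if (!is.null(run$pca_complete)) {
    readr::write_tsv(run$pca_complete$scores, p("pca_scores_complete.tsv"))
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(run$log, p("log.txt"))
  invisible(out_dir)
}

#' Reload a manifest's configuration
#'
#' The manifest written by [run_pipeline()] echoes the resolved
#' configuration; reloading it reproduces an identical run.
#'
#' @param path Path to a `manifest.json`.
#' @return A [pipeline_config()].
#' @export
read_manifest_config <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, m$config)
}

#' @export
print.pipeline_run <- function(x, ...) {
  g <- glance.de_table(x$de)
  cat(sprintf("# pipeline run: %d -> %d proteins, %d samples\n",
              x$manifest$n_proteins_input, x$manifest$n_proteins_filtered,
              x$manifest$n_samples))
  cat(sprintf("#   DE: %d significant (p <= %g), %d with |log2FC| >= %g\n",
              g$n_significant, g$p_threshold, g$n_fc_qualified, g$lfc_threshold))
  cat(sprintf("#   consensus NMF: selected k = %d (cophenetic %.3f, dispersion %.3f)\n",
              x$selected_k, x$consensus$cophenetic, x$consensus$dispersion))
  cat(sprintf("#   %d cluster-relevant proteins, %d candidates\n",
              sum(x$relevance$selected), nrow(x$candidates)))
  invisible(x)
}

#' Z-scored expression heatmap of candidate proteins
#'
#' Rows (proteins) are z-scored over their valid values — mean 0, sd 1 —
#' so expression patterns are comparable across proteins; missing values
#' are shown in grey.
#'
#' @param x A log2-scale intensity table (typically the normalized,
#'   unimputed matrix).
#' @param proteins Character vector of protein ids to show.
#' @param sheet Optional sample sheet used to order samples by tissue type.
#' @return A ggplot tile map.
#' @export
plot_candidate_heatmap <- function(x, proteins, sheet = NULL) {
  v <- im_values(x)
  v <- v[rownames(v) %in% proteins, , drop = FALSE]
  if (!nrow(v)) rlang::abort("none of the requested proteins are in the matrix")
  z <- t(apply(v, 1L, function(r) (r - mean(r, na.rm = TRUE)) / stats::sd(r, na.rm = TRUE)))
  df <- tibble::as_tibble(as.table(z), .name_repair = ~ c("protein_id", "sample_id", "z"))
  if (!is.null(sheet)) {
    sheet <- validate_sample_sheet(sheet)
    ord <- sheet$sample_id[order(sheet$tissue_type, sheet$patient_id)]
    df$sample_id <- factor(df$sample_id, levels = ord)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$protein_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white", high = "#c0392b",
                                  na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
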