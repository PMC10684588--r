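#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative protein-by-sample matrix `V ~ W %*% H` with
#' `k` components, minimizing the squared Frobenius reconstruction error by
#' Lee-Seung multiplicative updates. The per-iteration error sequence is
#' non-increasing; iteration stops when the relative improvement falls below
#' `tol` or after `max_iter` updates. Initialization is stochastic
#' "random vcol": each basis column starts as the average of a few randomly
#' drawn data columns (which seeds the dominant flat component of log-scale
#' intensity data and converges far faster than uniform noise), with
#' uniform-random coefficients; it is fully determined by `seed`.
#'
#' @param V Nonnegative numeric matrix (proteins x samples), no missing
#'   values — impute and, if log2 values can be negative, shift first (see
#'   [nmf_input()]).
#' @param k Factorization rank, `1 <= k < min(dim(V))`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative improvement below which iteration stops.
#' @return List with `W` (proteins x k), `H` (k x samples), `error` (final
#'   squared Frobenius error), and `error_trace`.
#' @export
nmf_fit <- function(V, k, seed = 1L, max_iter = 3000L, tol = 1e-9) {
  V <- as.matrix(V)
  if (anyNA(V)) rlang::abort("V contains missing values; impute first")
  if (any(V < 0)) rlang::abort("V has negative entries; shift or impute to nonnegative first")
  if (k < 1 || k >= min(dim(V))) rlang::abort("k must satisfy 1 <= k < min(dim(V))")
  p <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  withr::with_seed(seed, {
    W <- vapply(seq_len(k), function(q) {
      rowMeans(V[, sample.int(n, min(5L, n)), drop = FALSE])
    }, numeric(p))
    H <- matrix(stats::runif(k * n), k, n)
  })
  W <- matrix(W, p, k)
  err <- function() sum((V - W %*% H)^2)
  trace <- numeric(0)
  prev <- err()
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- err()
    trace <- c(trace, cur)
    if (prev > 0 && (prev - cur) / prev < tol) { prev <- cur; break }
    prev <- cur
  }
  dimnames(W) <- list(rownames(V), NULL)
  dimnames(H) <- list(NULL, colnames(V))
  list(W = W, H = H, error = prev, error_trace = trace)
}

#' Prepare a log2 intensity table for NMF
#'
#' Consensus NMF consumes the imputed log2 matrix; log2 intensities of
#' values below 1 are negative, so the matrix is shifted globally (if
#' needed) to make its minimum zero. The shift preserves between-sample
#' structure and is recorded as an attribute for the run manifest.
#'
#' @param x A log2-scale intensity table with no missing values.
#' @return A nonnegative numeric matrix with attribute `shift`.
#' @export
nmf_input <- function(x) {
  stopifnot(inherits(x, "intensity_tbl"))
  v <- im_values(x)
  if (anyNA(v)) rlang::abort("matrix has missing values; impute first (impute_mean)")
  shift <- max(0, -min(v))
  structure(v + shift, shift = shift)
}

#' Consensus clustering by stochastic NMF restarts
#'
#' Runs `n_runs` random-restart NMF fits at rank `k`. In each run, samples
#' are assigned to the component with the largest coefficient in `H`; the
#' consensus matrix is the mean over runs of the co-assignment indicator, so
#' entries near 0 or 1 mark sample pairs whose (non-)co-clustering is
#' reproducible across restarts. Final cluster labels come from an
#' average-linkage hierarchical cut of `1 - consensus` into `k` groups (this
#' may yield fewer than `k` distinct labels on degenerate input); the
#' reported basis/coefficient matrices come from the restart with the lowest
#' reconstruction error.
#'
#' @inheritParams nmf_fit
#' @param n_runs Number of random restarts (>= 2; default 50).
#' @param seed Root seed; run `r` uses `seed + r - 1`.
#' @return Object of class `consensus_result`: list with `k`, `consensus`,
#'   `cophenetic`, `dispersion`, `labels` (tibble `sample_id`, `cluster`),
#'   `best_W`, `best_H`, `n_runs`, `reconstruction_errors`.
#' @export
consensus_cluster <- function(V, k, n_runs = 50L, seed = 1L, max_iter = 3000L, tol = 1e-9) {
  if (n_runs < 2L) rlang::abort("n_runs must be >= 2 for a consensus")
  n <- ncol(V)
  consensus <- matrix(0, n, n)
  best <- NULL
  errors <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- nmf_fit(V, k, seed = seed + r - 1L, max_iter = max_iter, tol = tol)
    errors[r] <- fit$error
    assign <- apply(fit$H, 2L, which.max)
    consensus <- consensus + outer(assign, assign, "==")
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(V), colnames(V))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  labels <- stats::cutree(hc, k = min(k, n))
  structure(list(
    k = k,
    consensus = consensus,
    cophenetic = cophenetic_correlation(consensus),
    dispersion = dispersion(consensus),
    labels = tibble::tibble(sample_id = colnames(V), cluster = unname(labels)),
    best_W = best$W, best_H = best$H,
    n_runs = n_runs,
    reconstruction_errors = errors
  ), class = "consensus_result")
}

#' Dispersion coefficient of a consensus matrix
#'
#' `mean(4 * (C - 1/2)^2)`: equals 1 when every entry is 0 or 1 (perfectly
#' reproducible clustering) and 0 when every entry is 1/2 (maximally
#' ambiguous).
#'
#' @param consensus Square symmetric matrix with entries in \[0, 1\].
#' @return A number in \[0, 1\].
#' @export
dispersion <- function(consensus) {
  mean(4 * (consensus - 0.5)^2)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the consensus-derived distances
#' `1 - C[i, j]` and the cophenetic distances of their average-linkage
#' dendrogram; equals 1 when the consensus distances are already ultrametric
#' (ideal block structure). Undefined (returned as `NA` with a warning) when
#' the off-diagonal distances have zero variance.
#'
#' @inheritParams dispersion
#' @return A number in \[-1, 1\], or `NA` for degenerate input.
#' @export
cophenetic_correlation <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) {
    rlang::warn("consensus distances have zero variance; cophenetic correlation undefined")
    return(NA_real_)
  }
  hc <- stats::hclust(d, method = "average")
  stats::cor(d, stats::cophenetic(hc))
}

#' Consensus NMF rank sweep
#'
#' Runs [consensus_cluster()] for every rank in `k_range` and tabulates the
#' rank-selection diagnostics.
#'
#' @inheritParams consensus_cluster
#' @param k_range Contiguous integer range of ranks (default `2:10`).
#' @return Object of class `nmf_sweep`: list with `results` (one
#'   `consensus_result` per rank, named by k) and `table` (tibble `k`,
#'   `cophenetic`, `dispersion`, `mean_error`). `tidy()` returns the table.
#' @export
nmf_rank_sweep <- function(V, k_range = 2:10, n_runs = 50L, seed = 1L,
                           max_iter = 3000L, tol = 1e-9) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!all(diff(k_range) == 1L)) rlang::abort("k_range must be contiguous")
  results <- purrr::map(k_range, function(k) {
    consensus_cluster(V, k, n_runs = n_runs, seed = seed + 1000L * k,
                      max_iter = max_iter, tol = tol)
  })
  names(results) <- k_range
  tab <- tibble::tibble(
    k = k_range,
    cophenetic = purrr::map_dbl(results, "cophenetic"),
    dispersion = purrr::map_dbl(results, "dispersion"),
    mean_error = purrr::map_dbl(results, ~ mean(.x$reconstruction_errors))
  )
  structure(list(results = results, table = tab), class = "nmf_sweep")
}

#' Select the factorization rank from a sweep
#'
#' Returns the smallest interior rank that is a strict local maximum of
#' both the cophenetic-correlation and the dispersion sequence — the
#' "distinctive peak for both" rule. If no rank qualifies, falls back to the
#' rank with the global cophenetic maximum (with a warning); ties go to the
#' smallest rank. Sweeps with fewer than three ranks have no interior and
#' use the fallback directly.
#'
#' @param sweep An `nmf_sweep` or its `table` (tibble with columns `k`,
#'   `cophenetic`, `dispersion`).
#' @return The selected rank (integer).
#' @export
select_rank <- function(sweep) {
  tab <- if (inherits(sweep, "nmf_sweep")) sweep$table else tibble::as_tibble(sweep)
  stopifnot(all(c("k", "cophenetic", "dispersion") %in% names(tab)))
  tab <- dplyr::arrange(tab, .data$k)
  n <- nrow(tab)
  fallback <- function(msg) {
    rlang::warn(msg)
    tab$k[which.max(tab$cophenetic)]
  }
  if (n < 3L) return(fallback("sweep has fewer than 3 ranks; using global cophenetic maximum"))
  co <- tab$cophenetic; di <- tab$dispersion
  interior <- 2:(n - 1L)
  is_peak <- function(v, i) v[i] > v[i - 1L] & v[i] > v[i + 1L]
  hit <- interior[is_peak(co, interior) & is_peak(di, interior)]
  if (!length(hit)) {
    return(fallback("no rank is a local maximum of both metrics; using global cophenetic maximum"))
  }
  tab$k[hit[1L]]
}

#' Kim-Park feature relevance scores
#'
#' Scores how specifically each protein loads on one NMF component: the row
#' of the basis matrix `W` is normalized to a probability profile
#' `p(i, q) = W[i, q] / sum_q W[i, q]` and the score is one minus its
#' normalized entropy, `1 + (1 / log2(k)) * sum_q p * log2(p)` (with
#' `0 * log 0 = 0`). The score is 1 for a one-hot row (fully
#' cluster-specific), 0 for a uniform row, and invariant to row rescaling.
#' All-zero rows score 0 with a warning. Proteins scoring strictly above the
#' `percentile`-th linear-interpolation percentile are flagged as selected.
#'
#' @param W Nonnegative basis matrix (proteins x k), `k >= 2`, with protein
#'   ids as rownames.
#' @param percentile Selection percentile (default 90, i.e. the top ~10%).
#' @return A tibble of class `relevance_scores` with columns `protein_id`,
#'   `score`, `selected`; the threshold value is attached as attribute
#'   `threshold`.
#' @export
relevance_scores <- function(W, percentile = 90) {
  W <- as.matrix(W)
  k <- ncol(W)
  if (k < 2L) rlang::abort("relevance scores need k >= 2 components")
  if (any(W < 0)) rlang::abort("W must be nonnegative")
  rs <- rowSums(W)
  if (any(rs == 0)) rlang::warn(sprintf("%d all-zero basis row(s) scored 0", sum(rs == 0)))
  P <- W / ifelse(rs == 0, 1, rs)
  plogp <- ifelse(P > 0, P * log2(P), 0)
  score <- 1 + rowSums(plogp) / log2(k)
  score[rs == 0] <- 0
  thr <- unname(stats::quantile(score, percentile / 100, type = 7))
  ids <- rownames(W)
  if (is.null(ids)) ids <- sprintf("feature%04d", seq_len(nrow(W)))
  out <- tibble::tibble(protein_id = ids, score = unname(score), selected = score > thr)
  structure(out, threshold = thr, percentile = percentile,
            class = c("relevance_scores", class(out)))
}

#' Principal component embedding of the samples
#'
#' Column-centered PCA with samples as observations and proteins as
#' variables. With `impute = FALSE` the analysis is restricted to proteins
#' quantified in every sample (the 100%-valid-value view); with
#' `impute = TRUE` the matrix is mean-imputed first. Component signs are
#' fixed so the loading with the largest magnitude on each component is
#' positive, making results deterministic.
#'
#' @param x A log2-scale intensity table.
#' @param impute Mean-impute missing values (`TRUE`) or restrict to complete
#'   proteins (`FALSE`, default).
#' @param n_components Number of components to keep.
#' @return Object of class `pca_embed`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ...), `explained_variance` (fractions),
#'   `n_proteins_used`, `imputed`.
#' @export
pca_embed <- function(x, impute = FALSE, n_components = 2L) {
  stopifnot(inherits(x, "intensity_tbl"))
  if (intensity_scale(x) != "log2") rlang::abort("pca_embed expects a log2-scale matrix")
  if (impute) x <- impute_mean(x)
  v <- im_values(x)
  v <- v[rowSums(is.na(v)) == 0L, , drop = FALSE]
  if (nrow(v) < 2L) rlang::abort("fewer than 2 complete proteins; impute or filter first")
  obs <- t(v)  # samples x proteins
  pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(n_components), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = tibble::tibble(sample_id = rownames(obs),
                            !!!as.data.frame(scores)),
    explained_variance = ev[seq_len(n_components)],
    n_proteins_used = nrow(v),
    imputed = impute
  ), class = "pca_embed")
}

#' @exportS3Method generics::tidy
tidy.nmf_sweep <- function(x, ...) x$table

#' @exportS3Method generics::tidy
tidy.consensus_result <- function(x, ...) x$labels

#' @exportS3Method generics::glance
glance.consensus_result <- function(x, ...) {
  tibble::tibble(k = x$k, cophenetic = x$cophenetic, dispersion = x$dispersion,
                 n_runs = x$n_runs, best_error = min(x$reconstruction_errors),
                 n_clusters_realized = dplyr::n_distinct(x$labels$cluster))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("# consensus NMF: k = %d, %d runs, cophenetic = %.3f, dispersion = %.3f\n",
              x$k, x$n_runs, x$cophenetic, x$dispersion))
  invisible(x)
}

#' Rank-selection diagnostics plot
#'
#' @param object An `nmf_sweep`.
#' @param ... Unused.
#' @return A ggplot object showing cophenetic correlation and dispersion by
#'   rank.
#' @exportS3Method ggplot2::autoplot
autoplot.nmf_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(object$table, c("cophenetic", "dispersion"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = object$table$k) +
    ggplot2::labs(x = "rank k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Consensus-matrix heatmap
#'
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot tile map of the consensus matrix with samples ordered by
#'   the dendrogram used for the labels.
#' @exportS3Method ggplot2::autoplot
autoplot.consensus_result <- function(object, ...) {
  C <- object$consensus
  ord <- stats::hclust(stats::as.dist(1 - C), method = "average")$order
  df <- tibble::as_tibble(as.table(C[ord, ord]), .name_repair = ~ c("a", "b", "consensus"))
  df$a <- factor(df$a, levels = colnames(C)[ord])
  df$b <- factor(df$b, levels = colnames(C)[ord])
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#1f4e79", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' PCA scatter of the samples
#'
#' @param object A `pca_embed`.
#' @param sheet Optional sample sheet; points are coloured by tissue type
#'   and labelled with metastasis localization codes when provided.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_embed <- function(object, sheet = NULL, ...) {
  df <- object$scores
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$explained_variance[1:2])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  if (!is.null(sheet)) {
    df <- dplyr::left_join(df, validate_sample_sheet(sheet), by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$tissue_type)) +
      ggplot2::geom_text(ggplot2::aes(label = dplyr::coalesce(.data$localization, "P")),
                         size = 3, vjust = -1, show.legend = FALSE)
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL) +
    ggplot2::theme_minimal()
}
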