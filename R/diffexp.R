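#' Two-sided Mann-Whitney U test
#'
#' Computes the rank-sum U statistic for `x` versus `y` (the number of
#' (x, y) pairs with x > y, counting ties as one half) and a two-sided
#' p-value: exact by enumeration of all label assignments when the combined
#' sample size is at most `exact_limit` and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact p-value; `NULL`
#'   (default) applies the size/tie rule above. Exact with ties is refused.
#' @param exact_limit Combined-size cutoff for the automatic exact rule.
#' @return A one-row tibble with columns `u` and `p_value`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_limit = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) rlang::abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (length(x) + length(y) <= exact_limit) && !ties
  if (exact && ties) rlang::abort("exact p-value is unavailable with ties")
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE, conf.int = FALSE)
  )
  tibble::tibble(u = unname(ht$statistic), p_value = min(1, ht$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: monotone, capped at 1,
#' returned in the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) rlang::abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pooled-group Mann-Whitney differential expression
#'
#' Tests every protein between all primary and all metastasis samples with
#' an unpaired two-sided Mann-Whitney U test over the valid (unimputed)
#' values, computes the log2 fold change as the difference of per-group
#' means of log2 intensities (primary minus metastasis, so a negative value
#' means higher in metastases), and classifies proteins against a volcano
#' rule: significant and `log2fc >= lfc_threshold` is `up_primary`,
#' significant and `log2fc <= -lfc_threshold` is `up_metastasis`, anything
#' else `not_significant`. Proteins with fewer than two valid values in
#' either group are reported with `p_value = NA` and `de_class = NA` and do
#' not enter significance counts. Benjamini-Hochberg adjusted p-values are
#' reported alongside; the class call uses the unadjusted p.
#'
#' @param x A log2-scale, unimputed intensity table.
#' @param sheet Sample sheet covering every sample column of `x`.
#' @param p_threshold Unadjusted significance threshold (default 0.05).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 0.5).
#' @param fc_estimator `"mean"` (default) or `"median"` of per-group log2
#'   values for the fold-change estimate.
#' @param exact `NULL`/`TRUE`/`FALSE`, passed to [mann_whitney_u()].
#' @return A tibble of class `de_table`, one row per protein, ordered as the
#'   input: `protein_id`, `n_primary`, `n_metastasis`, `mean_log2_primary`,
#'   `mean_log2_metastasis`, `log2fc`, `u_statistic`, `p_value`, `p_bh`,
#'   `de_class`. Thresholds are attached as attributes.
#' @export
run_diffexp <- function(x, sheet, p_threshold = 0.05, lfc_threshold = 0.5,
                        fc_estimator = c("mean", "median"), exact = NULL) {
  stopifnot(inherits(x, "intensity_tbl"))
  if (intensity_scale(x) != "log2") rlang::abort("run_diffexp expects a log2-scale matrix")
  fc_estimator <- match.arg(fc_estimator)
  sheet <- validate_sample_sheet(sheet)
  v <- im_values(x)
  unknown <- setdiff(colnames(v), sheet$sample_id)
  if (length(unknown)) {
    rlang::abort(paste0("sample(s) missing from sheet: ", paste(unknown, collapse = ", ")))
  }
  grp <- sheet$tissue_type[match(colnames(v), sheet$sample_id)]
  if (!any(grp == "primary") || !any(grp == "metastasis")) {
    rlang::abort("both tissue groups must be present in the matrix")
  }
  est <- if (fc_estimator == "mean") mean else stats::median
  rows <- purrr::map(seq_len(nrow(v)), function(i) {
    xp <- v[i, grp == "primary"]; xm <- v[i, grp == "metastasis"]
    xp <- xp[!is.na(xp)]; xm <- xm[!is.na(xm)]
    rec <- tibble::tibble(
      protein_id = rownames(v)[i],
      n_primary = length(xp), n_metastasis = length(xm),
      mean_log2_primary = if (length(xp)) est(xp) else NA_real_,
      mean_log2_metastasis = if (length(xm)) est(xm) else NA_real_,
      u_statistic = NA_real_, p_value = NA_real_
    )
    if (length(xp) >= 2L && length(xm) >= 2L) {
      mw <- mann_whitney_u(xp, xm, exact = exact)
      rec$u_statistic <- mw$u; rec$p_value <- mw$p_value
    }
    rec
  })
  out <- dplyr::bind_rows(rows)
  out$log2fc <- out$mean_log2_primary - out$mean_log2_metastasis
  out$p_bh <- bh_adjust(out$p_value)
  out$de_class <- dplyr::case_when(
    is.na(out$p_value) ~ NA_character_,
    out$p_value <= p_threshold & out$log2fc >= lfc_threshold ~ "up_primary",
    out$p_value <= p_threshold & out$log2fc <= -lfc_threshold ~ "up_metastasis",
    TRUE ~ "not_significant"
  )
  out <- out[, c("protein_id", "n_primary", "n_metastasis", "mean_log2_primary",
                 "mean_log2_metastasis", "log2fc", "u_statistic", "p_value",
                 "p_bh", "de_class")]
  structure(out, p_threshold = p_threshold, lfc_threshold = lfc_threshold,
            class = c("de_table", class(out)))
}

#' @exportS3Method generics::glance
glance.de_table <- function(x, ...) {
  p_thr <- attr(x, "p_threshold"); l_thr <- attr(x, "lfc_threshold")
  sig <- !is.na(x$p_value) & x$p_value <= p_thr
  tibble::tibble(
    n_proteins = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_significant = sum(sig),
    n_fc_qualified = sum(sig & abs(x$log2fc) >= l_thr, na.rm = TRUE),
    n_up_primary = sum(x$de_class == "up_primary", na.rm = TRUE),
    n_up_metastasis = sum(x$de_class == "up_metastasis", na.rm = TRUE),
    p_threshold = p_thr, lfc_threshold = l_thr
  )
}

#' Volcano plot of a differential-expression table
#'
#' Plots `-log10(p)` against the log2 fold change with the significance and
#' fold-change thresholds drawn as reference lines; metastasis-up proteins
#' (negative fold changes) sit on the left.
#'
#' @param object A `de_table` from [run_diffexp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.de_table <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_value),
                                   colour = .data$de_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "p_threshold")), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "lfc_threshold"), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up_metastasis = "#c0392b",
                                            up_primary = "#2980b9",
                                            not_significant = "grey60")) +
    ggplot2::labs(x = "log2 fold change (primary - metastasis)",
                  y = "-log10 unadjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}
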