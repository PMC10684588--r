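#' Select invariant proteins for normalization
#'
#' Among proteins quantified in every sample, returns the `n_invariant` with
#' the smallest variance of log2 intensity across samples — proteins whose
#' abundance is stable over the cohort and therefore tracks sample loading
#' rather than biology. Ties are broken deterministically by protein id. If
#' fewer complete proteins exist than requested, all of them are returned
#' with a warning.
#'
#' The low-variance criterion is the default of a pluggable ranking: pass a
#' different `statistic` function (protein row -> nonnegative score, smaller
#' = more invariant) to plug in an alternative invariance model.
#'
#' @param x A log2-scale intensity table.
#' @param n_invariant Number of invariant proteins to select (default 100).
#' @param statistic Function scoring one numeric row; smaller is more
#'   invariant. Defaults to [stats::var()].
#' @return Character vector of selected protein ids.
#' @export
select_invariant <- function(x, n_invariant = 100, statistic = stats::var) {
  stopifnot(inherits(x, "intensity_tbl"))
  if (intensity_scale(x) != "log2") rlang::abort("select_invariant expects a log2-scale matrix")
  if (n_invariant < 1) rlang::abort("n_invariant must be >= 1")
  v <- im_values(x)
  complete <- v[rowSums(is.na(v)) == 0L, , drop = FALSE]
  if (nrow(complete) == 0L) rlang::abort("no complete proteins available for invariant selection")
  score <- apply(complete, 1L, statistic)
  ord <- order(score, rownames(complete))
  if (nrow(complete) < n_invariant) {
    rlang::warn(sprintf("only %d complete proteins available (%d requested); returning all",
                        nrow(complete), n_invariant))
    n_invariant <- nrow(complete)
  }
  rownames(complete)[ord[seq_len(n_invariant)]]
}

#' Invariant-protein median normalization
#'
#' Removes per-sample depth offsets from a log2 matrix by anchoring every
#' sample's median over a panel of invariant proteins to the cohort grand
#' median: the offset of sample `j` is the median of its invariant-protein
#' log2 values minus the grand median of those per-sample medians, and the
#' normalized value is the input minus the sample offset (equivalent to a
#' per-sample division on the raw scale). Missing values stay missing.
#'
#' @param x A log2-scale intensity table.
#' @param invariant Character vector of invariant protein ids, typically from
#'   [select_invariant()].
#' @return An object of class `normics_norm`: list with `normalized` (the
#'   shifted intensity table), `invariant_proteins`, and `offsets` (tibble
#'   `sample_id`, `offset`). `tidy()` returns the offsets, `glance()` a
#'   one-row summary.
#' @export
normalize_median <- function(x, invariant) {
  stopifnot(inherits(x, "intensity_tbl"))
  if (intensity_scale(x) != "log2") rlang::abort("normalize_median expects a log2-scale matrix")
  invariant <- as.character(invariant)
  if (length(invariant) == 0L) rlang::abort("invariant protein list is empty")
  missing_ids <- setdiff(invariant, protein_ids(x))
  if (length(missing_ids)) {
    rlang::abort(paste0("invariant protein(s) absent from matrix: ",
                        paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  v <- im_values(x)
  inv <- v[invariant, , drop = FALSE]
  n_ok <- colSums(!is.na(inv))
  if (any(n_ok == 0L)) {
    rlang::abort(paste0("sample(s) with all invariant proteins missing: ",
                        paste(colnames(inv)[n_ok == 0L], collapse = ", ")))
  }
  med <- apply(inv, 2L, stats::median, na.rm = TRUE)
  grand <- stats::median(med)
  offset <- med - grand
  out <- sweep(v, 2L, offset, "-")
  structure(list(
    normalized = im_rebuild(out, x),
    invariant_proteins = invariant,
    offsets = tibble::tibble(sample_id = colnames(v), offset = unname(offset)),
    grand_median = grand
  ), class = "normics_norm")
}

#' @export
print.normics_norm <- function(x, ...) {
  cat(sprintf("# invariant-protein median normalization: %d invariant proteins, %d samples\n",
              length(x$invariant_proteins), nrow(x$offsets)))
  cat(sprintf("#   offsets: min %.3f, median %.3f, max %.3f (log2)\n",
              min(x$offsets$offset), stats::median(x$offsets$offset), max(x$offsets$offset)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.normics_norm <- function(x, ...) x$offsets

#' @exportS3Method generics::glance
glance.normics_norm <- function(x, ...) {
  tibble::tibble(n_invariant = length(x$invariant_proteins),
                 n_samples = nrow(x$offsets),
                 grand_median = x$grand_median,
                 max_abs_offset = max(abs(x$offsets$offset)))
}
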