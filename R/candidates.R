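#' Nominate candidates by intersecting DE and cluster-relevance sets
#'
#' Candidates are the proteins that are both significantly differentially
#' expressed in the pooled primary-vs-metastasis comparison and among the
#' most cluster-relevant proteins of the consensus NMF — two orthogonal
#' lines of evidence. By default the DE side is the full significant set
#' (unadjusted `p <= p_threshold`); set `require_lfc = TRUE` to restrict to
#' the fold-change-qualified classes.
#'
#' @param de A `de_table` from [run_diffexp()].
#' @param relevant Character vector of cluster-relevant protein ids, or a
#'   `relevance_scores` tibble (its `selected` rows are used).
#' @param p_threshold Significance cut on the unadjusted p (default the
#'   table's own threshold attribute).
#' @param require_lfc Restrict the DE side to `up_primary`/`up_metastasis`
#'   calls (default `FALSE`).
#' @return A tibble of class `candidate_table`, ordered by ascending p:
#'   `protein_id`, `de_class`, `log2fc`, `p_value`, `relevance_score`
#'   (`NA` when `relevant` is a plain id vector), `direction`.
#' @export
intersect_candidates <- function(de, relevant, p_threshold = NULL, require_lfc = FALSE) {
  stopifnot(inherits(de, "de_table") || is.data.frame(de))
  if (is.null(p_threshold)) p_threshold <- attr(de, "p_threshold") %||% 0.05
  scores <- NULL
  if (inherits(relevant, "relevance_scores") ||
      (is.data.frame(relevant) && all(c("protein_id", "score") %in% names(relevant)))) {
    scores <- relevant
    relevant_ids <- relevant$protein_id[relevant$selected]
  } else {
    relevant_ids <- as.character(relevant)
  }
  de <- tibble::as_tibble(de)
  sig <- de[!is.na(de$p_value) & de$p_value <= p_threshold, , drop = FALSE]
  if (require_lfc) sig <- sig[sig$de_class %in% c("up_primary", "up_metastasis"), , drop = FALSE]
  out <- sig[sig$protein_id %in% relevant_ids,
             c("protein_id", "de_class", "log2fc", "p_value"), drop = FALSE]
  out$relevance_score <- if (is.null(scores)) NA_real_ else
    scores$score[match(out$protein_id, scores$protein_id)]
  out$direction <- dplyr::case_when(
    out$log2fc < 0 ~ "higher_in_metastases",
    out$log2fc > 0 ~ "higher_in_primaries",
    TRUE ~ "flat"
  )
  out <- dplyr::arrange(out, .data$p_value, .data$protein_id)
  structure(out, class = c("candidate_table", class(out)))
}

#' Normalize immunoblot densitometry across gels
#'
#' Band densities from different gels are made comparable by dividing each
#' sample's raw density by the mean density of the cross-blot standards run
#' on the same gel, and then by the sample's loading-control density.
#' Technical replicates of a sample (several rows) are averaged after
#' normalization.
#'
#' @param measurements Tibble with columns `sample_id`, `gel_id`,
#'   `raw_density`, `loading_control_density`, and `is_standard` (logical;
#'   standard rows need no loading control).
#' @return A tibble with columns `sample_id`, `normalized`.
#' @export
blot_normalize <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  need <- c("sample_id", "gel_id", "raw_density", "is_standard")
  miss <- setdiff(need, names(m))
  if (length(miss)) rlang::abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  std <- dplyr::filter(m, .data$is_standard)
  smp <- dplyr::filter(m, !.data$is_standard)
  if (any(std$raw_density <= 0, na.rm = TRUE) || anyNA(std$raw_density)) {
    rlang::abort("standard densities must be positive")
  }
  gel_mean <- dplyr::summarise(dplyr::group_by(std, .data$gel_id),
                               std_mean = mean(.data$raw_density), .groups = "drop")
  no_std <- setdiff(unique(smp$gel_id), gel_mean$gel_id)
  if (length(no_std)) {
    rlang::abort(paste0("gel(s) without standards: ", paste(no_std, collapse = ", ")))
  }
  smp <- dplyr::left_join(smp, gel_mean, by = "gel_id")
  if (!"loading_control_density" %in% names(smp) ||
      anyNA(smp$loading_control_density) || any(smp$loading_control_density <= 0)) {
    bad <- if ("loading_control_density" %in% names(smp)) {
      smp$sample_id[is.na(smp$loading_control_density) | smp$loading_control_density <= 0]
    } else unique(smp$sample_id)
    rlang::abort(paste0("missing or nonpositive loading control for sample(s): ",
                        paste(utils::head(unique(bad), 5), collapse = ", ")))
  }
  smp$normalized <- (smp$raw_density / smp$std_mean) / smp$loading_control_density
  dplyr::summarise(dplyr::group_by(smp, .data$sample_id),
                   normalized = mean(.data$normalized), .groups = "drop")
}

#' Compare normalized blot intensities between tissue groups
#'
#' Delegates to the same unpaired two-sided Mann-Whitney U test used for
#' the proteomic differential expression.
#'
#' @param normalized Tibble with columns `sample_id`, `normalized` (from
#'   [blot_normalize()]), optionally `protein` for several targets at once.
#' @param sheet Sample sheet assigning `tissue_type` to each sample.
#' @return A tibble with one row (per protein if given): `u`, `p_value`,
#'   `n_primary`, `n_metastasis`.
#' @export
blot_compare <- function(normalized, sheet) {
  sheet <- validate_sample_sheet(sheet)
  df <- dplyr::left_join(tibble::as_tibble(normalized), sheet, by = "sample_id")
  if (anyNA(df$tissue_type)) {
    rlang::abort(paste0("sample(s) absent from sheet: ",
                        paste(df$sample_id[is.na(df$tissue_type)], collapse = ", ")))
  }
  one <- function(d) {
    xp <- d$normalized[d$tissue_type == "primary"]
    xm <- d$normalized[d$tissue_type == "metastasis"]
    if (!length(xp) || !length(xm)) rlang::abort("both tissue groups must be represented")
    mw <- mann_whitney_u(xp, xm)
    tibble::tibble(u = mw$u, p_value = mw$p_value,
                   n_primary = length(xp), n_metastasis = length(xm))
  }
  if ("protein" %in% names(df)) {
    dplyr::group_modify(dplyr::group_by(df, .data$protein), ~ one(.x)) |> dplyr::ungroup()
  } else {
    one(df)
  }
}
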