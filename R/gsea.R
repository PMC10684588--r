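#' Read a GMT gene-set collection
#'
#' Each GMT line is tab-separated: set name, description, then one or more
#' member gene symbols. Duplicate members within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_name`, `description`, and `genes`
#'   (list column of character vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(set_name = character(), description = character(),
                          genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    rlang::abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  out <- tibble::tibble(
    set_name = purrr::map_chr(parts, 1L),
    description = purrr::map_chr(parts, 2L),
    genes = purrr::map(parts, ~ unique(.x[-(1:2)]))
  )
  if (anyDuplicated(out$set_name)) {
    rlang::abort(paste0("duplicate set name(s): ",
                        paste(unique(out$set_name[duplicated(out$set_name)]), collapse = ", ")))
  }
  out
}

#' @rdname read_gmt
#' @param collection A gene-set tibble as returned by `read_gmt()`.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set_name, description, genes, ...) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

# vectorized pooled-variance two-sample t over the rows of a matrix with NAs;
# numerator is primary minus metastasis; var_floor guards ties
row_t_stats <- function(v, is_primary, var_floor = 1e-8) {
  ok <- !is.na(v)
  vz <- ifelse(ok, v, 0)
  n1 <- rowSums(ok[, is_primary, drop = FALSE])
  n2 <- rowSums(ok[, !is_primary, drop = FALSE])
  s1 <- rowSums(vz[, is_primary, drop = FALSE])
  s2 <- rowSums(vz[, !is_primary, drop = FALSE])
  q1 <- rowSums(vz[, is_primary, drop = FALSE]^2)
  q2 <- rowSums(vz[, !is_primary, drop = FALSE]^2)
  m1 <- s1 / n1; m2 <- s2 / n2
  ss1 <- q1 - n1 * m1^2
  ss2 <- q2 - n2 * m2^2
  df <- n1 + n2 - 2
  sp2 <- pmax((ss1 + ss2) / pmax(df, 1), var_floor)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[n1 < 2 | n2 < 2] <- NA_real_
  t
}

#' Rank proteins by a two-sample t statistic
#'
#' Pooled-variance two-sample t per protein over the valid (unimputed)
#' values, primary minus metastasis in the numerator, with a small variance
#' floor so tied values cannot produce infinite statistics. Proteins with
#' fewer than two valid values in either group are dropped with a warning.
#' Output is sorted by decreasing t with a deterministic tie-break on
#' protein id.
#'
#' @param x A log2-scale intensity table.
#' @param sheet Sample sheet covering the matrix samples.
#' @param var_floor Lower bound on the pooled variance (default 1e-8).
#' @return A tibble with columns `protein_id`, `t`, ordered for GSEA.
#' @export
rank_by_t <- function(x, sheet, var_floor = 1e-8) {
  stopifnot(inherits(x, "intensity_tbl"))
  sheet <- validate_sample_sheet(sheet)
  v <- im_values(x)
  grp <- sheet$tissue_type[match(colnames(v), sheet$sample_id)]
  if (anyNA(grp)) rlang::abort("matrix contains samples absent from the sheet")
  if (!any(grp == "primary") || !any(grp == "metastasis")) {
    rlang::abort("both tissue groups must be present")
  }
  t <- row_t_stats(v, grp == "primary", var_floor)
  drop <- is.na(t)
  if (any(drop)) {
    rlang::warn(sprintf("%d protein(s) dropped: fewer than 2 valid values in a group", sum(drop)))
  }
  out <- tibble::tibble(protein_id = rownames(v)[!drop], t = unname(t[!drop]))
  dplyr::arrange(out, dplyr::desc(.data$t), .data$protein_id)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom: hitting a set member adds its
#' weighted statistic share `|t|^weight / sum_hits |t|^weight`; missing one
#' subtracts `1 / (N - N_hits)`. The enrichment score is the running sum's
#' maximum deviation from zero, signed.
#'
#' @param ranked A tibble from [rank_by_t()] (columns `protein_id`, `t`),
#'   already ordered.
#' @param set Character vector of member gene/protein ids.
#' @param weight Exponent on `|t|` for hit increments (default 1; 0 gives
#'   the classic unweighted statistic).
#' @return List with `es` and `running` (tibble `protein_id`, `running_sum`).
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  hit <- ranked$protein_id %in% set
  if (!any(hit)) rlang::abort("set has no members in the ranked list")
  n <- nrow(ranked)
  n_hit <- sum(hit)
  if (n_hit == n) {
    w <- abs(ranked$t)^weight
    run <- cumsum(w / sum(w))
  } else {
    w <- abs(ranked$t)^weight
    inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - n_hit))
    run <- cumsum(inc)
  }
  es <- run[which.max(abs(run))]
  list(es = es, running = tibble::tibble(protein_id = ranked$protein_id, running_sum = run))
}

# ES only, from a precomputed t vector in ranked order and a hit mask
es_from_t <- function(t_ranked, hit, weight = 1) {
  n <- length(t_ranked)
  n_hit <- sum(hit)
  w <- abs(t_ranked)^weight
  denom <- sum(w[hit])
  if (denom == 0) denom <- 1
  inc <- ifelse(hit, w / denom, if (n_hit == n) 0 else -1 / (n - n_hit))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Phenotype-permutation gene set enrichment analysis
#'
#' GSEA on the primary-vs-metastasis contrast: proteins are ranked by the
#' two-sample t statistic of [rank_by_t()], each set's enrichment score (ES)
#' is the weighted running-sum statistic of [enrichment_score()], and the
#' null distribution comes from re-ranking under random permutations of the
#' tissue labels (phenotype permutation, which preserves the correlation
#' structure between proteins). For each set, the nominal p-value is
#' `(1 + b) / (1 + m)` where `m` counts permutation scores with the same
#' sign as the observed ES and `b` those at least as extreme; the normalized
#' enrichment score (NES) divides the ES by the mean magnitude of same-sign
#' permutation scores; and the FDR q-value compares the pooled permutation
#' NES distribution with the observed NES distribution, separately by sign,
#' as in standard GSEA practice.
#'
#' Protein ids are matched to gene-set members directly; supply `mapping`
#' (a two-column data frame, `protein_id` then gene symbol) to translate
#' first.
#'
#' @param x A log2-scale, unimputed intensity table.
#' @param sheet Sample sheet covering the matrix samples.
#' @param collection Gene-set tibble from [read_gmt()].
#' @param n_perm Number of label permutations (>= 10; default 100).
#' @param seed Integer seed (default 7).
#' @param min_size,max_size Set-size bounds applied after intersection with
#'   the measured proteins (defaults 5 and 500).
#' @param weight Hit-increment exponent (default 1).
#' @param mapping Optional two-column protein-to-gene mapping.
#' @return A tibble of class `gsea_table`, ordered by FDR then `-|NES|`:
#'   `set_name`, `size`, `es`, `nes`, `p_value`, `fdr_q`, `leading_edge`
#'   (list column).
#' @export
run_gsea <- function(x, sheet, collection, n_perm = 100L, seed = 7L,
                     min_size = 5L, max_size = 500L, weight = 1, mapping = NULL) {
  if (n_perm < 10L) rlang::abort("n_perm must be >= 10 (smaller nulls are unstable)")
  stopifnot(inherits(x, "intensity_tbl"))
  sheet <- validate_sample_sheet(sheet)
  v <- im_values(x)
  if (!is.null(mapping)) {
    mapping <- as.data.frame(mapping)
    sym <- mapping[[2]][match(rownames(v), mapping[[1]])]
    keep <- !is.na(sym)
    v <- v[keep, , drop = FALSE]
    rownames(v) <- sym[keep]
  }
  grp <- sheet$tissue_type[match(colnames(v), sheet$sample_id)]
  if (anyNA(grp)) rlang::abort("matrix contains samples absent from the sheet")
  is_primary <- grp == "primary"
  if (!any(is_primary) || all(is_primary)) rlang::abort("both tissue groups must be present")

  t_obs <- row_t_stats(v, is_primary)
  measured <- rownames(v)[!is.na(t_obs)]
  v <- v[!is.na(t_obs), , drop = FALSE]

  sets <- purrr::map(collection$genes, ~ intersect(.x, measured))
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  skipped <- collection$set_name[lengths(sets) == 0L]
  if (length(skipped)) {
    rlang::warn(paste0("set(s) disjoint from measured proteins skipped: ",
                       paste(utils::head(skipped, 5), collapse = ", ")))
  }
  collection <- collection[keep, , drop = FALSE]
  sets <- sets[keep]
  if (!nrow(collection)) {
    return(structure(tibble::tibble(set_name = character(), size = integer(),
                                    es = double(), nes = double(), p_value = double(),
                                    fdr_q = double(), leading_edge = list()),
                     class = c("gsea_table", class(tibble::tibble()))))
  }

  rank_order <- function(t) order(-t, rownames(v))
  ord <- rank_order(row_t_stats(v, is_primary))
  t_ranked <- row_t_stats(v, is_primary)[ord]
  ids_ranked <- rownames(v)[ord]
  hits <- purrr::map(sets, ~ ids_ranked %in% .x)
  es_obs <- purrr::map_dbl(hits, ~ es_from_t(t_ranked, .x, weight))

  n_sets <- length(sets)
  es_perm <- matrix(NA_real_, n_sets, n_perm)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(is_primary)
      t_p <- row_t_stats(v, perm)
      t_p[is.na(t_p)] <- 0
      op <- order(-t_p, rownames(v))
      t_pr <- t_p[op]
      ids_pr <- rownames(v)[op]
      for (s in seq_len(n_sets)) {
        es_perm[s, b] <- es_from_t(t_pr, ids_pr %in% sets[[s]], weight)
      }
    }
  })

  norm_one <- function(es, null) {
    same <- null[sign(null) == sign(es) & null != 0]
    if (!length(same)) return(c(nes = NA_real_, p = 1))
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    c(nes = es / mean(abs(same)), p = p)
  }
  np <- purrr::map2(es_obs, seq_len(n_sets), ~ norm_one(.x, es_perm[.y, ]))
  nes_obs <- purrr::map_dbl(np, "nes")
  p_nom <- purrr::map_dbl(np, "p")

  # pooled permutation NES (each permutation score normalized by its set's
  # same-sign mean magnitude), FDR by sign as in standard GSEA
  nes_perm <- es_perm
  for (s in seq_len(n_sets)) {
    null <- es_perm[s, ]
    for (sgn in c(-1, 1)) {
      same <- null[sign(null) == sgn]
      m <- mean(abs(same))
      if (length(same)) nes_perm[s, sign(null) == sgn] <- null[sign(null) == sgn] / m
    }
  }
  all_perm <- as.vector(nes_perm)
  fdr <- vapply(seq_len(n_sets), function(s) {
    nes <- nes_obs[s]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num_pool <- all_perm[all_perm >= 0]; num <- mean(num_pool >= nes)
      den_pool <- nes_obs[!is.na(nes_obs) & nes_obs >= 0]; den <- mean(den_pool >= nes)
    } else {
      num_pool <- all_perm[all_perm <= 0]; num <- mean(num_pool <= nes)
      den_pool <- nes_obs[!is.na(nes_obs) & nes_obs <= 0]; den <- mean(den_pool <= nes)
    }
    if (is.nan(num) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  leading <- purrr::map2(hits, es_obs, function(h, es) {
    run <- cumsum(ifelse(h, abs(t_ranked)^weight / max(sum(abs(t_ranked[h])^weight), 1e-300),
                         if (sum(h) == length(h)) 0 else -1 / (length(h) - sum(h))))
    peak <- which.max(abs(run))
    if (es >= 0) ids_ranked[seq_len(peak)][h[seq_len(peak)]]
    else ids_ranked[peak:length(h)][h[peak:length(h)]]
  })

  out <- tibble::tibble(set_name = collection$set_name, size = lengths(sets),
                        es = es_obs, nes = nes_obs, p_value = p_nom,
                        fdr_q = fdr, leading_edge = leading)
  out <- dplyr::arrange(out, .data$fdr_q, -abs(.data$nes))
  structure(out, n_perm = n_perm, seed = seed, weight = weight,
            min_size = min_size, max_size = max_size,
            class = c("gsea_table", class(out)))
}
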