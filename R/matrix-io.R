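#' Read and write wide intensity matrices
#'
#' The interchange format is a wide delimited text file: the first column
#' holds protein identifiers, the header row holds sample identifiers, and an
#' empty cell (or any string in `missing`) marks an unquantified value.
#'
#' @param path File path.
#' @param delim Field delimiter; tab by default.
#' @param missing Character vector of cell contents to treat as missing.
#' @param scale Scale tag of the stored values (`"raw"` or `"log2"`).
#' @return `read_intensity_matrix()` returns an [as_intensity_tbl()] tibble;
#'   `write_intensity_matrix()` returns `path` invisibly.
#' @export
read_intensity_matrix <- function(path, delim = "\t", missing = c("", "NA", "NaN"),
                                  scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2L) rlang::abort("matrix file needs an id column plus >= 1 sample column")
  smp <- names(raw)[-1]
  if (anyDuplicated(smp)) {
    rlang::abort(paste0("duplicated sample column(s): ",
                        paste(unique(smp[duplicated(smp)]), collapse = ", ")))
  }
  vals <- lapply(seq_along(smp), function(j) {
    cells <- raw[[j + 1L]]
    cells[cells %in% missing | is.na(cells)] <- NA_character_
    out <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(out) & !is.na(cells))
    if (length(bad)) {
      rlang::abort(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                           bad[1], smp[j], cells[bad[1]]))
    }
    out
  })
  names(vals) <- smp
  out <- tibble::tibble(protein_id = as.character(raw[[1]]), !!!vals)
  as_intensity_tbl(out, scale = scale)
}

#' @rdname read_intensity_matrix
#' @param x An intensity table.
#' @export
write_intensity_matrix <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "intensity_tbl"))
  out <- as.data.frame(x)
  # full-precision round trip
  for (j in seq(2L, ncol(out))) {
    out[[j]] <- ifelse(is.na(out[[j]]), "", formatC(out[[j]], digits = 17, format = "g"))
  }
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Read and write sample sheets
#'
#' A sample sheet is a delimited table with columns `sample_id`, `patient_id`,
#' `tissue_type` (`"primary"` or `"metastasis"`) and `localization` (a short
#' site code such as ADR, HEP, KID, OSS, OTH for metastases; empty for
#' primaries).
#'
#' @param path File path.
#' @return A tibble with the four columns above.
#' @export
read_sample_sheet <- function(path, delim = "\t") {
  sheet <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path, delim = "\t") {
  readr::write_delim(validate_sample_sheet(sheet), path, delim = delim, na = "")
  invisible(path)
}

validate_sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  need <- c("sample_id", "patient_id", "tissue_type")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) rlang::abort(paste0("sample sheet lacks column(s): ", paste(miss, collapse = ", ")))
  if (!"localization" %in% names(sheet)) sheet$localization <- NA_character_
  if (anyDuplicated(sheet$sample_id)) {
    rlang::abort(paste0("duplicate sample id(s): ",
                        paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", ")))
  }
  bad <- setdiff(unique(sheet$tissue_type), c("primary", "metastasis"))
  if (length(bad)) {
    rlang::abort(paste0("tissue_type must be 'primary' or 'metastasis'; found: ",
                        paste(bad, collapse = ", ")))
  }
  sheet
}

#' Keep proteins quantified in a minimum fraction of samples
#'
#' Retains exactly the proteins whose valid-value count divided by the total
#' number of samples is at least `min_valid_fraction` (inclusive boundary, so
#' 19 of 38 samples passes a 0.5 filter). Row order is preserved.
#'
#' @param x An intensity table.
#' @param min_valid_fraction Required fraction of samples with a valid value,
#'   in (0, 1]. Default 0.5, the conventional half-of-cohort filter.
#' @return The filtered intensity table.
#' @export
filter_valid <- function(x, min_valid_fraction = 0.5) {
  stopifnot(inherits(x, "intensity_tbl"))
  if (!is.numeric(min_valid_fraction) || length(min_valid_fraction) != 1L ||
      min_valid_fraction <= 0 || min_valid_fraction > 1) {
    rlang::abort("min_valid_fraction must be a single number in (0, 1]")
  }
  v <- im_values(x)
  keep <- rowSums(!is.na(v)) / ncol(v) >= min_valid_fraction
  as_intensity_tbl(x[keep, , drop = FALSE], scale = intensity_scale(x))
}

#' Log2-transform a raw-scale intensity table
#'
#' @param x A raw-scale intensity table with strictly positive values.
#' @return The same table on the log2 scale; missing values stay missing.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "intensity_tbl"))
  if (intensity_scale(x) != "raw") rlang::abort("matrix is already on the log2 scale")
  v <- im_values(x)
  if (any(v <= 0, na.rm = TRUE)) {
    idx <- which(v <= 0, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("cannot log2-transform nonpositive value at protein %s, sample %s",
                         rownames(v)[idx[1]], colnames(v)[idx[2]]))
  }
  im_rebuild(log2(v), x, scale = "log2")
}

#' Replace missing values by the per-protein mean
#'
#' Each missing cell of a protein is replaced by the mean of that protein's
#' valid values — a deliberately conservative imputation that shrinks group
#' differences rather than inventing them. A `"global"` variant substituting
#' the whole-matrix mean is available for sensitivity analysis. Imputation is
#' intended only for PCA and consensus clustering; differential expression and
#' enrichment run on unimputed data.
#'
#' @param x A log2-scale intensity table in which every protein has at least
#'   one valid value (apply [filter_valid()] first).
#' @param method `"protein_mean"` (default) or `"global_mean"`.
#' @return The imputed intensity table (no missing values).
#' @export
impute_mean <- function(x, method = c("protein_mean", "global_mean")) {
  stopifnot(inherits(x, "intensity_tbl"))
  method <- match.arg(method)
  v <- im_values(x)
  nvalid <- rowSums(!is.na(v))
  if (any(nvalid == 0L)) {
    rlang::abort(paste0("protein(s) with no valid values (filter first): ",
                        paste(utils::head(rownames(v)[nvalid == 0L], 5), collapse = ", ")))
  }
  if (method == "protein_mean") {
    fill <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- fill[idx[, 1]]
  } else {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
  }
  im_rebuild(v, x)
}

#' Per-sample coverage summary
#'
#' Counts the valid (quantified) values per sample. The median count is
#' attached as attribute `median_n_valid` and reported by `glance()`.
#'
#' @param x An intensity table.
#' @return A tibble with columns `sample_id` and `n_valid`.
#' @export
coverage_summary <- function(x) {
  stopifnot(inherits(x, "intensity_tbl"))
  v <- im_values(x)
  out <- tibble::tibble(sample_id = colnames(v), n_valid = unname(colSums(!is.na(v))))
  attr(out, "median_n_valid") <- stats::median(out$n_valid)
  out
}
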