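#' Intensity tables
#'
#' An intensity table is a tibble holding a protein-by-sample quantitative
#' matrix: the first column, `protein_id`, carries unique protein identifiers
#' and every remaining column is one sample of positive intensities (raw
#' scale) or real values (log2 scale), with `NA` marking a missing
#' (unquantified) value. A `scale` attribute, `"raw"` or `"log2"`, records
#' which scale the values are on so that transformations can refuse to be
#' applied twice.
#'
#' @param x A data frame whose first column is `protein_id` and whose
#'   remaining columns are numeric sample intensities.
#' @param scale Either `"raw"` (positive intensities) or `"log2"`.
#' @return A tibble of class `intensity_tbl` with a `scale` attribute.
#' @examples
#' m <- as_intensity_tbl(
#'   data.frame(protein_id = c("P1", "P2"), S1 = c(4, 16), S2 = c(8, NA)),
#'   scale = "raw"
#' )
#' intensity_scale(m)
#' @export
as_intensity_tbl <- function(x, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L || names(x)[1] != "protein_id") {
    rlang::abort("an intensity table needs a first column `protein_id` plus >= 1 sample column")
  }
  x$protein_id <- as.character(x$protein_id)
  if (anyDuplicated(x$protein_id)) {
    dup <- unique(x$protein_id[duplicated(x$protein_id)])
    rlang::abort(paste0("duplicate protein id(s): ", paste(dup, collapse = ", ")))
  }
  smp <- names(x)[-1]
  if (anyDuplicated(smp)) {
    rlang::abort(paste0("duplicate sample column(s): ",
                        paste(unique(smp[duplicated(smp)]), collapse = ", ")))
  }
  bad <- smp[!vapply(x[smp], is.numeric, logical(1))]
  if (length(bad)) {
    rlang::abort(paste0("non-numeric sample column(s): ", paste(bad, collapse = ", ")))
  }
  if (scale == "raw") {
    v <- as.matrix(x[smp])
    if (any(v <= 0, na.rm = TRUE)) {
      idx <- which(v <= 0, arr.ind = TRUE)[1, ]
      rlang::abort(sprintf("raw intensities must be positive; protein %s, sample %s is %g",
                           x$protein_id[idx[1]], smp[idx[2]], v[idx[1], idx[2]]))
    }
  }
  structure(x, scale = scale, class = c("intensity_tbl", class(tibble::tibble())))
}

#' @rdname as_intensity_tbl
#' @export
intensity_scale <- function(x) {
  sc <- attr(x, "scale", exact = TRUE)
  if (is.null(sc)) rlang::abort("not an intensity table: no scale attribute")
  sc
}

#' @rdname as_intensity_tbl
#' @export
sample_ids <- function(x) names(x)[-1]

#' @rdname as_intensity_tbl
#' @export
protein_ids <- function(x) x$protein_id

# numeric matrix view, proteins as rownames
im_values <- function(x) {
  v <- as.matrix(x[, -1, drop = FALSE])
  rownames(v) <- x$protein_id
  v
}

# rebuild an intensity_tbl from a values matrix, keeping ids and scale
im_rebuild <- function(values, template, scale = intensity_scale(template)) {
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  out <- tibble::add_column(out, protein_id = rownames(values), .before = 1)
  as_intensity_tbl(out, scale = scale)
}

#' @export
print.intensity_tbl <- function(x, ...) {
  cat(sprintf("# intensity table: %d proteins x %d samples [%s scale], %d missing\n",
              nrow(x), ncol(x) - 1L, intensity_scale(x), sum(is.na(x[, -1]))))
  NextMethod()
}
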