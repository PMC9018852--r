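PM_META <- c("chrom", "start", "end", "peak_id", "assay")

#' Construct a peak signal matrix
#'
#' A peak signal matrix holds one row per peak (cis-regulatory element) and
#' one column per sample, alongside BED-style peak metadata. The object is a
#' plain tibble whose first five columns are `chrom`, `start`, `end`
#' (0-based half-open), `peak_id` and `assay`; every remaining column is one
#' sample. A `layer` attribute tracks the normalisation stage
#' (`raw` -> `size-normalized` -> `residual` -> `int-transformed`), and each
#' pipeline step refuses input from the wrong stage.
#'
#' @param values numeric matrix, peaks x samples, with sample ids as column
#'   names.
#' @param peaks tibble/data.frame with columns `chrom`, `start`, `end`,
#'   `peak_id`, `assay`, one row per row of `values`.
#' @param layer normalisation layer tag.
#' @return a tibble of class `vcm_pm` with the layer recorded as an attribute.
#' @examples
#' pm <- peak_matrix(matrix(rpois(6, 10), 2, 3,
#'                          dimnames = list(NULL, c("s1", "s2", "s3"))),
#'                   tibble::tibble(chrom = "chr1", start = c(0L, 500L),
#'                                  end = c(200L, 900L),
#'                                  peak_id = c("p1", "p2"), assay = "H3K27ac"))
#' peak_layer(pm)
#' @export
peak_matrix <- function(values, peaks,
                        layer = c("raw", "size-normalized", "residual",
                                  "int-transformed")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  peaks <- as_tibble(peaks)
  if (!all(PM_META %in% names(peaks))) {
    abort(paste("`peaks` must have columns", paste(PM_META, collapse = ", ")))
  }
  if (nrow(peaks) != nrow(values)) abort("`peaks` and `values` row counts differ")
  if (is.null(colnames(values))) abort("`values` must carry sample ids as colnames")
  if (anyDuplicated(peaks$peak_id)) abort("duplicate peak_id")
  if (any(peaks$start >= peaks$end)) abort("peak start must be < end")
  if (layer == "raw" && any(values < 0)) abort("raw layer must be non-negative")
  out <- bind_cols(peaks[PM_META], as_tibble(values))
  new_peak_matrix(out, layer)
}

new_peak_matrix <- function(tbl, layer) {
  attr(tbl, "layer") <- layer
  class(tbl) <- unique(c("vcm_pm", class(tbl)))
  tbl
}

#' @rdname peak_matrix
#' @param x a `vcm_pm` peak matrix.
#' @export
peak_layer <- function(x) attr(x, "layer") %||% "raw"

#' @rdname peak_matrix
#' @export
peak_samples <- function(x) setdiff(names(x), PM_META)

#' @rdname peak_matrix
#' @export
peak_meta <- function(x) as_tibble(x)[PM_META]

#' @rdname peak_matrix
#' @export
peak_values <- function(x) {
  v <- as.matrix(as_tibble(x)[peak_samples(x)])
  rownames(v) <- x$peak_id
  v
}

check_layer <- function(x, allowed, fun) {
  if (!peak_layer(x) %in% allowed) {
    abort(sprintf("%s() expects layer %s, got '%s'", fun,
                  paste(sQuote(allowed), collapse = " or "), peak_layer(x)))
  }
  invisible(x)
}

# Rebuild a peak matrix with new values but the same metadata.
pm_replace_values <- function(x, values, layer) {
  peak_matrix_unchecked(peak_meta(x), values, layer)
}

peak_matrix_unchecked <- function(peaks, values, layer) {
  out <- bind_cols(peaks, as_tibble(values))
  new_peak_matrix(out, layer)
}

#' @export
print.vcm_pm <- function(x, ...) {
  cat(sprintf("# Peak signal matrix: %d peaks x %d samples [layer: %s]\n",
              nrow(x), length(peak_samples(x)), peak_layer(x)))
  NextMethod()
}

#' Read / write peak matrices as TSV with a JSON sidecar
#'
#' The TSV layout is `chrom start end peak_id assay <sample...>`; the
#' normalisation layer travels in `<path>.json` so round trips preserve the
#' pipeline stage.
#'
#' @param path TSV file path.
#' @return `read_peak_matrix()` a `vcm_pm`; `write_peak_matrix()` `path`,
#'   invisibly.
#' @export
read_peak_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".json")
  layer <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)$layer
  } else "raw"
  peak_matrix(as.matrix(tbl[setdiff(names(tbl), PM_META)]), tbl[PM_META],
              layer = layer)
}

#' @rdname read_peak_matrix
#' @param x a `vcm_pm` peak matrix.
#' @export
write_peak_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  jsonlite::write_json(list(layer = peak_layer(x)), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
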