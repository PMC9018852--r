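#' Library-size normalisation by median-of-ratios
#'
#' First stage of the normalisation chain. For paired-end counting pipelines
#' that report fragments as half-reads, counts are doubled before size-factor
#' estimation. Per-sample size factors are the median, across peaks, of the
#' ratio of the sample's count to the peak's geometric mean (peaks with any
#' zero are excluded from factor estimation, as their geometric mean is zero);
#' counts are divided by the factors.
#'
#' @param matrix a `vcm_pm` with layer `raw`.
#' @param paired_end if `TRUE`, all counts are multiplied by two before
#'   size-factor estimation.
#' @return a `vcm_pm` with layer `size-normalized`.
#' @seealso [regress_covariates()], [rank_inverse_normal()]
#' @export
normalize_counts <- function(matrix, paired_end = FALSE) {
  check_layer(matrix, "raw", "normalize_counts")
  v <- peak_values(matrix)
  if (paired_end) v <- v * 2
  sf <- size_factors(v)
  pm_replace_values(matrix, sweep(v, 2, sf, "/"), "size-normalized")
}

size_factors <- function(v) {
  log_geo <- rowMeans(log(v))
  use <- is.finite(log_geo)
  if (!any(use)) abort("no peak has all-positive counts; size factors undefined")
  apply(v, 2, function(col) exp(stats::median(log(col[use]) - log_geo[use])))
}

#' Regress covariates out of a peak matrix
#'
#' Per peak, replaces values by ordinary-least-squares residuals against an
#' intercept plus the supplied covariates (sample-level confounders such as
#' sex, batch or genotype PCs). Residuals per peak sum to zero.
#'
#' @param matrix a `vcm_pm` with layer `size-normalized`.
#' @param covariates tibble with a `sample_id` column and one numeric column
#'   per covariate; sample order need not match (joined by id). `NULL` fits
#'   intercept only (mean-centering).
#' @return a `vcm_pm` with layer `residual`.
#' @export
regress_covariates <- function(matrix, covariates = NULL) {
  check_layer(matrix, "size-normalized", "regress_covariates")
  v <- peak_values(matrix)
  n <- ncol(v)
  if (is.null(covariates) || ncol(covariates) <= 1L) {
    res <- v - rowMeans(v)
  } else {
    covariates <- as_tibble(covariates)
    if (!"sample_id" %in% names(covariates)) abort("covariates need `sample_id`")
    idx <- match(colnames(v), covariates$sample_id)
    if (anyNA(idx)) abort("covariates missing for some samples")
    X <- cbind(`(Intercept)` = 1,
               as.matrix(covariates[idx, setdiff(names(covariates), "sample_id")]))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      abort(paste("covariate matrix is rank deficient; collinear columns:",
                  paste(dropped, collapse = ", ")))
    }
    res <- t(qr.resid(qx, t(v)))
  }
  pm_replace_values(matrix, res, "residual")
}

#' Rank-based inverse normal transform
#'
#' Per peak across samples (the QTL-mapping convention), values are replaced
#' by `qnorm((rank - 3/8) / (n + 1/4))` (Blom offsets); ties get average
#' ranks. A per-sample mode (transforming each individual's profile across
#' peaks instead) is available behind `per_sample`.
#'
#' @param matrix a `vcm_pm` with layer `residual` or `size-normalized`.
#' @param per_sample transform each sample across peaks instead of each peak
#'   across samples.
#' @return a `vcm_pm` with layer `int-transformed`.
#' @export
rank_inverse_normal <- function(matrix, per_sample = FALSE) {
  check_layer(matrix, c("residual", "size-normalized"), "rank_inverse_normal")
  v <- peak_values(matrix)
  int1 <- function(x) {
    if (length(unique(x)) == 1L) {
      abort("constant row/column: inverse-normal transform undefined")
    }
    stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
  }
  out <- if (per_sample) apply(v, 2, int1) else t(apply(v, 1, int1))
  dimnames(out) <- dimnames(v)
  pm_replace_values(matrix, out, "int-transformed")
}
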