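#' Module activity score (aVCM) as the first principal component
#'
#' The activity of a module across individuals is the first principal
#' component of the samples-by-member-peaks submatrix (peaks standardised
#' first). PC1's sign is intrinsically arbitrary; it is fixed so the score
#' correlates positively with the mean standardised member signal, making
#' "higher score" mean "more active chromatin". The score is re-standardised
#' to mean 0, variance 1.
#'
#' @param matrix a `vcm_pm` with layer `int-transformed` (the scale modules
#'   were called on).
#' @param module one row of a `vcm_set` tibble (or any list with `module_id`
#'   and `members`).
#' @return object of class `vcm_activity`: tibble (`sample_id`, `score`) with
#'   `module_id`, `variance_explained` and `orientation` attributes; see
#'   [tidy.vcm_activity()] and [glance.vcm_activity()].
#' @export
compute_avcm <- function(matrix, module) {
  check_layer(matrix, "int-transformed", "compute_avcm")
  members <- if (is.list(module$members)) module$members[[1]] else module$members
  if (length(members) < 2) abort("a module needs at least 2 member peaks")
  v <- peak_values(matrix)
  miss <- setdiff(members, rownames(v))
  if (length(miss)) abort(paste("member peaks absent from matrix:",
                                paste(miss, collapse = ", ")))
  x <- t(v[members, , drop = FALSE])          # samples x peaks
  x <- scale(x)
  sv <- svd(x)
  score <- sv$u[, 1] * sv$d[1]
  m <- rowMeans(x)
  orientation <- if (stats::sd(m) > 1e-12) {
    if (stats::cor(score, m) < 0) -1L else 1L
  } else {
    # perfectly anti-correlated members: orient to the top-|loading| peak,
    # signed so the score tracks the positively loading member
    k <- which.max(abs(sv$v[, 1]))
    if (stats::cor(score, sign(sv$v[k, 1]) * x[, k]) < 0) -1L else 1L
  }
  score <- orientation * score
  score <- as.numeric(scale(score))
  out <- tibble(sample_id = colnames(v), score = score)
  attr(out, "module_id") <- module$module_id %||% NA_character_
  attr(out, "variance_explained") <- sv$d[1]^2 / sum(sv$d^2)
  attr(out, "orientation") <- orientation
  class(out) <- unique(c("vcm_activity", class(out)))
  out
}

#' @export
print.vcm_activity <- function(x, ...) {
  cat(sprintf("# aVCM score for %s (PC1, %.1f%% variance explained)\n",
              attr(x, "module_id"), 100 * attr(x, "variance_explained")))
  NextMethod()
}

#' Broom-style accessors for aVCM scores
#'
#' `tidy()` returns the per-sample scores; `glance()` the one-row module
#' summary (variance explained by PC1 and the orientation flag).
#'
#' @param x a `vcm_activity` object.
#' @param ... unused.
#' @export
tidy.vcm_activity <- function(x, ...) as_tibble(x)

#' @rdname tidy.vcm_activity
#' @export
glance.vcm_activity <- function(x, ...) {
  tibble(module_id = attr(x, "module_id"),
         variance_explained = attr(x, "variance_explained"),
         orientation = attr(x, "orientation"),
         n_samples = nrow(x))
}

#' Linear-regression QTL scan
#'
#' For every (variant, target) pair in the declared test universe, fits
#' ordinary least squares of the target on additive dosage (0/1/2) with an
#' intercept; reports the effect size per dosage unit (beta), its standard
#' error, the two-sided t-test p-value, and BH q-values over the universe.
#' Samples with missing dosage are dropped per test, never imputed. Variants
#' with constant dosage among non-missing samples are flagged `untestable`
#' and excluded from the FDR universe.
#'
#' @param targets tibble with `sample_id` plus one numeric column per target
#'   (module activity scores, expression, per-peak signal, ...).
#' @param genotypes tibble with `variant_id`, `chrom`, `pos`, `ref`, `alt`
#'   and one dosage column per sample.
#' @param universe optional tibble (`variant_id`, `target_id`) restricting
#'   the tested pairs (e.g. variant x peaks in the TAD and its neighbours);
#'   default tests all pairs.
#' @param min_n minimum non-missing samples per test.
#' @return tibble of class `vcm_qtl`: `variant_id`, `target_id`, `n`, `beta`,
#'   `se`, `p`, `q`, `status`.
#' @export
qtl_scan <- function(targets, genotypes, universe = NULL, min_n = 10L) {
  stopifnot("sample_id" %in% names(targets))
  target_ids <- setdiff(names(targets), "sample_id")
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
  samp <- setdiff(names(genotypes), meta_cols)
  shared <- intersect(targets$sample_id, samp)
  if (length(shared) < min_n) abort("fewer shared samples than min_n")
  pairs <- if (is.null(universe)) {
    tidyr::expand_grid(variant_id = genotypes$variant_id, target_id = target_ids)
  } else {
    as_tibble(universe)[c("variant_id", "target_id")]
  }
  tv <- as.matrix(targets[match(shared, targets$sample_id), target_ids,
                          drop = FALSE])
  rownames(tv) <- shared
  gv <- as.matrix(genotypes[, shared, drop = FALSE])
  rownames(gv) <- genotypes$variant_id
  res <- purrr::pmap(pairs, function(variant_id, target_id) {
    g <- gv[variant_id, ]
    y <- tv[, target_id]
    ok <- !is.na(g) & !is.na(y)
    g <- g[ok]; y <- y[ok]
    n <- length(g)
    if (n < min_n || stats::var(g) == 0) {
      return(tibble(variant_id = variant_id, target_id = target_id,
                    n = n, beta = NA_real_, se = NA_real_, p = NA_real_,
                    status = "untestable"))
    }
    vx <- stats::var(g)
    beta <- stats::cov(g, y) / vx
    alpha <- mean(y) - beta * mean(g)
    rss <- sum((y - alpha - beta * g)^2)
    se <- sqrt(rss / (n - 2) / ((n - 1) * vx))
    tstat <- beta / se
    tibble(variant_id = variant_id, target_id = target_id, n = n,
           beta = beta, se = se, p = 2 * stats::pt(-abs(tstat), df = n - 2),
           status = "tested")
  }) |> list_rbind()
  res$q <- NA_real_
  tested <- res$status == "tested"
  res$q[tested] <- fdr_adjust(res$p[tested])
  res <- relocate(res, "q", .after = "p")
  class(res) <- unique(c("vcm_qtl", class(res)))
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) in the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Three-way QTL screen for module-modulating variants
#'
#' Intersects the module-activity (vcmQTL), expression (eQTL) and TF-binding
#' (bQTL) scans: a variant passes if it is significant (q <= fdr) in all
#' three and its associated module coordinates at least two cis-regulatory
#' elements. Candidates are ordered by their minimum q across scans.
#'
#' @param vcmqtl,eqtl,bqtl `vcm_qtl` result tables sharing a variant id
#'   space; `vcmqtl` targets must be module ids present in `modules`.
#' @param modules a `vcm_set` tibble.
#' @param fdr significance threshold on q (default 0.10).
#' @return tibble: `variant_id`, `module_id`, `min_q`.
#' @export
screen_variants <- function(vcmqtl, eqtl, bqtl, modules, fdr = 0.10) {
  sig <- function(x) filter(as_tibble(x), .data$status == "tested",
                            .data$q <= fdr)
  sv <- sig(vcmqtl); se_ <- sig(eqtl); sb <- sig(bqtl)
  multi <- modules$module_id[modules$n_members >= 2]
  sv <- filter(sv, .data$target_id %in% multi)
  hits <- intersect(intersect(unique(sv$variant_id), unique(se_$variant_id)),
                    unique(sb$variant_id))
  if (!length(hits)) {
    return(tibble(variant_id = character(), module_id = character(),
                  min_q = double()))
  }
  all_q <- bind_rows(sv, se_, sb) |>
    filter(.data$variant_id %in% hits) |>
    group_by(.data$variant_id) |>
    summarise(min_q = min(.data$q), .groups = "drop")
  sv |>
    filter(.data$variant_id %in% hits) |>
    group_by(.data$variant_id) |>
    slice_min(.data$q, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("variant_id", module_id = "target_id") |>
    left_join(all_q, by = "variant_id") |>
    arrange(.data$min_q, .data$variant_id)
}
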