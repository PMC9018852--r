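#' Chromatin-tracing distance ensembles
#'
#' An ensemble holds single-cell pairwise 3D distances (nm) between ordered
#' genomic segments, as produced by sequential-imaging chromatin tracing.
#' The long tibble has one row per (cell, segment pair); `dist_nm` is `NA`
#' where a segment was not localised in that cell. Segment metadata and the
#' genotype tag travel as attributes.
#'
#' @param distances tibble: `cell_id`, `seg_i`, `seg_j` (integer segment
#'   indices, i < j), `dist_nm`.
#' @param segments tibble: `index`, `chrom`, `start`, `end`, ordered and
#'   non-overlapping.
#' @param genotype tag, e.g. `"REF"` / `"ALT"`.
#' @return tibble of class `orca_ensemble`.
#' @export
orca_ensemble <- function(distances, segments, genotype = "NA") {
  distances <- as_tibble(distances)
  stopifnot(all(c("cell_id", "seg_i", "seg_j", "dist_nm") %in% names(distances)))
  if (any(distances$seg_i >= distances$seg_j)) {
    abort("pairs must be stored with seg_i < seg_j")
  }
  if (any(distances$dist_nm < 0, na.rm = TRUE)) abort("distances must be >= 0")
  segments <- arrange(as_tibble(segments), .data$index)
  if (any(diff(segments$start) <= 0) ||
      any(segments$start[-1] < segments$end[-nrow(segments)])) {
    abort("segments must be ordered and non-overlapping")
  }
  attr(distances, "segments") <- segments
  attr(distances, "genotype") <- genotype
  class(distances) <- unique(c("orca_ensemble", class(distances)))
  distances
}

#' @export
print.orca_ensemble <- function(x, ...) {
  cat(sprintf("# Chromatin-tracing ensemble [%s]: %d cells, %d segments\n",
              attr(x, "genotype"), length(unique(x$cell_id)),
              nrow(attr(x, "segments"))))
  NextMethod()
}

#' Pool replicate ensembles cell-wise
#'
#' Mirrors merging imaging replicates into a single dataset before computing
#' population statistics. Segment tables must match.
#'
#' @param ... `orca_ensemble` objects with identical segments.
#' @return one `orca_ensemble`.
#' @export
merge_ensembles <- function(...) {
  es <- list(...)
  segs <- attr(es[[1]], "segments")
  for (e in es[-1]) {
    if (!identical(as.data.frame(attr(e, "segments")), as.data.frame(segs))) {
      abort("segment sets differ between ensembles")
    }
  }
  pooled <- bind_rows(lapply(seq_along(es), function(i) {
    mutate(as_tibble(es[[i]]), cell_id = paste0("rep", i, "_", .data$cell_id))
  }))
  orca_ensemble(pooled, segs, genotype = attr(es[[1]], "genotype"))
}

#' Convert per-cell 3D segment coordinates to a distance ensemble
#'
#' Convenience Euclidean transform for localisation tables.
#'
#' @param coords tibble: `cell_id`, `segment`, `x`, `y`, `z` (nm); missing
#'   segments simply yield missing pair distances.
#' @param segments segment metadata as for [orca_ensemble()].
#' @param genotype tag.
#' @export
coords_to_distances <- function(coords, segments, genotype = "NA") {
  segments <- as_tibble(segments)
  S <- nrow(segments)
  pairs <- utils::combn(S, 2)
  out <- coords |>
    group_by(.data$cell_id) |>
    group_map(function(df, key) {
      xyz <- matrix(NA_real_, S, 3)
      xyz[df$segment, ] <- as.matrix(df[c("x", "y", "z")])
      d <- sqrt(rowSums((xyz[pairs[1, ], , drop = FALSE] -
                           xyz[pairs[2, ], , drop = FALSE])^2))
      tibble(cell_id = key$cell_id, seg_i = pairs[1, ], seg_j = pairs[2, ],
             dist_nm = d)
    }) |> bind_rows()
  orca_ensemble(out, segments, genotype)
}

#' Population-median distance matrix
#'
#' Per segment pair, the median distance over cells, ignoring missing values;
#' pairs observed in fewer than `min_obs` cells are masked (too few
#' localisations for a stable median).
#'
#' @param ensemble an `orca_ensemble`.
#' @param min_obs minimum observations per pair (default 20).
#' @return tibble of class `orca_stat`: `seg_i`, `seg_j`, `value` (median
#'   nm, `NA` when masked), `n_obs`, `masked`; statistic and genotype as
#'   attributes.
#' @export
median_distance_matrix <- function(ensemble, min_obs = 20L) {
  summarise_pairs(ensemble, function(d) stats::median(d), min_obs,
                  stat = "median_nm")
}

#' Contact-fraction matrix
#'
#' Per segment pair, the fraction of cells whose distance is strictly below
#' `threshold_nm` (default 150 nm), with missing-aware denominators.
#'
#' @inheritParams median_distance_matrix
#' @param threshold_nm contact-calling distance threshold in nm.
#' @param min_obs minimum observations per pair.
#' @return an `orca_stat` tibble (`value` = contact fraction).
#' @export
contact_fraction <- function(ensemble, threshold_nm = 150, min_obs = 1L) {
  if (threshold_nm <= 0) abort("threshold_nm must be > 0")
  summarise_pairs(ensemble, function(d) mean(d < threshold_nm), min_obs,
                  stat = "contact_fraction")
}

summarise_pairs <- function(ensemble, f, min_obs, stat) {
  stopifnot(inherits(ensemble, "orca_ensemble"))
  res <- as_tibble(ensemble) |>
    group_by(.data$seg_i, .data$seg_j) |>
    summarise(n_obs = sum(!is.na(.data$dist_nm)),
              value = if (sum(!is.na(.data$dist_nm)) > 0)
                f(.data$dist_nm[!is.na(.data$dist_nm)]) else NA_real_,
              .groups = "drop") |>
    mutate(masked = .data$n_obs < min_obs,
           value = ifelse(.data$masked, NA_real_, .data$value)) |>
    select("seg_i", "seg_j", "value", "n_obs", "masked")
  if (all(res$masked)) abort("all segment pairs are masked")
  attr(res, "stat") <- stat
  attr(res, "genotype") <- attr(ensemble, "genotype")
  class(res) <- unique(c("orca_stat", class(res)))
  res
}

#' ALT - REF distance differences with a binomial compaction test
#'
#' Subtracts the REF population-median distance from ALT per segment pair and
#' asks whether pairs move closer more often than further: a two-sided exact
#' binomial test at success probability 0.5 on the counts of negative versus
#' positive differences, considering only changes different from 0 (p = 1 by
#' convention when every difference is zero). A negative median difference
#' with small p indicates global compaction on the ALT allele.
#'
#' @param alt,ref `orca_stat` median-distance tables over the same segments.
#' @return object of class `orca_diff` with the per-pair difference table and
#'   the summary statistics; see `tidy()`/`glance()`.
#' @export
diff_matrix_test <- function(alt, ref) {
  stopifnot(inherits(alt, "orca_stat"), inherits(ref, "orca_stat"))
  j <- inner_join(as_tibble(alt), as_tibble(ref),
                  by = c("seg_i", "seg_j"), suffix = c("_alt", "_ref"))
  if (nrow(j) != nrow(alt) || nrow(j) != nrow(ref)) {
    abort("segment pair sets differ between ALT and REF")
  }
  j <- j |>
    mutate(diff_nm = .data$value_alt - .data$value_ref) |>
    filter(!.data$masked_alt, !.data$masked_ref)
  if (nrow(j) < 2) abort("fewer than 2 unmasked shared pairs")
  nz <- j$diff_nm[j$diff_nm != 0]
  n_closer <- sum(nz < 0)
  n_further <- sum(nz > 0)
  p <- if (!length(nz)) 1 else
    stats::binom.test(n_closer, length(nz), p = 0.5)$p.value
  structure(list(diffs = select(j, "seg_i", "seg_j", "diff_nm"),
                 median_diff = stats::median(j$diff_nm),
                 n_closer = n_closer, n_further = n_further, p = p),
            class = "orca_diff")
}

#' @export
print.orca_diff <- function(x, ...) {
  cat(sprintf(
    "# ALT - REF distance change: median %.3f nm (%d closer / %d further), two-sided binomial p = %.3g\n",
    x$median_diff, x$n_closer, x$n_further, x$p))
  invisible(x)
}

#' @rdname tidy.vcm_activity
#' @export
tidy.orca_diff <- function(x, ...) x$diffs

#' @rdname tidy.vcm_activity
#' @export
glance.orca_diff <- function(x, ...) {
  tibble(median_diff_nm = x$median_diff, n_closer = x$n_closer,
         n_further = x$n_further, p = x$p)
}

#' Concordance between two pairwise matrices
#'
#' Pearson correlation over the shared, unmasked, off-diagonal segment pairs
#' of two `orca_stat` tables (e.g. tracing medians versus Hi-C contact
#' frequencies on a matched grid).
#'
#' @param a,b `orca_stat` tables.
#' @return Pearson r.
#' @export
ensemble_concordance <- function(a, b) {
  j <- inner_join(as_tibble(a), as_tibble(b), by = c("seg_i", "seg_j"),
                  suffix = c("_a", "_b")) |>
    filter(!.data$masked_a, !.data$masked_b, .data$seg_i != .data$seg_j)
  if (nrow(j) < 3) abort("fewer than 3 shared unmasked pairs")
  stats::cor(j$value_a, j$value_b)
}

#' Write / read distance tables as TSV
#'
#' Layout `cell_id seg_i seg_j dist_nm`; segment metadata in a BED sidecar
#' `<path>.segments.bed` (`chrom start end index`).
#'
#' @param ensemble an `orca_ensemble`.
#' @param path TSV path.
#' @export
write_orca <- function(ensemble, path) {
  readr::write_tsv(as_tibble(ensemble), path, progress = FALSE)
  segs <- attr(ensemble, "segments")
  readr::write_tsv(segs[c("chrom", "start", "end", "index")],
                   paste0(path, ".segments.bed"), col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_orca
#' @param genotype tag for the loaded ensemble.
#' @export
read_orca <- function(path, genotype = "NA") {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  segs <- readr::read_tsv(paste0(path, ".segments.bed"),
                          col_names = c("chrom", "start", "end", "index"),
                          show_col_types = FALSE, progress = FALSE)
  orca_ensemble(d, segs[c("index", "chrom", "start", "end")], genotype)
}

#' Capture-C fragment profiles
#'
#' A profile holds raw restriction-fragment interaction counts for one
#' replicate of one genotype, plus the viewpoint position and the bounding
#' TAD interval.
#'
#' @param fragments tibble: `chrom`, `start`, `end`, `count`.
#' @param viewpoint viewpoint (bait) position in bp.
#' @param tad numeric length-2, TAD start/end in bp; must contain the
#'   viewpoint.
#' @param genotype,replicate tags.
#' @return tibble of class `vcm_capc`, layer `raw`.
#' @export
capturec_profile <- function(fragments, viewpoint, tad, genotype = "NA",
                             replicate = 1L) {
  fragments <- as_tibble(fragments)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(fragments)))
  if (any(fragments$count < 0)) abort("counts must be >= 0")
  if (viewpoint < tad[1] || viewpoint > tad[2]) {
    abort("viewpoint must lie inside the TAD")
  }
  attr(fragments, "viewpoint") <- viewpoint
  attr(fragments, "tad") <- tad
  attr(fragments, "genotype") <- genotype
  attr(fragments, "replicate") <- replicate
  attr(fragments, "layer") <- "raw"
  class(fragments) <- unique(c("vcm_capc", class(fragments)))
  fragments
}

#' TAD-normalise and bin a Capture-C profile
#'
#' Fragments whose midpoints fall within `viewpoint_exclusion_bp` of the
#' viewpoint are excluded (they carry capture artefacts); remaining counts
#' inside the TAD are scaled to total 1 and aggregated, by fragment
#' midpoint, into fixed `bin_bp` bins tiled from the TAD start (half-open:
#' a midpoint exactly on a boundary joins the right-hand bin).
#'
#' @param profile a raw `vcm_capc`.
#' @param bin_bp bin width (default 5000).
#' @param viewpoint_exclusion_bp exclusion radius around the viewpoint
#'   (default 1000).
#' @return a `vcm_capc` with layer `binned`: `bin_start`, `bin_end`,
#'   `norm_count` summing to 1.
#' @export
capturec_bin_normalize <- function(profile, bin_bp = 5000L,
                                   viewpoint_exclusion_bp = 1000L) {
  stopifnot(inherits(profile, "vcm_capc"))
  if (!identical(attr(profile, "layer"), "raw")) {
    abort("capturec_bin_normalize() expects a raw profile")
  }
  vp <- attr(profile, "viewpoint"); tad <- attr(profile, "tad")
  frag <- as_tibble(profile) |>
    mutate(mid = (.data$start + .data$end) / 2) |>
    filter(abs(.data$mid - vp) > viewpoint_exclusion_bp,
           .data$mid >= tad[1], .data$mid < tad[2])
  total <- sum(frag$count)
  if (total == 0) abort("TAD total is 0 after viewpoint exclusion")
  frag <- mutate(frag, norm = .data$count / total,
                 bin = floor((.data$mid - tad[1]) / bin_bp))
  bins <- tibble(bin = 0:floor((tad[2] - tad[1] - 1) / bin_bp))
  out <- bins |>
    left_join(summarise(group_by(frag, .data$bin),
                        norm_count = sum(.data$norm), .groups = "drop"),
              by = "bin") |>
    mutate(norm_count = tidyr::replace_na(.data$norm_count, 0),
           bin_start = tad[1] + .data$bin * bin_bp,
           bin_end = pmin(tad[1] + (.data$bin + 1) * bin_bp, tad[2])) |>
    select("bin_start", "bin_end", "norm_count")
  for (a in c("viewpoint", "tad", "genotype", "replicate")) {
    attr(out, a) <- attr(profile, a)
  }
  attr(out, "layer") <- "binned"
  class(out) <- unique(c("vcm_capc", class(out)))
  out
}

#' Per-bin fold changes between genotypes, and the viewpoint-bin fraction
#'
#' Per bin, `log2((mean normalised ALT + eps) / (mean normalised REF + eps))`
#' with `eps` the smallest positive normalised value observed across all
#' profiles (so empty bins stay finite). Also reports, per replicate, the
#' fraction of TAD counts falling in the bin containing the viewpoint.
#'
#' @param alt_profiles,ref_profiles lists of binned `vcm_capc` profiles on
#'   identical bin grids.
#' @return list with `fold_changes` (tibble: `bin_start`, `bin_end`,
#'   `mean_alt`, `mean_ref`, `log2_fc`) and `viewpoint_fraction` (tibble:
#'   `genotype`, `replicate`, `fraction`).
#' @export
capturec_fold_changes <- function(alt_profiles, ref_profiles) {
  all_p <- c(alt_profiles, ref_profiles)
  if (!length(alt_profiles) || !length(ref_profiles)) {
    abort("need at least one profile per genotype")
  }
  grid <- tibble(bin_start = all_p[[1]]$bin_start,
                 bin_end = all_p[[1]]$bin_end)
  for (p in all_p) {
    same <- nrow(p) == nrow(grid) &&
      all(p$bin_start == grid$bin_start) && all(p$bin_end == grid$bin_end)
    if (!same) abort("bin grids differ between profiles")
  }
  stack <- function(ps) {
    vapply(ps, function(p) as_tibble(p)$norm_count, numeric(nrow(grid)))
  }
  m_alt <- rowMeans(stack(alt_profiles))
  m_ref <- rowMeans(stack(ref_profiles))
  pos <- unlist(lapply(all_p, function(p) as_tibble(p)$norm_count))
  eps <- min(pos[pos > 0])
  fc <- grid |>
    mutate(mean_alt = m_alt, mean_ref = m_ref,
           log2_fc = log2((m_alt + eps) / (m_ref + eps)))
  vp_frac <- purrr::map(all_p, function(p) {
    vp <- attr(p, "viewpoint")
    tb <- as_tibble(p)
    in_bin <- tb$bin_start <= vp & vp < tb$bin_end
    tibble(genotype = attr(p, "genotype"),
           replicate = attr(p, "replicate"),
           fraction = sum(tb$norm_count[in_bin]))
  }) |> list_rbind()
  list(fold_changes = fc, viewpoint_fraction = vp_frac)
}
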