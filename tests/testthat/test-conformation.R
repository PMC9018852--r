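tiny_segments <- function(S) {
  tibble::tibble(index = seq_len(S), chrom = "chr17",
                 start = 1000L + (seq_len(S) - 1L) * 100L,
                 end = 1000L + seq_len(S) * 100L)
}

tiny_ensemble <- function(dist_by_cell, genotype = "REF") {
  # dist_by_cell: list of named vectors "i_j" -> distance
  rows <- purrr::imap(dist_by_cell, function(d, cell) {
    ij <- do.call(rbind, strsplit(names(d), "_"))
    tibble::tibble(cell_id = cell, seg_i = as.integer(ij[, 1]),
                   seg_j = as.integer(ij[, 2]), dist_nm = unname(d))
  })
  S <- max(unlist(lapply(rows, function(r) r$seg_j)))
  orca_ensemble(dplyr::bind_rows(rows), tiny_segments(S), genotype)
}

test_that("ensemble construction validates order, sign and segments", {
  good <- tiny_ensemble(list(c1 = c("1_2" = 100, "1_3" = 150, "2_3" = 120)))
  expect_s3_class(good, "orca_ensemble")
  expect_error(tiny_ensemble(list(c1 = c("2_1" = 100))), "seg_i < seg_j")
  expect_error(tiny_ensemble(list(c1 = c("1_2" = -5))), ">= 0")
  segs <- tiny_segments(2); segs$start[2] <- segs$start[1]
  expect_error(orca_ensemble(tibble::tibble(cell_id = "c", seg_i = 1L,
                                            seg_j = 2L, dist_nm = 1),
                             segs), "ordered")
})

test_that("median matrix takes per-pair medians and masks sparse pairs", {
  e <- tiny_ensemble(list(
    c1 = c("1_2" = 100, "1_3" = 200),
    c2 = c("1_2" = 110, "1_3" = NA),
    c3 = c("1_2" = 300, "1_3" = 240)))
  m <- median_distance_matrix(e, min_obs = 2)
  expect_equal(m$value[m$seg_i == 1 & m$seg_j == 2], 110)
  expect_equal(m$value[m$seg_i == 1 & m$seg_j == 3], 220) # median of 200, 240
  masked <- median_distance_matrix(e, min_obs = 3)
  expect_true(masked$masked[masked$seg_j == 3])
  expect_true(is.na(masked$value[masked$seg_j == 3]))
  expect_error(median_distance_matrix(e, min_obs = 10), "masked")
})

test_that("contact fraction uses a strict threshold and missing-aware counts", {
  e <- tiny_ensemble(list(
    c1 = c("1_2" = 149.999), c2 = c("1_2" = 150), c3 = c("1_2" = 151),
    c4 = c("1_2" = NA)))
  cf <- contact_fraction(e, threshold_nm = 150)
  expect_equal(cf$value, 1 / 3) # 150 itself is not a contact; NA not counted
  expect_identical(cf$n_obs, 3L)
})

test_that("coordinates convert to Euclidean pair distances", {
  coords <- tibble::tibble(cell_id = "c1", segment = 1:3,
                           x = c(0, 3, 0), y = c(0, 4, 0), z = c(0, 0, 12))
  e <- coords_to_distances(coords, tiny_segments(3))
  d <- e$dist_nm[order(e$seg_i, e$seg_j)]
  expect_equal(d, c(5, 12, 13))
})

test_that("the compaction test recovers sign, p-value and factor", {
  cfg <- sim_config(seed = 12)
  cfg$orca_spec$n_cells <- 800L
  orca <- simulate_orca_ensembles(cfg)
  mref <- median_distance_matrix(orca$ref)
  malt <- median_distance_matrix(orca$alt)
  dt <- diff_matrix_test(malt, mref)
  expect_lt(dt$median_diff, 0)
  expect_lt(dt$p, 1e-10)
  # binomial oracle on the same sign counts
  expect_equal(dt$p, stats::binom.test(dt$n_closer,
                                       dt$n_closer + dt$n_further)$p.value,
               tolerance = 1e-12)
  # swapping the arguments flips the effect direction, not the p-value
  rev_ <- diff_matrix_test(mref, malt)
  expect_equal(rev_$median_diff, -dt$median_diff, tolerance = 1e-12)
  expect_equal(rev_$p, dt$p, tolerance = 1e-12)
  # recovered compaction factor is close to the planted 0.9
  j <- dplyr::inner_join(as_tibble(malt), as_tibble(mref),
                         by = c("seg_i", "seg_j"), suffix = c("_a", "_r"))
  expect_equal(stats::median(j$value_a / j$value_r), 0.9, tolerance = 0.03)
  gl <- generics::glance(dt)
  expect_identical(gl$n_closer, dt$n_closer)
  td <- generics::tidy(dt)
  expect_named(td, c("seg_i", "seg_j", "diff_nm"))
})

test_that("an all-zero difference matrix yields p = 1 by convention", {
  e <- tiny_ensemble(list(c1 = c("1_2" = 100, "1_3" = 150, "2_3" = 120),
                          c2 = c("1_2" = 100, "1_3" = 150, "2_3" = 120)))
  m <- median_distance_matrix(e, min_obs = 1)
  dt <- diff_matrix_test(m, m)
  expect_identical(dt$p, 1)
  expect_identical(dt$n_closer + dt$n_further, 0L)
  expect_equal(dt$median_diff, 0)
})

test_that("replicate pooling concatenates cells with identical segments", {
  e1 <- tiny_ensemble(list(c1 = c("1_2" = 100)))
  e2 <- tiny_ensemble(list(c1 = c("1_2" = 200)))
  pooled <- merge_ensembles(e1, e2)
  expect_identical(nrow(as_tibble(pooled)), 2L)
  expect_identical(length(unique(pooled$cell_id)), 2L)
  e3 <- tiny_ensemble(list(c1 = c("1_2" = 100, "2_3" = 50, "1_3" = 120)))
  expect_error(merge_ensembles(e1, e3), "segment sets differ")
})

test_that("concordance is 1 for identical matrices and drops with noise", {
  cfg <- sim_config(seed = 13)
  cfg$orca_spec$n_cells <- 200L
  orca <- simulate_orca_ensembles(cfg)
  m <- median_distance_matrix(orca$ref)
  expect_equal(ensemble_concordance(m, m), 1)
  m2 <- median_distance_matrix(orca$alt)
  expect_gt(ensemble_concordance(m, m2), 0.95) # same geometry, scaled
})

test_that("distance ensembles round-trip through TSV + segment BED", {
  cfg <- sim_config(seed = 14)
  cfg$orca_spec$n_cells <- 20L
  cfg$orca_spec$n_segments <- 5L
  e <- simulate_orca_ensembles(cfg)$ref
  path <- withr::local_tempfile(fileext = ".tsv")
  write_orca(e, path)
  back <- read_orca(path, genotype = "REF")
  expect_equal(as.data.frame(back), as.data.frame(e), tolerance = 1e-12)
  expect_equal(as.data.frame(attr(back, "segments")[c("index", "start", "end")]),
               as.data.frame(attr(e, "segments")[c("index", "start", "end")]),
               tolerance = 1e-12)
})

test_that("binned Capture-C profiles conserve mass and honour exclusions", {
  cfg <- sim_config(seed = 15)
  capc <- simulate_capturec(cfg)
  p <- capc$profiles[["REF_rep1"]]
  b <- capturec_bin_normalize(p)
  expect_equal(sum(b$norm_count), 1, tolerance = 1e-12)
  tad <- attr(p, "tad")
  expect_identical(b$bin_start[1], tad[1])
  expect_identical(b$bin_end[nrow(b)], tad[2])
  expect_identical(unique(diff(b$bin_start)), 5000)

  # widening the exclusion zone removes mass near the viewpoint
  vp <- attr(p, "viewpoint")
  wide <- capturec_bin_normalize(p, viewpoint_exclusion_bp = 10000L)
  near <- which(b$bin_start <= vp & vp < b$bin_end)
  expect_lt(wide$norm_count[near] / sum(wide$norm_count),
            b$norm_count[near] + 1e-12)
  expect_error(capturec_bin_normalize(b), "raw")
})

test_that("bin assignment is by fragment midpoint, half-open at boundaries", {
  frag <- tibble::tibble(chrom = "chr1",
                         start = c(0L, 4000L, 5000L),
                         end = c(2000L, 6000L, 5004L),
                         count = c(10L, 20L, 40L))
  # midpoints 1000 (bin 0), 5000 (bin 1, boundary joins right), 5002 (bin 1)
  p <- capturec_profile(frag, viewpoint = 9000, tad = c(0, 10000))
  b <- capturec_bin_normalize(p, bin_bp = 5000L, viewpoint_exclusion_bp = 100L)
  expect_equal(b$norm_count, c(10, 60) / 70, tolerance = 1e-12)
})

test_that("fold changes recover a planted boost and keep bins finite", {
  cfg <- sim_config(seed = 16)
  cfg$capturec_spec$boost_bin <- 63.55e6
  capc <- simulate_capturec(cfg)
  binned <- lapply(capc$profiles, capturec_bin_normalize)
  alt <- binned[grep("^ALT", names(binned))]
  ref <- binned[grep("^REF", names(binned))]
  fc <- capturec_fold_changes(alt, ref)
  expect_true(all(is.finite(fc$fold_changes$log2_fc)))
  boosted <- fc$fold_changes$log2_fc[fc$fold_changes$bin_start == 63.55e6]
  expect_gt(boosted, 0.6)
  expect_equal(max(fc$fold_changes$log2_fc), boosted)
  # viewpoint-bin fraction is reported per replicate and genotype
  expect_identical(nrow(fc$viewpoint_fraction), 6L)
  expect_true(all(fc$viewpoint_fraction$fraction >= 0 &
                    fc$viewpoint_fraction$fraction <= 1))
})

test_that("mismatched bin grids are refused", {
  cfg <- sim_config(seed = 16)
  capc <- simulate_capturec(cfg)
  a <- capturec_bin_normalize(capc$profiles[["ALT_rep1"]])
  r <- capturec_bin_normalize(capc$profiles[["REF_rep1"]], bin_bp = 2000L)
  expect_error(capturec_fold_changes(list(a), list(r)), "grids differ")
})
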