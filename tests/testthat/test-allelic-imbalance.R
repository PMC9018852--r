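test_that("region aggregation sums only variants inside half-open regions", {
  counts <- tibble::tibble(
    assay_id = "TF01",
    variant_id = sprintf("v%d", 1:4),
    chrom = "chr1",
    pos = c(100L, 150L, 200L, 250L), # 200 == region end: excluded
    alt_reads = c(3L, 4L, 100L, 7L),
    ref_reads = c(1L, 2L, 100L, 8L))
  regions <- tibble::tibble(region_id = c("rA", "rB", "rEmpty"),
                            chrom = "chr1",
                            start = c(100L, 240L, 900L),
                            end = c(200L, 260L, 950L))
  agg <- aggregate_region_counts(counts, regions)
  expect_identical(agg$alt_reads[agg$region_id == "rA"], 7L)
  expect_identical(agg$ref_reads[agg$region_id == "rA"], 3L)
  expect_identical(agg$alt_reads[agg$region_id == "rB"], 7L)
  expect_identical(agg$alt_reads[agg$region_id == "rEmpty"], 0L)
  expect_identical(agg$ref_reads[agg$region_id == "rEmpty"], 0L)
})

test_that("duplicated (assay, variant) rows are rejected, not double counted", {
  counts <- tibble::tibble(assay_id = "TF01", variant_id = c("v1", "v1"),
                           chrom = "chr1", pos = c(100L, 100L),
                           alt_reads = c(3L, 3L), ref_reads = c(1L, 1L))
  regions <- tibble::tibble(region_id = "rA", chrom = "chr1",
                            start = 50L, end = 200L)
  expect_error(aggregate_region_counts(counts, regions), "double count")
})

test_that("the exact two-sided p equals full enumeration, both conventions", {
  cases <- expand.grid(x = c(0, 1, 3, 5, 10), n = c(6, 10, 25),
                       p0 = c(0.3, 0.5, 0.62))
  cases <- cases[cases$x <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; n <- cases$n[i]; p0 <- cases$p0[i]
    counts <- tibble::tibble(assay_id = c("TF01", "input"), region_id = "r1",
                             alt_reads = c(x, round(p0 * 1e6)),
                             ref_reads = c(n - x, round((1 - p0) * 1e6)))
    got_min <- imbalance_test(counts, min_reads = 1)$p
    got_dbl <- imbalance_test(counts, min_reads = 1, two_sided = "double")$p
    p0_emp <- round(p0 * 1e6) / 1e6
    expect_equal(got_min, binom_minlike(x, n, p0_emp), tolerance = 1e-9)
    lo <- stats::pbinom(x, n, p0_emp)
    hi <- stats::pbinom(x - 1, n, p0_emp, lower.tail = FALSE)
    expect_equal(got_dbl, min(1, 2 * min(lo, hi)), tolerance = 1e-12)
  }
})

test_that("the worked example (10 vs 0 reads, balanced input) gives p = 2/1024", {
  counts <- tibble::tibble(assay_id = c("TF01", "input"), region_id = "r1",
                           alt_reads = c(10L, 500L), ref_reads = c(0L, 500L))
  res <- imbalance_test(counts)
  expect_equal(res$p, 2 / 1024, tolerance = 1e-12)
  expect_identical(res$status, "tested")
})

test_that("assays below the read floor are filtered, not tested", {
  counts <- tibble::tibble(assay_id = c("TF01", "TF02", "input"),
                           region_id = "r1",
                           alt_reads = c(3L, 4L, 50L),
                           ref_reads = c(2L, 2L, 50L))
  res <- imbalance_test(counts, min_reads = 6)
  expect_identical(res$status[res$assay_id == "TF01"], "filtered_low_reads")
  expect_true(is.na(res$p[res$assay_id == "TF01"]))
  expect_identical(res$status[res$assay_id == "TF02"], "tested")
})

test_that("allele labels are exchangeable when the input is balanced", {
  counts <- tibble::tibble(assay_id = c("TF01", "input"), region_id = "r1",
                           alt_reads = c(17L, 300L), ref_reads = c(5L, 300L))
  swapped <- dplyr::mutate(counts, tmp = alt_reads, alt_reads = ref_reads,
                           ref_reads = tmp, tmp = NULL)
  expect_equal(imbalance_test(counts)$p, imbalance_test(swapped)$p,
               tolerance = 1e-12)
})

test_that("q-values are BH within each region across tested assays", {
  set.seed(7)
  alt <- stats::rbinom(8, 40, 0.65)
  counts <- dplyr::bind_rows(
    tibble::tibble(assay_id = sprintf("TF%02d", 1:8), region_id = "r1",
                   alt_reads = alt, ref_reads = 40L - alt),
    tibble::tibble(assay_id = "input", region_id = "r1",
                   alt_reads = 200L, ref_reads = 200L))
  res <- imbalance_test(counts, min_reads = 1)
  expect_equal(res$q, bh_stepup(res$p), tolerance = 1e-12)
})

test_that("an empty input falls back to 0.5 and is flagged", {
  counts <- tibble::tibble(assay_id = c("TF01", "input"), region_id = "r1",
                           alt_reads = c(9L, 0L), ref_reads = c(3L, 0L))
  res <- imbalance_test(counts)
  expect_true(res$input_fallback)
  expect_equal(res$p0, 0.5)
  expect_equal(res$p, binom_minlike(9, 12, 0.5), tolerance = 1e-12)
})

test_that("log2 fold change applies the pseudocount only when an allele is 0", {
  expect_equal(log2fc_over_input(10, 10, input_alt_pct = 0.5), 0)
  expect_equal(log2fc_over_input(30, 10, input_alt_pct = 0.5),
               log2(0.75 / 0.5))
  # zero REF reads: one read added to both alleles first
  expect_equal(log2fc_over_input(10, 0, input_alt_pct = 0.5),
               log2((11 / 12) / 0.5))
  expect_equal(log2fc_over_input(0, 10, input_alt_pct = 0.5),
               log2((1 / 12) / 0.5))
  expect_error(log2fc_over_input(5, 5, input_alt_pct = 0), "undefined")
})

test_that("binding density counts assays, not peaks, per 10-bp bin", {
  peak_sets <- list(
    tfA = tibble::tibble(chrom = "chr1", start = c(100L, 104L), end = c(112L, 118L)),
    tfB = tibble::tibble(chrom = "chr1", start = 115L, end = 125L),
    tfC = tibble::tibble(chrom = "chr2", start = 100L, end = 200L)) # wrong chrom
  window <- list(chrom = "chr1", start = 100L, end = 130L)
  dens <- tf_binding_density(peak_sets, window, bin_bp = 10L)
  expect_identical(dens$start, c(100L, 110L, 120L))
  # bin 100-110: only tfA (two overlapping peaks count once)
  # bin 110-120: tfA (runs to 118) and tfB (starts 115)
  # bin 120-130: only tfB
  expect_identical(dens$n_assays, c(1L, 2L, 1L))
})

test_that("density tracks write as four-column BedGraph", {
  dens <- tibble::tibble(chrom = "chr1", start = c(0L, 10L), end = c(10L, 20L),
                         n_assays = c(2L, 0L))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(dens, path)
  back <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_identical(dim(back), c(2L, 4L))
  expect_equal(back$X4, c(2, 0))
})
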