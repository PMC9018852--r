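random_seqs <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                           collapse = ""),
         character(1))
}

test_that("pwm constructors produce finite 4 x L log-odds matrices", {
  p <- pwm_from_consensus("TF", "ACGTAC")
  expect_identical(dim(p$mat), c(4L, 6L))
  expect_identical(rownames(p$mat), c("A", "C", "G", "T"))
  # the consensus base scores log2(0.8 / 0.25) at each position
  expect_equal(unname(p$mat["A", 1]), log2(0.8 / 0.25), tolerance = 1e-12)
  expect_equal(unname(p$mat["C", 1]), log2((0.2 / 3) / 0.25), tolerance = 1e-12)
  # column probabilities sum to 1 before the log-odds transform
  expect_equal(colSums(2^p$mat * 0.25), rep(1, 6), tolerance = 1e-12)

  counts <- matrix(c(8, 0, 0, 0), 4, 3)
  pc <- pwm_from_counts("TF", counts)
  expect_true(all(is.finite(pc$mat)))
  expect_error(pwm("TF", matrix(1, 3, 5)), "4 x L")
  expect_error(pwm("TF", matrix(c(1, Inf, 1, 1), 4, 1)), "4 x L")
})

test_that("pwm_scan agrees with a naive per-window scorer on both strands", {
  set.seed(42)
  p <- random_pwm("TF", len = 7)
  seqs <- random_seqs(10, 40, seed = 9)
  for (s in seqs) {
    scan <- pwm_scan(p, s)
    chars <- strsplit(s, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- rev(unname(comp[chars]))
    for (i in sample(seq_len(40 - 6), 5)) {
      fwd <- window_score(p$mat, chars[i:(i + 6)])
      expect_equal(scan$score[scan$position == i & scan$strand == "+"], fwd,
                   tolerance = 1e-12)
    }
    expect_equal(max(scan$score), best_score_naive(p$mat, s), tolerance = 1e-12)
  }
})

test_that("scanning is strand-symmetric: the reverse complement scores equal", {
  set.seed(1)
  p <- random_pwm("TF", len = 8)
  for (s in random_seqs(5, 60, seed = 2)) {
    expect_equal(max(pwm_scan(p, s)$score),
                 max(pwm_scan(p, revcomp(s))$score), tolerance = 1e-12)
  }
})

test_that("windows containing ambiguous bases are skipped, not scored", {
  p <- pwm_from_consensus("TF", "ACGT")
  s <- "ACGTNNACGT"
  scan <- pwm_scan(p, s)
  # windows 1 and 7 are clean; everything touching the Ns is absent
  expect_setequal(unique(scan$position), c(1L, 7L))
  expect_error(pwm_scan(p, "ACG"), "shorter")
  expect_identical(top_scores(p, c("NNNN", "NNNN")), c(NA_real_, NA_real_))
})

test_that("batched top scores equal one-by-one scans (dual route)", {
  set.seed(3)
  pwms <- c(lapply(1:3, function(i) random_pwm(paste0("R", i),
                                               len = sample(6:11, 1))),
            list(pwm_from_consensus("C1", "ACGTACGTA")))
  seqs <- random_seqs(40, 80, seed = 4)
  for (p in pwms) {
    batch <- top_scores(p, seqs)
    single <- vapply(seqs, function(s) max(pwm_scan(p, s)$score), numeric(1),
                     USE.NAMES = FALSE)
    expect_equal(batch, single, tolerance = 1e-12)
  }
})

test_that("background calibration stores the plain mean and n-1 sd", {
  p <- random_pwm("TF", len = 6)
  seqs <- random_seqs(50, 30, seed = 5)
  cal <- calibrate_background(list(p), seqs)
  tops <- vapply(seqs, function(s) max(pwm_scan(p, s)$score), numeric(1))
  expect_equal(cal$mean_top_score, mean(tops), tolerance = 1e-12)
  expect_equal(cal$sd_top_score, stats::sd(tops), tolerance = 1e-12)
  expect_identical(cal$n_regions, 50L)
  expect_false(cal$degenerate)
  expect_error(calibrate_background(list(p), seqs[1]), "at least 2")
})

test_that("z-scores are invariant to per-column shifts of the matrix", {
  # adding a constant to every entry of a PWM column shifts every window
  # score by that constant, so background standardisation cancels it
  set.seed(6)
  p <- random_pwm("TF", len = 6)
  shifted <- pwm("TF", sweep(p$mat, 2, stats::runif(6, -2, 2), "+"))
  seqs <- random_seqs(60, 40, seed = 7)
  ref <- substr(seqs[1], 1, 30); alt <- substr(seqs[2], 1, 25)
  z1 <- allele_max_zscores(list(p), calibrate_background(list(p), seqs),
                           ref, alt)
  z2 <- allele_max_zscores(list(shifted),
                           calibrate_background(list(shifted), seqs), ref, alt)
  expect_equal(z1$z_ref, z2$z_ref, tolerance = 1e-9)
  expect_equal(z1$z_alt, z2$z_alt, tolerance = 1e-9)
  expect_equal(z1$delta_z, z2$delta_z, tolerance = 1e-9)
})

test_that("the planted deletion yields a dominant positive delta_z", {
  cfg <- sim_config(seed = 17)
  cfg$motif_spec$n_background <- 300L
  sim <- simulate_indel_sequences(cfg)
  cal <- calibrate_background(sim$pwms, sim$background)
  res <- allele_max_zscores(sim$pwms, cal, sim$ref_seq, sim$alt_seq)
  planted <- res[res$tf_id == "TF_PLANTED", ]
  expect_gt(planted$delta_z, 1)
  expect_gt(planted$z_alt, 3)
  ranked <- rank_allele_deltas(res)
  expect_identical(ranked$tf_id[1], "TF_PLANTED")
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
})

test_that("expression filtering drops silent TFs before ranking", {
  res <- tibble::tibble(tf_id = c("A", "B", "C"),
                        max_score_ref = 1, max_score_alt = 1,
                        z_ref = 0, z_alt = c(3, 2, 1),
                        delta_z = c(3, 2, 1),
                        pos_ref = 1L, strand_ref = "+",
                        pos_alt = 1L, strand_alt = "+")
  class(res) <- c("vcm_allele_scan", class(res))
  expr <- tibble::tibble(tf_id = c("A", "B", "C"),
                         mean_expression = c(0.1, 5, 5))
  ranked <- rank_allele_deltas(res, expr)
  expect_identical(ranked$tf_id, c("B", "C"))
  expect_error(rank_allele_deltas(res, expr[0, ]), "empty")
  # ties break lexicographically for a stable ordering
  res$delta_z <- c(2, 2, 2)
  expect_identical(rank_allele_deltas(res)$tf_id, c("A", "B", "C"))
})

test_that("variant-centred windows share flanks and differ by the indel", {
  cfg <- sim_config(seed = 23)
  cfg$motif_spec$n_background <- 2L
  sim <- simulate_indel_sequences(cfg)
  win <- extract_indel_window(sim$ref_seq, sim$alt_seq,
                              sim$truth$del_start, sim$truth$indel_len,
                              window = 101L)
  expect_identical(nchar(win$ref), 101L)
  expect_identical(nchar(win$alt), 101L - sim$truth$indel_len)
  expect_identical(substr(win$ref, 1, 10), substr(win$alt, 1, 10))
})

test_that("PWMs round-trip through TSV and parse from JASPAR-style text", {
  p <- random_pwm("MYTF", len = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm_tsv(p, path)
  back <- read_pwm_tsv(path)
  expect_equal(back$mat, p$mat, tolerance = 1e-6)

  jas <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TFX",
               "A [ 10  0  2 ]",
               "C [  0 12  2 ]",
               "G [  1  0  8 ]",
               "T [  1  0  0 ]"), jas)
  pw <- read_jaspar(jas)
  expect_length(pw, 1)
  expect_identical(pw[[1]]$tf_id, "MA0001.1")
  expect_identical(ncol(pw[[1]]$mat), 3L)
  # column 1 is A-dominated: A scores highest
  expect_identical(which.max(pw[[1]]$mat[, 1]), c(A = 1L))
})

test_that("FASTA files round-trip named sequences", {
  seqs <- c(REF = "ACGTACGGT", ALT = "ACGT")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)
})
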