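DNA_BASES <- c("A", "C", "G", "T")

#' Position weight models
#'
#' A PWM is a 4 x L matrix of log-odds scores (rows A, C, G, T in fixed
#' order). `pwm()` wraps a ready log-odds matrix; `pwm_from_counts()`
#' converts a count (or probability) matrix using a flat background and a
#' total pseudocount of 1 split by the background; `pwm_from_consensus()`
#' builds a sharply peaked model around a consensus; `random_pwm()` draws a
#' random moderately informative model (decoys for simulations).
#'
#' @param tf_id transcription-factor identifier.
#' @param mat 4 x L numeric matrix of log-odds scores.
#' @param source free-text provenance tag.
#' @return an object of class `vcm_pwm`.
#' @export
pwm <- function(tf_id, mat, source = "user") {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4 || ncol(mat) < 1 || any(!is.finite(mat))) {
    abort("PWM must be a finite 4 x L matrix")
  }
  rownames(mat) <- DNA_BASES
  structure(list(tf_id = tf_id, mat = mat, source = source),
            class = "vcm_pwm")
}

#' @rdname pwm
#' @param counts 4 x L matrix of base counts or probabilities.
#' @param background per-base background probabilities.
#' @param pseudocount total pseudocount, split by background.
#' @export
pwm_from_counts <- function(tf_id, counts, background = rep(0.25, 4),
                            pseudocount = 1, source = "counts") {
  counts <- as.matrix(counts)
  p <- sweep(counts + pseudocount * background, 2,
             colSums(counts) + pseudocount, "/")
  pwm(tf_id, log2(sweep(p, 1, background, "/")), source = source)
}

#' @rdname pwm
#' @param consensus character vector of bases (or a single string).
#' @param peak_prob probability of the consensus base at each position.
#' @export
pwm_from_consensus <- function(tf_id, consensus, peak_prob = 0.8,
                               source = "consensus") {
  if (length(consensus) == 1L) consensus <- strsplit(consensus, "")[[1]]
  L <- length(consensus)
  # peak_prob = 0.8 gives ~1.3 bits/position, typical of eukaryotic TF motifs
  p <- matrix((1 - peak_prob) / 3, 4, L, dimnames = list(DNA_BASES, NULL))
  p[cbind(match(consensus, DNA_BASES), seq_len(L))] <- peak_prob
  pwm(tf_id, log2(p / 0.25), source = source)
}

#' @rdname pwm
#' @param len motif length.
#' @export
random_pwm <- function(tf_id, len = 10L, source = "random") {
  p <- matrix(stats::rgamma(4 * len, shape = 0.8), 4, len)
  p <- sweep(p, 2, colSums(p), "/")
  p <- (p + 0.02) / 1.08
  pwm(tf_id, log2(p / 0.25), source = source)
}

#' @export
print.vcm_pwm <- function(x, ...) {
  cat(sprintf("# PWM %s (%d bp, %s)\n", x$tf_id, ncol(x$mat), x$source))
  print(round(x$mat, 3))
  invisible(x)
}

encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
}

#' Reverse complement of a DNA string
#' @param sequence DNA string.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# Scores of all forward-strand windows of `code` (integer-encoded sequence)
# under log-odds matrix `mat`; windows containing non-ACGT come back NA.
scan_scores <- function(mat, code) {
  L <- ncol(mat)
  n_win <- length(code) - L + 1L
  if (n_win < 1L) return(numeric(0))
  s <- numeric(n_win)
  for (j in seq_len(L)) s <- s + unname(mat[, j])[code[j:(j + n_win - 1L)]]
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window of length L at every offset on both strands (the
#' reverse strand is the scan of the reverse complement); a window's score is
#' the sum over positions of the log-odds entry for the observed base.
#' Windows containing non-ACGT characters are skipped, not scored.
#'
#' @param pwm a `vcm_pwm`.
#' @param sequence DNA string of length >= L.
#' @return tibble: `position` (1-based start of the window on the forward
#'   strand), `strand` (`+`/`-`), `score`.
#' @export
pwm_scan <- function(pwm, sequence) {
  stopifnot(inherits(pwm, "vcm_pwm"))
  if (!nzchar(sequence)) abort("empty sequence")
  code <- encode_dna(sequence)
  L <- ncol(pwm$mat)
  if (length(code) < L) abort("sequence shorter than the PWM")
  fwd <- scan_scores(pwm$mat, code)
  rc_mat <- pwm$mat[4:1, rev(seq_len(L)), drop = FALSE]  # revcomp-equivalent
  rev_ <- scan_scores(rc_mat, code)
  out <- tibble(position = rep(seq_along(fwd), 2L),
                strand = rep(c("+", "-"), each = length(fwd)),
                score = c(fwd, rev_))
  filter(out, !is.na(.data$score))
}

# Top score per sequence over both strands; NA if no scorable window.
# Integer-encode equal-length sequences row-wise; non-ACGT become code 5,
# which scores -Inf and so never wins a window maximum.
batch_codes <- function(sequences) {
  codes <- matrix(match(unlist(strsplit(toupper(sequences), "")), DNA_BASES),
                  nrow = length(sequences), byrow = TRUE)
  codes[is.na(codes)] <- 5L
  codes
}

# Equal-length sequences are scanned as one batch for speed.
top_scores <- function(pwm, sequences, codes = NULL) {
  L <- ncol(pwm$mat)
  lens <- nchar(sequences)
  if (length(unique(lens)) == 1L && length(sequences) > 1L && lens[1] >= L) {
    if (is.null(codes)) codes <- batch_codes(sequences)
    n_win <- lens[1] - L + 1L
    R <- length(sequences)
    best <- rep(-Inf, R)
    for (mat in list(pwm$mat, pwm$mat[4:1, rev(seq_len(L)), drop = FALSE])) {
      m5 <- rbind(mat, -Inf)
      s <- numeric(R * n_win)
      for (j in seq_len(L)) {
        s <- s + m5[, j][codes[, j:(j + n_win - 1L)]]
      }
      dim(s) <- c(R, n_win)
      best <- pmax(best, s[cbind(seq_len(R), max.col(s, ties.method = "first"))])
    }
    best[!is.finite(best)] <- NA_real_
    return(best)
  }
  vapply(sequences, function(s) {
    sc <- pwm_scan(pwm, s)$score
    if (!length(sc)) NA_real_ else max(sc)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Calibrate per-TF top-site score distributions on background regions
#'
#' For each PWM, collects the maximum (top-site) score per background region
#' and stores the mean and standard deviation (n - 1 denominator), which
#' standardise raw scan scores into Z-scores comparable across TFs. The
#' reference analysis samples > 5000 accessible genomic regions.
#'
#' @param pwm_set list of `vcm_pwm` objects.
#' @param regions character vector of background DNA sequences (>= 2, each at
#'   least as long as the longest PWM).
#' @return tibble of class `vcm_calibration`: `tf_id`, `n_regions`,
#'   `mean_top_score`, `sd_top_score`, `degenerate`.
#' @export
calibrate_background <- function(pwm_set, regions) {
  if (length(regions) < 2) abort("need at least 2 background regions")
  codes <- if (length(unique(nchar(regions))) == 1L) batch_codes(regions)
  res <- purrr::map(pwm_set, function(pw) {
    tops <- top_scores(pw, regions, codes = codes)
    tops <- tops[!is.na(tops)]
    if (length(tops) < 2) abort(paste("too few scorable regions for", pw$tf_id))
    sdv <- stats::sd(tops)
    if (sdv == 0) {
      warn(paste("degenerate calibration (sd = 0) for", pw$tf_id))
    }
    tibble(tf_id = pw$tf_id, n_regions = length(tops),
           mean_top_score = mean(tops), sd_top_score = sdv,
           degenerate = sdv == 0)
  }) |> list_rbind()
  class(res) <- unique(c("vcm_calibration", class(res)))
  res
}

#' Per-allele maximum PWM Z-scores and allele deltas
#'
#' Scans the REF and ALT allele sequences with every PWM, keeps only the
#' highest score per allele and TF, standardises it against the TF's
#' background calibration (`Z = (max score - mean) / sd` of background
#' top-site scores), and reports `delta_z = z_alt - z_ref` — positive for
#' motifs gained on the ALT allele.
#'
#' @param pwm_set list of `vcm_pwm` objects.
#' @param calibration a `vcm_calibration` covering every TF in `pwm_set`.
#' @param ref_sequence,alt_sequence allele sequences (typically windows of
#'   equal flank length centred on the variant).
#' @return tibble of class `vcm_allele_scan`: per TF the max scores, Z-scores,
#'   `delta_z`, and best position/strand per allele.
#' @export
allele_max_zscores <- function(pwm_set, calibration, ref_sequence,
                               alt_sequence) {
  stopifnot(inherits(calibration, "vcm_calibration"))
  res <- purrr::map(pwm_set, function(pw) {
    cal <- calibration[calibration$tf_id == pw$tf_id, ]
    if (!nrow(cal)) abort(paste("missing calibration for TF", pw$tf_id))
    one <- function(seq) {
      sc <- pwm_scan(pw, seq)
      best <- sc[which.max(sc$score), ]
      z <- if (cal$degenerate) {
        if (isTRUE(all.equal(best$score, cal$mean_top_score))) 0
        else abort(paste("degenerate calibration cannot standardise", pw$tf_id))
      } else (best$score - cal$mean_top_score) / cal$sd_top_score
      list(score = best$score, z = z, pos = best$position, strand = best$strand)
    }
    r <- one(ref_sequence); a <- one(alt_sequence)
    tibble(tf_id = pw$tf_id, max_score_ref = r$score, max_score_alt = a$score,
           z_ref = r$z, z_alt = a$z, delta_z = a$z - r$z,
           pos_ref = r$pos, strand_ref = r$strand,
           pos_alt = a$pos, strand_alt = a$strand)
  }) |> list_rbind()
  class(res) <- unique(c("vcm_allele_scan", class(res)))
  res
}

#' Rank TFs by allele Z-score delta
#'
#' Orders candidate TFs by `delta_z` descending (ties broken lexicographically
#' by `tf_id`, so the ordering is stable); when an expression table is
#' supplied, TFs below `min_expression` are dropped first — non-expressed
#' factors cannot explain an allele-specific binding gain.
#'
#' @param results a `vcm_allele_scan` table.
#' @param expression optional tibble `tf_id`, `mean_expression` (e.g. mean
#'   FPKM across the cohort). Supplying an empty table is an error, distinct
#'   from supplying none.
#' @param min_expression minimum mean expression to retain a TF
#'   (default 0.5).
#' @return the filtered table sorted by `delta_z`, with a `rank` column.
#' @export
rank_allele_deltas <- function(results, expression = NULL,
                               min_expression = 0.5) {
  res <- as_tibble(results)
  if (!is.null(expression)) {
    expression <- as_tibble(expression)
    if (!nrow(expression)) {
      abort("expression table is empty; omit it to skip expression filtering")
    }
    keep <- expression$tf_id[expression$mean_expression >= min_expression]
    res <- filter(res, .data$tf_id %in% keep)
  }
  res |>
    arrange(desc(.data$delta_z), .data$tf_id) |>
    mutate(rank = row_number())
}

#' Extract variant-centred scan windows from a REF/ALT sequence pair
#'
#' Both windows share equal flank lengths around the variant; because the ALT
#' allele lacks `indel_len` bases, its window is that much shorter in
#' genomic span.
#'
#' @param ref_seq,alt_seq full allele sequences (ALT = REF minus the indel).
#' @param del_start 1-based position of the first deleted base in `ref_seq`.
#' @param indel_len deletion length in bp.
#' @param window REF window length (default 757 bp).
#' @return list with `ref` and `alt` window strings.
#' @export
extract_indel_window <- function(ref_seq, alt_seq, del_start, indel_len = 5L,
                                 window = 757L) {
  center <- del_start + floor(indel_len / 2)
  h <- floor((window - 1) / 2)
  lo <- max(1L, center - h)
  hi <- min(nchar(ref_seq), lo + window - 1L)
  list(ref = substr(ref_seq, lo, hi),
       alt = substr(alt_seq, lo, hi - indel_len))
}

#' Read and write PWMs in JASPAR-style text or 4 x L TSV
#'
#' The JASPAR-style reader accepts blocks of the form `>ID name` followed by
#' four `A [ 1 2 3 ]`-style count rows, converting counts to log-odds via
#' [pwm_from_counts()]. The TSV form is a plain 4 x L log-odds matrix with
#' base rownames, one file per PWM.
#'
#' @param path input file.
#' @return `read_jaspar()`: a list of `vcm_pwm`; `read_pwm_tsv()`: one
#'   `vcm_pwm`.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  purrr::map(heads, function(h) {
    id <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    rows <- sub("^\\s*[ACGT]", "", lines[(h + 1):(h + 4)])
    nums <- lapply(rows, function(r) {
      as.numeric(regmatches(r, gregexpr("[-0-9.eE+]+", r))[[1]])
    })
    if (length(unique(lengths(nums))) != 1L) {
      abort("malformed JASPAR record: unequal row lengths")
    }
    counts <- do.call(rbind, nums)
    pwm_from_counts(id, counts, source = "jaspar")
  })
}

#' @rdname read_jaspar
#' @export
read_pwm_tsv <- function(path) {
  tbl <- utils::read.table(path, header = FALSE, row.names = 1)
  m <- as.matrix(tbl)[DNA_BASES, , drop = FALSE]
  dimnames(m)[2] <- list(NULL)
  pwm(tf_id = sub("\\.tsv$", "", basename(path)), m, source = "tsv")
}

#' @rdname read_jaspar
#' @param x a `vcm_pwm`.
#' @export
write_pwm_tsv <- function(x, path) {
  utils::write.table(x$mat, path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequence files
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
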