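#' Sum per-variant haplotype read counts over regions
#'
#' For each assay and region, ALT and REF read counts from all heterozygous
#' variants falling in the region are summed (half-open intervals: a variant
#' at `pos == end` is excluded). Regions containing no variants yield (0, 0).
#' Duplicate rows for one (assay, variant) are rejected to prevent double
#' counting.
#'
#' @param table tibble of per-variant counts: `assay_id`, `variant_id`,
#'   `chrom`, `pos` (1-based), `alt_reads`, `ref_reads`. The matched input
#'   assay uses `assay_id == "input"`.
#' @param regions tibble: `region_id`, `chrom`, `start`, `end` (1-based
#'   half-open: positions `start <= pos < end` are contained).
#' @return tibble keyed by region: `assay_id`, `region_id`, `alt_reads`,
#'   `ref_reads`.
#' @export
aggregate_region_counts <- function(table, regions) {
  table <- as_tibble(table)
  regions <- as_tibble(regions)
  if (anyDuplicated(table[c("assay_id", "variant_id")])) {
    abort("duplicate (assay_id, variant_id) rows would double count reads")
  }
  hits <- inner_join(table, regions,
                     by = join_by(chrom, pos >= start, pos < end))
  sums <- hits |>
    group_by(.data$assay_id, .data$region_id) |>
    summarise(alt_reads = sum(.data$alt_reads),
              ref_reads = sum(.data$ref_reads), .groups = "drop")
  tidyr::expand_grid(assay_id = unique(table$assay_id),
                     region_id = regions$region_id) |>
    left_join(sums, by = c("assay_id", "region_id")) |>
    mutate(alt_reads = tidyr::replace_na(.data$alt_reads, 0L),
           ref_reads = tidyr::replace_na(.data$ref_reads, 0L)) |>
    arrange(.data$region_id, .data$assay_id)
}

# Two-sided exact binomial p-value, "doubling" convention.
binom_p_double <- function(x, n, p0) {
  min(1, 2 * min(stats::pbinom(x, n, p0),
                 stats::pbinom(x - 1, n, p0, lower.tail = FALSE)))
}

#' Input-corrected allele-specific binding test
#'
#' Per assay and region, tests whether the ALT read fraction departs from the
#' input's ALT fraction: an exact two-sided binomial test of `alt_reads`
#' successes in `alt_reads + ref_reads` trials at success probability
#' `p0 = input_alt / (input_alt + input_ref)` — correcting for reference
#' mapping bias carried by the input. Assays with fewer than `min_reads`
#' total reads are flagged `filtered_low_reads` and carry no p-value. The
#' two-sided p sums the probabilities of all outcomes no more likely than the
#' observed one (minimum-likelihood rule; `two_sided = "double"` doubles the
#' smaller tail instead). q-values are BH-adjusted across tested assays
#' within each region. The reported `log2fc_over_input` compares the assay's
#' ALT percentage to the input's (see [log2fc_over_input()]).
#'
#' @param region_counts output of [aggregate_region_counts()] (or any table
#'   with `assay_id`, `region_id`, `alt_reads`, `ref_reads` including an
#'   `"input"` assay per region).
#' @param min_reads minimum total reads for an assay to be tested
#'   (default 6).
#' @param two_sided two-sided rule: `"minlike"` (default) or `"double"`.
#' @return tibble of class `vcm_ase`: `assay_id`, `region_id`, `n_total`,
#'   `alt_fraction`, `p0`, `p`, `q`, `log2fc_over_input`, `status`.
#' @export
imbalance_test <- function(region_counts, min_reads = 6L,
                           two_sided = c("minlike", "double")) {
  two_sided <- match.arg(two_sided)
  min_reads <- assert_count(min_reads, "min_reads")
  rc <- as_tibble(region_counts)
  input <- filter(rc, .data$assay_id == "input")
  if (!nrow(input)) abort("no `input` assay rows present")
  input <- input |>
    mutate(input_total = .data$alt_reads + .data$ref_reads,
           p0 = ifelse(.data$input_total == 0, 0.5,
                       .data$alt_reads / pmax(.data$input_total, 1)),
           input_fallback = .data$input_total == 0) |>
    select("region_id", "p0", "input_fallback",
           input_alt = "alt_reads", input_ref = "ref_reads")
  res <- rc |>
    filter(.data$assay_id != "input") |>
    inner_join(input, by = "region_id") |>
    mutate(n_total = .data$alt_reads + .data$ref_reads,
           alt_fraction = ifelse(.data$n_total > 0,
                                 .data$alt_reads / .data$n_total, NA_real_),
           status = ifelse(.data$n_total < min_reads,
                           "filtered_low_reads", "tested"))
  res$p <- NA_real_
  tested <- which(res$status == "tested")
  res$p[tested] <- vapply(tested, function(i) {
    x <- res$alt_reads[i]; n <- res$n_total[i]; p0 <- res$p0[i]
    if (two_sided == "minlike") {
      stats::binom.test(x, n, p = p0)$p.value
    } else {
      binom_p_double(x, n, p0)
    }
  }, numeric(1))
  res$log2fc_over_input <- NA_real_
  res$log2fc_over_input[tested] <- vapply(tested, function(i) {
    log2fc_over_input(res$alt_reads[i], res$ref_reads[i],
                      input_alt = res$input_alt[i], input_ref = res$input_ref[i])
  }, numeric(1))
  res <- res |>
    group_by(.data$region_id) |>
    mutate(q = ifelse(.data$status == "tested",
                      fdr_adjust_allow_na(.data$p), NA_real_)) |>
    ungroup() |>
    select("assay_id", "region_id", "n_total", "alt_fraction", "p0",
           "p", "q", "log2fc_over_input", "status", "input_fallback") |>
    arrange(.data$region_id, .data$assay_id)
  class(res) <- unique(c("vcm_ase", class(res)))
  res
}

# BH over the non-NA entries, keeping positions.
fdr_adjust_allow_na <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- fdr_adjust(p[ok])
  q
}

#' Log2 fold change of an assay's ALT percentage over the input's
#'
#' `log2(alt_pct_assay / alt_pct_input)`. If either allele count of the assay
#' is zero, one read is first added to both alleles (pseudocount), so the
#' output is always finite; an input ALT percentage of zero is an error.
#'
#' @param alt_reads,ref_reads assay haplotype counts.
#' @param input_alt,input_ref input haplotype counts (alternatively pass
#'   `input_alt_pct` directly).
#' @param input_alt_pct input ALT fraction in (0, 1\].
#' @return log2 fold change (scalar).
#' @export
log2fc_over_input <- function(alt_reads, ref_reads, input_alt = NULL,
                              input_ref = NULL, input_alt_pct = NULL) {
  if (is.null(input_alt_pct)) {
    tot <- input_alt + input_ref
    input_alt_pct <- if (tot > 0) input_alt / tot else 0.5
  }
  if (input_alt_pct == 0) abort("input ALT percentage is 0; fold change undefined")
  if (alt_reads == 0 || ref_reads == 0) {
    alt_reads <- alt_reads + 1
    ref_reads <- ref_reads + 1
  }
  log2((alt_reads / (alt_reads + ref_reads)) / input_alt_pct)
}

#' TF-binding density track over a genomic window
#'
#' Partitions the window into `bin_bp` bins (the last bin may be short) and
#' counts, per bin, the number of assays with at least one peak overlapping
#' the bin — a TF condensation density profile.
#'
#' @param peak_sets named list of per-assay peak tables (`chrom`, `start`,
#'   `end`; 0-based half-open).
#' @param window list or tibble row with `chrom`, `start`, `end`.
#' @param bin_bp bin width in bp (default 10).
#' @return tibble: `chrom`, `start`, `end`, `n_assays`.
#' @export
tf_binding_density <- function(peak_sets, window, bin_bp = 10L) {
  bin_bp <- assert_count(bin_bp, "bin_bp")
  starts <- seq(window$start, window$end - 1L, by = bin_bp)
  ends <- pmin(starts + bin_bp, window$end)
  bins <- IRanges::IRanges(start = starts + 1L, end = ends)  # 1-based closed
  counts <- rep(0L, length(bins))
  for (ps in peak_sets) {
    ps <- filter(as_tibble(ps), .data$chrom == window$chrom,
                 .data$end > window$start, .data$start < window$end)
    if (!nrow(ps)) next
    ir <- IRanges::IRanges(start = ps$start + 1L, end = ps$end)
    counts <- counts + as.integer(IRanges::countOverlaps(bins, ir) > 0)
  }
  tibble(chrom = window$chrom, start = as.integer(starts),
         end = as.integer(ends), n_assays = counts)
}

#' Write a density track as BedGraph
#'
#' @param density output of [tf_binding_density()].
#' @param path output file.
#' @export
write_bedgraph <- function(density, path) {
  readr::write_tsv(density[c("chrom", "start", "end", "n_assays")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
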