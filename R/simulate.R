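#' Simulation configuration with planted ground truth
#'
#' One configuration object drives every synthetic generator, so a single
#' `seed` fully determines all inputs to the pipeline. Defaults mirror the
#' study conditions the package targets: a cohort of 300 individuals typed at
#' a variant of minor allele frequency 0.27, chromatin-tracing geometry of 25
#' segments at 8 kb resolution, Capture-C profiles binned over a ~200 kb TAD,
#' and a 5-bp indel that creates one strong TF motif at its junction.
#'
#' @param seed integer master seed; all sub-generators draw from deterministic
#'   substreams derived from it, so e.g. adding noise peaks does not perturb
#'   module columns.
#' @param n_samples number of individuals in the peak cohort.
#' @param n_peaks total peaks (module members + independent noise peaks).
#' @param module_spec tibble with one row per planted module: `size`,
#'   `rho` (target within-module Pearson correlation in \[0,1\]), `chrom`,
#'   `start`, `span` (bp).
#' @param variant_maf minor allele frequency in (0, 0.5\]; genotypes are drawn
#'   under Hardy-Weinberg equilibrium.
#' @param genotype_effect_beta additive effect of one dosage unit on each
#'   planted module's latent factor.
#' @param ase_spec list: `n_assays`, `n_regions`, `mean_depth` (Poisson mean
#'   read depth per assay/region), `true_alt_fraction` (scalar or one per
#'   assay), `input_alt_fraction`, `input_depth`.
#' @param motif_spec list: `planted_tf`, `motif_len`, `indel_len`,
#'   `n_decoys`, `n_background`, `background_len`, `window` (scan window, bp).
#' @param orca_spec list: `n_segments`, `segment_bp`, `n_cells`,
#'   `compaction_factor` in (0,1\], `noise_sd` (nm), `missing_rate`,
#'   `chrom`, `start`.
#' @param capturec_spec list: `n_fragments`, `decay` (1/bp), `viewpoint`,
#'   `tad` = c(start, end), `depth` (expected total counts per replicate),
#'   `n_replicates`, `boost_bin` (bin start or NULL), `boost_factor`,
#'   `bin_bp`, `chrom`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 300L,
                       n_peaks = 60L,
                       module_spec = tibble(size = 10L, rho = 0.6,
                                            chrom = "chr17",
                                            start = 63.5e6 + (seq_len(1) - 1) * 5e5,
                                            span = 150e3),
                       variant_maf = 0.27,
                       genotype_effect_beta = 0.5,
                       ase_spec = list(n_assays = 20L, n_regions = 1L,
                                       mean_depth = 50, true_alt_fraction = 0.5,
                                       input_alt_fraction = 0.5, input_depth = 100),
                       motif_spec = list(planted_tf = "TF_PLANTED",
                                         motif_len = 10L, indel_len = 5L,
                                         n_decoys = 20L, n_background = 5000L,
                                         background_len = 757L, window = 757L),
                       orca_spec = list(n_segments = 25L, segment_bp = 8000L,
                                        n_cells = 2000L, compaction_factor = 0.9,
                                        noise_sd = 25, missing_rate = 0.2,
                                        chrom = "chr17", start = 63486119L),
                       capturec_spec = list(n_fragments = 400L, decay = 5e-5,
                                            viewpoint = 63.6e6, tad = c(63.5e6, 63.7e6),
                                            depth = 1e5, n_replicates = 3L,
                                            boost_bin = NULL, boost_factor = 2,
                                            bin_bp = 5000L, chrom = "chr17")) {
  seed <- assert_count(seed, "seed", min = 0)
  n_samples <- assert_count(n_samples, "n_samples", min = 3)
  n_peaks <- assert_count(n_peaks, "n_peaks", min = 1)
  module_spec <- as_tibble(module_spec)
  assert_fraction(variant_maf, "variant_maf", lo = 0, hi = 0.5, open_lo = TRUE)
  if (nrow(module_spec)) {
    assert_fraction(module_spec$rho, "module_spec$rho")
    if (sum(module_spec$size) > n_peaks) {
      abort("module sizes sum exceeds n_peaks")
    }
  }
  assert_fraction(ase_spec$true_alt_fraction, "true_alt_fraction")
  assert_fraction(ase_spec$input_alt_fraction, "input_alt_fraction")
  if (orca_spec$compaction_factor <= 0) abort("compaction_factor must be > 0")
  assert_fraction(orca_spec$missing_rate, "missing_rate")
  if (orca_spec$n_segments < 2) abort("orca n_segments must be >= 2")
  tad <- capturec_spec$tad
  if (capturec_spec$viewpoint < tad[1] || capturec_spec$viewpoint > tad[2]) {
    abort("Capture-C viewpoint must lie inside the TAD")
  }
  structure(list(seed = seed, n_samples = n_samples, n_peaks = n_peaks,
                 module_spec = module_spec, variant_maf = variant_maf,
                 genotype_effect_beta = genotype_effect_beta,
                 ase_spec = ase_spec, motif_spec = motif_spec,
                 orca_spec = orca_spec, capturec_spec = capturec_spec),
            class = "sim_config")
}

sample_ids <- function(n) sprintf("S%03d", seq_len(n))

#' Simulate a peak cohort with planted correlated modules and a genotype effect
#'
#' Builds a peaks-by-samples signal matrix in which each planted module's
#' member peaks share an equicorrelated latent factor (factor loading
#' `a = sqrt(rho / (1 - rho))` against unit noise, so the target pairwise
#' correlation is analytic), the latent factor receives an additive
#' `genotype_effect_beta * dosage` contribution, and the remaining peaks are
#' independent Gaussian noise. Genotype dosages are drawn under
#' Hardy-Weinberg equilibrium at `variant_maf`.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (a `vcm_pm`, layer `residual`),
#'   `genotypes` (tibble: variant metadata + one dosage column per sample),
#'   and `truth` (module labels per peak, the planted beta and MAF).
#' @examples
#' sim <- simulate_peak_cohort(sim_config(seed = 7, n_samples = 50, n_peaks = 12,
#'   module_spec = tibble::tibble(size = 5, rho = 0.6, chrom = "chr17",
#'                                start = 1e6, span = 5e4)))
#' sim$truth$module_labels
#' @export
simulate_peak_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  ids <- sample_ids(n)
  g <- with_substream(config$seed, "genotype",
                      stats::rbinom(n, 2L, config$variant_maf))
  ms <- config$module_spec
  values <- list(); meta <- list(); labels <- list()
  peak_counter <- 0L
  for (m in seq_len(nrow(ms))) {
    size <- ms$size[m]; rho <- ms$rho[m]
    if (rho < 0 || rho > 1) abort("within-module correlation must be in [0, 1]")
    block <- with_substream(config$seed, paste0("module", m), {
      f <- stats::rnorm(n) + config$genotype_effect_beta * g
      if (rho == 1) {
        matrix(rep(f, size), nrow = size, byrow = TRUE)
      } else {
        a <- sqrt(rho / (1 - rho))
        t(vapply(seq_len(size), function(i) a * f + stats::rnorm(n),
                 numeric(n)))
      }
    })
    starts <- round(seq(ms$start[m], ms$start[m] + ms$span[m], length.out = size))
    pid <- sprintf("peak%04d", peak_counter + seq_len(size))
    meta[[m]] <- tibble(chrom = ms$chrom[m], start = as.integer(starts),
                        end = as.integer(starts + 500L), peak_id = pid,
                        assay = "H3K27ac")
    labels[[m]] <- tibble(peak_id = pid, module = sprintf("planted_%d", m))
    values[[m]] <- block
    peak_counter <- peak_counter + size
  }
  n_noise <- config$n_peaks - peak_counter
  if (n_noise > 0) {
    noise <- t(vapply(seq_len(n_noise), function(i) {
      with_substream(config$seed, paste0("noise", i), stats::rnorm(n))
    }, numeric(n)))
    # noise peaks interleave between/around modules on the first chromosome
    chrom <- if (nrow(ms)) ms$chrom[1] else "chr17"
    base <- if (nrow(ms)) max(ms$start + ms$span) + 2e4 else 63.5e6
    starts <- round(base + (seq_len(n_noise) - 1) * 3e3)
    pid <- sprintf("peak%04d", peak_counter + seq_len(n_noise))
    meta[[length(meta) + 1L]] <- tibble(chrom = chrom, start = as.integer(starts),
                                        end = as.integer(starts + 500L),
                                        peak_id = pid, assay = "H3K27ac")
    labels[[length(labels) + 1L]] <- tibble(peak_id = pid, module = "noise")
    values[[length(values) + 1L]] <- noise
  }
  vals <- do.call(rbind, values)
  colnames(vals) <- ids
  pm <- peak_matrix(vals, bind_rows(meta), layer = "residual")
  geno <- bind_cols(
    tibble(variant_id = "var1",
           chrom = if (nrow(ms)) ms$chrom[1] else "chr17",
           pos = if (nrow(ms)) as.integer(ms$start[1] - 2500L) else 63497779L,
           ref = "ATCAAA", alt = "A"),
    as_tibble(as.list(stats::setNames(g, ids)))
  )
  truth <- structure(list(module_labels = bind_rows(labels),
                          true_beta = config$genotype_effect_beta,
                          variant_maf = config$variant_maf,
                          seed = config$seed),
                     class = "vcm_truth")
  list(matrix = pm, genotypes = geno, truth = truth)
}

#' Simulate a raw count matrix for the normalisation chain
#'
#' Lognormal peak abundances scaled by per-sample library-depth factors and
#' Poisson-sampled, for exercising size-factor normalisation.
#'
#' @param n_peaks,n_samples dimensions.
#' @param seed integer seed.
#' @param depth_range range of per-sample relative library depths.
#' @return a `vcm_pm` with layer `raw`.
#' @export
simulate_count_matrix <- function(n_peaks = 50L, n_samples = 20L, seed = 1L,
                                  depth_range = c(0.5, 2)) {
  withr::with_seed(as.integer(seed), {
    mu <- exp(stats::rnorm(n_peaks, 4, 1))
    depth <- stats::runif(n_samples, depth_range[1], depth_range[2])
    lam <- outer(mu, depth)
    vals <- matrix(stats::rpois(length(lam), lam), n_peaks, n_samples)
    colnames(vals) <- sample_ids(n_samples)
    starts <- 1e6 + (seq_len(n_peaks) - 1L) * 2000L
    peak_matrix(vals, tibble(chrom = "chr17", start = as.integer(starts),
                             end = as.integer(starts + 500L),
                             peak_id = sprintf("peak%04d", seq_len(n_peaks)),
                             assay = "H3K27ac"))
  })
}

#' Simulate phased-haplotype allele-specific read counts
#'
#' For each assay and region, ALT read counts are Binomial(n, true ALT
#' fraction) with n Poisson-distributed around `mean_depth`; a matched input
#' assay is drawn at `input_alt_fraction` (set below 0.5 to emulate reference
#' mapping bias in the input).
#'
#' @param config a [sim_config()].
#' @return list with `counts` (tibble: `assay_id`, `region_id`, `alt_reads`,
#'   `ref_reads`; the input assay has `assay_id == "input"`) and `truth`.
#' @export
simulate_allelic_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$ase_spec
  n_assays <- assert_count(sp$n_assays, "n_assays")
  n_regions <- assert_count(sp$n_regions, "n_regions")
  frac <- rep(sp$true_alt_fraction, length.out = n_assays)
  assert_fraction(frac, "true_alt_fraction")
  assert_fraction(sp$input_alt_fraction, "input_alt_fraction")
  counts <- with_substream(config$seed, "ase", {
    grid <- tidyr::expand_grid(assay = seq_len(n_assays), region = seq_len(n_regions))
    n <- stats::rpois(nrow(grid), sp$mean_depth)
    alt <- stats::rbinom(nrow(grid), n, frac[grid$assay])
    assay_tbl <- tibble(assay_id = sprintf("TF%02d", grid$assay),
                        region_id = sprintf("region%04d", grid$region),
                        alt_reads = alt, ref_reads = n - alt)
    n_in <- stats::rpois(n_regions, sp$input_depth)
    alt_in <- stats::rbinom(n_regions, n_in, sp$input_alt_fraction)
    input_tbl <- tibble(assay_id = "input",
                        region_id = sprintf("region%04d", seq_len(n_regions)),
                        alt_reads = alt_in, ref_reads = n_in - alt_in)
    bind_rows(assay_tbl, input_tbl)
  })
  truth <- structure(list(true_alt_fractions =
                            tibble(assay_id = sprintf("TF%02d", seq_len(n_assays)),
                                   true_alt_fraction = frac),
                          input_alt_fraction = sp$input_alt_fraction,
                          seed = config$seed),
                     class = "vcm_truth")
  list(counts = counts, truth = truth)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a REF/ALT sequence pair where a short deletion creates a motif
#'
#' The ALT sequence equals REF minus an `indel_len`-bp deletion whose junction
#' creates an exact match to the planted PWM's consensus; the consensus is
#' split across the deletion so it exists on neither side of REF alone. Decoy
#' PWMs carry no planted site, and background regions are uniform-random DNA
#' for top-site Z-score calibration.
#'
#' @param config a [sim_config()].
#' @return list with `ref_seq`, `alt_seq` (character), `pwms` (list of
#'   [pwm()] objects, planted PWM first), `background` (character vector),
#'   `truth` (planted TF id, deletion position, indel length).
#' @export
simulate_indel_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$motif_spec
  L <- assert_count(sp$motif_len, "motif_len", min = 4)
  indel <- assert_count(sp$indel_len, "indel_len")
  win <- assert_count(sp$window, "window", min = L + indel + 2L)
  with_substream(config$seed, "motif", {
    consensus <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    planted <- pwm_from_consensus(sp$planted_tf, consensus)
    decoys <- lapply(seq_len(sp$n_decoys), function(i) {
      random_pwm(sprintf("DECOY%02d", i), len = sample(6:12, 1))
    })
    seq_len_ref <- win + indel
    del_start <- floor(seq_len_ref / 2) - floor(indel / 2)  # 1-based, inclusive
    k <- floor(L / 2)
    ref <- NULL
    for (attempt in seq_len(100)) {
      s <- strsplit(random_dna(seq_len_ref), "")[[1]]
      s[(del_start - k):(del_start - 1L)] <- consensus[seq_len(k)]
      s[(del_start + indel):(del_start + indel + (L - k) - 1L)] <-
        consensus[(k + 1L):L]
      # the deleted bases disrupt the motif on the REF allele: draw each to
      # mismatch the consensus continuation of both flanking half-sites
      for (t in seq_len(indel)) {
        forbidden <- character()
        if (k + t <= L) forbidden <- c(forbidden, consensus[k + t])
        ci <- k - indel + t
        if (ci >= 1 && ci <= L) forbidden <- c(forbidden, consensus[ci])
        s[del_start + t - 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                                forbidden), 1L)
      }
      cand <- paste(s, collapse = "")
      # the planted site must exist on ALT only: reject REF candidates that
      # carry the consensus or a near-perfect (>= L - 1 matching bases) copy
      # of it on either strand anywhere else in the sequence
      cons_rc <- strsplit(revcomp(paste(consensus, collapse = "")), "")[[1]]
      n_win <- length(s) - L + 1L
      best_match <- 0L
      for (cons_v in list(consensus, cons_rc)) {
        m <- integer(n_win)
        for (j in seq_len(L)) m <- m + (s[j:(j + n_win - 1L)] == cons_v[j])
        best_match <- max(best_match, m)
      }
      if (best_match < L - 1L) {
        ref <- cand
        break
      }
    }
    if (is.null(ref)) abort("could not embed motif without a REF-side match")
    alt <- paste0(substr(ref, 1L, del_start - 1L),
                  substr(ref, del_start + indel, seq_len_ref))
    background <- vapply(seq_len(sp$n_background), function(i)
      random_dna(sp$background_len), character(1))
    truth <- structure(list(planted_motif_tf = sp$planted_tf,
                            consensus = paste(consensus, collapse = ""),
                            del_start = del_start, indel_len = indel,
                            seed = config$seed),
                       class = "vcm_truth")
    list(ref_seq = ref, alt_seq = alt, pwms = c(list(planted), decoys),
         background = background, truth = truth)
  })
}

#' Simulate paired chromatin-tracing distance ensembles
#'
#' Per-cell pairwise distances follow a monotone power-law distance-versus-
#' genomic-separation curve plus Gaussian noise; the ALT ensemble applies a
#' global `compaction_factor` to the curve before adding independent noise,
#' and entries are masked missing at `missing_rate` (imaging dropout).
#'
#' @param config a [sim_config()].
#' @return list with `ref`, `alt` (long tibbles of class `orca_ensemble`:
#'   `cell_id`, `seg_i`, `seg_j`, `dist_nm`, NA when missing; segment
#'   metadata and genotype tag as attributes) and `truth`.
#' @export
simulate_orca_ensembles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$orca_spec
  S <- assert_count(sp$n_segments, "n_segments", min = 2)
  pairs <- utils::combn(S, 2)
  sep <- pairs[2, ] - pairs[1, ]
  curve <- 120 * sep^(1 / 3)
  segments <- tibble(index = seq_len(S), chrom = sp$chrom,
                     start = as.integer(sp$start + (seq_len(S) - 1L) * sp$segment_bp),
                     end = as.integer(sp$start + seq_len(S) * sp$segment_bp))
  draw <- function(tag, factor) {
    with_substream(config$seed, paste0("orca_", tag), {
      n_cells <- sp$n_cells
      base <- matrix(rep(factor * curve, each = n_cells), n_cells, ncol(pairs))
      d <- base + matrix(stats::rnorm(length(base), 0, sp$noise_sd),
                         n_cells, ncol(pairs))
      d <- pmax(d, 0)
      if (sp$missing_rate > 0) {
        d[stats::runif(length(d)) < sp$missing_rate] <- NA_real_
      }
      tbl <- tibble(cell_id = rep(sprintf("%s_cell%05d", tag, seq_len(n_cells)),
                                  times = ncol(pairs)),
                    seg_i = rep(pairs[1, ], each = n_cells),
                    seg_j = rep(pairs[2, ], each = n_cells),
                    dist_nm = as.vector(d))
      orca_ensemble(tbl, segments, genotype = toupper(tag))
    })
  }
  truth <- structure(list(compaction_factor = sp$compaction_factor,
                          noise_sd = sp$noise_sd,
                          missing_rate = sp$missing_rate, seed = config$seed),
                     class = "vcm_truth")
  list(ref = draw("ref", 1), alt = draw("alt", sp$compaction_factor),
       truth = truth)
}

#' Simulate Capture-C fragment count profiles
#'
#' Expected counts per restriction fragment decay exponentially with distance
#' from the viewpoint (`decay` -> 0 gives a uniform profile); replicate counts
#' are independent Poisson draws, and for the ALT genotype a multiplicative
#' `boost_factor` can be planted on all fragments whose midpoints fall in the
#' `bin_bp` bin starting at `boost_bin`.
#'
#' @param config a [sim_config()].
#' @return list with `profiles` (list of [capturec_profile()] objects, one per
#'   genotype x replicate) and `truth`.
#' @export
simulate_capturec <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$capturec_spec
  tad <- sp$tad
  bounds <- round(seq(tad[1], tad[2], length.out = sp$n_fragments + 1L))
  frag <- tibble(chrom = sp$chrom, start = as.integer(bounds[-length(bounds)]),
                 end = as.integer(bounds[-1]))
  mid <- (frag$start + frag$end) / 2
  lam <- exp(-sp$decay * abs(mid - sp$viewpoint))
  lam <- lam / sum(lam) * sp$depth
  boost <- rep(1, nrow(frag))
  if (!is.null(sp$boost_bin)) {
    in_bin <- mid >= sp$boost_bin & mid < sp$boost_bin + sp$bin_bp
    boost[in_bin] <- sp$boost_factor
  }
  profiles <- list()
  for (gt in c("REF", "ALT")) {
    for (r in seq_len(sp$n_replicates)) {
      mult <- if (gt == "ALT") boost else rep(1, nrow(frag))
      counts <- with_substream(config$seed, paste0("capc_", gt, "_", r),
                               stats::rpois(nrow(frag), lam * mult))
      profiles[[paste0(gt, "_rep", r)]] <-
        capturec_profile(mutate(frag, count = counts), viewpoint = sp$viewpoint,
                         tad = tad, genotype = gt, replicate = r)
    }
  }
  truth <- structure(list(boost_bin = sp$boost_bin,
                          boost_factor = sp$boost_factor,
                          decay = sp$decay, seed = config$seed),
                     class = "vcm_truth")
  list(profiles = profiles, truth = truth)
}

#' Write / read a planted-truth object as JSON
#'
#' Truth objects round-trip losslessly so simulations can be archived next to
#' their outputs.
#'
#' @param truth a `vcm_truth` object.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "vcm_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(x)) if (is.list(x[[nm]]) && !is.null(names(x[[nm]])) &&
                           length(unique(lengths(x[[nm]]))) == 1 &&
                           lengths(x[[nm]])[1] > 1) {
    x[[nm]] <- as_tibble(x[[nm]])
  }
  structure(x, class = "vcm_truth")
}
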