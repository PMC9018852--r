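#' Windowed pairwise peak correlations
#'
#' Computes Pearson correlations for every unordered pair of peaks on the
#' same chromosome whose midpoints lie within `window_bp` of each other (the
#' cis test universe). Two-sided p-values come from the exact t-distribution
#' of r with n - 2 degrees of freedom; q-values are Benjamini-Hochberg,
#' computed per chromosome over the emitted pairs.
#'
#' @param matrix a `vcm_pm` with layer `int-transformed`.
#' @param window_bp maximum midpoint distance between tested peaks (default
#'   2 Mb, bracketing the TAD scale of cis-regulatory coordination).
#' @return tibble of class `vcm_pairs`: `chrom`, `peak_a`, `peak_b`, `r`,
#'   `p`, `q`; peak metadata and the sample size travel as attributes.
#' @export
pairwise_correlations <- function(matrix, window_bp = 2e6) {
  check_layer(matrix, "int-transformed", "pairwise_correlations")
  if (window_bp <= 0) abort("window_bp must be > 0")
  meta <- peak_meta(matrix)
  v <- peak_values(matrix)
  n <- ncol(v)
  if (n < 4) abort("need at least 4 samples to test correlations")
  out <- lapply(split(seq_len(nrow(meta)), meta$chrom), function(idx) {
    if (length(idx) < 2) return(NULL)
    m <- meta[idx, ]
    mid <- (m$start + m$end) / 2
    cors <- stats::cor(t(v[idx, , drop = FALSE]))
    pr <- which(upper.tri(cors), arr.ind = TRUE)
    keep <- abs(mid[pr[, 1]] - mid[pr[, 2]]) <= window_bp
    pr <- pr[keep, , drop = FALSE]
    if (!nrow(pr)) return(NULL)
    r <- cors[pr]
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    tibble(chrom = m$chrom[1], peak_a = m$peak_id[pr[, 1]],
           peak_b = m$peak_id[pr[, 2]], r = r, p = p,
           q = stats::p.adjust(p, method = "BH"))
  })
  res <- bind_rows(out)
  attr(res, "peaks") <- meta
  attr(res, "n_samples") <- n
  attr(res, "window_bp") <- window_bp
  class(res) <- unique(c("vcm_pairs", class(res)))
  res
}

# Connected components over a kept-edge set -> module table.
modules_from_edges <- function(edges, peaks, method) {
  empty <- tibble(module_id = character(), chrom = character(),
                  start = integer(), end = integer(), method = character(),
                  n_members = integer(), mean_r = double(),
                  members = list())
  if (is.null(edges) || !nrow(edges)) return(new_vcm_set(empty))
  g <- igraph::graph_from_data_frame(edges[c("peak_a", "peak_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  mods <- purrr::imap(membership, function(pk, i) {
    m <- peaks[match(pk, peaks$peak_id), ]
    in_mod <- edges$peak_a %in% pk & edges$peak_b %in% pk
    tibble(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
           method = method, n_members = length(pk),
           mean_r = mean(edges$r[in_mod]), members = list(sort(pk)))
  })
  res <- bind_rows(mods) |>
    arrange(.data$chrom, .data$start) |>
    mutate(module_id = sprintf("vcm_%03d", row_number()), .before = 1)
  new_vcm_set(res)
}

new_vcm_set <- function(tbl, genome = NULL) {
  attr(tbl, "genome") <- genome
  class(tbl) <- unique(c("vcm_set", class(tbl)))
  tbl
}

#' Call variable chromatin modules by FDR-thresholded correlation grouping
#'
#' Keeps peak pairs with `q <= fdr` (and `r > 0` unless `positive_only =
#' FALSE`) and reports the connected components of the kept-pair graph as
#' modules; grouping is therefore transitive (a chain A-B, B-C joins A and C
#' even if the A-C pair alone is not significant). Singleton peaks are never
#' reported — a module must coordinate at least two cis-regulatory elements.
#'
#' @param pairs a `vcm_pairs` table from [pairwise_correlations()].
#' @param fdr BH FDR threshold on pair q-values (default 0.001, i.e. 0.1%).
#' @param positive_only admit positively correlated edges only (module
#'   activity is a coordinated-activation concept).
#' @return tibble of class `vcm_set`: `module_id`, `chrom`, `start`, `end`,
#'   `method`, `n_members`, `mean_r`, `members` (list column of peak ids).
#' @export
call_vcms_fdr <- function(pairs, fdr = 0.001, positive_only = TRUE) {
  stopifnot(inherits(pairs, "vcm_pairs"))
  keep <- pairs$q <= fdr
  if (positive_only) keep <- keep & pairs$r > 0
  modules_from_edges(pairs[keep, , drop = FALSE], attr(pairs, "peaks"), "fdr")
}

#' Call modules by a fixed correlation threshold
#'
#' Identical grouping to [call_vcms_fdr()] but edges are kept where
#' `r >= r_min`. At large cohort sizes a 0.1% pair FDR corresponds to weak
#' correlations (r around 0.24 at n near 311), so a fixed threshold (default
#' r > 0.5) gives tighter, better-delineated modules.
#'
#' @inheritParams call_vcms_fdr
#' @param r_min minimum Pearson correlation in (0, 1).
#' @return a `vcm_set` tibble, `method = "r-threshold"`.
#' @export
call_vcms_rthreshold <- function(pairs, r_min = 0.5) {
  stopifnot(inherits(pairs, "vcm_pairs"))
  if (r_min <= 0 || r_min >= 1) abort("r_min must be in (0, 1)")
  modules_from_edges(pairs[pairs$r >= r_min, , drop = FALSE],
                     attr(pairs, "peaks"), "r-threshold")
}

#' Call modules by hierarchical clustering of the correlation structure
#'
#' Per chromosome, peaks are clustered by average-linkage agglomeration on
#' distance 1 - r (pairs beyond `window_bp` are treated as uncorrelated);
#' the maximal tree nodes whose mean within-node |r| reaches
#' `mean_abs_r_cut` are reported as modules. This delineates nested module
#' structure instead of a single fixed edge threshold.
#'
#' @inheritParams pairwise_correlations
#' @param mean_abs_r_cut minimum mean absolute pairwise correlation within a
#'   reported node.
#' @return a `vcm_set` tibble, `method = "hclust"`.
#' @export
call_vcms_hclust <- function(matrix, window_bp = 2e6, mean_abs_r_cut = 0.5) {
  check_layer(matrix, "int-transformed", "call_vcms_hclust")
  meta <- peak_meta(matrix)
  v <- peak_values(matrix)
  if (ncol(v) < 4) abort("need at least 4 samples")
  mods <- list()
  for (idx in split(seq_len(nrow(meta)), meta$chrom)) {
    if (length(idx) < 2) next
    m <- meta[idx, ]
    ord <- order(m$start)
    m <- m[ord, ]; idx <- idx[ord]
    mid <- (m$start + m$end) / 2
    r <- stats::cor(t(v[idx, , drop = FALSE]))
    r[abs(outer(mid, mid, "-")) > window_bp] <- 0
    diag(r) <- 1
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
    nodes <- maximal_nodes(hc, abs(r), mean_abs_r_cut)
    for (members in nodes) {
      pk <- m$peak_id[members]
      sub <- r[members, members]
      mods[[length(mods) + 1L]] <-
        tibble(chrom = m$chrom[1], start = min(m$start[members]),
               end = max(m$end[members]), method = "hclust",
               n_members = length(pk),
               mean_r = mean(sub[upper.tri(sub)]), members = list(sort(pk)))
    }
  }
  res <- bind_rows(mods)
  if (!nrow(res)) return(modules_from_edges(NULL, meta, "hclust"))
  res <- res |>
    arrange(.data$chrom, .data$start) |>
    mutate(module_id = sprintf("vcm_%03d", row_number()), .before = 1)
  new_vcm_set(res)
}

# Depth-first search of an hclust tree: return member index sets of the
# maximal (closest-to-root) nodes whose mean |r| >= cut.
maximal_nodes <- function(hc, abs_r, cut) {
  n <- nrow(abs_r)
  members_of <- function(node) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    c(members_of(kids[1]), members_of(kids[2]))
  }
  out <- list()
  visit <- function(node) {
    if (node < 0) return(invisible(NULL))  # singleton leaf: never a module
    mem <- members_of(node)
    sub <- abs_r[mem, mem]
    if (mean(sub[upper.tri(sub)]) >= cut) {
      out[[length(out) + 1L]] <<- mem
    } else {
      visit(hc$merge[node, 1]); visit(hc$merge[node, 2])
    }
  }
  if (n >= 2) visit(nrow(hc$merge))
  out
}

#' Merge module calls from several datasets into consensus modules
#'
#' Modules whose genomic spans overlap (across or within call sets) are
#' merged into one consensus module: union of member peaks, union of spans.
#' Provenance of the source calls is retained in a `sources` list column.
#'
#' @param calls list of `vcm_set` tibbles sharing one coordinate system. A
#'   `genome` attribute, when present on the inputs, must agree.
#' @return a `vcm_set` tibble, `method = "consensus"`.
#' @export
consensus_vcms <- function(calls) {
  stopifnot(is.list(calls), length(calls) >= 2)
  genomes <- unique(unlist(lapply(calls, attr, "genome")))
  if (length(genomes) > 1) {
    abort(paste("mixed genome builds:", paste(genomes, collapse = ", ")))
  }
  pooled <- bind_rows(lapply(seq_along(calls), function(i) {
    mutate(as_tibble(calls[[i]]), .call_set = i)
  }))
  if (!nrow(pooled)) return(new_vcm_set(pooled[0, ], genome = genomes))
  merged <- list()
  for (tbl in split(pooled, pooled$chrom)) {
    tbl <- arrange(tbl, .data$start, .data$end)
    grp <- integer(nrow(tbl)); grp[1] <- 1L; hi <- tbl$end[1]
    for (i in seq_len(nrow(tbl))[-1]) {
      if (tbl$start[i] < hi) grp[i] <- grp[i - 1] else grp[i] <- grp[i - 1] + 1L
      hi <- max(hi, tbl$end[i])
    }
    for (g in split(seq_len(nrow(tbl)), grp)) {
      sub <- tbl[g, ]
      merged[[length(merged) + 1L]] <-
        tibble(chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end), method = "consensus",
               n_members = length(unique(unlist(sub$members))),
               mean_r = mean(sub$mean_r, na.rm = TRUE),
               members = list(sort(unique(unlist(sub$members)))),
               sources = list(sub$module_id))
    }
  }
  res <- bind_rows(merged) |>
    arrange(.data$chrom, .data$start) |>
    mutate(module_id = sprintf("vcm_%03d", row_number()), .before = 1)
  new_vcm_set(res, genome = genomes)
}

#' Agreement between called and planted module labels
#'
#' Adjusted Rand index between the called partition and the planted truth.
#' Peaks outside any called module, and peaks labelled noise in the truth,
#' are each treated as their own singleton cluster, so spurious grouping of
#' noise peaks is penalised.
#'
#' @param vcms a `vcm_set` tibble.
#' @param truth_labels tibble with `peak_id`, `module` (planted label,
#'   `"noise"` for background peaks).
#' @return adjusted Rand index in \[-1, 1\].
#' @export
module_recovery_score <- function(vcms, truth_labels) {
  called <- stats::setNames(rep(NA_character_, nrow(truth_labels)),
                            truth_labels$peak_id)
  for (i in seq_len(nrow(vcms))) {
    called[vcms$members[[i]]] <- vcms$module_id[i]
  }
  singleton <- is.na(called)
  called[singleton] <- paste0("single_", names(called)[singleton])
  truth <- truth_labels$module
  noise <- truth == "noise"
  truth[noise] <- paste0("tsingle_", truth_labels$peak_id[noise])
  mclust::adjustedRandIndex(called, truth)
}

#' Write modules as BED plus a membership TSV
#'
#' @param vcms a `vcm_set` tibble.
#' @param bed_path,membership_path output paths (either may be `NULL`).
#' @export
write_vcms <- function(vcms, bed_path = NULL, membership_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- tibble(chrom = vcms$chrom, start = vcms$start, end = vcms$end,
                  name = vcms$module_id,
                  score = round(1000 * pmin(pmax(vcms$mean_r, 0), 1)),
                  strand = ".")
    readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  }
  if (!is.null(membership_path)) {
    mem <- vcms |>
      select("module_id", "members", "method", "mean_r") |>
      tidyr::unnest_longer("members", values_to = "peak_id")
    readr::write_tsv(mem, membership_path, progress = FALSE)
  }
  invisible(vcms)
}
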