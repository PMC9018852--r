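#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_chr map2 imap list_rbind
NULL

# Deterministic substream seeding: one master seed per generator call, split
# per sub-task by hashing a string key, so e.g. adding noise peaks does not
# perturb already-generated module columns.
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483647
  as.integer((as.double(seed) * 2654435 + h + 1) %% 2147483647)
}

with_substream <- function(seed, key, code) {
  withr::with_seed(substream_seed(seed, key), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  bad <- !is.numeric(x) || anyNA(x) ||
    any(if (open_lo) x <= lo else x < lo) ||
    any(if (open_hi) x >= hi else x > hi)
  if (bad) {
    abort(sprintf("`%s` must lie in %s%g, %g%s", name,
                  if (open_lo) "(" else "[", lo, hi,
                  if (open_hi) ")" else "]"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
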