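#' @importFrom stats p.adjust ppois pbinom dbinom phyper pnorm pt rnbinom
#'   rpois runif rnorm kmeans median sd cor setNames complete.cases
#' @importFrom utils read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with the cumulative-minimum tie
#' rule. Thin, named wrapper so every module shares one FDR code path.
#'
#' @param p numeric vector of p-values.
#' @param n number of tests in the candidate family (default
#'   `length(p)`). Island calling passes the total window count here:
#'   islands are the extreme members of the window family, so adjusting
#'   only over surviving islands would be anti-conservative.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, n = length(p)) {
  stats::p.adjust(p, method = "BH", n = n)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score cluster recovery against planted classes.
#'
#' @param a,b vectors of cluster labels (any atomic type), equal length.
#' @return scalar ARI in \[-1, 1\]; 1 means identical partitions up to
#'   relabeling.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic 31-bit sub-seed from a base seed plus a stream name, so each
# (sample, chromosome) draws from its own reproducible RNG stream and adding
# a sample never perturbs the others.
stream_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_stream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, ...))
  expr
}

# Sum of per-bp density over [from, to) for a window-count vector: each
# window of width w holds `counts[i]` reads spread uniformly over its bp.
# Vectorised over bins given numeric breakpoints.
bin_from_windows <- function(counts, window_size, from, to) {
  stopifnot(length(from) == length(to), all(to >= from))
  n <- length(counts)
  out <- numeric(length(from))
  for (i in seq_along(from)) {
    a <- max(from[i], 0)
    b <- min(to[i], n * window_size)
    if (b <= a) next
    w0 <- floor(a / window_size) + 1
    w1 <- ceiling(b / window_size)
    idx <- w0:w1
    lo <- pmax(a, (idx - 1) * window_size)
    hi <- pmin(b, idx * window_size)
    out[i] <- sum(counts[idx] * (hi - lo) / window_size)
  }
  out
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("'%s' must be a probability in (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}
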