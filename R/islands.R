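# SICER-style broad-island calling. A documented simplified
# reimplementation of the algorithm class: per-window Poisson eligibility
# against a library-scaled control rate, gap-bridged aggregation of
# eligible windows into islands, an island-level Poisson tail test, and
# Benjamini-Hochberg control over islands. The original's island-score
# recursion and E-value are deliberately not retained.

#' Island-calling parameters
#'
#' @param window window width W in bp (default 200).
#' @param gap maximum bridged gap G in bp (multiple of `window`).
#' @param window_pvalue_cutoff permissive per-window Poisson eligibility
#'   cutoff (default 0.2); the island-level FDR does the real filtering.
#' @param island_fdr island-level BH FDR threshold (default 0.01).
#' @param effective_genome_fraction fraction of the genome assumed
#'   mappable (default 0.8). The control-rate floor is the genome-average
#'   chip rate over the effective genome (library / (windows x
#'   fraction)), so zero-count control windows cannot force p = 0 and the
#'   plug-in control noise cannot understate the background.
#' @return validated list of class `island_params`.
#' @export
island_params <- function(window = 200, gap = 200,
                          window_pvalue_cutoff = 0.2, island_fdr = 0.01,
                          effective_genome_fraction = 0.8) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  if (gap < 0 || gap %% window != 0) {
    stop("gap must be a non-negative multiple of window", call. = FALSE)
  }
  check_probability(window_pvalue_cutoff, "window_pvalue_cutoff")
  check_probability(island_fdr, "island_fdr")
  check_probability(effective_genome_fraction, "effective_genome_fraction")
  structure(list(window = window, gap = gap,
                 window_pvalue_cutoff = window_pvalue_cutoff,
                 island_fdr = island_fdr,
                 effective_genome_fraction = effective_genome_fraction),
            class = "island_params")
}

check_same_grid <- function(a, b) {
  if (a$window_size != b$window_size ||
      !setequal(names(a$counts), names(b$counts)) ||
      !all(lengths(a$counts)[names(b$counts)] == lengths(b$counts))) {
    stop("coverage tracks are not on the same window grid", call. = FALSE)
  }
}

empty_island_df <- function(diff = FALSE) {
  base <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), stringsAsFactors = FALSE)
  if (diff) {
    cbind(base, data.frame(count_a = numeric(), count_b = numeric(),
                           scaled_a = numeric(), scaled_b = numeric(),
                           direction = character(), p_value = numeric(),
                           q_value = numeric(), stringsAsFactors = FALSE))
  } else {
    cbind(base, data.frame(chip_count = numeric(), control_count = numeric(),
                           score = numeric(), p_value = numeric(),
                           q_value = numeric(), stringsAsFactors = FALSE))
  }
}

#' Call H2A.Z-enriched islands against a control track
#'
#' Per window, the chip count is tested against a Poisson rate equal to
#' the library-scaled control count, floored at the genome-average chip
#' rate times `effective_genome_fraction`. Windows with one-sided Poisson
#' `p < window_pvalue_cutoff` are eligible; runs of eligible windows
#' separated by at most `gap` bp of ineligible windows merge into one
#' island (bridged windows contribute their counts). Each island's
#' p-value is the Poisson upper tail of its total chip count against its
#' total control expectation; BH-adjusted q-values are thresholded at
#' `island_fdr`.
#'
#' @param chip,control `coverage_track`s on the same window grid; the
#'   control may be an input or pre-immune library.
#' @param params `island_params`.
#' @param keep_all if TRUE, return all candidate islands with q-values
#'   (no FDR filtering); used for diagnostics.
#' @return data.frame: chrom, start, end (0-based half-open), chip_count,
#'   control_count (scaled expectation), score (`-log10 p`), p_value,
#'   q_value; sorted, non-overlapping.
#' @export
call_islands <- function(chip, control, params = island_params(),
                         keep_all = FALSE) {
  check_same_grid(chip, control)
  if (chip$window_size != params$window) {
    stop("track window size does not match params$window", call. = FALSE)
  }
  if (chip$library_size <= 0) stop("zero-depth chip library", call. = FALSE)
  scale <- if (control$library_size > 0) {
    chip$library_size / control$library_size
  } else {
    0
  }
  total_windows <- sum(lengths(chip$counts))
  # background rate over the effective (mappable) genome: a smaller
  # effective fraction concentrates the same library into fewer usable
  # windows, so the floor divides by it
  floor_rate <- chip$library_size / total_windows /
    params$effective_genome_fraction
  gap_windows <- params$gap / params$window

  out <- list()
  for (ch in names(chip$counts)) {
    x <- chip$counts[[ch]]
    lam <- pmax(control$counts[[ch]] * scale, floor_rate)
    p_win <- ppois(x - 1, lam, lower.tail = FALSE)
    eligible <- which(p_win < params$window_pvalue_cutoff & x > 0)
    if (length(eligible) == 0) next
    # merge eligible windows bridged across <= gap_windows ineligible ones
    brk <- c(TRUE, diff(eligible) > gap_windows + 1)
    grp <- cumsum(brk)
    first <- tapply(eligible, grp, min)
    last <- tapply(eligible, grp, max)
    W <- params$window
    out[[ch]] <- data.frame(
      chrom = ch,
      start = (first - 1) * W,
      end = last * W,
      chip_count = vapply(seq_along(first),
                          function(i) sum(x[first[i]:last[i]]), numeric(1)),
      control_count = vapply(seq_along(first),
                             function(i) sum(lam[first[i]:last[i]]),
                             numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(empty_island_df())
  isl <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  isl$p_value <- ppois(isl$chip_count - 1, isl$control_count,
                       lower.tail = FALSE)
  # multiplicity over the candidate window family, not just the islands
  # that emerged from it (selection of extremes would otherwise defeat
  # the FDR control)
  isl$q_value <- bh_adjust(isl$p_value, n = total_windows)
  isl$score <- -log10(pmax(isl$p_value, 1e-300))
  if (!keep_all) isl <- isl[isl$q_value < params$island_fdr, , drop = FALSE]
  isl <- isl[order(isl$chrom, isl$start), , drop = FALSE]
  rownames(isl) <- NULL
  isl[, c("chrom", "start", "end", "chip_count", "control_count", "score",
          "p_value", "q_value")]
}

#' Merge two island sets into a union of intervals
#'
#' @param a,b island data.frames (need chrom/start/end).
#' @param gap intervals closer than `gap` bp are merged (default 0:
#'   touching intervals merge).
#' @return data.frame chrom/start/end, sorted, non-overlapping.
#' @export
island_union <- function(a, b = NULL, gap = 0) {
  df <- rbind(a[, c("chrom", "start", "end")],
              if (!is.null(b)) b[, c("chrom", "start", "end")])
  if (is.null(df) || nrow(df) == 0) return(empty_island_df()[1:3])
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    s <- d$start[1]; e <- d$end[1]
    res <- list()
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= e + gap) {
        e <- max(e, d$end[i])
      } else {
        res[[length(res) + 1]] <- c(s, e)
        s <- d$start[i]; e <- d$end[i]
      }
    }
    res[[length(res) + 1]] <- c(s, e)
    m <- do.call(rbind, res)
    out[[ch]] <- data.frame(chrom = ch, start = m[, 1], end = m[, 2],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

count_in_interval <- function(track, chrom, start, end) {
  W <- track$window_size
  v <- track$counts[[chrom]]
  if (is.null(v)) return(0)
  w0 <- floor(start / W) + 1
  w1 <- min(ceiling(end / W), length(v))
  if (w1 < w0) return(0)
  sum(v[w0:w1])
}

#' Differential islands between two conditions
#'
#' For each union island, the chip counts of the two conditions are
#' compared with an exact two-sided Poisson rate test conditional on the
#' total (a binomial test of the b-count against the library-size ratio).
#' BH across islands; islands with `q < island_fdr` are kept. Direction
#' is `increase` when the library-scaled b rate exceeds a.
#'
#' @param a,b `coverage_track`s for the two conditions (same grid).
#' @param islands_union data.frame of merged intervals, e.g. from
#'   [island_union()] of the islands called in each condition.
#' @param params `island_params`.
#' @param keep_all if TRUE, skip the FDR filter.
#' @return data.frame: chrom, start, end, count_a, count_b, scaled_a,
#'   scaled_b, direction, p_value, q_value.
#' @export
call_differential <- function(a, b, islands_union,
                              params = island_params(), keep_all = FALSE) {
  check_same_grid(a, b)
  if (nrow(islands_union) == 0) return(empty_island_df(diff = TRUE))
  if (a$library_size <= 0 || b$library_size <= 0) {
    stop("zero-depth library", call. = FALSE)
  }
  n <- nrow(islands_union)
  ca <- numeric(n); cb <- numeric(n)
  for (i in seq_len(n)) {
    ca[i] <- count_in_interval(a, islands_union$chrom[i],
                               islands_union$start[i], islands_union$end[i])
    cb[i] <- count_in_interval(b, islands_union$chrom[i],
                               islands_union$start[i], islands_union$end[i])
  }
  p_b <- b$library_size / (a$library_size + b$library_size)
  pvals <- vapply(seq_len(n), function(i) {
    tot <- ca[i] + cb[i]
    if (tot == 0) return(1)
    stats::binom.test(cb[i], tot, p = p_b)$p.value
  }, numeric(1))
  # common scale: counts per mean library
  mean_lib <- (a$library_size + b$library_size) / 2
  scaled_a <- ca / (a$library_size / mean_lib)
  scaled_b <- cb / (b$library_size / mean_lib)
  res <- data.frame(
    chrom = islands_union$chrom, start = islands_union$start,
    end = islands_union$end, count_a = ca, count_b = cb,
    scaled_a = scaled_a, scaled_b = scaled_b,
    direction = ifelse(scaled_b > scaled_a, "increase", "decrease"),
    p_value = pvals, stringsAsFactors = FALSE
  )
  res$q_value <- bh_adjust(res$p_value)
  if (!keep_all) res <- res[res$q_value < params$island_fdr, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
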