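# Overlap-enrichment statistics: a bootstrap null for DEG/category
# overlap with a binomial test (the study's bespoke statistic), and
# hypergeometric singular enrichment analysis over term annotations.

#' Bootstrap overlap enrichment of a DEG set within a gene category
#'
#' The observed overlap `x` between a DEG set (size m) and a category
#' (size K) inside a background of N genes is compared with a resampled
#' null: each of `n_iter` iterations draws m genes from the background
#' without replacement and records the overlap, giving the descriptive
#' null mean +/- SD. Significance is a one-sided binomial test of x with
#' m trials and success probability K/N, in the empirical direction
#' (`over` when x exceeds m*K/N, else `under`).
#'
#' @param deg_set,category_set character vectors, subsets of
#'   `background`.
#' @param background character vector of gene ids (the sampling
#'   universe).
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return list of class `bootstrap_result`: m, K, N, observed_overlap,
#'   null_mean, null_sd, n_iterations, binomial_p, direction, degenerate
#'   (TRUE when the null is deterministic, e.g. category = background).
#' @export
bootstrap_overlap <- function(deg_set, category_set, background,
                              n_iter = 1000, seed = 1) {
  deg_set <- unique(deg_set)
  category_set <- unique(category_set)
  background <- unique(background)
  if (length(deg_set) == 0 || length(category_set) == 0) {
    stop("empty deg_set or category_set", call. = FALSE)
  }
  if (!all(deg_set %in% background) || !all(category_set %in% background)) {
    stop("deg_set and category_set must be subsets of background",
         call. = FALSE)
  }
  m <- length(deg_set)
  K <- length(category_set)
  N <- length(background)
  x <- length(intersect(deg_set, category_set))
  in_cat <- background %in% category_set
  null <- with_stream(seed, "bootstrap", expr = {
    vapply(seq_len(n_iter),
           function(i) sum(in_cat[sample.int(N, m)]), numeric(1))
  })
  p0 <- K / N
  direction <- if (x > m * p0) "over" else "under"
  binomial_p <- if (direction == "over") {
    pbinom(x - 1, m, p0, lower.tail = FALSE)
  } else {
    pbinom(x, m, p0)
  }
  structure(list(m = m, K = K, N = N, observed_overlap = x,
                 null_mean = mean(null), null_sd = sd(null),
                 n_iterations = n_iter, binomial_p = binomial_p,
                 direction = direction, degenerate = sd(null) == 0),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> x=%d of m=%d (K=%d, N=%d); null %.2f +/- %.2f (%d iter); %s, binomial p=%.3g%s\n",
    x$observed_overlap, x$m, x$K, x$N, x$null_mean, x$null_sd,
    x$n_iterations, x$direction, x$binomial_p,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Singular enrichment analysis (hypergeometric)
#'
#' Upper-tail hypergeometric test of each term's hits in the query
#' against its background frequency, BH-adjusted. Terms with no member
#' in the background are skipped with a warning.
#'
#' @param query_genes character vector, subset of `background`.
#' @param term_annotation data.frame (`term_id`, `gene_id`).
#' @param background character vector of gene ids.
#' @param alpha significance threshold on the q-value (default 0.05).
#' @return data.frame: term_id, k (query hits), n (query size), K
#'   (background hits), N, p_value, q_value, significant; zero rows for
#'   an empty term set.
#' @export
sea_enrichment <- function(query_genes, term_annotation, background,
                           alpha = 0.05) {
  query_genes <- unique(query_genes)
  background <- unique(background)
  if (!all(query_genes %in% background)) {
    stop("query genes must be a subset of background", call. = FALSE)
  }
  empty <- data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(term_annotation) == 0) return(empty)
  n <- length(query_genes)
  N <- length(background)
  terms <- split(term_annotation$gene_id, term_annotation$term_id)
  rows <- list()
  skipped <- character()
  for (tid in names(terms)) {
    members <- intersect(unique(terms[[tid]]), background)
    K <- length(members)
    if (K == 0) {
      skipped <- c(skipped, tid)
      next
    }
    k <- length(intersect(members, query_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[tid]] <- data.frame(term_id = tid, k = k, n = n, K = K, N = N,
                              p_value = p, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning("terms absent from background skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  res[order(res$p_value), ]
}

#' Bootstrap overlap matrix: DEG direction x differential-H2A.Z category
#'
#' Runs [bootstrap_overlap()] for each combination of DEG direction
#' (up/down) and differential category (tss/gb x increase/decrease).
#' The background defaults to all annotated PCGs with at least one
#' nonzero count, the universe within which both DEGs and categories
#' live.
#'
#' @param deg_results data.frame from [de_test()].
#' @param gene_calls `calls` data.frame from [classify_differential()].
#' @param background character vector of gene ids.
#' @param n_iter,seed passed to [bootstrap_overlap()].
#' @return data.frame, one row per (deg_direction, category): sizes,
#'   observed overlap, null mean/SD, direction, binomial_p; rows with an
#'   empty DEG set or category are reported with NA statistics.
#' @export
overlap_summary <- function(deg_results, gene_calls, background,
                            n_iter = 1000, seed = 1) {
  categories <- c("tss_increase", "tss_decrease", "gb_increase",
                  "gb_decrease")
  out <- list()
  for (dir in c("up", "down")) {
    degs <- intersect(deg_results$gene_id[deg_results$direction == dir],
                      background)
    for (cat in categories) {
      genes <- intersect(unique(gene_calls$gene_id[gene_calls$category ==
                                                     cat]), background)
      row <- data.frame(deg_direction = dir, category = cat,
                        m = length(degs), K = length(genes),
                        N = length(unique(background)),
                        observed_overlap = NA_real_, null_mean = NA_real_,
                        null_sd = NA_real_, direction = NA_character_,
                        binomial_p = NA_real_, stringsAsFactors = FALSE)
      if (length(degs) > 0 && length(genes) > 0) {
        br <- bootstrap_overlap(degs, genes, background, n_iter = n_iter,
                                seed = stream_seed(seed, dir, cat))
        row$observed_overlap <- br$observed_overlap
        row$null_mean <- br$null_mean
        row$null_sd <- br$null_sd
        row$direction <- br$direction
        row$binomial_p <- br$binomial_p
      }
      out[[paste(dir, cat)]] <- row
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}
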