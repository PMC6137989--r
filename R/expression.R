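# Expression analysis: median-of-ratios size factors, FPKM, a shifted-log
# transform, a simplified NB Wald differential-expression test, and fuzzy
# k-means interaction clustering.

#' Median-of-ratios size factors
#'
#' Per-sample median of count / per-gene geometric mean, over genes with
#' all-positive counts, rescaled so the factors have geometric mean 1.
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene with positive counts in every sample", call. = FALSE)
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  sf / exp(mean(log(sf)))
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count / (length_kb * mapped_millions)`.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths named vector of gene lengths in bp.
#' @param library_sizes named vector of mapped reads per sample
#'   (default: column sums).
#' @return gene x sample FPKM matrix.
#' @export
fpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  stopifnot(all(rownames(counts) %in% names(gene_lengths)))
  len_kb <- gene_lengths[rownames(counts)] / 1000
  if (any(len_kb <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(library_sizes <= 0)) stop("zero library size", call. = FALSE)
  sweep(counts / len_kb, 2, library_sizes / 1e6, "/")
}

#' Shifted-log transform of normalized counts
#'
#' `log2(count / size_factor + 1)`: a variance-stabilising stand-in for a
#' regularized log transform, adequate for clustering.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors from [size_factors()].
#' @return gene x sample matrix.
#' @export
rlog_like <- function(counts, sf = size_factors(counts)) {
  log2(sweep(counts, 2, sf, "/") + 1)
}

# dispersion trend alpha(mu) = a0 + a1/mu fitted to per-gene MoM
# estimates (genes with positive estimates), gamma-GLM style via a simple
# least-squares fit on the positive estimates.
fit_dispersion_trend <- function(mu, disp) {
  keep <- is.finite(mu) & is.finite(disp) & mu > 0 & disp > 0
  if (sum(keep) < 10) {
    return(function(m) rep(max(stats::median(disp[keep]), 0.01,
                               na.rm = TRUE), length(m)))
  }
  fit <- stats::lm(disp[keep] ~ I(1 / mu[keep]))
  a0 <- max(unname(stats::coef(fit)[1]), 1e-8)
  a1 <- max(unname(stats::coef(fit)[2]), 0)
  function(m) a0 + a1 / pmax(m, 1e-8)
}

#' Simplified NB Wald differential-expression test
#'
#' A self-contained stand-in for a full NB GLM pipeline. Per gene, group
#' means of normalized counts give the log2 fold change (with a 0.5
#' moderation pseudocount); dispersion is a method-of-moments estimate on
#' normalized counts pooled across groups, floored at 1e-8 and taken as
#' the maximum of the gene-wise estimate and a fitted mean-dispersion
#' trend (the conservative shrinkage keeps the 2-vs-2 normal Wald test
#' calibrated; see the methods vignette); the Wald statistic uses a
#' delta-method SE and a normal reference. Genes all-zero in both groups
#' report `p = 1`, direction `ns`.
#'
#' @param counts gene x sample count matrix.
#' @param groups vector (length = samples) with exactly two levels; the
#'   log2 fold change is level 2 over level 1 (levels in order of first
#'   appearance, or factor levels).
#' @param sf size factors (default computed).
#' @param alpha_fdr BH FDR threshold for the direction call
#'   (default 0.001).
#' @return data.frame: gene_id, base_mean, log2fc, se, p_value, q_value,
#'   direction (`up`/`down`/`ns`).
#' @export
de_test <- function(counts, groups, sf = size_factors(counts),
                    alpha_fdr = 0.001) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required",
                                 call. = FALSE)
  if (any(table(groups) < 2)) stop(">= 2 replicates per group required",
                                   call. = FALSE)
  norm <- sweep(counts, 2, sf, "/")
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  # pooled MoM dispersion: var = mu + a*mu^2 within each group
  mu_pool <- (n1 * m1 + n2 * m2) / (n1 + n2)
  var_pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu2_pool <- (n1 * m1^2 + n2 * m2^2) / (n1 + n2)
  a_gene <- (var_pool - mu_pool) / pmax(mu2_pool, 1e-8)
  a_gene <- pmax(a_gene, 1e-8)
  trend <- fit_dispersion_trend(mu_pool, a_gene)
  # conservative shrinkage: never below the trend, never below the
  # gene-wise estimate
  a <- pmax(a_gene, trend(mu_pool), 1e-8)
  cmod <- 0.5
  log2fc <- log2(m2 + cmod) - log2(m1 + cmod)
  se_m1 <- sqrt((m1 + a * m1^2) / n1)
  se_m2 <- sqrt((m2 + a * m2^2) / n2)
  se <- sqrt(se_m1^2 / (m1 + cmod)^2 + se_m2^2 / (m2 + cmod)^2) / log(2)
  zero <- m1 == 0 & m2 == 0
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(stat))
  p[zero] <- 1
  log2fc[zero] <- 0
  q <- bh_adjust(p)
  direction <- ifelse(q < alpha_fdr & log2fc > 0, "up",
                      ifelse(q < alpha_fdr & log2fc < 0, "down", "ns"))
  direction[zero] <- "ns"
  data.frame(gene_id = rownames(counts), base_mean = mu_pool,
             log2fc = log2fc, se = se, p_value = p, q_value = q,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Fuzzy c-means (Bezdek): memberships u_ij = softmin of squared
# distances with exponent 2/(m-1); centers are u^m-weighted means.
fuzzy_cmeans <- function(x, k, m = 1.2, iter_max = 200, tol = 1e-8) {
  n <- nrow(x)
  d2_to <- function(centers) {
    t(apply(x, 1, function(row) colSums((t(centers) - row)^2)))
  }
  centers <- x[sample.int(n, k), , drop = FALSE]
  u_old <- NULL
  for (it in seq_len(iter_max)) {
    d2 <- pmax(d2_to(centers), 1e-12)
    # softmin in ratio form: dividing by the row minimum keeps the
    # largest weight at 1, so small fuzzifiers cannot underflow all
    # weights at once
    ratio <- d2 / apply(d2, 1, min)
    w <- ratio^(-1 / (m - 1))
    u <- w / rowSums(w)
    um <- u^m
    centers <- t(um) %*% x / colSums(um)
    if (!is.null(u_old) && max(abs(u - u_old)) < tol) break
    u_old <- u
  }
  list(membership = u, centers = centers)
}

#' Fuzzy k-means interaction clustering
#'
#' Rows (genes selected as DE in at least one contrast) are standardized
#' to mean 0, SD 1 and clustered by fuzzy c-means. A gene is assigned to
#' its argmax cluster iff its membership reaches `cutoff`, otherwise it
#' stays unassigned. Clusters are ordered by assigned size, largest
#' first, and named C1..Cn.
#'
#' @param rlog_matrix gene x sample matrix (e.g. from [rlog_like()]),
#'   rows restricted to the DE union.
#' @param k number of clusters (the method's reference scale is 14;
#'   desk-scale runs use fewer).
#' @param fuzziness fuzzifier m > 1 (default 1.2).
#' @param cutoff minimum membership for assignment (default 0.5).
#' @param seed RNG seed.
#' @param restarts random restarts, best objective kept (default 5).
#' @return list of class `interaction_clusters`: `assignment` (named
#'   vector gene -> `C1`.. or NA), `membership` (genes x k, rows sum to
#'   1, columns in C-order), `centers`.
#' @export
cluster_interactions <- function(rlog_matrix, k, fuzziness = 1.2,
                                 cutoff = 0.5, seed = 1, restarts = 5) {
  if (k > nrow(rlog_matrix)) stop("k exceeds number of genes",
                                  call. = FALSE)
  if (fuzziness <= 1) stop("fuzziness must be > 1", call. = FALSE)
  x <- t(scale(t(rlog_matrix)))
  x[!is.finite(x)] <- 0
  best <- NULL
  best_obj <- Inf
  for (r in seq_len(restarts)) {
    fit <- with_stream(seed, "fcm", r,
                       expr = fuzzy_cmeans(x, k, m = fuzziness))
    d2 <- t(apply(x, 1, function(row)
      colSums((t(fit$centers) - row)^2)))
    obj <- sum(fit$membership^fuzziness * d2)
    if (obj < best_obj) {
      best <- fit
      best_obj <- obj
    }
  }
  u <- best$membership
  top <- apply(u, 1, which.max)
  top_val <- u[cbind(seq_len(nrow(u)), top)]
  assigned <- ifelse(top_val >= cutoff, top, NA_integer_)
  sizes <- tabulate(assigned[!is.na(assigned)], nbins = k)
  ord <- order(-sizes)
  relabel <- match(seq_len(k), ord)
  assignment <- setNames(
    ifelse(is.na(assigned), NA_character_, sprintf("C%d", relabel[assigned])),
    rownames(rlog_matrix))
  u_ord <- u[, ord, drop = FALSE]
  colnames(u_ord) <- sprintf("C%d", seq_len(k))
  rownames(u_ord) <- rownames(rlog_matrix)
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- sprintf("C%d", seq_len(k))
  structure(list(assignment = assignment, membership = u_ord,
                 centers = centers, cutoff = cutoff),
            class = "interaction_clusters")
}
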