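# Input-normalised metagene profiling: genes x bins matrices over a
# fixed 1 kb upstream flank, a scaled gene body, and a 1 kb downstream
# flank; expression-quintile stratification; k-means deposition-pattern
# clustering with shape-based semantic labels.

N_FLANK_BINS <- 50   # 20 bp bins over the 1 kb flanks
N_BODY_BINS <- 100   # gene_length / 100 bins over the body
FLANK_BP <- 1000

profile_bin_count <- function() 2 * N_FLANK_BINS + N_BODY_BINS

# indices used by the semantic label rule
tss_bin_idx <- function() (N_FLANK_BINS - 12):(N_FLANK_BINS + 12)
body_bin_idx <- function() (N_FLANK_BINS + 21):(N_FLANK_BINS + N_BODY_BINS)

#' Build an input-normalised metagene matrix
#'
#' Each gene's row spans 1 kb upstream of the TSS (50 fixed 20 bp bins),
#' the gene body (100 bins of `gene_length/100` bp), and 1 kb downstream
#' of the TTS (50 bins). Bin values are
#' `log2((chip_count + c) / (control_count + c) * lib_ctrl / lib_chip)`,
#' i.e. a library-scaled density log-ratio with pseudocount `c` added to
#' the per-bin counts (bin width cancels). Minus-strand rows are
#' reversed so the TSS is always on the left. Rows whose flanks leave
#' the chromosome are clipped with a warning (out-of-range bins read 0).
#'
#' @param chip,control `coverage_track`s on the same grid.
#' @param genes `gene_model` data.frame.
#' @param pseudocount count added per bin before the ratio (default 0.5).
#' @return list of class `metaprofile_matrix`: `values` (genes x 200
#'   matrix), `pseudocount`, `bin_grid` description.
#' @export
build_matrix <- function(chip, control, genes, pseudocount = 0.5) {
  check_same_grid(chip, control)
  if (nrow(genes) == 0) stop("no genes to profile", call. = FALSE)
  W <- chip$window_size
  nb <- profile_bin_count()
  vals <- matrix(NA_real_, nrow(genes), nb,
                 dimnames = list(genes$gene_id, NULL))
  lib_ratio <- if (chip$library_size > 0 && control$library_size > 0) {
    control$library_size / chip$library_size
  } else {
    1
  }
  clipped <- FALSE
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    L <- length(chip$counts[[ch]]) * W
    s <- genes$start[i]; e <- genes$end[i]
    breaks <- c(seq(s - FLANK_BP, s, length.out = N_FLANK_BINS + 1),
                seq(s, e, length.out = N_BODY_BINS + 1)[-1],
                seq(e, e + FLANK_BP, length.out = N_FLANK_BINS + 1)[-1])
    if (breaks[1] < 0 || breaks[length(breaks)] > L) clipped <- TRUE
    from <- breaks[-length(breaks)]
    to <- breaks[-1]
    cc <- bin_from_windows(chip$counts[[ch]], W, from, to)
    kk <- bin_from_windows(control$counts[[ch]], W, from, to)
    row <- log2((cc + pseudocount) / (kk + pseudocount) * lib_ratio)
    if (genes$strand[i] == "-") row <- rev(row)
    vals[i, ] <- row
  }
  if (clipped) {
    warning("some gene flanks extend beyond chromosome bounds; clipped",
            call. = FALSE)
  }
  structure(list(values = vals, pseudocount = pseudocount,
                 bin_grid = c(flank_bins = N_FLANK_BINS,
                              body_bins = N_BODY_BINS, flank_bp = FLANK_BP)),
            class = "metaprofile_matrix")
}

#' Average metagene profile over a gene subset
#'
#' @param matrix `metaprofile_matrix`.
#' @param gene_subset character vector of gene ids (default: all rows).
#' @return data.frame: bin, mean, se.
#' @export
average_profile <- function(matrix, gene_subset = NULL) {
  v <- matrix$values
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(v))
    if (length(missing) > 0) {
      stop("unknown gene ids in subset: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    v <- v[gene_subset, , drop = FALSE]
  }
  if (nrow(v) == 0) stop("empty gene subset", call. = FALSE)
  data.frame(bin = seq_len(ncol(v)), mean = colMeans(v),
             se = apply(v, 2, sd) / sqrt(nrow(v)))
}

#' Assign expression quintiles (Q0, Q1..Q5)
#'
#' Expressed genes (replicate-mean FPKM > 0 in the stated condition) are
#' ranked descending (ties broken by gene_id) and split into five rank
#' bins with sizes differing by at most one; when the count is not a
#' multiple of five the earliest bins take the remainder. Q1 is the
#' highest-expressed quintile. Genes with FPKM exactly 0 in all
#' replicates form Q0, optionally sub-grouped into Q0a/Q0b by 2-means on
#' their metagene rows (Q0b is the H2A.Z-depleted subgroup).
#'
#' @param fpkm gene x sample FPKM matrix from [fpkm()].
#' @param samples sample metadata data.frame with `sample_id` and a
#'   grouping column.
#' @param condition value of `group_col` selecting the condition.
#' @param group_col metadata column to match (default "group").
#' @param matrix optional `metaprofile_matrix` for the Q0 sub-grouping.
#' @param seed RNG seed for the 2-means sub-grouping.
#' @return data.frame: gene_id, quintile (`Q0`..`Q5`), subgroup (`Q0a`/
#'   `Q0b` or NA).
#' @export
assign_quintiles <- function(fpkm, samples, condition,
                             group_col = "group", matrix = NULL, seed = 1) {
  cols <- samples$sample_id[samples[[group_col]] == condition]
  if (length(cols) == 0) stop("no samples for condition ", condition,
                              call. = FALSE)
  sub <- fpkm[, cols, drop = FALSE]
  mean_fpkm <- rowMeans(sub)
  expressed <- names(mean_fpkm)[mean_fpkm > 0]
  zero <- names(mean_fpkm)[apply(sub == 0, 1, all)]
  if (length(expressed) < 5) {
    stop("fewer than 5 expressed genes; cannot form quintiles",
         call. = FALSE)
  }
  ord <- expressed[order(-mean_fpkm[expressed], expressed)]
  n <- length(ord)
  sizes <- rep(n %/% 5, 5)
  r <- n %% 5
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  quintile <- rep(sprintf("Q%d", 1:5), times = sizes)
  out <- data.frame(gene_id = c(ord, zero),
                    quintile = c(quintile, rep("Q0", length(zero))),
                    subgroup = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(matrix) && length(zero) >= 2) {
    rows <- intersect(zero, rownames(matrix$values))
    if (length(rows) >= 2) {
      m <- matrix$values[rows, , drop = FALSE]
      km <- with_stream(seed, "q0split",
                        expr = kmeans(m, centers = 2, nstart = 10))
      # Q0a: the sub-group with higher mean signal; Q0b: depleted
      hi <- which.max(rowMeans(km$centers))
      lab <- ifelse(km$cluster == hi, "Q0a", "Q0b")
      out$subgroup[match(rows, out$gene_id)] <- lab
    }
  }
  out
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    dj <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  x[centers, , drop = FALSE]
}

#' Cluster deposition patterns by k-means
#'
#' Euclidean k-means with k-means++ seeding, 25 restarts, best total
#' within-cluster sum of squares kept. Semantic labels are attached by a
#' centroid-shape rule: the centroid with the largest mean absolute
#' value over gene-body bins is `k1` (broad, stress-related); among the
#' rest, the centroid with the largest TSS-peak minus body-mean contrast
#' is `k2` (sharp TSS, housekeeping); the remainder is `k3` (depleted).
#'
#' @param matrix `metaprofile_matrix`.
#' @param k number of clusters (default 3; semantic labels need k = 3).
#' @param seed RNG seed.
#' @param restarts k-means++ restarts (default 25).
#' @return list of class `pattern_clusters`: `cluster` (named vector
#'   gene_id -> `k1`/`k2`/`k3`), `centroids` (k x bins), `labels`
#'   (semantic names), `inertia`.
#' @export
cluster_patterns <- function(matrix, k = 3, seed = 1, restarts = 25) {
  x <- matrix$values
  if (nrow(x) < k) stop("fewer rows than clusters", call. = FALSE)
  if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    stop("degenerate input: all rows identical, single effective cluster",
         call. = FALSE)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_stream(seed, "kmeans", r, expr = {
      centers <- kmeanspp_centers(x, k)
      suppressWarnings(kmeans(x, centers = centers, iter.max = 100))
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  cen <- best$centers
  body <- body_bin_idx()
  tssb <- tss_bin_idx()
  ord <- integer(3)
  if (k == 3) {
    ord[1] <- which.max(rowMeans(abs(cen[, body, drop = FALSE])))
    rest <- setdiff(1:3, ord[1])
    contrast <- apply(cen[rest, tssb, drop = FALSE], 1, max) -
      rowMeans(cen[rest, body, drop = FALSE])
    ord[2] <- rest[which.max(contrast)]
    ord[3] <- setdiff(rest, ord[2])
    labels <- c(k1 = "stress_related", k2 = "housekeeping", k3 = "depleted")
    cluster <- setNames(paste0("k", match(best$cluster, ord)), rownames(x))
    cen <- cen[ord, , drop = FALSE]
    rownames(cen) <- names(labels)
  } else {
    labels <- setNames(sprintf("cluster_%d", seq_len(k)),
                       sprintf("k%d", seq_len(k)))
    cluster <- setNames(sprintf("k%d", best$cluster), rownames(x))
    rownames(cen) <- names(labels)
  }
  structure(list(cluster = cluster, centroids = cen, labels = labels,
                 inertia = best$tot.withinss),
            class = "pattern_clusters")
}

#' Replicate concordance of two coverage tracks
#'
#' Pearson correlation of genome-wide binned, library-scaled counts.
#'
#' @param track_a,track_b `coverage_track`s on the same genome.
#' @param bin bin width in bp (default 1000).
#' @return scalar r, or NA (with a warning) for a zero-variance track.
#' @export
replicate_concordance <- function(track_a, track_b, bin = 1000) {
  check_same_grid(track_a, track_b)
  rebin <- function(track) {
    unlist(lapply(names(track$counts), function(ch) {
      v <- track$counts[[ch]]
      grp <- ceiling(seq_along(v) * track$window_size / bin)
      as.numeric(tapply(v, grp, sum))
    }), use.names = FALSE) / max(track$library_size, 1)
  }
  a <- rebin(track_a)
  b <- rebin(track_b)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance track; concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(a, b)
}
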