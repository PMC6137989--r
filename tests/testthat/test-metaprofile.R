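test_that("log-ratio matrix is zero for identical tracks and ~1 at 2x", {
  g <- make_genes("g1", "chr1", 4000, 7000, "+",
                  chrom_lengths = c(chr1 = 20000))
  tr <- make_track(rep(200, 100), chrom = "chr1")
  m0 <- build_matrix(tr, tr, g)
  expect_true(all(m0$values == 0))
  # chip uniformly 2x the scaled control: pad the control library on a
  # second chromosome so library sizes match
  chip <- coverage_track(list(chr1 = rep(400, 100), chr2 = rep(0, 100)),
                         200, "chip")
  ctrl <- coverage_track(list(chr1 = rep(200, 100), chr2 = rep(200, 100)),
                         200, "ctrl")
  m2 <- build_matrix(chip, ctrl, g)
  expect_true(all(abs(m2$values - 1) < 0.05))
})

test_that("planted TSS-peak genes peak inside the TSS region bins", {
  cfg <- small_config(seed = 9)
  ann <- generate_annotation(cfg)
  chip <- generate_chip_coverage(ann$genes, ann$truth, cfg, "control",
                                 "chip")
  inp <- generate_chip_coverage(ann$genes, ann$truth, cfg, "control",
                                "input")
  mat <- build_matrix(chip, inp, ann$genes)
  k2 <- ann$truth$gene_id[ann$truth$planted_class == "k2_tss"]
  lens <- (ann$genes$end - ann$genes$start)[match(k2, ann$genes$gene_id)]
  hits <- vapply(seq_along(k2), function(i) {
    am <- which.max(mat$values[k2[i], ])
    # convert bin index to bp relative to the TSS
    bp <- if (am <= 50) {
      (am - 50) * 20 - 10
    } else if (am <= 150) {
      (am - 50 - 0.5) * lens[i] / 100
    } else {
      lens[i] + (am - 150) * 20 - 10
    }
    bp >= -250 && bp < 500
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("mirroring the genome leaves profile rows unchanged", {
  L <- 20000
  set.seed(12)
  counts <- rpois(L / 200, 5)
  g_minus <- make_genes("g", "chr1", 6000, 9000, "-",
                        chrom_lengths = c(chr1 = L))
  g_plus <- make_genes("g", "chr1", L - 9000, L - 6000, "+",
                       chrom_lengths = c(chr1 = L))
  tr <- make_track(counts)
  tr_rev <- make_track(rev(counts))
  ctrl <- make_track(rep(5, L / 200))
  row_minus <- build_matrix(tr, ctrl, g_minus)$values[1, ]
  row_plus <- build_matrix(tr_rev, ctrl, g_plus)$values[1, ]
  expect_equal(row_minus, row_plus, tolerance = 1e-12)
})

test_that("average_profile handles identity, symmetry and empty subsets", {
  m <- structure(list(values = rbind(g1 = rep(2, 200), g2 = rep(2, 200)),
                      pseudocount = 0.5, bin_grid = NULL),
                 class = "metaprofile_matrix")
  p <- average_profile(m)
  expect_equal(p$mean, rep(2, 200))
  expect_equal(p$se, rep(0, 200))
  v <- rnorm(200)
  m2 <- structure(list(values = rbind(a = v, b = -v), pseudocount = 0.5,
                       bin_grid = NULL), class = "metaprofile_matrix")
  expect_equal(average_profile(m2)$mean, rep(0, 200))
  expect_error(average_profile(m, character(0)), "empty")
  expect_error(average_profile(m, "nope"), "unknown")
})

test_that("quintile assignment follows rank, remainder and Q0 rules", {
  counts <- matrix(0L, 12, 2, dimnames = list(sprintf("g%02d", 1:12),
                                              c("c_1", "c_2")))
  counts[1:10, ] <- matrix(rep((10:1) * 100L, 2), 10, 2)
  samples <- data.frame(sample_id = c("c_1", "c_2"),
                        group = "control", stringsAsFactors = FALSE)
  fp <- fpkm(counts, setNames(rep(1000, 12), rownames(counts)),
             library_sizes = c(c_1 = 1e6, c_2 = 1e6))
  q <- assign_quintiles(fp, samples, "control")
  expect_equal(sum(q$quintile == "Q0"), 2)
  expect_equal(unname(table(q$quintile)[sprintf("Q%d", 1:5)]),
               rep(2L, 5), ignore_attr = TRUE)
  expect_true(all(q$quintile[q$gene_id %in% c("g01", "g02")] == "Q1"))
  # 11 expressed genes: earliest bin takes the remainder
  counts2 <- rbind(counts[1:10, ], g11 = c(5L, 5L))
  fp2 <- fpkm(counts2, setNames(rep(1000, 11), rownames(counts2)),
              library_sizes = c(c_1 = 1e6, c_2 = 1e6))
  q2 <- assign_quintiles(fp2, samples, "control")
  expect_equal(unname(c(table(q2$quintile)[sprintf("Q%d", 1:5)])),
               c(3L, 2L, 2L, 2L, 2L))
  expect_error(assign_quintiles(fp[9:12, , drop = FALSE], samples,
                                "control"), "fewer than 5")
})

test_that("pattern clustering is invariant to row order and duplication", {
  set.seed(14)
  nb <- 200
  arch <- rbind(c(rep(0, 50), rep(2, 100), rep(0, 50)),
                c(rep(0, 40), rep(3, 25), rep(0, 135)),
                rep(-0.5, nb))
  rows <- arch[rep(1:3, each = 20), ] + matrix(rnorm(60 * nb, 0, 0.2),
                                               60, nb)
  rownames(rows) <- sprintf("g%02d", 1:60)
  mk <- function(v) structure(list(values = v, pseudocount = 0.5,
                                   bin_grid = NULL),
                              class = "metaprofile_matrix")
  cl <- cluster_patterns(mk(rows), seed = 5)
  expect_setequal(unique(cl$cluster), c("k1", "k2", "k3"))
  expect_equal(unname(cl$labels["k1"]), "stress_related")
  # k1 rows really are the broad-body archetype
  expect_true(all(cl$cluster[1:20] == "k1"))
  expect_true(all(cl$cluster[21:40] == "k2"))
  perm <- sample(nrow(rows))
  cl2 <- cluster_patterns(mk(rows[perm, ]), seed = 5)
  expect_equal(cl2$cluster[rownames(rows)], cl$cluster)
  dup <- cluster_patterns(mk(rows[rep(1:60, 2), ]), seed = 5)
  expect_equal(dup$centroids, cl$centroids, tolerance = 1e-6)
  expect_error(cluster_patterns(mk(rows[rep(1, 10), ])), "degenerate")
})

test_that("replicate concordance behaves under identity, scaling and null", {
  set.seed(6)
  a <- make_track(rpois(4000, 3))
  expect_equal(replicate_concordance(a, a), 1)
  a2 <- make_track(2 * a$counts$chr1)
  expect_equal(replicate_concordance(a, a2), 1)
  b <- make_track(rpois(4000, 3))
  r <- replicate_concordance(a, b)
  expect_lt(abs(r), 2 / sqrt(800))
  flat <- make_track(rep(2, 4000))
  expect_warning(rc <- replicate_concordance(flat, a), "zero-variance")
  expect_true(is.na(rc))
})
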