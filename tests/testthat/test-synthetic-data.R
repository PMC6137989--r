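test_that("annotation generation honours layout and capacity rules", {
  cfg <- small_config(seed = 4)
  ann <- generate_annotation(cfg)
  g <- ann$genes
  expect_equal(nrow(g), 50)
  expect_true(all(g$end - g$start >= 1000 & g$end - g$start <= 5000))
  lens <- attr(g, "chrom_lengths")
  expect_true(all(g$start >= 1000 & g$end <= lens[g$chrom] - 1000))
  for (ch in unique(g$chrom)) {
    d <- g[g$chrom == ch, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_equal(ann$truth$gene_id, g$gene_id)
  # infeasible layout is an explicit capacity error
  expect_error(generate_annotation(sim_config(n_chromosomes = 1,
                                              chrom_length = 5e4,
                                              n_genes = 50)),
               "infeasible")
  # empty case
  empty <- generate_annotation(small_config(n_genes = 0))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("planted class counts stay inside the binomial 99% envelope", {
  cfg <- sim_config(n_genes = 300,
                    class_proportions = c(k1_broad = 0.5, k2_tss = 0.33,
                                          k3_depleted = 0.17),
                    seed = 7)
  ann <- generate_annotation(cfg)
  counts <- table(factor(ann$truth$planted_class,
                         levels = names(cfg$class_proportions)))
  for (cls in names(cfg$class_proportions)) {
    bounds <- qbinom(c(0.005, 0.995), 300, cfg$class_proportions[[cls]])
    expect_gte(counts[[cls]], bounds[1])
    expect_lte(counts[[cls]], bounds[2])
  }
})

test_that("same seed gives byte-identical fixture files", {
  cfg <- small_config(seed = 11, n_replicates = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, groups = c(WTC = "control", WTP = "stress"),
                   out_dir = d1)
  simulate_dataset(cfg, groups = c(WTC = "control", WTP = "stress"),
                   out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("coupling rule is respected and 'none' decouples", {
  ann <- generate_annotation(small_config(seed = 2))
  up <- ann$truth[ann$truth$planted_de == "up", ]
  down <- ann$truth[ann$truth$planted_de == "down", ]
  expect_gt(nrow(up), 0)
  expect_true(all(up$planted_h2az_change == "gb_down"))
  expect_true(all(down$planted_h2az_change == "gb_up"))
  expect_true(all(up$planted_class == "k1_broad"))
  dec <- generate_annotation(small_config(seed = 2,
                                          coupling_rule = "none"))
  expect_true(all(dec$truth$planted_h2az_change == "none"))
  expect_gt(sum(dec$truth$planted_de != "null"), 0)
})

test_that("depleted genes and control libraries stay at background", {
  cfg <- small_config(seed = 5)
  ann <- generate_annotation(cfg)
  truth <- make_truth(ann$genes, class = "k3_depleted")
  tr <- generate_chip_coverage(ann$genes, truth, cfg, "control", "chip",
                               return_expected = TRUE)
  mu <- unlist(attr(tr, "expected"))
  expect_true(all(mu <= cfg$background_level + 1e-12))
  inp <- generate_chip_coverage(ann$genes, ann$truth, cfg, "stress",
                                "input", return_expected = TRUE)
  expect_true(all(unlist(attr(inp, "expected")) == cfg$background_level))
  expect_error(generate_chip_coverage(ann$genes, ann$truth, cfg, "frozen"),
               "arg")
})

test_that("no redistribution and no planted changes makes conditions equal", {
  cfg <- small_config(seed = 6, redistribution_effect = 0,
                      coupling_rule = "none")
  ann <- generate_annotation(cfg)
  ctl <- generate_chip_coverage(ann$genes, ann$truth, cfg, "control",
                                "chip", return_expected = TRUE)
  str <- generate_chip_coverage(ann$genes, ann$truth, cfg, "stress",
                                "chip", return_expected = TRUE)
  expect_equal(attr(ctl, "expected"), attr(str, "expected"))
  # observed difference of window means within the Poisson envelope
  mu <- unlist(attr(ctl, "expected"))
  n <- length(mu)
  se_diff <- sqrt(2 * mean(mu) / n)
  obs <- mean(unlist(ctl$counts)) - mean(unlist(str$counts))
  expect_lt(abs(obs), 4 * se_diff)
})

test_that("a single TSS-peak gene puts its expectation peak in the TSS region", {
  genes <- make_genes("g1", "chr1", 10000, 13000, "+",
                      chrom_lengths = c(chr1 = 30000))
  truth <- make_truth(genes, class = "k2_tss")
  cfg <- small_config()
  tr <- generate_chip_coverage(genes, truth, cfg, "control", "chip",
                               return_expected = TRUE)
  mu <- attr(tr, "expected")$chr1
  peak_mid <- (which.max(mu) - 0.5) * 200
  expect_gte(peak_mid, 10000 - 250)
  expect_lt(peak_mid, 10000 + 500)
  # replicate index changes draws, not expectations
  tr2 <- generate_chip_coverage(genes, truth, cfg, "control", "chip",
                                replicate = 2, return_expected = TRUE)
  expect_equal(attr(tr2, "expected"), attr(tr, "expected"))
  expect_false(identical(tr2$counts, tr$counts))
})

test_that("RNA counts honour zeros, baselines and planted fold changes", {
  cfg <- sim_config(seed = 8, n_genes = 300, nb_dispersion = 0.05)
  ann <- generate_annotation(cfg)
  rna <- generate_rna_counts(ann$genes, ann$truth, cfg)
  zeros <- ann$truth$planted_zero
  expect_true(all(rna$counts[zeros, ] == 0))
  expect_gt(diff(range(log10(rna$baseline[!zeros]))), 3.5)
  # pooled stress/control mean ratio of up genes is near 2^lfc
  ctl_cols <- rna$samples$sample_id[rna$samples$condition == "control"]
  str_cols <- rna$samples$sample_id[rna$samples$condition == "stress"]
  up <- ann$truth$planted_de == "up"
  ratio <- sum(rna$counts[up, str_cols]) / sum(rna$counts[up, ctl_cols])
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.7)
  expect_error(generate_rna_counts(ann$genes, ann$truth,
                                   small_config(n_replicates = 1)),
               "n_replicates")
})

test_that("term annotation plants class-enriched terms", {
  cfg <- sim_config(seed = 13, n_genes = 300, term_odds_ratio = 8)
  ann <- generate_annotation(cfg)
  terms <- generate_term_annotation(ann$truth, cfg)
  expect_true(all(c("TERM01", "TERM02") %in% terms$term_id))
  freq <- function(tid, cls) {
    members <- terms$gene_id[terms$term_id == tid]
    in_cls <- ann$truth$gene_id[ann$truth$planted_class == cls]
    c(mean(in_cls %in% members),
      mean(setdiff(ann$truth$gene_id, in_cls) %in% members))
  }
  f1 <- freq("TERM01", "k1_broad")
  expect_gt(f1[1], f1[2])
  # empty term set
  expect_equal(nrow(generate_term_annotation(ann$truth,
                                             small_config(n_terms = 0))), 0)
})

test_that("adding a sample does not perturb another sample's stream", {
  cfg <- small_config(seed = 3)
  ann <- generate_annotation(cfg)
  a1 <- generate_chip_coverage(ann$genes, ann$truth, cfg, "control", "chip")
  invisible(generate_chip_coverage(ann$genes, ann$truth, cfg, "stress",
                                   "chip"))
  a2 <- generate_chip_coverage(ann$genes, ann$truth, cfg, "control", "chip")
  expect_identical(a1$counts, a2$counts)
})
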