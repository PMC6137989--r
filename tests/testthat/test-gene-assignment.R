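test_that("TSS/GB partition matches the quoted arithmetic on both strands", {
  g <- make_genes(c("p", "m"), "chr1", c(1000, 1000), c(3000, 3000),
                  c("+", "-"), chrom_lengths = c(chr1 = 1e5))
  r <- compute_gene_regions(g)
  expect_equal(unlist(r[r$gene_id == "p", c("tss_start", "tss_end")],
                      use.names = FALSE), c(750, 1500))
  expect_equal(unlist(r[r$gene_id == "p", c("gb_start", "gb_end")],
                      use.names = FALSE), c(1500, 3250))
  expect_equal(unlist(r[r$gene_id == "m", c("tss_start", "tss_end")],
                      use.names = FALSE), c(2500, 3250))
  expect_equal(unlist(r[r$gene_id == "m", c("gb_start", "gb_end")],
                      use.names = FALSE), c(750, 2500))
})

test_that("short genes have an empty GB and a TSS region spanning the envelope", {
  g <- make_genes("s", "chr1", 1000, 1400, "+",
                  chrom_lengths = c(chr1 = 1e5))
  r <- compute_gene_regions(g)
  expect_equal(r$gb_start, r$gb_end)
  expect_equal(c(r$tss_start, r$tss_end), c(750, 1650))
  expect_equal(c(r$env_start, r$env_end), c(750, 1650))
})

test_that("partition exactness holds for random genes on both strands", {
  set.seed(31)
  n <- 1000
  start <- runif(n, 2000, 9e5)
  len <- runif(n, 300, 6000)
  g <- make_genes(sprintf("g%04d", 1:n), "chr1", start, start + len,
                  sample(c("+", "-"), n, TRUE),
                  chrom_lengths = c(chr1 = 1e6))
  r <- compute_gene_regions(g)
  # disjoint
  expect_true(all(pmin(r$tss_end, r$gb_end) <= pmax(r$tss_start,
                                                    r$gb_start) |
                    r$gb_start == r$gb_end))
  # union of widths equals envelope width
  expect_equal((r$tss_end - r$tss_start) + (r$gb_end - r$gb_start),
               r$env_end - r$env_start)
  # contiguity: regions tile the envelope
  plus_long <- g$strand == "+" & (g$end - g$start) > 500
  expect_true(all(r$tss_end[plus_long] == r$gb_start[plus_long]))
})

test_that("reflecting the genome mirrors the regions", {
  L <- 50000
  g <- make_genes("g", "chr1", 8000, 11000, "+",
                  chrom_lengths = c(chr1 = L))
  m <- make_genes("g", "chr1", L - 11000, L - 8000, "-",
                  chrom_lengths = c(chr1 = L))
  rg <- compute_gene_regions(g)
  rm_ <- compute_gene_regions(m)
  expect_equal(c(rm_$tss_start, rm_$tss_end), c(L - rg$tss_end,
                                                L - rg$tss_start))
  expect_equal(c(rm_$gb_start, rm_$gb_end), c(L - rg$gb_end,
                                              L - rg$gb_start))
})

test_that("island assignment uses >= 1 bp overlap with the envelope", {
  g <- make_genes("g1", "chr1", 1000, 3000, "+",
                  chrom_lengths = c(chr1 = 1e5))
  islands <- data.frame(chrom = "chr1", start = c(500, 700),
                        end = c(600, 800))
  asg <- assign_islands_to_genes(islands, g)
  expect_equal(asg$g1, 2L)  # [700,800) overlaps envelope [750,3250) by 50bp
  # an island spanning two envelopes assigns to both
  g2 <- make_genes(c("a", "b"), "chr1", c(1000, 4000), c(3000, 6000),
                   c("+", "+"), chrom_lengths = c(chr1 = 1e5))
  wide <- data.frame(chrom = "chr1", start = 2000, end = 4200)
  asg2 <- assign_islands_to_genes(wide, g2)
  expect_setequal(names(asg2), c("a", "b"))
})

test_that("differential classification sets categories by region overlap", {
  g <- make_genes("g1", "chr1", 1000, 3000, "+",
                  chrom_lengths = c(chr1 = 1e5))
  reg <- compute_gene_regions(g)
  # decrease island inside the TSS region only
  d1 <- data.frame(chrom = "chr1", start = 800, end = 1200,
                   direction = "decrease")
  cls <- classify_differential(d1, reg)
  expect_equal(cls$calls$category, "tss_decrease")
  expect_equal(cls$summary$decrease_region_breakdown[["tss"]], 1)
  # island straddling the TSS/GB boundary sets both categories
  d2 <- data.frame(chrom = "chr1", start = 1400, end = 1700,
                   direction = "increase")
  cls2 <- classify_differential(d2, reg)
  expect_setequal(cls2$calls$category, c("tss_increase", "gb_increase"))
  # no differential islands: empty, not NaN
  cls3 <- classify_differential(d1[0, ], reg)
  expect_equal(cls3$summary$n_genes_with_diff, 0L)
  expect_length(cls3$summary$category_fraction, 0)
})

test_that("planted gene-body changes are recovered on synthetic data", {
  cfg <- sim_config(seed = 21)
  ann <- generate_annotation(cfg)
  chipC <- generate_chip_coverage(ann$genes, ann$truth, cfg, "control",
                                  "chip")
  inC <- generate_chip_coverage(ann$genes, ann$truth, cfg, "control",
                                "input")
  chipS <- generate_chip_coverage(ann$genes, ann$truth, cfg, "stress",
                                  "chip")
  inS <- generate_chip_coverage(ann$genes, ann$truth, cfg, "stress",
                                "input")
  uni <- island_union(call_islands(chipC, inC), call_islands(chipS, inS))
  d <- call_differential(chipC, chipS, uni)
  cls <- classify_differential(d, compute_gene_regions(ann$genes))
  gbd <- ann$truth$gene_id[ann$truth$planted_h2az_change == "gb_down"]
  hit <- cls$calls$gene_id[cls$calls$category == "gb_decrease"]
  expect_gte(mean(gbd %in% hit), 0.9)
})
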