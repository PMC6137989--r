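test_that("island params validate their invariants", {
  expect_error(island_params(window = 0), "window")
  expect_error(island_params(gap = 300), "multiple")
  expect_error(island_params(island_fdr = 1.5), "probability")
  expect_silent(island_params(gap = 0))
})

test_that("the toy gap-bridging example produces one island with exact p", {
  # chr1 carries the toy counts; chr2 pads both libraries to 30 over 40
  # windows total, so the library scale is 1 (scaled control rate exactly
  # 1 where control = 1) and the floor 30/40/0.8 = 0.9375 stays below it
  chip <- coverage_track(list(chr1 = c(0, 0, 9, 9, 0, 9, 0, 0, 0, 0),
                              chr2 = c(rep(0, 27), 1, 1, 1)), 200, "chip")
  ctrl <- coverage_track(list(chr1 = rep(1, 10), chr2 = rep(c(1, 0),
                                                            c(20, 10))),
                         200, "ctrl")
  isl <- call_islands(chip, ctrl, island_params())
  isl <- isl[isl$chrom == "chr1", ]
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 400)
  expect_equal(isl$end, 1200)
  expect_equal(isl$chip_count, 27)
  expect_equal(isl$p_value, ppois(26, 4, lower.tail = FALSE))
})

test_that("degenerate inputs behave: no signal, grid mismatch, zero depth", {
  zero <- make_track(rep(0, 20))
  ctrl <- make_track(rep(2, 20))
  expect_error(call_islands(zero, ctrl), "zero-depth")
  expect_equal(nrow(call_islands(ctrl, ctrl,
                                 island_params(window_pvalue_cutoff = 0.9))),
               0)
  other <- make_track(rep(1, 10))
  expect_error(call_islands(ctrl, other), "grid")
})

test_that("caller matches the brute-force oracle on random toy tracks", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    chip_counts <- rpois(n, sample(c(1, 3, 8), 1) *
                           (1 + 3 * (runif(n) < 0.2)))
    ctrl_counts <- rpois(n, 2)
    if (sum(chip_counts) == 0) next
    chip <- make_track(chip_counts)
    ctrl <- make_track(ctrl_counts)
    got <- call_islands(chip, ctrl, island_params(), keep_all = TRUE)
    want <- oracle_islands(chip_counts, ctrl_counts)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
      expect_equal(got$q_value, want$q_value, tolerance = 1e-12)
    }
  }
})

test_that("doubling counts and libraries changes p only through the Poisson", {
  set.seed(55)
  chip_counts <- rpois(30, 4)
  ctrl_counts <- rpois(30, 2)
  got <- call_islands(make_track(2 * chip_counts), make_track(2 * ctrl_counts),
                      island_params(), keep_all = TRUE)
  want <- oracle_islands(2 * chip_counts, 2 * ctrl_counts)
  expect_equal(got$start, want$start)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
})

test_that("raising an island window's chip count never drops it", {
  set.seed(77)
  for (rep in 1:20) {
    chip_counts <- rpois(40, 3 * (1 + 2 * (runif(40) < 0.3)))
    ctrl_counts <- rpois(40, 2)
    if (sum(chip_counts) == 0) next
    chip <- make_track(chip_counts)
    ctrl <- make_track(ctrl_counts)
    isl <- call_islands(chip, ctrl, island_params(), keep_all = TRUE)
    if (nrow(isl) == 0) next
    w <- floor(isl$start[1] / 200) + 1
    boosted <- chip_counts
    boosted[w] <- boosted[w] + 5
    isl2 <- call_islands(make_track(boosted), ctrl, island_params(),
                         keep_all = TRUE)
    covered <- any(isl2$start <= (w - 1) * 200 & isl2$end >= w * 200)
    expect_true(covered)
  }
})

test_that("island_union merges overlapping and touching intervals", {
  a <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(600, 1400))
  b <- data.frame(chrom = c("chr1", "chr2"), start = c(400, 0),
                  end = c(1000, 200))
  u <- island_union(a, b)
  expect_equal(u$start, c(0, 0))
  expect_equal(u$end, c(1400, 200))
  expect_equal(u$chrom, c("chr1", "chr2"))
})

test_that("differential islands: null, exact binomial, and symmetry", {
  set.seed(42)
  counts <- rpois(40, 5)
  a <- make_track(counts, id = "a")
  uni <- data.frame(chrom = "chr1", start = 0, end = 8000)
  none <- call_differential(a, a, uni)
  expect_equal(nrow(none), 0)

  # island over window 1 with a = 10, b = 40; tails pad the library
  # sizes to 110 each so the conditional ratio is exactly 1/2
  a2 <- make_track(c(10, rep(5, 20)), id = "a")
  b2 <- make_track(c(40, rep(3.5, 20)), id = "b")
  expect_equal(a2$library_size, b2$library_size)
  isl <- data.frame(chrom = "chr1", start = 0, end = 200)
  d <- call_differential(a2, b2, isl, keep_all = TRUE)
  expect_equal(d$direction, "increase")
  expect_equal(d$p_value, binom.test(40, 50, 0.5)$p.value, tolerance = 1e-12)

  # swapping a and b flips directions and preserves p
  set.seed(43)
  b3 <- make_track(rpois(40, 8), id = "b")
  uni2 <- data.frame(chrom = "chr1", start = c(0, 2000),
                     end = c(1000, 4000))
  d1 <- call_differential(a, b3, uni2, keep_all = TRUE)
  d2 <- call_differential(b3, a, uni2, keep_all = TRUE)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
  expect_true(all(d1$direction != d2$direction |
                    d1$scaled_a == d1$scaled_b))
  # empty union is an empty result, not an error
  expect_equal(nrow(call_differential(a, b3, uni2[0, ])), 0)
})
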