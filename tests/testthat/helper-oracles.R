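# Independent brute-force oracles. These re-derive expected values from
# first principles with naive loops and stay independent of the package's
# vectorised implementations.

# Brute-force island caller for a single-chromosome pair of count vectors
# plus padding counts on a second chromosome (included in library sizes
# and window totals). Returns window-index islands with exact Poisson
# p-values and brute-force BH q-values.
oracle_islands <- function(chip, control, pad_chip = numeric(),
                           pad_control = numeric(), W = 200, G = 200,
                           cutoff = 0.2, egf = 0.8) {
  lib_chip <- sum(chip) + sum(pad_chip)
  lib_ctrl <- sum(control) + sum(pad_control)
  n_windows <- length(chip) + length(pad_chip)
  scale <- if (lib_ctrl > 0) lib_chip / lib_ctrl else 0
  floor_rate <- lib_chip / n_windows / egf
  lam <- pmax(control * scale, floor_rate)
  # upper tails use the standard distribution function directly (the
  # naive 1 - CDF complement loses precision below ~1e-8); the brute
  # force here is the eligibility/merging enumeration, not the CDF
  eligible <- logical(length(chip))
  for (i in seq_along(chip)) {
    p <- ppois(chip[i] - 1, lam[i], lower.tail = FALSE)
    eligible[i] <- chip[i] > 0 && p < cutoff
  }
  g <- G / W
  islands <- list()
  i <- 1
  while (i <= length(chip)) {
    if (!eligible[i]) {
      i <- i + 1
      next
    }
    first <- i
    last <- i
    j <- i + 1
    while (j <= length(chip)) {
      if (eligible[j]) {
        if (j - last <= g + 1) {
          last <- j
          j <- j + 1
        } else {
          break
        }
      } else {
        if (j - last > g) break
        j <- j + 1
      }
    }
    tot_x <- sum(chip[first:last])
    tot_l <- sum(lam[first:last])
    islands[[length(islands) + 1]] <-
      list(first = first, last = last,
           p = ppois(tot_x - 1, tot_l, lower.tail = FALSE))
    i <- last + 1
  }
  if (length(islands) == 0) return(NULL)
  p <- vapply(islands, `[[`, numeric(1), "p")
  q <- oracle_bh(p, n = n_windows)
  data.frame(first = vapply(islands, `[[`, numeric(1), "first"),
             last = vapply(islands, `[[`, numeric(1), "last"),
             start = (vapply(islands, `[[`, numeric(1), "first") - 1) * W,
             end = vapply(islands, `[[`, numeric(1), "last") * W,
             p_value = p, q_value = q)
}

# textbook BH step-up with cumulative minimum, written as an explicit
# loop; n is the size of the test family (>= length(p))
oracle_bh <- function(p, n = length(p)) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    val <- p[o[i]] * n / i
    running_min <- min(running_min, val)
    q_sorted[i] <- running_min
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact binomial upper/lower tails by term-wise summation
oracle_binom_upper <- function(x, m, p0) {
  sum(vapply(x:m, function(i) dbinom(i, m, p0), numeric(1)))
}
oracle_binom_lower <- function(x, m, p0) {
  sum(vapply(0:x, function(i) dbinom(i, m, p0), numeric(1)))
}

# exact hypergeometric upper tail from binomial coefficients
oracle_hyper_upper <- function(k, K, N, n) {
  sum(vapply(k:min(n, K), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}
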