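# one chromosome of n bins at binsize s, plus observed counts
decay_universe <- function(counts_by_distance, binsize = 1000) {
  # build a universe whose distinct distances are 1..k bins and whose
  # per-distance totals are as given (one pair per distance)
  k <- length(counts_by_distance)
  data.table(distance = seq_len(k) * binsize, count = counts_by_distance)
}

test_that("enumerate_possible_pairs counts the in-window pair universe", {
  bins <- make_bins(c(chr1 = 4000), 1000)  # 4 bins, mids spaced 1000
  u <- enumerate_possible_pairs(bins, 1000, 3000)
  expect_equal(nrow(u), 6)                 # all off-diagonal pairs
  expect_equal(sort(unique(u$distance)), c(1000, 2000, 3000))
  u2 <- enumerate_possible_pairs(bins, 2000, 3000)
  expect_equal(nrow(u2), 3)
  expect_error(enumerate_possible_pairs(bins, 10, 5), "dist_low")
  # two chromosomes never pair together
  bins2 <- make_bins(c(chr1 = 3000, chr2 = 3000), 1000)
  u3 <- enumerate_possible_pairs(bins2, 0, Inf)
  expect_true(all(u3$chrom1 == u3$chrom2))
  expect_equal(nrow(u3), 2 * 3)
})

test_that("naive_pvalue is the uniform-null binomial tail", {
  expect_equal(naive_pvalue(0, 10, 4), 1)
  expect_equal(naive_pvalue(1, 1, 4), 0.25)
  for (k in 0:5) expect_equal(naive_pvalue(k, 20, 7), binom_sf(k, 20, 1 / 7))
})

test_that("equal-occupancy binning follows the greedy oracle", {
  u <- decay_universe(c(5, 3, 2, 2, 2, 1, 1))
  bb <- equal_occupancy_binning(u, b = 2)
  expect_equal(bb$assignment$bin, c(1, 1, 2, 2, 2, 2, 2))  # totals 8 | 8
  expect_equal(bb$boundaries$s, c(1000, 3000))
  expect_equal(bb$boundaries$e, c(3000, Inf))

  one <- equal_occupancy_binning(u, b = 1)
  expect_equal(unique(one$assignment$bin), 1L)

  expect_warning(equal_occupancy_binning(u, b = 100), "reducing b")

  # per-bin totals deviate from N/b by at most the largest
  # single-distance total (random inputs)
  for (s in 1:10) {
    cnt <- withr::with_seed(s, rpois(50, 4))
    if (sum(cnt) == 0) cnt[1] <- 1
    u2 <- decay_universe(cnt)
    b <- 7
    bb2 <- equal_occupancy_binning(u2, b = b)
    tot <- merge(u2, bb2$assignment, by = "distance")[, sum(count), by = bin]$V1
    expect_true(all(abs(tot - sum(cnt) / b) <= max(cnt) + 1e-9))
  }
})

test_that("bin statistics include zero-count pairs and conserve reads", {
  u <- data.table(distance = c(1000, 1000, 2000), count = c(4, 0, 3))
  bb <- equal_occupancy_binning(u, b = 2)
  st <- bin_statistics(u, bb, N = 7)
  expect_equal(st[bin == 1, c], 2)        # mean of {4, 0}
  expect_equal(st[bin == 2, c], 3)
  expect_equal(st[bin == 2, prior], 3 / 7)
  expect_equal(st[bin == 2, d], 2000)
  expect_equal(sum(st$n_pairs * st$c), sum(u$count))  # conservation
  expect_equal(sum(st$n_pairs), nrow(u))
})

test_that("fit_distance_function is monotone, clamped and flat-safe", {
  # all priors equal: constant function everywhere
  f <- fit_distance_function(c(1000, 2000, 3000), rep(0.01, 3))
  expect_equal(f(c(500, 1500, 9000)), rep(0.01, 3))

  # two points: interpolation through them, non-increasing between
  f2 <- fit_distance_function(c(1000, 2000), c(0.01, 0.001))
  expect_equal(f2(1000), 0.01, tolerance = 1e-9)
  expect_equal(f2(2000), 0.001, tolerance = 1e-9)
  grid <- f2(seq(1000, 2000, by = 10))
  expect_true(all(diff(grid) <= 1e-12))
  # constant extrapolation beyond the fitted range
  expect_equal(f2(5000), f2(2000))
  expect_equal(f2(10), f2(1000))

  # a spline through noisy decay is projected non-increasing
  d <- seq(1000, 50000, length.out = 30)
  pr <- 0.05 / d * 1000 + withr::with_seed(2, rnorm(30, 0, 1e-4))
  f3 <- fit_distance_function(d, abs(pr))
  vals <- f3(seq(1000, 60000, by = 100))
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals >= 1e-15 & vals <= 1))

  expect_error(fit_distance_function(c(1, NA), c(0.1, 0.2)), "non-finite")
})

test_that("spline p-values reduce to the naive test under a flat prior", {
  bins <- make_bins(c(chr1 = 20e3), 1e3)
  u <- enumerate_possible_pairs(bins, 2e3, Inf)
  M <- nrow(u)
  u[, count := withr::with_seed(3, rpois(.N, 2))]
  N <- sum(u$count)
  f_flat <- function(d) rep(1 / M, length(d))
  expect_identical(spline_pvalues(u, f_flat, N),
                   naive_pvalue(u$count, N, M))
  u0 <- copy(u)[, count := 0]
  expect_equal(spline_pvalues(u0, f_flat, N), rep(1, M))
})

test_that("run_fithic runs the two-phase pipeline end to end", {
  bins <- make_bins(c(chr1 = 80e4), 1e4)
  m <- simulate_decay(bins, N = 2e4, seed = 5)
  res <- suppressWarnings(run_fithic(m, b = 40))
  expect_true(all(res$chrom1 == res$chrom2))
  expect_true(all(res$distance >= 2 * 1e4))   # default dist_low = 2*binsize
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))

  # refinement disabled reproduces phase 1 exactly
  res0 <- suppressWarnings(run_fithic(m, b = 40, refine_q = 0))
  expect_identical(res0$pvalue, res0$pvalue1)

  # nothing significant in phase 1 -> identical phase-2 prior
  if (!any(res$qvalue1 < 0.05)) {
    expect_identical(attr(res, "phase1")$f(res$distance),
                     attr(res, "phase2")$f(res$distance))
  }

  # trans input is rejected
  mt <- canonicalize(raw_pairs("chr1", 0, "chr2", 0, 3))
  expect_error(run_fithic(mt, dist_low = 0), "trans")
})

test_that("a planted loop is boosted by refinement", {
  bins <- make_bins(c(chr1 = 120e4), 1e4)
  loops <- data.table(chrom = "chr1", start1 = 10e4, start2 = 40e4,
                      fold = 12)
  m <- simulate_decay(bins, N = 5e4, loops = loops, seed = 4)
  res <- suppressWarnings(run_fithic(m, b = 60))
  r <- as.data.table(res)[start1 == 10e4 & start2 == 40e4]
  expect_equal(nrow(r), 1)
  expect_true(r$qvalue < 0.05)
  # phase-2 p-value for the excluded loop never exceeds phase 1
  expect_lte(r$pvalue, r$pvalue1 + 1e-15)
})

test_that("run_fithic is invariant to input record order", {
  bins <- make_bins(c(chr1 = 50e4), 1e4)
  m <- simulate_decay(bins, N = 1e4, seed = 10)
  shuffled <- withr::with_seed(2, m$pairs[sample(.N)])
  m2 <- canonicalize(shuffled, bins = m$bins, binsize = m$resolution)
  r1 <- suppressWarnings(run_fithic(m, b = 30))
  r2 <- suppressWarnings(run_fithic(m2, b = 30))
  expect_equal(as.data.table(r1), as.data.table(r2))
})
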