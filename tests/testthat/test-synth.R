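test_that("make_bins tiles chromosomes and truncates the last bin", {
  b <- make_bins(c(chr1 = 10 * 1000), 1000)
  expect_equal(nrow(b), 10)
  expect_equal(b$end - b$start, rep(1000, 10))

  b2 <- make_bins(c(chr1 = 10500), 1000)
  expect_equal(nrow(b2), 11)
  expect_equal(b2$end[11] - b2$start[11], 500)

  expect_identical(make_bins(c(chr1 = 5000), 1000),
                   make_bins(c(chr1 = 5000), 1000))
})

test_that("gothic-null simulation conserves N and respects weights", {
  bins <- make_bins(c(chr1 = 10e3), 1e3)
  w <- c(0, rep(1, 9))
  m <- simulate_gothic_null(bins, coverage_weights = w, N = 5000, seed = 3)
  expect_equal(m$N, 5000)
  expect_false(any(m$pairs$start1 == 0 | m$pairs$start2 == 0))  # zero-weight bin
  expect_identical(simulate_gothic_null(bins, N = 100, seed = 7)$pairs,
                   simulate_gothic_null(bins, N = 100, seed = 7)$pairs)
  expect_false(identical(simulate_gothic_null(bins, N = 100, seed = 7)$pairs,
                         simulate_gothic_null(bins, N = 100, seed = 8)$pairs))
})

test_that("gothic-null pair frequencies match the target probabilities", {
  bins <- make_bins(c(chr1 = 8e3), 1e3)   # 8 bins -> 28 pairs
  w <- withr::with_seed(1, runif(8, 0.5, 2))
  N <- 1e6
  m <- simulate_gothic_null(bins, coverage_weights = w, N = N, seed = 2)
  b <- as.data.table(bins)
  idx <- CJ(i = 1:8, j = 1:8)[i < j]
  prob <- w[idx$i] * w[idx$j]
  prob <- prob / sum(prob)
  key <- paste(b$start[idx$i], b$start[idx$j])
  obs <- setNames(rep(0, length(key)), key)
  obs[paste(m$pairs$start1, m$pairs$start2)] <- m$pairs$count
  se <- sqrt(N * prob * (1 - prob))
  expect_true(all(abs(obs - N * prob) <= 3.5 * se))
})

test_that("hicnorm simulation hits its Poisson moments", {
  bins <- make_bins(c(chr1 = 60e4), 1e4)
  ft <- feature_table(bins$chrom, bins$start, bins$end,
                      eff_len = rep(1, 60), gc = rep(1, 60),
                      mappability = rep(1, 60))
  m <- simulate_hicnorm(bins, ft, beta0 = 2, beta_len = 0, beta_gc = 0,
                        seed = 4)
  n_pairs <- 60 * 59 / 2
  lambda <- exp(2)
  mean_obs <- m$N / n_pairs
  expect_lt(abs(mean_obs - lambda), 3 * sqrt(lambda / n_pairs))
  expect_identical(simulate_hicnorm(bins, ft, seed = 5)$pairs,
                   simulate_hicnorm(bins, ft, seed = 5)$pairs)
})

test_that("decay simulation plants loops where asked", {
  bins <- make_bins(c(chr1 = 100e4), 1e4)
  loops <- data.table(chrom = "chr1", start1 = 10e4, start2 = 30e4, fold = 5)
  m0 <- simulate_decay(bins, N = 5e4, seed = 6)
  m1 <- simulate_decay(bins, N = 5e4, loops = loops, seed = 6)
  c0 <- m0$pairs[start1 == 10e4 & start2 == 30e4, count]
  c1 <- m1$pairs[start1 == 10e4 & start2 == 30e4, count]
  expect_gt(c1, c0)                     # boosted above the no-loop draw
  expect_equal(m1$N, 5e4)

  # fold 1 leaves the distribution untouched
  l1 <- copy(loops)[, fold := 1]
  expect_identical(simulate_decay(bins, N = 5e4, loops = l1, seed = 6)$pairs,
                   m0$pairs)

  bad <- data.table(chrom = "chr5", start1 = 0, start2 = 1e4, fold = 2)
  expect_error(simulate_decay(bins, loops = bad, seed = 1), "outside")
})

test_that("emitted fixtures round-trip through every reader", {
  m <- remove_diagonal(random_map(5, n_bins = 8, n_reads = 60))
  dir <- withr::local_tempdir()

  fp <- emit_fixture_files(m, "hicpro", dir)
  back <- read_hicpro(fp[1], fp[2])
  expect_equal(back$pairs, m$pairs)

  fh <- emit_fixture_files(m, "homer", dir)
  expect_equal(read_homer(fh, binsize = m$resolution)$pairs, m$pairs)

  fi <- emit_fixture_files(m, "interactions", dir)
  expect_equal(read_interactions(fi, binsize = m$resolution)$pairs, m$pairs)

  fu <- emit_fixture_files(m, "hicup", dir)
  bu <- read_hicup(fu[1], fu[2])
  expect_equal(bu$pairs[, .(chrom1, start1, chrom2, start2, count)],
               m$pairs[, .(chrom1, start1, chrom2, start2, count)])

  # a count-3 pair expands into 3 read-pair id groups
  m3 <- canonicalize(raw_pairs("chr1", 0, "chr1", 1000, 3),
                     bins = data.table(chrom = "chr1", start = c(0, 1000),
                                       end = c(1000, 2000)), binsize = 1000)
  f3 <- emit_fixture_files(m3, "hicup", dir, prefix = "three")
  expect_equal(length(readLines(f3[1])), 6)

  expect_error(emit_fixture_files(m, "cooler", dir), "unknown dialect")

  # empty map -> valid empty files
  e <- canonicalize(data.table(), bins = m$bins, binsize = m$resolution)
  fe <- emit_fixture_files(e, "hicpro", dir, prefix = "empty")
  expect_equal(read_hicpro(fe[1], fe[2])$N, 0)
})
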