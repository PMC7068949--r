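# 3 bins with hand-set covariates on one chromosome
toy_features <- function(eff_len = c(1, 1, 1), gc = c(0.5, 0.5, 0.5),
                         mp = c(1, 1, 1)) {
  feature_table("chr1", c(0, 1000, 2000), c(1000, 2000, 3000),
                eff_len, gc, mp)
}

toy_map <- function(counts = c(2, 4, 6)) {
  canonicalize(raw_pairs("chr1", c(0, 0, 1000), "chr1",
                         c(1000, 2000, 2000), counts),
               bins = data.table(chrom = "chr1", start = c(0, 1000, 2000),
                                 end = c(1000, 2000, 3000)),
               binsize = 1000)
}

test_that("build_design produces log-product covariates and offset", {
  des <- build_design(toy_map(), toy_features(), "chr1")
  expect_equal(des$cov_len, rep(0, 3))   # log(1*1)
  expect_equal(des$off, rep(0, 3))
  expect_equal(des$cov_gc, rep(log(0.25), 3))

  des2 <- build_design(toy_map(), toy_features(eff_len = c(2, 8, 1)), "chr1")
  expect_equal(des2[start1 == 0 & start2 == 1000, cov_len], log(16))
  # symmetric in the endpoints: same covariate whichever bin comes first
  expect_equal(des2[start1 == 0 & start2 == 1000, cov_len],
               log(2 * 8))

  # unusable bins are excluded before fitting
  expect_error(build_design(toy_map(), toy_features(eff_len = c(0, 0, 1)),
                            "chr1"), "fewer than 2 usable")
})

test_that("intercept-only Poisson MLE is the count mean", {
  fit <- fit_poisson(toy_map(c(2, 4, 6)), toy_features(), "chr1")
  expect_equal(unname(fit$pairs$t), rep(4, 3), tolerance = 1e-8)
  expect_equal(fit$pairs$e, c(0.5, 1, 1.5), tolerance = 1e-8)
  norm <- hicnorm_normalize(toy_map(c(2, 4, 6)), fit)
  expect_equal(norm$pairs$count, c(0.5, 1, 1.5), tolerance = 1e-8)
  expect_equal(norm$stage, "normalized")
  expect_error(fit_poisson(toy_map(c(2.5, 4, 6)), toy_features(), "chr1"),
               "integer")
})

test_that("globally rescaling mappability leaves e unchanged", {
  bins <- make_bins(c(chr1 = 40e4), 1e4)
  ft <- make_features(bins, seed = 2)
  m <- simulate_hicnorm(bins, ft, seed = 2)
  fit1 <- fit_poisson(m, ft, "chr1")
  # rescale z downward so it stays inside [0, 1]; offsets shift by
  # log(1/4) and beta0 absorbs it exactly
  ft_half <- feature_table(ft$chrom, ft$start, ft$end, ft$eff_len, ft$gc,
                           ft$mappability / 2)
  fit2 <- fit_poisson(m, ft_half, "chr1")
  expect_equal(fit2$coefficients["beta0"] - fit1$coefficients["beta0"],
               c(beta0 = log(4)), tolerance = 1e-6)
  expect_lt(max(abs(fit2$pairs$e - fit1$pairs$e)), 1e-8)
  expect_lt(max(abs(fit2$pairs$t - fit1$pairs$t)), 1e-6 * max(fit1$pairs$t))
})

test_that("simulated coefficients are recovered", {
  bins <- make_bins(c(chr1 = 200e4), 1e4)
  ft <- make_features(bins, seed = 6)
  m <- simulate_hicnorm(bins, ft, beta0 = -1, beta_len = 0.9, beta_gc = 0.3,
                        seed = 6)
  fit <- fit_poisson(m, ft, "chr1")
  expect_equal(unname(fit$coefficients),
               c(-1, 0.9, 0.3), tolerance = 0.1)
})

test_that("cis fits never mix chromosomes", {
  bins <- make_bins(c(chr1 = 10e4, chr2 = 8e4), 1e4)
  ft <- make_features(bins, seed = 9)
  m <- simulate_hicnorm(bins, ft, beta0 = 1, seed = 9)
  f1 <- fit_poisson(m, ft, "chr1")
  expect_equal(nrow(f1$pairs), 10 * 9 / 2)
  expect_true(all(f1$pairs$chrom1 == "chr1" & f1$pairs$chrom2 == "chr1"))
  f2 <- fit_poisson(m, ft, "chr2")
  expect_equal(nrow(f2$pairs), 8 * 7 / 2)
})

test_that("poisson_tail_pvalue matches brute-force pmf summation", {
  expect_equal(poisson_tail_pvalue(0, 5), 1)
  # oracle: 1 - e^-1 (1 + 1 + 1/2)
  expect_equal(poisson_tail_pvalue(3, 1), 1 - exp(-1) * 2.5, tolerance = 1e-12)
  expect_true(all(diff(poisson_tail_pvalue(0:10, 2)) <= 0))
  expect_error(poisson_tail_pvalue(1, 0), "positive")
})

test_that("run_hicnorm fits per scope and flags the test as an extension", {
  bins <- make_bins(c(chr1 = 30e4, chr2 = 30e4), 1e4)
  ft <- make_features(bins, seed = 12)
  cis <- simulate_hicnorm(bins, ft, beta0 = -1, seed = 12)
  # add a block of trans counts so a trans scope is fitted too
  b <- as.data.table(bins)
  trans <- data.table(chrom1 = "chr1", start1 = b[chrom == "chr1", start],
                      end1 = b[chrom == "chr1", end], chrom2 = "chr2",
                      start2 = b[chrom == "chr2", start],
                      end2 = b[chrom == "chr2", end],
                      count = withr::with_seed(12, rpois(30, 3)))
  m <- canonicalize(rbind(cis$pairs[, -c("mid1", "mid2")], trans),
                    bins = bins, binsize = 1e4)
  res <- run_hicnorm(m, ft)
  expect_equal(attr(res, "model"), "hicnorm+poisson-tail")
  expect_true(any(res$chrom1 != res$chrom2))
  scopes <- sapply(attr(res, "fits"), function(f) scope_label <- paste(f$scope, collapse = ":"))
  expect_true("chr1:chr2" %in% scopes)
  expect_equal(res$e, res$count / res$t)

  # unusable bins are reported, their pairs skipped
  ft_bad <- copy(ft)
  ft_bad[1, `:=`(eff_len = 0, usable = FALSE)]
  expect_warning(res2 <- run_hicnorm(m, ft_bad), "unnormalizable")
  expect_false(any(res2$chrom1 == "chr1" & res2$start1 == ft$start[1]))
})
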