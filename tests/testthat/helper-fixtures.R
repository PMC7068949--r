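library(data.table)

# small raw pair-record table on a fixed 1 kb grid
raw_pairs <- function(chrom1, start1, chrom2, start2, count, binsize = 1000) {
  data.table(chrom1 = chrom1, start1 = start1, end1 = start1 + binsize,
             chrom2 = chrom2, start2 = start2, end2 = start2 + binsize,
             count = count)
}

# random small canonical map for property tests
random_map <- function(seed, n_bins = 12, binsize = 1000, n_reads = 300,
                       n_chroms = 2) {
  withr::with_seed(seed, {
    lens <- setNames(rep(n_bins * binsize, n_chroms),
                     paste0("chr", seq_len(n_chroms)))
    bins <- make_bins(lens, binsize)
    b <- as.data.table(bins)
    i <- sample(nrow(b), n_reads, replace = TRUE)
    j <- sample(nrow(b), n_reads, replace = TRUE)
    raw <- data.table(chrom1 = b$chrom[i], start1 = b$start[i],
                      end1 = b$end[i], chrom2 = b$chrom[j],
                      start2 = b$start[j], end2 = b$end[j], count = 1)
    canonicalize(raw, bins = bins, binsize = binsize)
  })
}

# independent brute-force binomial upper tail: direct log-pmf summation
brute_binom_sf <- function(n, N, p) {
  if (n == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  i <- n:N
  sum(exp(lchoose(N, i) + i * log(p) + (N - i) * log1p(-p)))
}

# independent BH step-up oracle: walk ranks from largest down, taking the
# running minimum of p * m / rank
brute_bh <- function(p, m = length(p)) {
  k <- length(p)
  if (!k) return(numeric(0))
  o <- order(p)
  q_sorted <- numeric(k)
  running <- 1
  for (r in k:1) {
    running <- min(running, p[o[r]] * m / r)
    q_sorted[r] <- running
  }
  q <- numeric(k)
  q[o] <- q_sorted
  q
}
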