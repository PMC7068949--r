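# Synthetic-data generators.
#
# Each generator draws from the corresponding background model's own
# generative assumptions, so model calibration and power can be checked
# against a known truth without downloading real Hi-C data.  Every
# function takes an integer seed and uses one local random stream
# (global RNG state is untouched).

#' Tile chromosomes into fixed-size bins
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param binsize Bin size in bp; the last bin of a chromosome is
#'   truncated at the chromosome end.
#' @return A [fragment_table()] of contiguous half-open bins.
#' @export
make_bins <- function(chrom_lengths, binsize) {
  stopifnot(binsize > 0, all(chrom_lengths >= binsize))
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  rows <- lapply(names(chrom_lengths), function(cc) {
    len <- chrom_lengths[[cc]]
    starts <- seq(0, len - 1, by = binsize)
    data.table(chrom = cc, start = starts, end = pmin(starts + binsize, len))
  })
  b <- rbindlist(rows)
  fragment_table(b$chrom, b$start, b$end)
}

#' Random per-bin covariates for normalization tests
#'
#' Effective length uniform on `[0.2, 1] * binwidth`, GC uniform on
#' `[0.3, 0.6]`, mappability uniform on `[0.5, 1]`: plausible and
#' strictly positive, so every bin is usable.
#'
#' @param bins A bin table.
#' @param seed Integer seed.
#' @return A [feature_table()] aligned with `bins`.
#' @export
make_features <- function(bins, seed = 1L) {
  b <- as.data.table(bins)
  withr::with_seed(seed, {
    w <- b$end - b$start
    feature_table(b$chrom, b$start, b$end,
                  eff_len = runif(nrow(b), 0.2, 1) * w,
                  gc = runif(nrow(b), 0.3, 0.6),
                  mappability = runif(nrow(b), 0.5, 1))
  })
}

#' Simulate reads under the coverage-product null
#'
#' Distributes `N` read pairs over distinct bin pairs `(j, h)`, `j != h`,
#' with probability proportional to `w_j * w_h` (the spurious-ligation
#' null of the coverage model).  The total count equals `N` exactly.
#'
#' @param bins Bin table.
#' @param coverage_weights Non-negative per-bin weights, not all zero;
#'   default 1 (uniform coverage).
#' @param N Total read-pair count.
#' @param seed Integer seed.
#' @return A `contact_map` with `bins` as its universe.
#' @export
simulate_gothic_null <- function(bins, coverage_weights = NULL, N = 1e5,
                                 seed = 1L) {
  b <- as.data.table(bins)
  nb <- nrow(b)
  w <- coverage_weights %||% rep(1, nb)
  stopifnot(length(w) == nb, all(w >= 0), any(w > 0))
  idx <- CJ(i = seq_len(nb), j = seq_len(nb))[i < j]
  prob <- w[idx$i] * w[idx$j]
  counts <- withr::with_seed(seed,
    as.vector(rmultinom(1, size = N, prob = prob)))
  keep <- counts > 0
  raw <- data.table(chrom1 = b$chrom[idx$i][keep], start1 = b$start[idx$i][keep],
                    end1 = b$end[idx$i][keep],
                    chrom2 = b$chrom[idx$j][keep], start2 = b$start[idx$j][keep],
                    end2 = b$end[idx$j][keep], count = counts[keep])
  binsize <- unique(b$end - b$start)
  canonicalize(raw, bins = b,
               binsize = if (length(binsize) == 1L) binsize else NA_real_)
}

#' Simulate counts from the Poisson-normalization model
#'
#' For every intra-chromosomal pair of usable bins, draws an independent
#' `Poisson(t)` count with
#' `t = exp[beta0 + beta_len*log(x_j x_h) + beta_gc*log(y_j y_h) + log(z_j z_h)]`.
#'
#' @param bins Bin table.
#' @param features A [feature_table()] aligned with `bins`.
#' @param beta0,beta_len,beta_gc Model coefficients.
#' @param seed Integer seed.
#' @return A `contact_map` (zero-count pairs omitted from the records
#'   but recoverable from the bin universe).
#' @export
simulate_hicnorm <- function(bins, features, beta0 = -1, beta_len = 0.9,
                             beta_gc = 0.3, seed = 1L) {
  b <- as.data.table(bins)
  f <- as.data.table(features)
  stopifnot(nrow(f) == nrow(b), all(f$usable))
  rows <- lapply(unique(b$chrom), function(cc) {
    fc <- f[chrom == cc]
    n <- nrow(fc)
    if (n < 2) return(NULL)
    idx <- CJ(i = seq_len(n), j = seq_len(n))[i < j]
    t <- exp(beta0 +
               beta_len * log(fc$eff_len[idx$i] * fc$eff_len[idx$j]) +
               beta_gc * log(fc$gc[idx$i] * fc$gc[idx$j]) +
               log(fc$mappability[idx$i] * fc$mappability[idx$j]))
    data.table(chrom1 = cc, start1 = fc$start[idx$i], end1 = fc$end[idx$i],
               chrom2 = cc, start2 = fc$start[idx$j], end2 = fc$end[idx$j],
               t = t)
  })
  raw <- rbindlist(rows)
  raw[, count := withr::with_seed(seed, rpois(.N, t))]
  raw <- raw[count > 0][, t := NULL]
  binsize <- unique(b$end - b$start)
  canonicalize(raw, bins = b,
               binsize = if (length(binsize) == 1L) binsize else NA_real_)
}

#' Simulate distance-decay counts with optional planted loops
#'
#' `N` reads are dropped multinomially over all intra-chromosomal bin
#' pairs with weight `distance^-decay_exponent`, multiplied by `fold`
#' for planted loop pairs.
#'
#' @param bins Bin table.
#' @param N Total read count.
#' @param decay_exponent Positive decay power (default 1).
#' @param loops Optional data.frame with columns `chrom`, `start1`,
#'   `start2`, `fold` (`fold >= 1`) naming pairs whose weight is
#'   multiplied.
#' @param seed Integer seed.
#' @return A `contact_map`.
#' @export
simulate_decay <- function(bins, N = 1e5, decay_exponent = 1, loops = NULL,
                           seed = 1L) {
  stopifnot(decay_exponent > 0)
  b <- as.data.table(bins)
  rows <- lapply(unique(b$chrom), function(cc) {
    bc <- b[chrom == cc]
    n <- nrow(bc)
    if (n < 2) return(NULL)
    idx <- CJ(i = seq_len(n), j = seq_len(n))[i < j]
    d <- abs(bc$mid[idx$j] - bc$mid[idx$i])
    data.table(chrom1 = cc, start1 = bc$start[idx$i], end1 = bc$end[idx$i],
               chrom2 = cc, start2 = bc$start[idx$j], end2 = bc$end[idx$j],
               w = ifelse(d > 0, d^(-decay_exponent), 0))
  })
  u <- rbindlist(rows)
  if (!is.null(loops)) {
    lp <- as.data.table(loops)
    stopifnot(all(lp$fold >= 1))
    key <- paste(u$chrom1, pmin(u$start1, u$start2), pmax(u$start1, u$start2))
    lkey <- paste(lp$chrom, pmin(lp$start1, lp$start2),
                  pmax(lp$start1, lp$start2))
    hit <- match(lkey, key)
    if (anyNA(hit)) {
      stop("simulate_decay: loop pair(s) outside the bin universe: ",
           paste(head(lkey[is.na(hit)], 3), collapse = "; "))
    }
    u$w[hit] <- u$w[hit] * lp$fold
  }
  u[, count := withr::with_seed(seed,
      as.vector(rmultinom(1, size = N, prob = w)))]
  raw <- u[count > 0][, w := NULL]
  binsize <- unique(b$end - b$start)
  canonicalize(raw, bins = b,
               binsize = if (length(binsize) == 1L) binsize else NA_real_)
}

#' Write a map to disk in a named input dialect
#'
#' Emits files that the corresponding reader parses back into an
#' equivalent map, for reader round-trip tests and CLI fixtures.
#'
#' @param map A `contact_map` (integer counts required for the `hicup`
#'   dialect, which expands each count into that many read-pair id
#'   groups).
#' @param dialect One of `"hicup"`, `"hicpro"`, `"homer"`,
#'   `"interactions"`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Character vector of the files written.
#' @export
emit_fixture_files <- function(map, dialect, dir, prefix = "synthetic") {
  stopifnot(is_contact_map(map))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(ext) file.path(dir, paste0(prefix, ext))
  switch(dialect,
    hicpro = {
      write_hicpro(map, fp(".matrix"), fp(".bed"))
      c(fp(".matrix"), fp(".bed"))
    },
    interactions = {
      write_interactions(map, fp(".tsv"))
      fp(".tsv")
    },
    homer = {
      out <- map$pairs[, .(chr1 = chrom1, start1, chr2 = chrom2, start2,
                           count)]
      fwrite(out, fp(".csv"))
      fp(".csv")
    },
    hicup = {
      p <- map$pairs
      if (nrow(p) && any(abs(p$count - round(p$count)) > 1e-9)) {
        stop("emit_fixture_files: hicup dialect requires integer counts")
      }
      reps <- rep(seq_len(nrow(p)), times = if (nrow(p)) p$count else 0)
      ids <- seq_along(reps)
      rd <- rbind(
        data.table(id = ids, flag = 0L, chrom = p$chrom1[reps],
                   pos = p$mid1[reps]),
        data.table(id = ids, flag = 0L, chrom = p$chrom2[reps],
                   pos = p$mid2[reps]))
      setorder(rd, id)
      fwrite(rd, fp(".pairs.txt"), sep = "\t", col.names = FALSE)
      bins <- map$bins
      if (is.null(bins)) stop("emit_fixture_files: hicup dialect needs a bin universe")
      fwrite(as.data.table(bins)[, .(chrom, start, end)], fp(".digest.txt"),
             sep = "\t", col.names = FALSE)
      c(fp(".pairs.txt"), fp(".digest.txt"))
    },
    stop("emit_fixture_files: unknown dialect '", dialect, "'")
  )
}
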