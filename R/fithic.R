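# Distance-decay binomial background model (Fit-Hi-C).
#
# Intra-chromosomal only.  A single observed contact is equally likely to
# come from any of the M possible locus pairs in the mid-range distance
# window (naive null p = 1/M); the refined null replaces p with a spline
# estimate f(d) of the prior contact probability at genomic distance d,
# built from b equal-occupancy distance bins, with one refinement round
# that excludes likely-real contacts before refitting.

#' Enumerate the possible intra-chromosomal pair universe
#'
#' All bin pairs on the same chromosome whose midpoint distance lies in
#' `[dist_low, dist_high]`, including pairs with zero observed count.
#'
#' @param bins Bin table (`chrom`, `start`, `end`, `mid`), e.g.
#'   `map$bins` or a [fragment_table()].
#' @param dist_low,dist_high Inclusive distance window in bp.
#' @return data.table of pairs with their `distance`; `M = nrow()`.
#' @export
enumerate_possible_pairs <- function(bins, dist_low = 0, dist_high = Inf) {
  if (dist_low > dist_high) stop("enumerate_possible_pairs: dist_low > dist_high")
  b <- as.data.table(bins)[, .(chrom = as.character(chrom), start, end, mid)]
  out <- b[, {
    n <- .N
    if (n < 2) NULL else {
      idx <- CJ(i = seq_len(n), j = seq_len(n))[i < j]
      d <- abs(mid[idx$j] - mid[idx$i])
      keep <- d >= dist_low & d <= dist_high
      list(start1 = start[idx$i][keep], end1 = end[idx$i][keep],
           mid1 = mid[idx$i][keep], start2 = start[idx$j][keep],
           end2 = end[idx$j][keep], mid2 = mid[idx$j][keep],
           distance = d[keep])
    }
  }, by = chrom]
  setnames(out, "chrom", "chrom1")
  out[, chrom2 := chrom1]
  setcolorder(out, c("chrom1", "start1", "end1", "mid1",
                     "chrom2", "start2", "end2", "mid2", "distance"))
  out[]
}

#' Naive uniform-null p-value
#'
#' Cumulative binomial tail with the uniform contact probability
#' `p = 1/M` over the `M` possible pairs.
#'
#' @param k Observed contact count(s).
#' @param N Total number of (mid-range) reads.
#' @param M Number of possible locus pairs, `>= 1`.
#' @return `P(K >= k)` for `K ~ Binomial(N, 1/M)`.
#' @export
naive_pvalue <- function(k, N, M) {
  if (any(M < 1)) stop("naive_pvalue: M must be >= 1")
  binom_sf(k, N, 1 / M)
}

#' Equal-occupancy distance binning
#'
#' Sorts locus pairs by genomic distance and greedily accumulates whole
#' distance groups (all pairs at one distance are indivisible) until each
#' bin holds approximately `N/b` total contact count (occupancy
#' `"count"`, the default) or `M/b` pairs (occupancy `"pairs"`).
#'
#' @param universe Pair table with `distance` and `count` columns.
#' @param b Requested number of bins (default 200); reduced with a
#'   warning when there are fewer distinct distances.
#' @param occupancy `"count"` or `"pairs"`.
#' @return List with `assignment` (data.table `distance` -> `bin`) and
#'   `boundaries` (per bin: `s` = smallest distance in the bin, `e` =
#'   smallest distance in the next bin, `Inf` for the last).
#' @export
equal_occupancy_binning <- function(universe, b = 200,
                                    occupancy = c("count", "pairs")) {
  occupancy <- match.arg(occupancy)
  if (b < 1) stop("equal_occupancy_binning: b must be >= 1")
  grp <- as.data.table(universe)[, .(w = if (occupancy == "count")
    sum(count) else .N), by = distance]
  setorder(grp, distance)
  total <- sum(grp$w)
  if (total <= 0) stop("equal_occupancy_binning: no occupancy to distribute")
  if (b > nrow(grp)) {
    warning("reducing b from ", b, " to the ", nrow(grp),
            " distinct distances available")
    b <- nrow(grp)
  }
  # a distance group starting at cumulative occupancy c belongs to bin
  # 1 + floor(c / (total/b)); this keeps every bin's occupancy within one
  # single-distance total of the ideal total/b.  Bins skipped entirely by
  # a very large group are dropped and the rest renumbered.
  target <- total / b
  cum_before <- cumsum(grp$w) - grp$w
  raw <- pmin(b, 1 + floor(cum_before / target))
  grp[, bin := as.integer(factor(raw))]
  bounds <- grp[, .(s = min(distance)), by = bin]
  bounds[, e := c(s[-1], Inf)]
  list(assignment = grp[, .(distance, bin)], boundaries = bounds[])
}

#' Per-bin statistics for the spline fit
#'
#' For each equal-occupancy bin: the mean contact count per locus pair
#' `c_i` (zero-count pairs included), the prior contact probability
#' `c_i / N`, and the mean interaction distance `d_i`.
#'
#' @param universe Pair table with `distance` and `count`.
#' @param binning Result of [equal_occupancy_binning()].
#' @param N Total mid-range read count used for the prior.
#' @return data.table with `bin`, `n_pairs`, `c`, `prior`, `d`, `s`, `e`.
#' @export
bin_statistics <- function(universe, binning, N) {
  u <- as.data.table(universe)
  u <- merge(u, binning$assignment, by = "distance")
  st <- u[, .(n_pairs = .N, c = mean(count), d = mean(distance)), by = bin]
  setorder(st, bin)
  if (nrow(st) < nrow(binning$boundaries)) stop("bin_statistics: empty bin")
  st[, prior := c / N]
  merge(st, binning$boundaries, by = "bin")[]
}

#' Fit the distance-decay prior f(d)
#'
#' A cubic smoothing spline (smoothing parameter by generalized
#' cross-validation) through the points `(d_i, prior_i)`, projected to be
#' non-increasing in distance (a contact prior that grows with distance
#' is non-physical) and clamped to `[1e-15, 1]`.  Beyond the fitted
#' distance range the function is constant at the boundary value.  With
#' fewer than four points the spline degenerates to monotone linear
#' interpolation; a single point gives a constant function.
#'
#' @param d Bin mean distances (ascending).
#' @param prior Bin priors `c_i / N`.
#' @return A function `f(distance) -> probability`.
#' @export
fit_distance_function <- function(d, prior) {
  if (length(d) != length(prior) || !length(d)) {
    stop("fit_distance_function: need matching non-empty d and prior")
  }
  if (any(!is.finite(d)) || any(!is.finite(prior))) {
    stop("fit_distance_function: non-finite points")
  }
  o <- order(d)
  d <- d[o]; prior <- prior[o]
  eps <- 1e-15
  if (length(d) == 1L || length(unique(d)) == 1L) {
    val <- min(max(mean(prior), eps), 1)
    f <- function(x) rep(val, length(x))
    attr(f, "grid") <- data.table(d = d[1], y = val)
    return(f)
  }
  grid_d <- seq(d[1], d[length(d)], length.out = max(512L, length(d)))
  if (length(unique(d)) >= 4L) {
    sp <- smooth.spline(d, prior, cv = FALSE)   # GCV-chosen penalty
    y <- predict(sp, grid_d)$y
  } else {
    y <- approx(d, prior, xout = grid_d, rule = 2)$y
  }
  # non-increasing projection: isotonic regression on the reversed series
  y <- rev(isoreg(seq_along(y), rev(y))$yf)
  y <- pmin(pmax(y, eps), 1)
  f <- function(x) approx(grid_d, y, xout = x, rule = 2)$y
  attr(f, "grid") <- data.table(d = grid_d, y = y)
  f
}

#' Spline-null p-values for a pair universe
#'
#' For each pair with count `k` at distance `d`:
#' `pval = P(K >= k)` under `K ~ Binomial(N, f(d))`.
#'
#' @param universe Pair table with `distance` and `count`.
#' @param f Fitted prior function from [fit_distance_function()].
#' @param N Total mid-range read count.
#' @return Vector of p-values aligned with `universe` rows.
#' @export
spline_pvalues <- function(universe, f, N) {
  u <- as.data.table(universe)
  binom_sf(u$count, N, f(u$distance))
}

# One spline-fitting phase over a (possibly reduced) universe.
fithic_phase <- function(universe, b, N, occupancy) {
  binning <- equal_occupancy_binning(universe, b = b, occupancy = occupancy)
  stats <- bin_statistics(universe, binning, N)
  f <- fit_distance_function(stats$d, stats$prior)
  list(binning = binning, stats = stats, f = f)
}

#' Call significant cis interactions with the distance-decay spline model
#'
#' Full two-phase pipeline: distance-window filter, equal-occupancy
#' binning, per-bin statistics, spline prior, binomial p-values and BH
#' correction; then one refinement round that excludes pairs with
#' phase-1 `q < refine_q` from the binning/statistics, refits the
#' spline, and recomputes p-values for all pairs from the refined prior.
#'
#' @param map A cis-only `contact_map` (trans pairs are an error) with a
#'   bin universe (fixed resolution, or fragments with midpoints).
#' @param b Number of equal-occupancy bins (default 200).
#' @param dist_low Lower distance bound in bp; default `2 * binsize`
#'   (excludes adjacent-bin pairs) when the resolution is known.
#' @param dist_high Upper distance bound in bp (default `Inf`).
#' @param fdr_threshold Final q-value significance cutoff (default 0.05).
#' @param refine_q Phase-1 q-value below which a pair is treated as
#'   likely real and excluded from the refit (default 0.05; 0 disables
#'   refinement).
#' @param occupancy Equal-occupancy criterion, `"count"` (default) or
#'   `"pairs"`.
#' @param include_zero Also report zero-count pairs (p-value 1) in the
#'   result (default `FALSE`: only observed pairs are tested, which sets
#'   the number of BH comparisons).
#' @return An `hic_result` on the tested pairs with `distance`, phase-1
#'   `pvalue1`/`qvalue1`, refined `null_p = f2(d)`, `pvalue`, `qvalue`
#'   and `significant`.  Attributes: `M`, `N_range`, `phase1`, `phase2`
#'   (each with binning, stats and the fitted `f`).
#' @export
run_fithic <- function(map, b = 200, dist_low = NULL, dist_high = Inf,
                       fdr_threshold = 0.05, refine_q = 0.05,
                       occupancy = c("count", "pairs"),
                       include_zero = FALSE) {
  stopifnot(is_contact_map(map))
  occupancy <- match.arg(occupancy)
  if (any(map$pairs$chrom1 != map$pairs$chrom2)) {
    stop("run_fithic: trans pairs present; the model is intra-chromosomal only")
  }
  if (is.null(dist_low)) {
    if (is.na(map$resolution)) {
      stop("run_fithic: dist_low required for fragment-level maps")
    }
    dist_low <- 2 * map$resolution
  }
  bins <- map$bins
  if (is.null(bins)) {
    bins <- unique(rbind(
      map$pairs[, .(chrom = chrom1, start = start1, end = end1, mid = mid1)],
      map$pairs[, .(chrom = chrom2, start = start2, end = end2, mid = mid2)]))
  }
  universe <- enumerate_possible_pairs(bins, dist_low, dist_high)
  M <- nrow(universe)
  if (M == 0) stop("run_fithic: no possible pairs in the distance window")
  cnt <- setNames(map$pairs$count,
                  paste(map$pairs$chrom1, map$pairs$start1, map$pairs$start2))
  universe[, count := cnt[paste(chrom1, start1, start2)]]
  universe[is.na(count), count := 0]
  N <- sum(universe$count)
  if (N <= 0) stop("run_fithic: no reads in the distance window")

  phase1 <- fithic_phase(universe, b, N, occupancy)
  tested_idx <- if (include_zero) seq_len(nrow(universe)) else
    which(universe$count > 0)
  tested <- universe[tested_idx]
  pval1 <- spline_pvalues(tested, phase1$f, N)
  qval1 <- bh_adjust(pval1)

  excl <- tested_idx[qval1 < refine_q]
  if (length(excl) >= nrow(universe)) {
    stop("run_fithic: refinement excluded every pair")
  }
  phase2 <- if (length(excl)) {
    fithic_phase(universe[-excl], b, N, occupancy)
  } else phase1
  pval2 <- spline_pvalues(tested, phase2$f, N)

  res <- significance_result(
    tested[, c(pair_cols), with = FALSE], pval2,
    null_p = phase2$f(tested$distance), model = "fithic", N = N,
    m = nrow(tested), fdr_threshold = fdr_threshold,
    extra = list(distance = tested$distance, pvalue1 = pval1, qvalue1 = qval1))
  setattr(res, "M", M)
  setattr(res, "N_range", N)
  setattr(res, "phase1", phase1)
  setattr(res, "phase2", phase2)
  res
}
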