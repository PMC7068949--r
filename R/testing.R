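# Shared statistical kernels used by the GOTHiC and Fit-Hi-C models.

#' Cumulative binomial upper tail
#'
#' Probability of observing at least `n` successes in `N` Bernoulli trials
#' with success probability `p`, i.e. `P(K >= n)` for `K ~ Binomial(N, p)`.
#' Computed via the numerically stable survival function rather than naive
#' term-by-term summation, so it is usable at sequencing-scale `N`.
#'
#' @param n Observed count(s), `0 <= n <= N`.
#' @param N Number of trials.
#' @param p Success probability in `[0, 1]` (values within `1e-12` outside
#'   the interval are clamped; anything further out is an error).
#' @return `P(K >= n)`, vectorized over the longest argument.
#' @export
binom_sf <- function(n, N, p) {
  tol <- 1e-12
  if (any(p < -tol | p > 1 + tol)) stop("binom_sf: p outside [0, 1]")
  p <- pmin(pmax(p, 0), 1)
  if (any(n < 0) || any(n > N)) stop("binom_sf: need 0 <= n <= N")
  pbinom(n - 1, size = N, prob = p, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Implements the rank formula `q_j = p_j * m / r_j` followed by the
#' standard step-up enforcement of monotonicity (cumulative minimum from
#' the largest rank downward) and clamping to `[0, 1]`.  Ties in `p`
#' receive equal q-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Number of comparisons; defaults to `length(p)` (the number of
#'   tested pairs).  A larger `m` (e.g. all possible locus pairs) may be
#'   supplied for a more conservative correction.
#' @return Vector of q-values aligned with the input order; empty input
#'   yields empty output.
#' @export
bh_adjust <- function(p, m = length(p)) {
  k <- length(p)
  if (k == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_adjust: p outside [0, 1]")
  if (m < k) stop("bh_adjust: m cannot be smaller than length(p)")
  o <- order(p)                      # stable: ties keep input order
  r <- seq_len(k)
  q_sorted <- p[o] * m / r
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(k)
  q[o] <- q_sorted
  q
}

# Assemble the common per-pair significance table shared by all models.
significance_result <- function(pairs, pvalue, null_p, model, N, m,
                                fdr_threshold, extra = NULL) {
  res <- copy(pairs)
  res[, `:=`(null_p = null_p, pvalue = pvalue)]
  res[, rank := frank(pvalue, ties.method = "first")]
  res[, qvalue := bh_adjust(pvalue, m = m)]
  res[, significant := qvalue < fdr_threshold]
  if (!is.null(extra)) for (nm in names(extra)) set(res, j = nm, value = extra[[nm]])
  setattr(res, "class", c("hic_result", class(res)))
  setattr(res, "model", model)
  setattr(res, "N", N)
  setattr(res, "m", m)
  setattr(res, "fdr_threshold", fdr_threshold)
  res[]
}

#' @export
print.hic_result <- function(x, ...) {
  cat(sprintf("hic_result (%s): %d tested pairs, %d significant at q < %g\n",
              attr(x, "model"), nrow(x), sum(x$significant),
              attr(x, "fdr_threshold")))
  NextMethod()
}
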