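# Coverage-product binomial background model (GOTHiC).
#
# Both ends of a read pair are assumed to be affected by bias, so the
# chance that a spurious ligation joins loci j and h is proportional to
# the product of their relative coverages; observed counts are tested
# against the cumulative binomial tail of that null.

#' Relative coverage of every locus in a contact map
#'
#' `reads_j` is the mapped read count incident to bin `j` (a self pair,
#' if still present, contributes both of its ends), and the relative
#' coverage is `reads_j / (2N)`.  On a self-pair-free map the coverages
#' sum to 1.
#'
#' @param map A `contact_map` with `N > 0`.
#' @return A `gothic_model`: list with `coverage` (data.table `chrom`,
#'   `start`, `end`, `mid`, `reads`, `relative_coverage`), `N`, and the
#'   bin universe used.  Bins in the universe with no incident reads get
#'   coverage 0.
#' @export
compute_relative_coverage <- function(map) {
  stopifnot(is_contact_map(map))
  if (map$N <= 0) stop("compute_relative_coverage: map has no reads")
  p <- map$pairs
  ends <- rbind(
    p[, .(chrom = chrom1, start = start1, end = end1, mid = mid1, count)],
    p[, .(chrom = chrom2, start = start2, end = end2, mid = mid2, count)])
  cov <- ends[, .(reads = sum(count)), by = .(chrom, start, end, mid)]
  if (!is.null(map$bins)) {
    cov <- merge(map$bins, cov, by = c("chrom", "start", "end", "mid"),
                 all.x = TRUE)
    cov[is.na(reads), reads := 0]
  }
  lev <- natural_chrom_levels(cov$chrom)
  setorderv(cov[, .cr := chrom_rank(chrom, lev)], c(".cr", "start"))
  cov[, .cr := NULL]
  cov[, relative_coverage := reads / (2 * map$N)]
  structure(list(coverage = cov[], N = map$N), class = "gothic_model")
}

#' Null contact probability for a locus pair under the coverage model
#'
#' `p = 2 * rc_j * rc_h`, clamped to at most 1 (the raw product formula
#' can exceed 1 for very high-coverage pairs).
#'
#' @param rc_j,rc_h Relative coverages in `[0, 1]` (vectorized).
#' @return Null probability per pair.
#' @export
pair_null_probability <- function(rc_j, rc_h) {
  if (any(rc_j < 0 | rc_j > 1 | rc_h < 0 | rc_h > 1)) {
    stop("pair_null_probability: relative coverage outside [0, 1]")
  }
  pmin(1, 2 * rc_j * rc_h)
}

#' Call significant interactions with the coverage-product binomial model
#'
#' Tests every observed pair (cis and trans alike) for an excess of
#' read pairs over the spurious-ligation null: `pval = P(K >= n)` for
#' `K ~ Binomial(N, 2 rc_j rc_h)`, followed by Benjamini-Hochberg
#' correction.
#'
#' @param map A `contact_map`; the diagonal is removed first by default.
#' @param fdr_threshold Significance cutoff on the q-value (default 0.05).
#' @param remove_diag Drop self pairs before testing (default `TRUE`).
#' @param m_mode `"tested"` (default) uses the number of tested pairs as
#'   the number of comparisons; `"possible"` uses the number of possible
#'   bin pairs in the map's bin universe.
#' @return An `hic_result` table with per-pair count, null probability,
#'   p-value, rank, q-value and significance flag.
#' @export
run_gothic <- function(map, fdr_threshold = 0.05, remove_diag = TRUE,
                       m_mode = c("tested", "possible")) {
  stopifnot(is_contact_map(map))
  m_mode <- match.arg(m_mode)
  if (remove_diag) map <- remove_diagonal(map)
  if (map$N <= 0) stop("run_gothic: map has no reads")
  model <- compute_relative_coverage(map)
  cov <- model$coverage
  p <- copy(map$pairs)
  key1 <- paste(p$chrom1, p$start1); key2 <- paste(p$chrom2, p$start2)
  ckey <- paste(cov$chrom, cov$start)
  rc <- setNames(cov$relative_coverage, ckey)
  null_p <- pair_null_probability(rc[key1], rc[key2])
  pval <- binom_sf(p$count, map$N, null_p)
  m <- if (m_mode == "tested") nrow(p) else {
    nb <- if (!is.null(map$bins)) nrow(map$bins) else nrow(cov)
    nb * (nb - 1) / 2
  }
  significance_result(p, pval, null_p, model = "gothic", N = map$N, m = m,
                      fdr_threshold = fdr_threshold)
}
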