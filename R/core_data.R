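#' @import data.table
#' @importFrom stats ppois pbinom rpois setNames approx smooth.spline predict
#'   isoreg rmultinom runif glm poisson coef fitted p.adjust quantile update
#' @importFrom utils head tail modifyList
NULL

# Natural chromosome ordering: "chr2" < "chr10", purely numeric names sort
# numerically, everything else falls back to lexicographic after numbered
# chromosomes.
natural_chrom_levels <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(sub("^(chr|Chr|CHR)?", "", u)))
  ord <- order(is.na(num), num, u)
  u[ord]
}

chrom_rank <- function(chroms, levels = natural_chrom_levels(chroms)) {
  match(as.character(chroms), levels)
}

#' Construct a genomic bin
#'
#' A bin (locus) is a half-open genomic interval `[start, end)` with a
#' deterministic midpoint `mid = floor((start + end) / 2)` used for
#' distance computations.
#'
#' @param chrom Chromosome identifier (character).
#' @param start 0-based inclusive start in bp.
#' @param end Exclusive end in bp; must satisfy `0 <= start < end`.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `mid`.
#' @export
genomic_bin <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(start >= end)) {
    stop("genomic_bin: need 0 <= start < end")
  }
  data.table(chrom = as.character(chrom), start = start, end = end,
             mid = floor((start + end) / 2))
}

#' Build a fragment/bin table
#'
#' @param chrom,start,end Vectors defining the intervals.
#' @param id Optional unique fragment identifiers; defaults to row order.
#' @return A `data.table` (class `fragment_table`) sorted by chromosome
#'   (natural order) then start, with columns `chrom`, `start`, `end`,
#'   `mid`, `id`.  Overlapping fragments on one chromosome are rejected.
#' @export
fragment_table <- function(chrom, start, end, id = NULL) {
  ft <- genomic_bin(chrom, start, end)
  if (is.null(id)) id <- seq_len(nrow(ft))
  if (anyDuplicated(id)) stop("fragment_table: fragment identifiers must be unique")
  ft[, id := id]
  lev <- natural_chrom_levels(ft$chrom)
  setorderv(ft[, `:=`(.cr = chrom_rank(chrom, lev))], c(".cr", "start"))
  ft[, .cr := NULL]
  bad <- ft[, any(head(end, -1) > tail(start, -1)), by = chrom][V1 == TRUE]
  if (nrow(bad)) {
    stop("fragment_table: overlapping fragments on ", paste(bad$chrom, collapse = ", "))
  }
  setattr(ft, "class", c("fragment_table", class(ft)))
  ft[]
}

pair_cols <- c("chrom1", "start1", "end1", "mid1",
               "chrom2", "start2", "end2", "mid2", "count")

empty_pairs <- function() {
  data.table(chrom1 = character(), start1 = numeric(), end1 = numeric(),
             mid1 = numeric(), chrom2 = character(), start2 = numeric(),
             end2 = numeric(), mid2 = numeric(), count = numeric())
}

#' Canonicalize raw locus-pair records into a contact map
#'
#' Orders each record so that `(chrom1, start1) <= (chrom2, start2)` under
#' natural chromosome ordering, aggregates duplicate pairs by summing
#' their counts, and recomputes the total read count `N`.
#'
#' @param records A data.frame with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `count` (ends may be omitted when
#'   `binsize` is given, in which case `end = start + binsize`).
#' @param bins Optional bin/fragment universe (`fragment_table` or a
#'   data.frame with `chrom`, `start`, `end`); kept on the map so models
#'   can enumerate zero-count pairs.
#' @param binsize Fixed resolution in bp, or `NA` for fragment-level maps.
#' @param stage `"raw"` (integer counts) or `"normalized"` (real-valued).
#' @return A `contact_map` object.
#' @export
canonicalize <- function(records, bins = NULL, binsize = NA_real_,
                         stage = c("raw", "normalized")) {
  stage <- match.arg(stage)
  dt <- as.data.table(records)
  if (!nrow(dt)) {
    return(new_contact_map(empty_pairs(), bins, binsize, stage))
  }
  if (!"end1" %in% names(dt)) {
    if (is.na(binsize)) stop("canonicalize: ends absent and no binsize given")
    dt[, `:=`(end1 = start1 + binsize, end2 = start2 + binsize)]
  }
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "count")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("canonicalize: missing columns ", paste(miss, collapse = ", "))
  neg <- which(dt$count < 0)
  if (length(neg)) stop("canonicalize: negative count at record(s) ",
                        paste(head(neg, 5), collapse = ", "))
  dt <- dt[, .(chrom1 = as.character(chrom1), start1 = as.numeric(start1),
               end1 = as.numeric(end1),
               chrom2 = as.character(chrom2), start2 = as.numeric(start2),
               end2 = as.numeric(end2), count = as.numeric(count))]
  lev <- natural_chrom_levels(c(dt$chrom1, dt$chrom2))
  flip <- chrom_rank(dt$chrom1, lev) > chrom_rank(dt$chrom2, lev) |
    (dt$chrom1 == dt$chrom2 & dt$start1 > dt$start2)
  if (any(flip)) {
    dt[flip, c("chrom1", "start1", "end1", "chrom2", "start2", "end2") :=
         .(chrom2, start2, end2, chrom1, start1, end1)]
  }
  dt <- dt[, .(count = sum(count)),
           by = .(chrom1, start1, end1, chrom2, start2, end2)]
  dt[, `:=`(mid1 = floor((start1 + end1) / 2), mid2 = floor((start2 + end2) / 2))]
  dt[, `:=`(.c1 = chrom_rank(chrom1, lev), .c2 = chrom_rank(chrom2, lev))]
  setorderv(dt, c(".c1", "start1", ".c2", "start2"))
  dt[, c(".c1", ".c2") := NULL]
  setcolorder(dt, pair_cols)
  new_contact_map(dt, bins, binsize, stage)
}

new_contact_map <- function(pairs, bins, resolution, stage) {
  if (!is.null(bins)) {
    bins <- as.data.table(bins)[, .(chrom = as.character(chrom),
                                    start = as.numeric(start),
                                    end = as.numeric(end))]
    bins[, mid := floor((start + end) / 2)]
    lev <- natural_chrom_levels(bins$chrom)
    setorderv(bins[, .cr := chrom_rank(chrom, lev)], c(".cr", "start"))
    bins[, .cr := NULL]
  }
  structure(list(pairs = pairs, bins = bins,
                 resolution = as.numeric(resolution),
                 N = sum(pairs$count), stage = stage),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  res <- if (is.na(x$resolution)) "fragment-level" else
    sprintf("%g bp bins", x$resolution)
  cat(sprintf("contact_map: %d pairs, N = %g reads, %s, stage = %s\n",
              nrow(x$pairs), x$N, res, x$stage))
  if (!is.null(x$bins)) cat(sprintf("  bin universe: %d bins on %d chromosome(s)\n",
                                    nrow(x$bins), length(unique(x$bins$chrom))))
  invisible(x)
}

#' @export
is_contact_map <- function(x) inherits(x, "contact_map")

#' Rebin a contact map to a coarser fixed resolution
#'
#' Each locus is assigned to the bin `floor(mid / binsize)`; counts from
#' fragment pairs landing in the same bin pair are aggregated.  The total
#' read count is conserved exactly.
#'
#' @param map A `contact_map` (fragment-level or finer fixed binsize).
#' @param binsize Target bin size in bp (> 0, and coarser than the
#'   current resolution when that is known).
#' @return A `contact_map` at the new resolution; the bin universe, when
#'   present, is retiled accordingly.
#' @export
rebin <- function(map, binsize) {
  stopifnot(is_contact_map(map))
  if (!is.numeric(binsize) || length(binsize) != 1L || binsize <= 0) {
    stop("rebin: binsize must be a positive number")
  }
  if (!is.na(map$resolution) && binsize < map$resolution) {
    stop("rebin: cannot refine a map of resolution ", map$resolution,
         " to finer binsize ", binsize)
  }
  p <- map$pairs
  raw <- if (nrow(p)) {
    data.table(chrom1 = p$chrom1, start1 = floor(p$mid1 / binsize) * binsize,
               chrom2 = p$chrom2, start2 = floor(p$mid2 / binsize) * binsize,
               count = p$count)
  } else NULL
  bins <- NULL
  if (!is.null(map$bins)) {
    bins <- map$bins[, .(last = max(floor(mid / binsize))), by = chrom]
    bins <- bins[, .(start = seq(0, last) * binsize), by = chrom]
    bins[, end := start + binsize]
  }
  if (is.null(raw)) return(new_contact_map(empty_pairs(), bins, binsize, map$stage))
  canonicalize(raw, bins = bins, binsize = binsize, stage = map$stage)
}

#' Remove diagonal (self-pair) interactions
#'
#' @param map A `contact_map`.
#' @return The map without records where both loci are the same bin; `N`
#'   is updated.
#' @export
remove_diagonal <- function(map) {
  stopifnot(is_contact_map(map))
  keep <- !(map$pairs$chrom1 == map$pairs$chrom2 &
              map$pairs$start1 == map$pairs$start2)
  new_contact_map(map$pairs[keep], map$bins, map$resolution, map$stage)
}

#' Split a contact map into cis and trans components
#'
#' @param map A `contact_map`.
#' @return `list(cis = , trans = )`; the two maps partition the records
#'   (and `N`) exactly.
#' @export
split_cis_trans <- function(map) {
  stopifnot(is_contact_map(map))
  cis <- map$pairs$chrom1 == map$pairs$chrom2
  list(cis = new_contact_map(map$pairs[cis], map$bins, map$resolution, map$stage),
       trans = new_contact_map(map$pairs[!cis], map$bins, map$resolution, map$stage))
}

#' Genomic distance between two bins
#'
#' Distance is the absolute difference of bin midpoints; defined only for
#' bins on the same chromosome.
#'
#' @param a,b Bins as returned by [genomic_bin()] (vectorized: equal-length
#'   tables are compared row-wise).
#' @return Distance(s) in bp.
#' @export
pair_distance <- function(a, b) {
  a <- as.data.table(a); b <- as.data.table(b)
  if (any(a$chrom != b$chrom)) {
    stop("pair_distance: bins on different chromosomes have no genomic distance")
  }
  abs(a$mid - b$mid)
}
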