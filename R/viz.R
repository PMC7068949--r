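# Static arc-diagram and heatmap rendering.
#
# Both functions compute their drawable geometry first and return it
# (arc table / matrix) so tests and callers can query exactly what was
# rendered; writing a figure file is optional and driven by the
# out_path extension (.png, .svg or .pdf).

viz_pairs <- function(data) {
  if (is_contact_map(data)) {
    p <- copy(data$pairs)
    p[, significant := NA]
    list(pairs = p, bins = data$bins, resolution = data$resolution)
  } else if (inherits(data, "hic_result")) {
    list(pairs = as.data.table(data), bins = NULL, resolution = NA_real_)
  } else stop("viz: expected a contact_map or hic_result")
}

open_device <- function(out_path, width = 7, height = 5) {
  ext <- tolower(sub(".*\\.", "", out_path))
  switch(ext,
    png = grDevices::png(out_path, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(out_path, width = width, height = height),
    pdf = grDevices::pdf(out_path, width = width, height = height),
    stop("viz: unsupported output extension '", ext, "'"))
}

arc_xy <- function(x1, x2, n = 64) {
  th <- seq(0, pi, length.out = n)
  list(x = (x1 + x2) / 2 + (x2 - x1) / 2 * cos(th), y = sin(th))
}

#' Arc diagram of cis interactions
#'
#' One arc per surviving cis pair between the two bin midpoints; arc
#' line width maps linearly from count (clamped to `[w_min, w_max]`),
#' significant pairs are drawn in a distinct colour, and an optional
#' annotation track is rendered above the axis.  Trans pairs are dropped
#' with a message; pairs below `min_count` are dropped.
#'
#' @param data A `contact_map` or `hic_result`.
#' @param region Optional `list(chrom, start, end)` restricting the plot.
#' @param min_count Read-count threshold (default 0).
#' @param annotations Optional [read_annotations()] track.
#' @param out_path Optional figure path (`.png`, `.svg` or `.pdf`).
#' @param highlight_significant Colour significant pairs (default `TRUE`).
#' @param only_significant Drop non-significant pairs (default `FALSE`).
#' @param col,col_significant Arc colours.
#' @param w_min,w_max Line-width range for the count mapping.
#' @return Invisibly, a `hic_arc_plot` list whose `$arcs` table has one
#'   row per rendered arc (`mid1`, `mid2`, `count`, `lwd`, `col`) and
#'   `$n_dropped_trans` the number of trans pairs removed.
#' @export
arc_plot <- function(data, region = NULL, min_count = 0, annotations = NULL,
                     out_path = NULL, highlight_significant = TRUE,
                     only_significant = FALSE, col = "grey30",
                     col_significant = "firebrick", w_min = 0.5, w_max = 4) {
  v <- viz_pairs(data)
  p <- v$pairs
  cis <- p$chrom1 == p$chrom2
  n_trans <- sum(!cis)
  if (n_trans) message("arc_plot: dropping ", n_trans, " trans pair(s)")
  p <- p[cis]
  if (!is.null(region)) {
    chroms <- unique(c(p$chrom1, if (!is.null(v$bins)) v$bins$chrom))
    if (!region$chrom %in% chroms) {
      stop("arc_plot: chromosome '", region$chrom, "' absent from the data")
    }
    p <- p[chrom1 == region$chrom & mid1 >= region$start & mid2 <= region$end]
  }
  p <- p[count >= min_count]
  if (only_significant) p <- p[significant %in% TRUE]
  if (nrow(p)) {
    rng <- range(p$count)
    lwd <- if (rng[1] == rng[2]) rep((w_min + w_max) / 2, nrow(p)) else
      w_min + (w_max - w_min) * (p$count - rng[1]) / (rng[2] - rng[1])
    colv <- rep(col, nrow(p))
    if (highlight_significant) colv[p$significant %in% TRUE] <- col_significant
    arcs <- p[, .(chrom = chrom1, mid1, mid2, count,
                  significant = significant)][, `:=`(lwd = lwd, col = colv)]
  } else {
    arcs <- data.table(chrom = character(), mid1 = numeric(),
                       mid2 = numeric(), count = numeric(),
                       significant = logical(), lwd = numeric(),
                       col = character())
  }
  obj <- structure(list(arcs = arcs, n_dropped_trans = n_trans,
                        region = region, annotations = annotations),
                   class = "hic_arc_plot")
  if (!is.null(out_path)) {
    open_device(out_path)
    on.exit(grDevices::dev.off())
    plot(obj)
  }
  invisible(obj)
}

#' @export
plot.hic_arc_plot <- function(x, ...) {
  a <- x$arcs
  xlim <- if (!is.null(x$region)) c(x$region$start, x$region$end)
          else if (nrow(a)) range(c(a$mid1, a$mid2)) else c(0, 1)
  graphics::plot(NA, xlim = xlim, ylim = c(0, 1.25), xlab = "position (bp)",
                 ylab = "", yaxt = "n", bty = "n",
                 main = if (nrow(a)) unique(a$chrom)[1] else "")
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      xy <- arc_xy(a$mid1[i], a$mid2[i])
      graphics::lines(xy$x, xy$y, lwd = a$lwd[i], col = a$col[i])
    }
  }
  trk <- x$annotations
  if (!is.null(trk) && nrow(trk)) {
    cols <- c(promoter = "steelblue", enhancer = "gold", other = "grey60")
    graphics::rect(trk$start, 1.1, trk$end, 1.2, col = cols[trk$class],
                   border = NA)
  }
  invisible(x)
}

#' Contact-map heatmap
#'
#' Assembles the symmetric count (or -log10 p-value) matrix over one,
#' several, or all chromosomes; multi-chromosome selections are
#' concatenated with boundary separators.  Cell colour interpolates
#' linearly between `color_low` and `color_high`; pairs below
#' `min_count` are blanked.
#'
#' @param data A `contact_map` or `hic_result`.
#' @param chroms Chromosome selection, or `"all"` (default).
#' @param value `"count"` (default) or `"pvalue"` (requires a result
#'   carrying p-values; plotted as `-log10 p`).
#' @param color_low,color_high Colour ramp endpoints (default yellow to
#'   black).
#' @param min_count Blank cells with a count below this threshold.
#' @param out_path Optional figure path (`.png`, `.svg` or `.pdf`).
#' @return Invisibly, a `hic_heatmap` list: `$matrix` (symmetric, with
#'   bin labels), `$boundaries` (first row index of each chromosome
#'   block) and the colour ramp.
#' @export
heatmap_plot <- function(data, chroms = "all", value = c("count", "pvalue"),
                         color_low = "yellow", color_high = "black",
                         min_count = 0, out_path = NULL) {
  value <- match.arg(value)
  v <- viz_pairs(data)
  p <- v$pairs
  if (value == "pvalue" && !"pvalue" %in% names(p)) {
    stop("heatmap_plot: value = 'pvalue' needs data with computed p-values")
  }
  bins <- v$bins
  if (is.null(bins)) {
    bins <- unique(rbind(
      p[, .(chrom = chrom1, start = start1, end = end1, mid = mid1)],
      p[, .(chrom = chrom2, start = start2, end = end2, mid = mid2)]))
    lev <- natural_chrom_levels(bins$chrom)
    setorderv(bins[, .cr := chrom_rank(chrom, lev)], c(".cr", "start"))
    bins[, .cr := NULL]
  }
  if (!identical(chroms, "all")) {
    missing <- setdiff(chroms, unique(bins$chrom))
    if (length(missing)) stop("heatmap_plot: chromosome(s) absent: ",
                              paste(missing, collapse = ", "))
    bins <- bins[chrom %in% chroms]
    p <- p[chrom1 %in% chroms & chrom2 %in% chroms]
  }
  nb <- nrow(bins)
  key <- paste(bins$chrom, bins$start)
  mat <- matrix(NA_real_, nb, nb,
                dimnames = list(paste0(bins$chrom, ":", bins$start),
                                paste0(bins$chrom, ":", bins$start)))
  p <- p[count >= min_count]
  if (nrow(p)) {
    i <- match(paste(p$chrom1, p$start1), key)
    j <- match(paste(p$chrom2, p$start2), key)
    val <- if (value == "count") p$count else -log10(pmax(p$pvalue, 1e-300))
    mat[cbind(i, j)] <- val
    mat[cbind(j, i)] <- val
  }
  first_rows <- c(1, 1 + cumsum(rle(bins$chrom)$lengths))
  boundaries <- head(first_rows, -1)
  names(boundaries) <- rle(bins$chrom)$values
  obj <- structure(list(matrix = mat, boundaries = boundaries, value = value,
                        color_low = color_low, color_high = color_high),
                   class = "hic_heatmap")
  if (!is.null(out_path)) {
    open_device(out_path, width = 6, height = 6)
    on.exit(grDevices::dev.off())
    plot(obj)
  }
  invisible(obj)
}

#' @export
plot.hic_heatmap <- function(x, n_colors = 100, ...) {
  ramp <- grDevices::colorRampPalette(c(x$color_low, x$color_high))(n_colors)
  m <- x$matrix
  nb <- nrow(m)
  ttl <- if (x$value == "count") "contact counts" else "-log10 p-value"
  if (!nb || !any(is.finite(m))) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "bin",
                   ylab = "bin", axes = FALSE, main = ttl)
    graphics::box()
    return(invisible(x))
  }
  graphics::image(seq_len(nb), seq_len(nb), t(m[nb:1, , drop = FALSE]),
                  col = ramp, xlab = "bin", ylab = "bin", axes = FALSE,
                  main = ttl)
  graphics::box()
  if (length(x$boundaries) > 1) {
    graphics::abline(v = x$boundaries[-1] - 0.5,
                     h = nb - x$boundaries[-1] + 1.5, col = "white")
  }
  invisible(x)
}
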