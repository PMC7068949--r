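# Readers and writers for the supported input dialects.
#
# Coordinates are 0-based half-open throughout; HiC-Pro bed starts are
# taken as 0-based (that tool's convention) and the same convention is
# applied to HiCUP digest tables.  Output files report bin start
# positions.

#' Read a HiCUP-style paired-read file plus restriction digest
#'
#' The pairs file has four whitespace-delimited columns: read-pair id,
#' flag (read and ignored), chromosome, and locus position.  Two rows
#' sharing an id define one interaction of count 1; each locus is
#' snapped to the restriction fragment containing it.
#'
#' @param pairs_path Path to the 4-column read file.
#' @param digest_path Path to the digest table (chromosome, start, end;
#'   a header line is skipped if present).
#' @return A fragment-level `contact_map` whose bin universe is the
#'   digest.  Ids with a number of rows other than two, and positions
#'   not covered by any fragment, are skipped with a warning.
#' @export
read_hicup <- function(pairs_path, digest_path) {
  dg <- fread(digest_path, header = FALSE)
  if (!is.numeric(dg[[2]])) dg <- dg[-1]  # tolerate a header line
  frags <- fragment_table(dg[[1]], as.numeric(dg[[2]]), as.numeric(dg[[3]]))
  rd <- suppressWarnings(tryCatch(fread(pairs_path, header = FALSE),
                                  error = function(e) data.table()))
  if (!nrow(rd)) {
    return(canonicalize(data.table(), bins = frags))
  }
  setnames(rd, seq_len(4), c("id", "flag", "chrom", "pos"))
  cnt <- rd[, .N, by = id]
  bad <- cnt[N != 2]
  if (nrow(bad)) {
    warning(nrow(bad), " read id(s) without exactly two rows were skipped")
    rd <- rd[!id %in% bad$id]
  }
  # snap each locus to its containing digest fragment
  rd[, fid := NA_integer_]
  for (cc in unique(rd$chrom)) {
    fc <- frags[chrom == cc]
    if (!nrow(fc)) next
    ii <- findInterval(rd[chrom == cc, pos], fc$start)
    ok <- ii >= 1L & rd[chrom == cc, pos] < fc$end[pmax(ii, 1L)]
    rd[chrom == cc, fid := ifelse(ok, fc$id[pmax(ii, 1L)], NA_integer_)]
  }
  if (anyNA(rd$fid)) {
    drop_ids <- unique(rd[is.na(fid), id])
    warning(sum(is.na(rd$fid)), " position(s) not covered by any fragment; ",
            length(drop_ids), " read pair(s) skipped")
    rd <- rd[!id %in% drop_ids]
  }
  if (!nrow(rd)) return(canonicalize(data.table(), bins = frags))
  setorder(rd, id, chrom, pos)
  wide <- rd[, .(f1 = fid[1], f2 = fid[2]), by = id]
  fi <- frags[match(wide$f1, frags$id)]
  fj <- frags[match(wide$f2, frags$id)]
  raw <- data.table(chrom1 = fi$chrom, start1 = fi$start, end1 = fi$end,
                    chrom2 = fj$chrom, start2 = fj$start, end2 = fj$end,
                    count = 1)
  canonicalize(raw, bins = frags)
}

#' Read a HiC-Pro sparse matrix plus bed bin definition
#'
#' The matrix file has three tab-separated columns (locus-1 id, locus-2
#' id, interaction count); the bed file has chromosome, start, end and
#' fragment id.  Non-integer counts are accepted (HiC-Pro can emit
#' normalized matrices) and flag the map as `"normalized"`; models that
#' require raw counts validate integrality themselves.
#'
#' @param matrix_path,bed_path File paths.
#' @return A canonical `contact_map` with the bed intervals as its bin
#'   universe; resolution is inferred when all bins share one width.
#' @export
read_hicpro <- function(matrix_path, bed_path) {
  bed <- fread(bed_path, header = FALSE,
               col.names = c("chrom", "start", "end", "id"))
  frags <- fragment_table(bed$chrom, bed$start, bed$end, id = bed$id)
  widths <- unique(frags$end - frags$start)
  res <- if (length(widths) == 1L) widths else NA_real_
  mx <- suppressWarnings(tryCatch(fread(matrix_path, header = FALSE),
                                  error = function(e) data.table()))
  if (!nrow(mx)) return(canonicalize(data.table(), bins = frags, binsize = res))
  setnames(mx, seq_len(3), c("id1", "id2", "count"))
  missing <- setdiff(unique(c(mx$id1, mx$id2)), frags$id)
  if (length(missing)) {
    stop("read_hicpro: matrix id(s) absent from bed: ",
         paste(head(missing, 5), collapse = ", "))
  }
  integral <- all(abs(mx$count - round(mx$count)) < 1e-9)
  fi <- frags[match(mx$id1, frags$id)]
  fj <- frags[match(mx$id2, frags$id)]
  raw <- data.table(chrom1 = fi$chrom, start1 = fi$start, end1 = fi$end,
                    chrom2 = fj$chrom, start2 = fj$start, end2 = fj$end,
                    count = mx$count)
  canonicalize(raw, bins = frags, binsize = res,
               stage = if (integral) "raw" else "normalized")
}

#' Write a contact map in HiC-Pro matrix + bed form
#'
#' @param map A `contact_map`.
#' @param matrix_path,bed_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_hicpro <- function(map, matrix_path, bed_path) {
  stopifnot(is_contact_map(map))
  bins <- map$bins
  if (is.null(bins)) {
    bins <- unique(rbind(
      map$pairs[, .(chrom = chrom1, start = start1, end = end1)],
      map$pairs[, .(chrom = chrom2, start = start2, end = end2)]))
    bins <- fragment_table(bins$chrom, bins$start, bins$end)
  }
  ids <- copy(as.data.table(bins))
  if (!"id" %in% names(ids)) ids[, id := seq_len(.N)]
  fwrite(ids[, .(chrom, start, end, id)], bed_path, sep = "\t",
         col.names = FALSE)
  key <- setNames(ids$id, paste(ids$chrom, ids$start))
  p <- map$pairs
  mx <- data.table(id1 = key[paste(p$chrom1, p$start1)],
                   id2 = key[paste(p$chrom2, p$start2)], count = p$count)
  fwrite(mx, matrix_path, sep = "\t", col.names = FALSE)
  invisible(c(matrix_path, bed_path))
}

#' Read a minimal HOMER-style interaction table
#'
#' Header-driven delimited text (comma or tab) with columns `chr1`,
#' `start1`, `chr2`, `start2`, `count` (case-insensitive; extra columns
#' ignored).  This is a documented minimal dialect, not HOMER's full
#' file ecosystem.
#'
#' @param path File path.
#' @param binsize Bin size in bp; when `NULL` it is inferred from the
#'   spacing of start positions.
#' @return A canonical `contact_map`.
#' @export
read_homer <- function(path, binsize = NULL) {
  dt <- fread(path, header = TRUE)
  want <- c("chr1", "start1", "chr2", "start2", "count")
  idx <- match(want, tolower(names(dt)))
  if (anyNA(idx)) {
    stop("read_homer: missing column(s) ",
         paste(want[is.na(idx)], collapse = ", "),
         "; header found: ", paste(names(dt), collapse = ", "))
  }
  dt <- dt[, idx, with = FALSE]
  setnames(dt, want)
  if (!nrow(dt)) return(canonicalize(data.table(), binsize = binsize %||% NA_real_))
  if (is.null(binsize)) {
    starts <- sort(unique(c(dt$start1, dt$start2)))
    gaps <- diff(starts)
    if (!length(gaps)) stop("read_homer: cannot infer binsize; supply it")
    binsize <- min(gaps[gaps > 0])
  }
  raw <- dt[, .(chrom1 = chr1, start1 = start1, chrom2 = chr2,
                start2 = start2, count = count)]
  canonicalize(raw, binsize = binsize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a per-bin feature table for normalization
#'
#' Delimited text with columns chromosome, start, end, effective length,
#' GC fraction, mappability fraction (header optional).
#'
#' @param path File path.
#' @param bins Optional bin table (e.g. `map$bins`); when given, every
#'   bin must have a feature row (error otherwise) and rows are aligned
#'   to it.
#' @return A [feature_table()].
#' @export
read_features <- function(path, bins = NULL) {
  dt <- fread(path, header = "auto")
  if (ncol(dt) < 6) stop("read_features: expected 6 columns, found ", ncol(dt))
  setnames(dt, seq_len(6),
           c("chrom", "start", "end", "eff_len", "gc", "mappability"))
  ft <- feature_table(dt$chrom, dt$start, dt$end, dt$eff_len, dt$gc,
                      dt$mappability)
  if (!is.null(bins)) {
    b <- as.data.table(bins)
    key <- paste(ft$chrom, ft$start)
    missing <- !(paste(b$chrom, b$start) %in% key)
    if (any(missing)) {
      stop("read_features: no feature row for bin(s) ",
           paste(head(paste0(b$chrom[missing], ":", b$start[missing]), 5),
                 collapse = ", "))
    }
    ft <- ft[match(paste(b$chrom, b$start), key)]
  }
  ft
}

#' Read a BED3+ annotation track
#'
#' Accepts chrom, start, end and optionally name, score, strand.
#' Malformed lines are skipped with a warning naming the line number.
#' Interval class (promoter / enhancer / other) is inferred from the
#' name field for plotting.
#'
#' @param bed_path File path.
#' @return An `annotation_track` data.table (`chrom`, `start`, `end`,
#'   `label`, `strand`, `class`).
#' @export
read_annotations <- function(bed_path) {
  lines <- readLines(bed_path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    fx <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    st <- suppressWarnings(as.numeric(fx[2]))
    en <- suppressWarnings(as.numeric(fx[3]))
    if (length(fx) < 3 || is.na(st) || is.na(en) || st >= en) {
      warning("read_annotations: skipping malformed line ", i)
      next
    }
    j <- j + 1L
    rows[[j]] <- data.table(
      chrom = fx[1], start = st, end = en,
      label = if (length(fx) >= 4 && fx[4] != ".") fx[4] else NA_character_,
      strand = if (length(fx) >= 6 && fx[6] %in% c("+", "-")) fx[6]
               else NA_character_)
  }
  trk <- if (j) rbindlist(rows[seq_len(j)]) else
    data.table(chrom = character(), start = numeric(), end = numeric(),
               label = character(), strand = character())
  trk[, class := fifelse(grepl("promoter", label, ignore.case = TRUE), "promoter",
                 fifelse(grepl("enhancer", label, ignore.case = TRUE), "enhancer",
                         "other"))]
  trk[is.na(label), class := "other"]
  setattr(trk, "class", c("annotation_track", class(trk)))
  trk[]
}

#' Write interactions to the tab-separated exchange format
#'
#' A raw `contact_map` yields the five-column layout `chr1`, `locus1`,
#' `chr2`, `locus2`, `readCount` (locus = bin start); a significance
#' result appends `pvalue`, `qvalue` and `significant`.  Rows are in
#' canonical pair order.
#'
#' @param x A `contact_map` or `hic_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interactions <- function(x, path) {
  if (is_contact_map(x)) {
    out <- x$pairs[, .(chr1 = chrom1, locus1 = start1, chr2 = chrom2,
                       locus2 = start2, readCount = count)]
  } else if (inherits(x, "hic_result")) {
    out <- as.data.table(x)[, .(chr1 = chrom1, locus1 = start1,
                                chr2 = chrom2, locus2 = start2,
                                readCount = count, pvalue, qvalue,
                                significant)]
  } else stop("write_interactions: expected a contact_map or hic_result")
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an interaction file written by [write_interactions()]
#'
#' @param path File path.
#' @param binsize Bin size used to reconstruct interval ends; inferred
#'   from locus spacing when `NULL`.
#' @return A `contact_map`; p/q-value columns, when present, are
#'   attached as attribute `"stats"`.
#' @export
read_interactions <- function(path, binsize = NULL) {
  dt <- fread(path, header = TRUE)
  req <- c("chr1", "locus1", "chr2", "locus2", "readCount")
  if (!all(req %in% names(dt))) {
    stop("read_interactions: missing column(s) ",
         paste(setdiff(req, names(dt)), collapse = ", "))
  }
  if (!nrow(dt)) return(canonicalize(data.table(), binsize = binsize %||% NA_real_))
  if (is.null(binsize)) {
    starts <- sort(unique(c(dt$locus1, dt$locus2)))
    gaps <- diff(starts)
    binsize <- if (length(gaps) && any(gaps > 0)) min(gaps[gaps > 0]) else 1
  }
  raw <- dt[, .(chrom1 = chr1, start1 = locus1, chrom2 = chr2,
                start2 = locus2, count = readCount)]
  map <- canonicalize(raw, binsize = binsize)
  if ("pvalue" %in% names(dt)) {
    setattr(map, "stats", dt[, .(chr1, locus1, chr2, locus2, pvalue, qvalue,
                                 significant)])
  }
  map
}
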