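# Poisson-regression normalization (HiCNorm).
#
# Per chromosome (cis) or per chromosome pair (trans), observed counts u
# are regressed on log effective-length and log GC-content products with
# the log mappability product as a fixed offset:
#   t = exp[beta0 + beta_len*log(x_j x_h) + beta_gc*log(y_j y_h) + log(z_j z_h)]
# and the normalized map is e = u / t.  "lg" is taken as the natural log,
# which makes the offset coefficient exactly 1.

#' Per-bin covariate table for normalization
#'
#' @param chrom,start,end Bin intervals (must align 1:1 with the map's
#'   bins when used for fitting).
#' @param eff_len Effective length `x` in bp, `>= 0`.
#' @param gc GC-content fraction `y` in `[0, 1]`.
#' @param mappability Mappability fraction `z` in `[0, 1]`.
#' @return A `feature_table` data.table.  Bins with any feature equal to
#'   0 are retained but are unusable for fitting (log domain) and are
#'   excluded by the model functions.
#' @export
feature_table <- function(chrom, start, end, eff_len, gc, mappability) {
  if (any(eff_len < 0)) stop("feature_table: effective length must be >= 0")
  if (any(gc < 0 | gc > 1)) stop("feature_table: gc outside [0, 1]")
  if (any(mappability < 0 | mappability > 1)) {
    stop("feature_table: mappability outside [0, 1]")
  }
  ft <- data.table(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), eff_len = as.numeric(eff_len),
                   gc = as.numeric(gc), mappability = as.numeric(mappability))
  if (anyDuplicated(ft[, .(chrom, start)])) {
    stop("feature_table: duplicate bin rows")
  }
  ft[, usable := eff_len > 0 & gc > 0 & mappability > 0]
  setattr(ft, "class", c("feature_table", class(ft)))
  ft[]
}

scope_label <- function(scope) paste(scope, collapse = ":")

# Pair universe + covariates for one fitting scope.  scope is one
# chromosome name (cis) or two (trans).  Zero-count pairs carry
# likelihood information and are included by default.
#' Per-pair design (covariates and offset) for one fitting scope
#'
#' @param map A `contact_map`.
#' @param features A [feature_table()] covering the map's bins.
#' @param scope One chromosome identifier (cis fit) or two (trans fit).
#' @param include_zero Include zero-count pairs of usable bins
#'   (default `TRUE`).
#' @return data.table with pair coordinates, observed count `u`,
#'   `cov_len = log(x_j x_h)`, `cov_gc = log(y_j y_h)` and
#'   `off = log(z_j z_h)`.
#' @export
build_design <- function(map, features, scope, include_zero = TRUE) {
  stopifnot(is_contact_map(map), inherits(features, "feature_table"))
  scope <- as.character(scope)
  if (!length(scope) %in% 1:2) stop("build_design: scope must be 1 or 2 chromosomes")
  cis <- length(scope) == 1L || scope[1] == scope[2]
  if (!cis) scope <- natural_chrom_levels(scope)  # canonical pair order
  f1 <- features[chrom == scope[1]][order(start)]
  f2 <- if (cis) f1 else features[chrom == scope[length(scope)]][order(start)]
  if (!nrow(f1) || !nrow(f2)) stop("build_design: no feature rows for scope ",
                                   scope_label(scope))
  u1 <- f1[usable == TRUE]; u2 <- f2[usable == TRUE]
  if (cis) {
    if (nrow(u1) < 2) stop("build_design: fewer than 2 usable bins on ", scope[1])
    idx <- CJ(i = seq_len(nrow(u1)), j = seq_len(nrow(u1)))[i < j]
    des <- data.table(chrom1 = scope[1], start1 = u1$start[idx$i],
                      chrom2 = scope[1], start2 = u1$start[idx$j])
    xi <- u1[idx$i]; xj <- u1[idx$j]
  } else {
    idx <- CJ(i = seq_len(nrow(u1)), j = seq_len(nrow(u2)))
    des <- data.table(chrom1 = scope[1], start1 = u1$start[idx$i],
                      chrom2 = scope[2], start2 = u2$start[idx$j])
    xi <- u1[idx$i]; xj <- u2[idx$j]
  }
  des[, `:=`(cov_len = log(xi$eff_len * xj$eff_len),
             cov_gc = log(xi$gc * xj$gc),
             off = log(xi$mappability * xj$mappability))]
  p <- if (cis) {
    map$pairs[chrom1 == scope[1] & chrom2 == scope[1] & start1 != start2]
  } else {
    map$pairs[chrom1 == scope[1] & chrom2 == scope[2]]
  }
  uvals <- setNames(p$count, paste(p$chrom1, p$start1, p$chrom2, p$start2))
  des[, u := uvals[paste(chrom1, start1, chrom2, start2)]]
  des[is.na(u), u := 0]
  if (!include_zero) des <- des[u > 0]
  des[]
}

#' Fit the Poisson normalization model on one scope
#'
#' Maximum-likelihood Poisson regression of counts on the two covariates
#' with the mappability offset entering with fixed coefficient 1,
#' performed separately per chromosome (cis) or chromosome pair (trans).
#'
#' @inheritParams build_design
#' @return A `hicnorm_fit`: scope, coefficients (`beta0`, `beta_len`,
#'   `beta_gc`), and the per-pair table with fitted expected counts `t`
#'   and normalized values `e = u / t`.
#' @export
fit_poisson <- function(map, features, scope, include_zero = TRUE) {
  des <- build_design(map, features, scope, include_zero = include_zero)
  if (nrow(des) < 3) stop("fit_poisson: fewer pairs (", nrow(des),
                          ") than parameters on scope ", scope_label(scope))
  if (any(abs(des$u - round(des$u)) > 1e-8)) {
    stop("fit_poisson: counts must be integers for the Poisson model")
  }
  # drop degenerate covariates (constant columns) to keep the fit ranked
  form <- u ~ cov_len + cov_gc
  if (length(unique(des$cov_len)) == 1L) form <- update(form, . ~ . - cov_len)
  if (length(unique(des$cov_gc)) == 1L) form <- update(form, . ~ . - cov_gc)
  fit <- glm(form, family = poisson(), data = des, offset = des$off)
  if (!fit$converged) stop("fit_poisson: IRLS did not converge after ",
                           fit$iter, " iterations on scope ", scope_label(scope))
  cf <- coef(fit)
  beta <- c(beta0 = unname(cf["(Intercept)"]),
            beta_len = if ("cov_len" %in% names(cf)) unname(cf["cov_len"]) else 0,
            beta_gc = if ("cov_gc" %in% names(cf)) unname(cf["cov_gc"]) else 0)
  des[, t := exp(beta[1] + beta[2] * cov_len + beta[3] * cov_gc + off)]
  des[, e := ifelse(u == 0, 0, u / t)]
  structure(list(scope = scope, coefficients = beta, pairs = des[],
                 include_zero = include_zero), class = "hicnorm_fit")
}

#' @export
print.hicnorm_fit <- function(x, ...) {
  cat(sprintf("hicnorm_fit [%s]: beta0 = %.4f, beta_len = %.4f, beta_gc = %.4f (%d pairs)\n",
              scope_label(x$scope), x$coefficients[1], x$coefficients[2],
              x$coefficients[3], nrow(x$pairs)))
  invisible(x)
}

#' Normalize a contact map with a fitted model
#'
#' Applies `e = u / t` to every pair of the map covered by the fit's
#' scope; zero-count pairs map to 0.
#'
#' @param map A `contact_map`.
#' @param fit A `hicnorm_fit` (or list of them covering the map).
#' @return A real-valued `contact_map` (stage `"normalized"`) over the
#'   fitted pairs with a positive observed count.
#' @export
hicnorm_normalize <- function(map, fit) {
  fits <- if (inherits(fit, "hicnorm_fit")) list(fit) else fit
  tv <- rbindlist(lapply(fits, function(f)
    f$pairs[, .(chrom1, start1, chrom2, start2, t)]))
  p <- copy(map$pairs)
  key <- paste(p$chrom1, p$start1, p$chrom2, p$start2)
  tm <- setNames(tv$t, paste(tv$chrom1, tv$start1, tv$chrom2, tv$start2))
  t <- tm[key]
  if (anyNA(t)) {
    miss <- p[is.na(t)][1]
    stop("hicnorm_normalize: no fitted t for pair ", miss$chrom1, ":",
         miss$start1, " x ", miss$chrom2, ":", miss$start2)
  }
  p[, count := ifelse(count == 0, 0, count / t)]
  canonicalize(p, bins = map$bins, binsize = map$resolution,
               stage = "normalized")
}

#' Poisson upper-tail p-value
#'
#' `P(U >= u)` for `U ~ Poisson(t)`.  This is the package's documented
#' extension for deriving a significance call from the HiCNorm fit (the
#' normalization model itself defines no test); results that use it are
#' flagged as such in the output metadata.
#'
#' @param u Observed count(s) `>= 0`.
#' @param t Fitted expected count(s) `> 0`.
#' @return Upper-tail probability, vectorized.
#' @export
poisson_tail_pvalue <- function(u, t) {
  if (any(t <= 0)) stop("poisson_tail_pvalue: t must be positive")
  if (any(u < 0)) stop("poisson_tail_pvalue: u must be >= 0")
  ppois(u - 1, lambda = t, lower.tail = FALSE)
}

#' Call interactions from the Poisson-normalization model
#'
#' Fits the normalization per chromosome (cis pairs) and per chromosome
#' pair (trans pairs), then scores every observed pair by the Poisson
#' upper tail against its fitted expectation, with Benjamini-Hochberg
#' correction.  Pairs involving unusable bins (any covariate zero) are
#' reported as unnormalizable and skipped with a warning.
#'
#' @param map A `contact_map` (diagonal removed first by default).
#' @param features A [feature_table()] aligned with the map's bins.
#' @param fdr_threshold Q-value significance cutoff (default 0.05).
#' @param remove_diag Drop self pairs before fitting (default `TRUE`).
#' @param include_zero Include zero-count pairs in the fits (default
#'   `TRUE`).
#' @param cis_only Skip trans scopes (default `FALSE`).
#' @return An `hic_result` with fitted `t` and normalized `e` per pair;
#'   attribute `model` is `"hicnorm+poisson-tail"` to mark the test as an
#'   extension of the normalization model.  Attribute `fits` holds the
#'   per-scope `hicnorm_fit` objects.
#' @export
run_hicnorm <- function(map, features, fdr_threshold = 0.05,
                        remove_diag = TRUE, include_zero = TRUE,
                        cis_only = FALSE) {
  stopifnot(is_contact_map(map), inherits(features, "feature_table"))
  if (remove_diag) map <- remove_diagonal(map)
  p <- map$pairs
  if (!nrow(p)) stop("run_hicnorm: empty map")
  fkey <- paste(features$chrom, features$start)
  us <- setNames(features$usable, fkey)
  ok <- us[paste(p$chrom1, p$start1)] & us[paste(p$chrom2, p$start2)]
  if (anyNA(ok)) stop("run_hicnorm: map bin missing from the feature table")
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) on unusable bins are unnormalizable and skipped")
  }
  scopes <- unique(p[ok, .(chrom1, chrom2)])
  if (cis_only) scopes <- scopes[chrom1 == chrom2]
  fits <- lapply(seq_len(nrow(scopes)), function(i) {
    sc <- unique(c(scopes$chrom1[i], scopes$chrom2[i]))
    fit_poisson(map, features, sc, include_zero = include_zero)
  })
  tv <- rbindlist(lapply(fits, function(f)
    f$pairs[, .(chrom1, start1, chrom2, start2, t)]))
  tested <- p[ok]
  if (cis_only) tested <- tested[chrom1 == chrom2]
  tm <- setNames(tv$t, paste(tv$chrom1, tv$start1, tv$chrom2, tv$start2))
  t <- unname(tm[paste(tested$chrom1, tested$start1, tested$chrom2, tested$start2)])
  pval <- poisson_tail_pvalue(tested$count, t)
  res <- significance_result(tested, pval, null_p = t / map$N,
                             model = "hicnorm+poisson-tail", N = map$N,
                             m = nrow(tested), fdr_threshold = fdr_threshold,
                             extra = list(t = t, e = tested$count / t))
  setattr(res, "fits", fits)
  res
}
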