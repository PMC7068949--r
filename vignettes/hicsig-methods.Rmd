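---
title: "Background models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicsig)
```

## The problem

A Hi-C experiment yields a contact map: read-pair counts between all
pairs of genomic loci (restriction fragments, or fixed-size bins after
aggregation). Counts are confounded by locus-level biases — fragment
effective length, GC content, mappability — and, within a chromosome,
by the strong monotone decay of contact frequency with genomic
distance. "Significant interaction" therefore only has meaning relative
to a background model, and different models answer different questions.
`hicsig` implements three, sharing one data model and one statistical
kernel (exact binomial tail + Benjamini–Hochberg).

## Data model and preprocessing

A `contact_map` is a canonical sparse table of locus-pair counts: each
record is ordered so `(chrom1, start1) <= (chrom2, start2)` under a
natural chromosome sort (chr2 before chr10), duplicates are aggregated,
and the total read count `N` is the sum of counts. Coordinates are
0-based half-open; HiC-Pro bed starts are taken as 0-based (that tool's
convention) and HiCUP digest tables are read the same way. Distances
are between bin midpoints, `mid = floor((start + end)/2)` — the floor
(rather than rounding) is an arbitrary but documented tie-break; it
affects nothing downstream because both endpoints use the same rule.

Preprocessing steps are explicit and composable: `rebin()` reassigns
each locus to `floor(mid/binsize)` and conserves `N` exactly;
`remove_diagonal()` drops self-pairs; `split_cis_trans()` partitions
records. Counts are integers pre-normalization and reals afterwards;
one type with a `stage` flag rather than two parallel classes.

## Coverage-product binomial model

The relative coverage of locus *j* is `rc_j = reads_j/(2N)`; on a
self-pair-free map the coverages sum to 1 because every read pair
contributes two endpoint reads. The null probability that a random
spurious ligation joins *j* and *h* is `p = 2·rc_j·rc_h`, clamped to 1
(the raw product can exceed 1 for extreme coverage; a probability
must not). The p-value is the exact binomial survival function
`P(K >= n)` at `N` trials, computed by the numerically stable
`pbinom(..., lower.tail = FALSE)` rather than naive term summation —
at sequencing scale `N ~ 10^7` naive summation is both slow and
cancellation-prone. Only pairs with at least one observed read are
tested by default: zero-count pairs have p-value 1 and would only
inflate the number of comparisons. The number of BH comparisons `m` is
the number of tested pairs; `m_mode = "possible"` switches to all
possible bin pairs for a more conservative correction (the source
material is ambiguous about which is meant, so both are available and
the less conservative, more common convention is the default).

Under its own generative null (reads multinomially assigned to pairs
with probability proportional to the coverage product) the discrete
binomial test is conservative: the empirical fraction of p < 0.05 sits
around 0.04–0.05 at 100 bins and N = 10^5, which the acceptance suite
bounds at 0.07.

## Poisson-regression normalization

Per chromosome *i* (and per chromosome pair for trans contacts), counts
are regressed as

$$t_{jh} = \exp\left[\beta_0 + \beta_{len}\log(x_j x_h) +
\beta_{gc}\log(y_j y_h) + \log(z_j z_h)\right]$$

by Poisson maximum likelihood (`glm`, IRLS), with mappability entering
as a fixed offset. The log base is taken as natural: only the offset's
base is consequential, and the natural log makes its coefficient
exactly 1. The normalized map is `e = u/t`; a global rescaling of `z`
shifts every offset by a constant which the intercept absorbs exactly,
so `e` is invariant (checked to 1e-8). Bins with any zero covariate lie
outside the log domain; they are excluded from fitting and their pairs
reported unnormalizable. Zero-count pairs carry likelihood information
and are included in the fit by default. Constant covariate columns
(e.g. all-equal GC in a degenerate fixture) are dropped from the design
to keep it full-rank, with their coefficient reported as 0.

The normalization model defines no significance test. As a clearly
flagged extension (`model = "hicnorm+poisson-tail"` in the result
metadata), pairs are scored by the Poisson upper tail against their
fitted expectation, then BH-corrected. This is the package's own
design choice for completing the call pipeline, not a claim about any
upstream tool's internals.

## Distance-decay spline model

Intra-chromosomal pairs only. The pair universe is every same-chromosome
bin pair with midpoint distance in `[dist_low, dist_high]`, including
zero-count pairs; its size is `M` and the read total within the window
is `N`. The defaults are `dist_low = 2·binsize` — excluding
adjacent-bin pairs, which are dominated by self-ligation and
incomplete-digestion artifacts — and no upper bound; both are exposed.

Pairs are sorted by distance and grouped into `b` (default 200)
equal-occupancy bins: a distance group whose cumulative contact count
before it is `c` joins bin `1 + floor(c/(N/b))`. All pairs at one
distance are indivisible (deterministic boundaries), empty bins skipped
by one enormous group are dropped, and `b` is reduced with a warning
when there are fewer distinct distances. This construction guarantees
each bin's total is within one single-distance total of the ideal
`N/b`; a naive "close the bin at the target" greedy does not have that
guarantee on non-monotone inputs, which is why the boundary form is
used. Per bin, the mean count per pair `c_i` (zeros included), the
prior `c_i/N`, and the mean distance `d_i` are computed; a cubic
smoothing spline with GCV-chosen penalty is fitted through
`(d_i, c_i/N)`, evaluated on a fine grid, projected non-increasing by
isotonic regression (a contact prior that grows with distance is
non-physical), clamped to `[1e-15, 1]`, and extended as a constant
beyond the fitted range. With fewer than four points the spline
degenerates to monotone linear interpolation; one point gives a
constant — which makes the flat-prior case reduce exactly to the
uniform `p = 1/M` test, a degeneracy the tests assert.

Each pair's p-value is the binomial tail at probability `f(d)`. One
refinement round follows: pairs with phase-1 `q` below `refine_q`
(default 0.05; 0 disables refinement exactly) are excluded from the
binning and statistics, the spline is refitted, and phase-2 p-values
are computed for all pairs — including the excluded ones — from the
refined prior. `N` is kept at the phase-1 window total so the binomial
trial count is unchanged between phases.

## Synthetic data: what a green test establishes

Each generator draws from the corresponding model's own assumptions:
multinomial reads with coverage-product pair probabilities; independent
Poisson counts from the regression mean; multinomial reads with weight
`d^-1` (the canonical decay exponent observed in mammalian Hi-C at
sub-Mb scales) and planted loops as multiplicative weight folds.
Default covariates are uniform — effective length on
`[0.2, 1]·binsize`, GC on `[0.3, 0.6]`, mappability on `[0.5, 1]` —
plausible ranges that keep every bin usable. Default scale for the
calibration suites is 100–150 bins and `N = 10^5`, i.e. a small
chromosome at coarse resolution, chosen so the full acceptance suite
runs in seconds.

These simulations deliberately lack features of real data: no TAD or
compartment structure, no copy-number variation, no correlated biases,
no trans-chromosomal structure beyond uniform noise. A green
calibration test therefore establishes that each model is correctly
implemented against its own null — not that the null is an adequate
description of any particular genome. The worked example in the README
makes the converse point: the coverage model, run on distance-decay
data, flags hundreds of short-range pairs, because distance is simply
outside its model.

## Numerical and design choices

- Binomial and Poisson tails use R's stable survival functions; the
  test oracles are independent log-space pmf summations.
- BH is implemented from the rank formula `q = p·m/r` plus the
  step-up cumulative minimum and a clamp at 1; the rank formula alone
  does not yield monotone q-values.
- Ties in p share ranks by stable input order; the cumulative minimum
  makes tied q-values equal regardless.
- Probability clamps: coverage-product null at 1; spline prior to
  `[1e-15, 1]`; `binom_sf` tolerates p outside `[0,1]` by at most
  1e-12 (floating-point slack) and rejects anything further.
- Seeds: every generator takes one integer seed driving one local
  stream (`withr::with_seed`); no global RNG state is disturbed.
- Arc width is a linear map from count to `[w_min, w_max]` (only
  monotonicity is semantically required); heatmap colours interpolate
  linearly between two endpoints, defaulting to yellow/black, with
  p-values shown as `-log10 p`.
- The interactive HTML viewer of the upstream ecosystem is out of
  scope; rendering is static (PNG/SVG/PDF by extension) and both plot
  functions return their computed geometry so rendered element counts
  are queryable and testable.

## Known limitations

- No matrix-balancing (ICE) normalization, TAD calling, or binary
  `.hic`/`.cool` formats.
- The HOMER dialect is a documented minimal header-driven table, not
  HOMER's full file ecosystem.
- The trans normalization fits each chromosome pair separately rather
  than a genome-wide joint model.
- Fragment-level maps are supported through midpoints, but the
  distance-decay model's default `dist_low` needs a fixed resolution;
  supply `dist_low` explicitly for fragment maps.
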