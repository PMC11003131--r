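# Bond-length / bond-angle time series, distribution summaries and the
# Jensen-Shannon divergence used as the refinement convergence measure.

#' Measure a bond-length time series
#'
#' One value per frame: the minimum-image distance between the two beads.
#'
#' @param cg_traj a bead `cg_trajectory`, nm.
#' @param term length-2 vector of bead indices (1-based).
#' @return numeric vector of nm distances, one per frame.
#' @export
measure_bond_series <- function(cg_traj, term) {
  .assert(inherits(cg_traj, "cg_trajectory"), "cg_traj must be a cg_trajectory")
  term <- as.integer(term)
  .assert(length(term) == 2 && all(term >= 1 & term <= cg_traj$atom_count),
          "bond term indices out of range")
  d <- cg_traj$coords[term[1], , ] - cg_traj$coords[term[2], , ]
  if (cg_traj$n_frames == 1) d <- matrix(d, nrow = 3)
  if (!is.null(cg_traj$box)) {
    for (k in 1:3)
      d[k, ] <- d[k, ] - cg_traj$box[, k] * round(d[k, ] / cg_traj$box[, k])
  }
  sqrt(colSums(d^2))
}

#' Measure a bond-angle time series
#'
#' One value per frame: the angle at the middle bead, in degrees in
#' `[0, 180]`, with minimum-image arms under periodic boundaries.
#'
#' @param cg_traj a bead `cg_trajectory`, nm.
#' @param term length-3 vector of bead indices; the vertex is the middle one.
#' @return numeric vector of degree values, one per frame.
#' @export
measure_angle_series <- function(cg_traj, term) {
  .assert(inherits(cg_traj, "cg_trajectory"), "cg_traj must be a cg_trajectory")
  term <- as.integer(term)
  .assert(length(term) == 3 && all(term >= 1 & term <= cg_traj$atom_count),
          "angle term indices out of range")
  .assert(length(unique(term)) == 3, "angle term needs three distinct beads")
  u <- cg_traj$coords[term[1], , ] - cg_traj$coords[term[2], , ]
  v <- cg_traj$coords[term[3], , ] - cg_traj$coords[term[2], , ]
  if (cg_traj$n_frames == 1) { u <- matrix(u, 3); v <- matrix(v, 3) }
  if (!is.null(cg_traj$box)) {
    for (k in 1:3) {
      u[k, ] <- u[k, ] - cg_traj$box[, k] * round(u[k, ] / cg_traj$box[, k])
      v[k, ] <- v[k, ] - cg_traj$box[, k] * round(v[k, ] / cg_traj$box[, k])
    }
  }
  nu <- sqrt(colSums(u^2)); nv <- sqrt(colSums(v^2))
  bad <- which(nu < 1e-12 | nv < 1e-12)
  if (length(bad) > 0)
    stop(sprintf("zero-length angle arm at frame %d", bad[1]), call. = FALSE)
  cosx <- pmin(1, pmax(-1, colSums(u * v) / (nu * nv)))
  acos(cosx) * 180 / pi
}

#' Summarize samples as a bonded distribution
#'
#' Computes the sample mean, the unbiased (n-1) variance and a histogram.
#' Default binning: `n_bins` uniform bins over `[min, max]` of the samples
#' padded by 5% of the span on each side.
#'
#' @param samples numeric vector (nm for bonds, degrees for angles); at
#'   least 2 values.
#' @param n_bins number of uniform bins (default 100).
#' @param range optional length-2 bin range overriding the padded default.
#' @param kind `"bond"` or `"angle"` (metadata; angles are checked to lie in
#'   `[0, 180]`, bonds to be non-negative).
#' @param term optional term identifier carried along as metadata.
#' @return an object of class `bonded_distribution` with fields `term`,
#'   `kind`, `samples`, `mean`, `variance`, `n`, `breaks`, `counts`.
#' @export
summarize_distribution <- function(samples, n_bins = 100, range = NULL,
                                   kind = c("bond", "angle"), term = NULL) {
  kind <- match.arg(kind)
  .assert(length(samples) > 0, "empty sample list")
  .assert(length(samples) >= 2, "need at least 2 samples for a variance")
  .assert(all(is.finite(samples)), "samples must be finite")
  if (kind == "bond") .assert(all(samples >= 0), "bond samples must be >= 0")
  else .assert(all(samples >= 0 & samples <= 180),
               "angle samples must lie in [0, 180] degrees")
  .assert(n_bins >= 1, "n_bins must be >= 1")
  if (is.null(range)) {
    lo <- min(samples); hi <- max(samples)
    pad <- 0.05 * (hi - lo)
    if (pad == 0) pad <- max(abs(lo) * 1e-3, 1e-9)
    range <- c(lo - pad, hi + pad)
  }
  .assert(range[2] > range[1], "range must be increasing")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  counts <- bin_counts(samples, breaks)
  structure(list(term = term, kind = kind, samples = samples,
                 mean = mean(samples), variance = var(samples),
                 n = length(samples), breaks = breaks, counts = counts),
            class = "bonded_distribution")
}

#' @export
print.bonded_distribution <- function(x, ...) {
  cat(sprintf("bonded_distribution [%s%s]: n = %d, mean = %.6g, var = %.6g\n",
              x$kind, if (is.null(x$term)) "" else paste0(" ", x$term),
              x$n, x$mean, x$variance))
  invisible(x)
}

# histogram counts over fixed breaks; samples outside the breaks are clamped
# into the edge bins so counts always sum to length(samples).
bin_counts <- function(samples, breaks) {
  nb <- length(breaks) - 1
  idx <- findInterval(samples, breaks, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > nb] <- nb
  tabulate(idx, nbins = nb)
}

#' Jensen-Shannon divergence between two bonded distributions
#'
#' Both sample sets are rebinned onto a shared uniform edge set covering the
#' union of their supports, converted to probability mass per bin, and
#' compared with the base-2 Jensen-Shannon divergence: symmetric, 0 for
#' identical histograms and 1 for fully disjoint supports. Using probability
#' mass (not density) makes the value invariant to the shared bin width.
#'
#' @param dist_a,dist_b `bonded_distribution` objects (or plain numeric
#'   sample vectors).
#' @param n_bins number of shared bins (default 60; the finite-sample bias
#'   of the plug-in JSD estimate grows roughly as `(n_bins - 1) / (4 ln 2)`
#'   times the summed reciprocal sample sizes, so more bins are not better
#'   for the sample sizes this package works at).
#' @return divergence in `[0, 1]` (bits).
#' @export
distribution_divergence <- function(dist_a, dist_b, n_bins = 60) {
  sa <- if (inherits(dist_a, "bonded_distribution")) dist_a$samples else dist_a
  sb <- if (inherits(dist_b, "bonded_distribution")) dist_b$samples else dist_b
  .assert(length(sa) > 0 && length(sb) > 0, "empty histogram")
  lo <- min(sa, sb); hi <- max(sa, sb)
  pad <- max(1e-12, 1e-9 * max(abs(lo), abs(hi), 1))
  breaks <- seq(lo - pad, hi + pad, length.out = n_bins + 1)
  p <- bin_counts(sa, breaks) / length(sa)
  q <- bin_counts(sb, breaks) / length(sb)
  jsd_base2(p, q)
}

jsd_base2 <- function(p, q) {
  m <- 0.5 * (p + q)
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  d <- 0.5 * kl(p) + 0.5 * kl(q)
  min(1, max(0, d))
}

#' Tabulate per-term distribution summaries
#'
#' Measures every bond and angle term of a CG topology on a bead trajectory
#' and returns one row per term.
#'
#' @param cg_traj a bead `cg_trajectory`.
#' @param topology the [cg_topology()] declaring the terms.
#' @param n_bins bins forwarded to [summarize_distribution()].
#' @return `data.frame(term, kind, mean, variance, n)`.
#' @export
bonded_summary_table <- function(cg_traj, topology, n_bins = 100) {
  dists <- measure_all_terms(cg_traj, topology, n_bins = n_bins)
  data.frame(term = names(dists),
             kind = vapply(dists, `[[`, character(1), "kind"),
             mean = vapply(dists, `[[`, numeric(1), "mean"),
             variance = vapply(dists, `[[`, numeric(1), "variance"),
             n = vapply(dists, `[[`, numeric(1), "n"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# measure + summarize every bonded term; returns a named list of
# bonded_distribution keyed by canonical term key.
measure_all_terms <- function(cg_traj, topology, n_bins = 100) {
  out <- list()
  bt <- topology$bond_terms
  for (r in seq_len(nrow(bt))) {
    k <- bond_key(bt[r, 1], bt[r, 2])
    out[[k]] <- summarize_distribution(measure_bond_series(cg_traj, bt[r, ]),
                                       n_bins = n_bins, kind = "bond", term = k)
  }
  at <- topology$angle_terms
  for (r in seq_len(nrow(at))) {
    k <- angle_key(at[r, 1], at[r, 2], at[r, 3])
    out[[k]] <- summarize_distribution(measure_angle_series(cg_traj, at[r, ]),
                                       n_bins = n_bins, kind = "angle", term = k)
  }
  out
}
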