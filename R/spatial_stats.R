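# 1D point-process statistics linking sharp bends and neurite outgrowths.
#
# The dendrite is imagined stretched out along one dimension; every bend
# and every outgrowth attachment is a point at its distance from the most
# distal main-branch point. The empty-space function F(r) of the bend
# pattern (fraction of dendrite length within r of a bend) is the baseline
# for how outgrowths would distribute if placed independently; comparing
# it per neuron with the observed fraction of outgrowths within an
# interaction distance of a bend yields a paired signed-rank test.

#' Event positions along a stretched neuron
#'
#' @param neuron_id Identifier carried into cohort tables.
#' @param bend_positions,outgrowth_positions Distances (um) from the most
#'   distal main-branch point; all within `[0, main_length]`.
#' @param main_length Main-branch length, um.
#' @return An object of class `event_positions`.
#' @export
event_positions <- function(neuron_id, bend_positions, outgrowth_positions,
                            main_length) {
  stopifnot(main_length > 0)
  pos <- c(bend_positions, outgrowth_positions)
  if (length(pos) && (min(pos) < -1e-9 || max(pos) > main_length + 1e-9))
    stop("event positions must lie within [0, main_length]")
  structure(list(neuron_id = neuron_id,
                 bend_positions = as.numeric(bend_positions),
                 outgrowth_positions = as.numeric(outgrowth_positions),
                 main_length = main_length),
            class = "event_positions")
}

#' Localize detected events relative to the distal tip
#'
#' Converts arclengths measured from the root-side end of the main branch
#' (as produced by [detect_bends()] and [branch_inventory()]) into
#' distances from the most distal main-branch point.
#'
#' @param ct A `classified_tree`.
#' @param bends Bend event data frame with an `arclength` column.
#' @param outgrowths Branch inventory rows with an `attachment_um` column
#'   (only rows labelled `neuriteoutgrowth` are used; rows without a
#'   main-branch attachment are dropped).
#' @param neuron_id Identifier for the result.
#' @return An [event_positions()] object.
#' @export
positions_from_distal <- function(ct, bends, outgrowths,
                                  neuron_id = "neuron") {
  stopifnot(inherits(ct, "classified_tree"))
  L <- ct$main_length
  ba <- bends$arclength
  if (length(ba) && (min(ba) < -1e-9 || max(ba) > L + 1e-9))
    stop("bend event lies off the main branch")
  og <- outgrowths[outgrowths$label == "neuriteoutgrowth" &
                     !is.na(outgrowths$attachment_um), , drop = FALSE]
  event_positions(neuron_id,
                  bend_positions = L - ba,
                  outgrowth_positions = L - og$attachment_um,
                  main_length = L)
}

#' Nearest-bend distance for every outgrowth
#'
#' @param ep An [event_positions()] object with at least one bend.
#' @return Numeric vector, one 1D distance (um) per outgrowth.
#' @export
nearest_bend_distances <- function(ep) {
  stopifnot(inherits(ep, "event_positions"))
  if (!length(ep$bend_positions))
    stop("no bends: nearest-bend distances are undefined")
  vapply(ep$outgrowth_positions,
         function(p) min(abs(p - ep$bend_positions)), numeric(1))
}

#' Empty-space function of the bend pattern
#'
#' F(r) is the fraction of the `[0, main_length]` interval lying within
#' distance r of some bend, computed exactly from the union of intervals
#' (no sampling).
#'
#' @param ep An [event_positions()] object with at least one bend.
#' @param grid Distances r (um) at which to evaluate F.
#' @return Numeric vector of F values, same length as `grid`.
#' @export
empty_space_cdf <- function(ep, grid) {
  stopifnot(inherits(ep, "event_positions"))
  if (!length(ep$bend_positions))
    stop("no bends: empty-space function is undefined")
  b <- sort(ep$bend_positions)
  L <- ep$main_length
  vapply(grid, function(r) {
    lo <- pmax(b - r, 0)
    hi <- pmin(b + r, L)
    tot <- 0
    cur_lo <- lo[1L]
    cur_hi <- hi[1L]
    for (i in seq_along(b)[-1L]) {
      if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
      else {
        tot <- tot + cur_hi - cur_lo
        cur_lo <- lo[i]
        cur_hi <- hi[i]
      }
    }
    (tot + cur_hi - cur_lo) / L
  }, numeric(1))
}

#' Exact Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences with zero differences dropped and
#' ties handled by average ranks. The null distribution of the statistic W
#' (sum of ranks of positive differences) is computed exactly by dynamic
#' programming over all 2^n sign assignments, so tied ranks and small n are
#' handled without normal approximation.
#'
#' @param d Numeric vector of paired differences.
#' @param alternative `"greater"` (W larger than expected), `"less"`, or
#'   `"two.sided"`.
#' @return List with `statistic` (W), `p.value`, `n` (non-zero pairs), and
#'   `degenerate` (TRUE when every difference is zero, in which case
#'   p = 1).
#' @export
signed_rank_exact <- function(d, alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  d <- d[is.finite(d)]
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = 0, p.value = 1, n = 0L, degenerate = TRUE))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  # doubled ranks are integers even with .5 average ranks
  ri <- as.integer(round(2 * r))
  total <- sum(ri)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (x in ri) {
    g <- f
    g[(x + 1L):(total + 1L)] <- g[(x + 1L):(total + 1L)] +
      f[1L:(total + 1L - x)]
    f <- g / 2
  }
  w2 <- as.integer(round(2 * w))
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  p_le <- sum(f[1L:(w2 + 1L)])
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = w, p.value = p, n = length(d), degenerate = FALSE)
}

#' Bend-outgrowth association test for a cohort
#'
#' For each neuron with at least one bend and one outgrowth, pairs the
#' observed fraction of outgrowths within `r` of a bend with the
#' empty-space value F(r) (the fraction expected under independent
#' placement), then runs an exact Wilcoxon signed-rank test on the paired
#' differences (one-sided "greater" by default, i.e. outgrowths closer to
#' bends than chance). Also returns pooled curves for plotting: the
#' empirical CDF of all nearest-bend distances and the cohort mean of the
#' per-neuron empty-space functions.
#'
#' @param cohort List of [event_positions()] objects.
#' @param r Interaction distance, um.
#' @param alternative Passed to [signed_rank_exact()].
#' @param grid Distance grid (um) for the pooled curves.
#' @return List of class `association_result`: `n_neurons`, `observed`,
#'   `expected`, `statistic`, `p.value`, `degenerate`, `r`, `grid`,
#'   `nearest_cdf`, `esd_cdf`, `excluded`.
#' @export
association_test <- function(cohort, r = 1, alternative = "greater",
                             grid = seq(0, 10, by = 0.1)) {
  usable <- vapply(cohort, function(ep)
    length(ep$bend_positions) > 0 && length(ep$outgrowth_positions) > 0,
    logical(1))
  used <- cohort[usable]
  if (length(used) < 6L)
    warning("fewer than 6 usable neurons; the signed-rank test has little ",
            "power at this size")
  if (!length(used)) stop("no neuron has both bends and outgrowths")
  obs <- vapply(used, function(ep)
    mean(nearest_bend_distances(ep) <= r), numeric(1))
  expd <- vapply(used, function(ep) empty_space_cdf(ep, r), numeric(1))
  test <- signed_rank_exact(obs - expd, alternative = alternative)
  nbd <- unlist(lapply(used, nearest_bend_distances))
  nearest_cdf <- vapply(grid, function(g) mean(nbd <= g), numeric(1))
  esd_mat <- vapply(used, function(ep) empty_space_cdf(ep, grid),
                    numeric(length(grid)))
  structure(list(n_neurons = length(used), observed = obs, expected = expd,
                 statistic = test$statistic, p.value = test$p.value,
                 degenerate = test$degenerate, r = r, grid = grid,
                 nearest_cdf = nearest_cdf,
                 esd_cdf = rowMeans(as.matrix(esd_mat)),
                 excluded = sum(!usable)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(paste0("<association_result> %d neurons (%d excluded), ",
                     "r = %.2g um\n  W = %.1f, p = %.3g\n"),
              x$n_neurons, x$excluded, x$r, x$statistic, x$p.value))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of event positions
#'
#' Two-sided two-sample KS test on pooled event positions (exact p for
#' small samples, asymptotic otherwise, as in [stats::ks.test()]).
#'
#' @param positions_a,positions_b Numeric vectors of positions (um).
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(positions_a, positions_b) {
  stopifnot(length(positions_a) > 0, length(positions_b) > 0)
  kt <- suppressWarnings(stats::ks.test(positions_a, positions_b,
                                        alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Optional RNG seed; a fixed seed gives a bitwise-identical
#'   interval on repeat.
#' @param conf Confidence level.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci_mean <- function(values, n_boot = 10000, seed = NULL,
                              conf = 0.95) {
  stopifnot(length(values) >= 2L, n_boot >= 1000L)
  with_seed(seed, {
    n <- length(values)
    means <- colMeans(matrix(sample(values, n * n_boot, replace = TRUE),
                             nrow = n))
    a <- (1 - conf) / 2
    stats::setNames(stats::quantile(means, c(a, 1 - a), names = FALSE),
                    c("low", "high"))
  })
}
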