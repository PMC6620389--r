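# Sharp-bend (kink) and bead/bleb detection along the classified main
# branch.
#
# Bends: for every interior node, directions are fitted separately to the
# upstream and downstream nodes within 2 um of accumulated arclength
# (total-least-squares principal direction), and the turning angle between
# the two outward directions is computed (straight = 180 deg). Nodes with
# an angle below the threshold (default 155 deg) are bend candidates;
# candidates are selected sequentially starting with the sharpest while
# suppressing others within 4 um (non-maximum suppression).
#
# Beads: local thickness (mean radius in an 8 um window) is subtracted from
# the node radii; residual maxima exceeding 2 standard deviations of the
# residuals are counted sequentially with the same suppression scheme.

#' Morphometry thresholds
#'
#' @param bend_window Arclength window per side (um) for the upstream and
#'   downstream line fits.
#' @param bend_threshold Angle (degrees); nodes with a turning angle below
#'   this are sharp-bend candidates. Straight = 180.
#' @param bend_nms Non-maximum-suppression radius (um) between reported
#'   bends.
#' @param thickness_window Total window (um) for the local-thickness
#'   estimate used by bead detection.
#' @param bead_sd_multiplier Residuals must exceed this multiple of the
#'   residual standard deviation to count as a bead.
#' @param bead_nms Suppression radius (um) between reported beads.
#' @param bead_sd_source `"residual"` (default) computes the detection SD
#'   from the local-thickness residuals; `"raw"` uses the raw radii.
#' @return A list of class `morph_config`.
#' @export
morph_config <- function(bend_window = 2, bend_threshold = 155, bend_nms = 4,
                         thickness_window = 8, bead_sd_multiplier = 2,
                         bead_nms = 4,
                         bead_sd_source = c("residual", "raw")) {
  stopifnot(bend_window > 0, bend_threshold > 0, bend_threshold < 180,
            bend_nms > 0, thickness_window > 0, bead_sd_multiplier > 0,
            bead_nms > 0)
  structure(list(bend_window = bend_window, bend_threshold = bend_threshold,
                 bend_nms = bend_nms, thickness_window = thickness_window,
                 bead_sd_multiplier = bead_sd_multiplier, bead_nms = bead_nms,
                 bead_sd_source = match.arg(bead_sd_source)),
            class = "morph_config")
}

as_branch_geometry <- function(x) {
  if (inherits(x, "classified_tree")) return(main_branch_geometry(x))
  if (is.matrix(x)) {
    seg <- sqrt(rowSums((x[-1L, , drop = FALSE] -
                           x[-nrow(x), , drop = FALSE])^2))
    return(data.frame(node_id = seq_len(nrow(x)), x = x[, 1L], y = x[, 2L],
                      z = x[, 3L], radius = NA_real_,
                      arclength = c(0, cumsum(seg))))
  }
  stopifnot(is.data.frame(x),
            all(c("x", "y", "z", "arclength") %in% names(x)))
  x
}

#' Windowed turning angles along a branch
#'
#' For each node with at least two upstream and two downstream neighbours
#' within `window` um of accumulated arclength, fits a total-least-squares
#' direction to each side (node included), orients both away from the node,
#' and returns the angle between the two outward directions in degrees
#' (collinear points give 180). Nodes within `window` of either branch end,
#' or with degenerate (coincident) side points, get `NA`.
#'
#' @param branch A `classified_tree`, an n x 3 coordinate matrix, or a
#'   geometry data frame from [main_branch_geometry()].
#' @param window Arclength window per side, um.
#' @return Numeric vector of angles (degrees), one per node.
#' @export
node_angles <- function(branch, window = 2) {
  g <- as_branch_geometry(branch)
  stopifnot(window > 0)
  n <- nrow(g)
  if (n < 3L) stop("need at least 3 nodes to compute angles")
  p <- cbind(g$x, g$y, g$z)
  s <- g$arclength
  total <- s[n]
  ang <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (s[i] < window || total - s[i] < window) next
    up <- which(s >= s[i] - window & s < s[i])
    dn <- which(s > s[i] & s <= s[i] + window)
    if (length(up) < 2L || length(dn) < 2L) next
    u <- tls_outward(p[c(up, i), , drop = FALSE], p[i, ])
    v <- tls_outward(p[c(i, dn), , drop = FALSE], p[i, ])
    if (is.null(u) || is.null(v)) next
    ang[i] <- angle_between_deg(u, v)
  }
  ang
}

# First principal direction of a point set, oriented away from `origin`
# (towards the side centroid). NULL for degenerate (coincident) points.
tls_outward <- function(pts, origin) {
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2L, ctr)
  if (sum(cc^2) < 1e-16) return(NULL)
  v <- svd(cc, nu = 0L, nv = 1L)$v[, 1L]
  away <- ctr - origin
  if (sum(away * v) < 0) v <- -v
  v
}

# Numerically stable angle between two vectors via atan2(|u x v|, u.v).
angle_between_deg <- function(u, v) {
  cr <- pracma_cross(u, v)
  atan2(vec_norm(cr), sum(u * v)) * 180 / pi
}

# Greedy sequential selection with 1D non-maximum suppression: candidates
# ordered by strength (strongest first, ties broken by position then id);
# each selection suppresses candidates within `window` arclength.
nms_select <- function(arclength, strength, window, ids = seq_along(arclength)) {
  ord <- order(strength, arclength, ids, decreasing = c(TRUE, FALSE, FALSE),
               method = "radix")
  alive <- rep(TRUE, length(arclength))
  picked <- integer(0)
  for (j in ord) {
    if (!alive[j]) next
    picked <- c(picked, j)
    alive[abs(arclength - arclength[j]) <= window] <- FALSE
  }
  sort(picked)
}

#' Detect sharp bends along the main branch
#'
#' Nodes with a turning angle below `cfg$bend_threshold` are candidates;
#' bends are selected sequentially starting with the sharpest, suppressing
#' candidates within `cfg$bend_nms` um of each selection.
#'
#' @param branch As in [node_angles()].
#' @param cfg A [morph_config()].
#' @param angles Optional precomputed [node_angles()] vector (used by
#'   [threshold_sweep()] to avoid refitting).
#' @return Data frame of bend events sorted by arclength: `node_id`,
#'   `angle`, `arclength`.
#' @export
detect_bends <- function(branch, cfg = morph_config(), angles = NULL) {
  g <- as_branch_geometry(branch)
  if (is.null(angles)) angles <- node_angles(g, cfg$bend_window)
  cand <- which(!is.na(angles) & angles < cfg$bend_threshold)
  if (!length(cand))
    return(data.frame(node_id = integer(0), angle = numeric(0),
                      arclength = numeric(0)))
  sel <- cand[nms_select(g$arclength[cand], -angles[cand], cfg$bend_nms,
                         g$node_id[cand])]
  data.frame(node_id = g$node_id[sel], angle = angles[sel],
             arclength = g$arclength[sel])
}

#' Bend (or bead) density
#'
#' @param events Event data frame (or anything with a row count).
#' @param main_length Main-branch length, um; must be positive.
#' @return Events per um.
#' @export
event_density <- function(events, main_length) {
  if (!is.finite(main_length) || main_length <= 0)
    stop("main_length must be positive")
  nrow(as.data.frame(events)) / main_length
}

#' @rdname event_density
#' @export
bend_density <- event_density

#' Bend density across a range of angle thresholds
#'
#' Recomputes the bend count with identical windows and suppression for
#' each threshold. Densities are non-decreasing in the threshold because a
#' larger threshold only adds weaker candidates, which cannot alter the
#' greedy selection of stronger ones.
#'
#' @param branch As in [node_angles()].
#' @param cfg A [morph_config()] providing window and suppression settings.
#' @param thresholds Angle thresholds in degrees, each in (0, 180).
#' @return Data frame with `threshold`, `count`, `density`.
#' @export
threshold_sweep <- function(branch, cfg = morph_config(),
                            thresholds = seq(135, 165, by = 5)) {
  stopifnot(all(thresholds > 0 & thresholds < 180))
  g <- as_branch_geometry(branch)
  angles <- node_angles(g, cfg$bend_window)
  L <- max(g$arclength)
  rows <- lapply(thresholds, function(th) {
    cfg_th <- cfg
    cfg_th$bend_threshold <- th
    ev <- detect_bends(g, cfg_th, angles = angles)
    data.frame(threshold = th, count = nrow(ev),
               density = nrow(ev) / L)
  })
  do.call(rbind, rows)
}

#' Local-thickness residual of the radius profile
#'
#' Per node, the node radius minus the mean radius over all nodes within
#' half the window of arclength (node included) - a running-mean estimate
#' of the local process thickness, so that focal enlargements stand out as
#' positive residuals.
#'
#' @param radius Node radii (um) along the branch.
#' @param arclength Node arclengths (um), same length, non-decreasing.
#' @param window Total window width, um.
#' @return Numeric vector of excess radii (um).
#' @export
local_thickness_residual <- function(radius, arclength, window = 8) {
  stopifnot(length(radius) == length(arclength), window > 0)
  half <- window / 2
  cs <- c(0, cumsum(radius))
  lo <- findInterval(arclength - half, arclength, left.open = TRUE) + 1L
  hi <- findInterval(arclength + half, arclength)
  mean_r <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  radius - mean_r
}

#' Detect beads/blebs along the main branch
#'
#' Computes local-thickness residuals, their standard deviation over the
#' whole branch, and counts residual maxima sequentially (suppressing
#' neighbours within `cfg$bead_nms` um) while the residual exceeds
#' `cfg$bead_sd_multiplier` standard deviations.
#'
#' @param branch A `classified_tree` or geometry data frame with `radius`
#'   and `arclength` columns.
#' @param cfg A [morph_config()].
#' @return Data frame of bead events sorted by arclength: `node_id`,
#'   `excess_radius`, `arclength`.
#' @export
detect_beads <- function(branch, cfg = morph_config()) {
  g <- as_branch_geometry(branch)
  if (nrow(g) < 3L) stop("need at least 3 nodes for bead detection")
  res <- local_thickness_residual(g$radius, g$arclength,
                                  cfg$thickness_window)
  sd0 <- if (cfg$bead_sd_source == "residual") stats::sd(res)
         else stats::sd(g$radius)
  # floor at 1 nm so float round-off on constant radii never fires
  cut <- max(cfg$bead_sd_multiplier * sd0, 1e-9)
  cand <- which(res > cut)
  if (!length(cand))
    return(data.frame(node_id = integer(0), excess_radius = numeric(0),
                      arclength = numeric(0)))
  sel <- cand[nms_select(g$arclength[cand], res[cand], cfg$bead_nms,
                         g$node_id[cand])]
  data.frame(node_id = g$node_id[sel], excess_radius = res[sel],
             arclength = g$arclength[sel])
}

#' Smoothing-spline curvature profile (diagnostic)
#'
#' Approximates the 3D main branch with smoothing cubic splines of each
#' coordinate against arclength and returns the absolute curvature
#' |r' x r''| / |r'|^3 on a uniform arclength grid. This is the
#' spline-based alternative to the windowed-angle bend detector; it is
#' exposed for diagnostics only and is not used for bend counts (it is
#' less robust to tracing noise).
#'
#' @param branch As in [node_angles()].
#' @param smoothing Non-negative smoothing penalty (the `lambda` of
#'   [stats::smooth.spline()]); 0 gives near-interpolation.
#' @param n_grid Number of arclength grid points.
#' @return Data frame with `arclength` and `curvature` (1/um).
#' @export
spline_curvature <- function(branch, smoothing = 0, n_grid = 200) {
  g <- as_branch_geometry(branch)
  if (nrow(g) < 5L) stop("need at least 5 nodes for spline curvature")
  s <- g$arclength
  if (max(s) <= 0) stop("degenerate branch: zero total arclength")
  lam <- max(smoothing, 1e-10)
  grid <- seq(min(s), max(s), length.out = n_grid)
  d1 <- matrix(0, n_grid, 3L)
  d2 <- matrix(0, n_grid, 3L)
  for (k in 1:3) {
    fit <- stats::smooth.spline(s, g[[c("x", "y", "z")[k]]], lambda = lam,
                                all.knots = TRUE, keep.data = FALSE)
    d1[, k] <- stats::predict(fit, grid, deriv = 1L)$y
    d2[, k] <- stats::predict(fit, grid, deriv = 2L)$y
  }
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  kappa <- sqrt(rowSums(cr^2)) / pmax(sqrt(rowSums(d1^2))^3, 1e-12)
  data.frame(arclength = grid, curvature = kappa)
}
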