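# Synthetic neurons and rendered image stacks with known ground truth.
#
# The generator emulates the morphology catalogued for aged C. elegans
# touch receptor neurons: a long main dendrite with planted sharp bends of
# known angle and position, side branches (soma outgrowths, neurite
# outgrowths, a PVM-like crossing branch carrying a large-radius soma
# node), Gaussian radius bumps (beads), and a spherical soma, optionally
# rendered into a noisy anisotropic voxel stack. Every planted feature is
# reported in a ground-truth record so recovery can be scored exactly.

#' Specification of one synthetic neuron
#'
#' @param main_length Main dendrite length, um.
#' @param node_spacing Node spacing along all processes, um (APP2-style
#'   traces are used without resampling, so spacing is roughly uniform).
#' @param bends Data frame with `arclength` (um from the root end) and
#'   `angle` (interior angle, degrees; straight = 180). May be `NULL`.
#' @param branches Data frame with `arclength`, `length` (um) and `label`
#'   (`"somaoutgrowth"`, `"neuriteoutgrowth"` or `"pvm"`). May be `NULL`.
#' @param beads Data frame with `arclength`, `amplitude` (um of excess
#'   radius) and `width` (Gaussian sigma, um). May be `NULL`.
#' @param soma_radius Soma radius in um, or `NULL` for no soma (PLM-style
#'   traces that enter the field of view without the cell body).
#' @param baseline_radius Dendrite radius, um.
#' @param radius_noise_sd SD of i.i.d. noise added to node radii, um.
#' @param coordinate_noise_sd SD of i.i.d. noise added to every node
#'   coordinate, um (emulates tracing jitter).
#' @param pvm_soma_radius Radius given to the large node planted on a
#'   `pvm`-labelled branch, um.
#' @param seed RNG seed; a fixed seed reproduces the tree bitwise.
#' @return A list of class `neuron_spec`.
#' @export
neuron_spec <- function(main_length = 100, node_spacing = 0.25,
                        bends = NULL, branches = NULL, beads = NULL,
                        soma_radius = NULL, baseline_radius = 0.4,
                        radius_noise_sd = 0.02, coordinate_noise_sd = 0.05,
                        pvm_soma_radius = 3, seed = 1) {
  stopifnot(main_length > 0, node_spacing > 0, baseline_radius > 0)
  if (!is.null(bends) && nrow(bends)) {
    bends <- bends[order(bends$arclength), , drop = FALSE]
    if (any(bends$arclength <= 0 | bends$arclength >= main_length))
      stop("infeasible spec: bend arclengths must lie inside (0, main_length)")
    if (any(diff(bends$arclength) < node_spacing))
      stop("infeasible spec: bends closer than the node spacing")
    if (any(bends$angle <= 0 | bends$angle >= 180))
      stop("infeasible spec: bend angles must lie in (0, 180)")
  }
  if (!is.null(branches) && nrow(branches)) {
    stopifnot(all(branches$label %in%
                    c("somaoutgrowth", "neuriteoutgrowth", "pvm")),
              all(branches$length > 0))
    if (any(branches$label == "somaoutgrowth") && is.null(soma_radius))
      stop("infeasible spec: somaoutgrowth branches require a soma")
    if (any(branches$arclength[branches$label != "somaoutgrowth"] >=
              main_length))
      stop("infeasible spec: branch attachment beyond the main branch")
  }
  if (!is.null(beads) && nrow(beads))
    stopifnot(all(beads$arclength > 0 & beads$arclength < main_length),
              all(beads$amplitude > 0), all(beads$width > 0))
  structure(list(main_length = main_length, node_spacing = node_spacing,
                 bends = bends, branches = branches, beads = beads,
                 soma_radius = soma_radius,
                 baseline_radius = baseline_radius,
                 radius_noise_sd = radius_noise_sd,
                 coordinate_noise_sd = coordinate_noise_sd,
                 pvm_soma_radius = pvm_soma_radius, seed = seed),
            class = "neuron_spec")
}

#' Generate a synthetic neuron tree with ground truth
#'
#' Realizes the planted geometry as a 3D polyline: the dendrite runs
#' straight between bends, each bend turns the travel direction by
#' (180 - angle) degrees about a random out-of-plane axis (so tests cover
#' genuine 3D geometry, not planar special cases); side branches leave in
#' random perpendicular directions; radii are baseline + planted bead
#' bumps + noise; coordinates are jittered; an optional soma cluster of
#' large-radius nodes is attached at the root.
#'
#' @param spec A [neuron_spec()].
#' @return List with `tree` (a [neuron_tree()]) and `truth` (a list with
#'   `bends`, `beads`, `branches` data frames recording the planted
#'   arclengths, plus `main_length` and `soma_radius`).
#' @export
make_neuron <- function(spec) {
  stopifnot(inherits(spec, "neuron_spec"))
  with_seed(spec$seed, make_neuron_impl(spec))
}

make_neuron_impl <- function(spec) {
  delta <- spec$node_spacing
  n_main <- floor(spec$main_length / delta) + 1L
  s <- (seq_len(n_main) - 1L) * delta
  # plant each bend at the nearest node (not the two ends)
  bend_nodes <- integer(0)
  bend_angles <- numeric(0)
  if (!is.null(spec$bends) && nrow(spec$bends)) {
    bend_nodes <- pmin(pmax(round(spec$bends$arclength / delta) + 1L, 2L),
                       n_main - 1L)
    bend_angles <- spec$bends$angle
  }
  dir <- c(1, 0, 0)
  pts <- matrix(0, n_main, 3L)
  for (i in seq_len(n_main - 1L)) {
    if (i %in% bend_nodes) {
      k <- which(bend_nodes == i)[1L]
      axis <- random_perpendicular(dir)
      dir <- rotate_about_axis(dir, axis, (180 - bend_angles[k]) * pi / 180)
    }
    pts[i + 1L, ] <- pts[i, ] + dir * delta
  }
  radius <- rep(spec$baseline_radius, n_main)
  if (!is.null(spec$beads) && nrow(spec$beads)) {
    for (j in seq_len(nrow(spec$beads)))
      radius <- radius + spec$beads$amplitude[j] *
        exp(-(s - spec$beads$arclength[j])^2 / (2 * spec$beads$width[j]^2))
  }
  radius <- pmax(radius + stats::rnorm(n_main, 0, spec$radius_noise_sd),
                 0.05)
  nodes <- data.frame(id = seq_len(n_main), type = 3L,
                      x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                      radius = radius,
                      parent = c(-1L, seq_len(n_main - 1L)))
  next_id <- n_main
  soma_ids <- integer(0)
  if (!is.null(spec$soma_radius)) {
    # the root carries the soma: one large-radius node, so the rendered
    # soma is a single sphere of the planted radius
    nodes$radius[1L] <- spec$soma_radius
    nodes$type[1L] <- 1L
    soma_ids <- 1L
  }
  branch_info <- list()
  if (!is.null(spec$branches) && nrow(spec$branches)) {
    for (j in seq_len(nrow(spec$branches))) {
      lab <- spec$branches$label[j]
      len <- spec$branches$length[j]
      m <- max(1L, round(len / delta))
      if (lab == "somaoutgrowth") {
        att_id <- soma_ids[1L + (j %% length(soma_ids))]
        att_pt <- unlist(nodes[match(att_id, nodes$id), c("x", "y", "z")])
        bdir <- stats::rnorm(3)
        bdir <- bdir / vec_norm(bdir)
        att_node_i <- NA_integer_
      } else {
        att_node_i <- pmin(pmax(round(spec$branches$arclength[j] / delta)
                                + 1L, 2L), n_main - 1L)
        att_id <- att_node_i
        att_pt <- pts[att_node_i, ]
        main_dir <- pts[min(att_node_i + 1L, n_main), ] - pts[att_node_i, ]
        bdir <- random_perpendicular(main_dir)
      }
      ids <- next_id + seq_len(m)
      bp <- sweep(outer(seq_len(m) * (len / m), bdir), 2L, att_pt, `+`)
      brad <- pmax(spec$baseline_radius +
                     stats::rnorm(m, 0, spec$radius_noise_sd), 0.05)
      if (lab == "pvm") brad[m] <- spec$pvm_soma_radius
      nodes <- rbind(nodes, data.frame(
        id = ids, type = 3L, x = bp[, 1L], y = bp[, 2L], z = bp[, 3L],
        radius = brad, parent = c(att_id, ids[-m])))
      next_id <- next_id + m
      branch_info[[j]] <- list(label = lab, nominal_length = len,
                               ids = ids, att_id = att_id,
                               att_node_i = att_node_i)
    }
  }
  if (spec$coordinate_noise_sd > 0) {
    jit <- matrix(stats::rnorm(3L * nrow(nodes), 0,
                               spec$coordinate_noise_sd), ncol = 3L)
    nodes$x <- nodes$x + jit[, 1L]
    nodes$y <- nodes$y + jit[, 2L]
    nodes$z <- nodes$z + jit[, 3L]
  }
  # ground truth is recorded in the realized (jittered) geometry: the
  # arclength metric the tracer-facing detectors actually measure along
  mp <- cbind(nodes$x[seq_len(n_main)], nodes$y[seq_len(n_main)],
              nodes$z[seq_len(n_main)])
  s_real <- c(0, cumsum(sqrt(rowSums(
    (mp[-1L, , drop = FALSE] - mp[-n_main, , drop = FALSE])^2))))
  truth_branches <- data.frame(label = character(0), length = numeric(0),
                               nominal_length = numeric(0),
                               attachment_arclength = numeric(0))
  for (bi in branch_info) {
    ii <- match(bi$ids, nodes$id)
    pr <- match(nodes$parent[ii], nodes$id)
    real_len <- sum(sqrt((nodes$x[ii] - nodes$x[pr])^2 +
                           (nodes$y[ii] - nodes$y[pr])^2 +
                           (nodes$z[ii] - nodes$z[pr])^2))
    truth_branches <- rbind(truth_branches, data.frame(
      label = bi$label, length = real_len,
      nominal_length = bi$nominal_length,
      attachment_arclength = if (is.na(bi$att_node_i)) NA_real_
      else s_real[bi$att_node_i]))
  }
  bead_nodes <- if (!is.null(spec$beads) && nrow(spec$beads))
    pmin(pmax(round(spec$beads$arclength / delta) + 1L, 1L), n_main)
  else integer(0)
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$type <- as.integer(nodes$type)
  truth <- list(
    bends = if (length(bend_nodes))
      data.frame(arclength = s_real[bend_nodes],
                 nominal_arclength = s[bend_nodes], angle = bend_angles)
    else data.frame(arclength = numeric(0), nominal_arclength = numeric(0),
                    angle = numeric(0)),
    beads = if (length(bead_nodes))
      data.frame(arclength = s_real[bead_nodes],
                 nominal_arclength = spec$beads$arclength,
                 amplitude = spec$beads$amplitude, width = spec$beads$width)
    else data.frame(arclength = numeric(0), nominal_arclength = numeric(0),
                    amplitude = numeric(0), width = numeric(0)),
    branches = truth_branches,
    main_length = s_real[n_main],
    nominal_main_length = spec$main_length,
    main_end_id = n_main,
    soma_radius = spec$soma_radius)
  list(tree = neuron_tree(nodes), truth = truth)
}

#' Match detected events to planted ground truth
#'
#' Greedy nearest-first matching of detected to true event positions with
#' a tolerance; used by every recovery test and by the acceptance script.
#'
#' @param detected,truth Numeric vectors of positions (um).
#' @param tol Maximum |detected - truth| for a match, um.
#' @return List with `n_matched`, `false_pos` (unmatched detections) and
#'   `false_neg` (unmatched truths).
#' @export
match_events <- function(detected, truth, tol = 1) {
  used_d <- logical(length(detected))
  used_t <- logical(length(truth))
  if (length(detected) && length(truth)) {
    pairs <- expand.grid(d = seq_along(detected), t = seq_along(truth))
    pairs$dist <- abs(detected[pairs$d] - truth[pairs$t])
    pairs <- pairs[pairs$dist <= tol, , drop = FALSE]
    pairs <- pairs[order(pairs$dist), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      if (used_d[pairs$d[i]] || used_t[pairs$t[i]]) next
      used_d[pairs$d[i]] <- TRUE
      used_t[pairs$t[i]] <- TRUE
    }
  }
  list(n_matched = sum(used_t), false_pos = sum(!used_d),
       false_neg = sum(!used_t))
}

#' Render a neuron tree into a synthetic confocal stack
#'
#' Rasterizes every process as a tube (spheres swept along edges at the
#' node radii), blurs with an anisotropic Gaussian PSF, and adds Poisson
#' photon noise. The stack origin is chosen so the tree fits with a
#' padding margin; it is stored in the result so tree coordinates map to
#' voxels.
#'
#' @param tree A [neuron_tree()] (coordinates in um).
#' @param voxel_dims Voxel size (dx, dy, dz) in um.
#' @param psf_sigma Gaussian PSF sigma per axis, in voxels.
#' @param photon_scale Expected photon count inside the neuron; background
#'   is 2% of it. Larger values give higher SNR.
#' @param noise Add Poisson noise? `FALSE` returns the noiseless expected
#'   image.
#' @param pad Padding margin around the tree, um.
#' @param max_voxels Guard against runaway stack sizes.
#' @param seed RNG seed for the Poisson noise.
#' @return An `image_stack` (see [image_stack()]) with an `origin` field
#'   (um position of the voxel-(0,0,0) center).
#' @export
render_stack <- function(tree, voxel_dims = c(0.223, 0.223, 0.3),
                         psf_sigma = c(0.7, 0.7, 0.52), photon_scale = 100,
                         noise = TRUE, pad = 2, max_voxels = 2.5e7,
                         seed = 1) {
  nd <- tree$nodes
  lo <- c(min(nd$x - nd$radius), min(nd$y - nd$radius),
          min(nd$z - nd$radius)) - pad
  hi <- c(max(nd$x + nd$radius), max(nd$y + nd$radius),
          max(nd$z + nd$radius)) + pad
  dims <- ceiling((hi - lo) / voxel_dims) + 1L
  if (prod(dims) > max_voxels)
    stop("tree exceeds the rendering bounds (", prod(dims),
         " voxels); shrink the tree or raise max_voxels")
  vox <- array(0, dim = dims)
  # sample points along every edge at half the smallest voxel size
  step <- min(voxel_dims) / 2
  pidx <- match(nd$parent, nd$id)
  centers <- list()
  radii <- list()
  for (i in seq_len(nrow(nd))) {
    p1 <- c(nd$x[i], nd$y[i], nd$z[i])
    r1 <- nd$radius[i]
    if (is.na(pidx[i])) {
      centers[[length(centers) + 1L]] <- matrix(p1, 1L)
      radii[[length(radii) + 1L]] <- r1
      next
    }
    p0 <- c(nd$x[pidx[i]], nd$y[pidx[i]], nd$z[pidx[i]])
    r0 <- nd$radius[pidx[i]]
    len <- vec_norm(p1 - p0)
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    centers[[length(centers) + 1L]] <-
      cbind(p0[1L] + ts * (p1[1L] - p0[1L]),
            p0[2L] + ts * (p1[2L] - p0[2L]),
            p0[3L] + ts * (p1[3L] - p0[3L]))
    radii[[length(radii) + 1L]] <- r0 + ts * (r1 - r0)
  }
  centers <- do.call(rbind, centers)
  radii <- unlist(radii)
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    r <- radii[i]
    i0 <- pmax(floor((ctr - r - lo) / voxel_dims) + 1L, 1L)
    i1 <- pmin(ceiling((ctr + r - lo) / voxel_dims) + 1L, dims)
    xs <- lo[1L] + (i0[1L]:i1[1L] - 1L) * voxel_dims[1L] - ctr[1L]
    ys <- lo[2L] + (i0[2L]:i1[2L] - 1L) * voxel_dims[2L] - ctr[2L]
    zs <- lo[3L] + (i0[3L]:i1[3L] - 1L) * voxel_dims[3L] - ctr[3L]
    d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
    sub <- vox[i0[1L]:i1[1L], i0[2L]:i1[2L], i0[3L]:i1[3L]]
    sub[d2 <= r^2] <- 1
    vox[i0[1L]:i1[1L], i0[2L]:i1[2L], i0[3L]:i1[3L]] <- sub
  }
  lambda <- photon_scale * 0.02 + photon_scale * vox
  stk <- image_stack(lambda, voxel_dims, origin = lo)
  stk <- gaussian_smooth(stk, psf_sigma)
  if (noise)
    stk$voxels <- array(with_seed(seed,
                                  stats::rpois(length(stk$voxels),
                                               pmax(stk$voxels, 0))),
                        dim = dims)
  stk
}

#' Specification of a synthetic cohort
#'
#' Distribution-level description of a group of neurons, emulating the
#' age/genotype contrasts seen in aged touch receptor neurons: bend count
#' scales with a density, outgrowth counts are Poisson, outgrowth lengths
#' log-normal, and outgrowths can be coupled to bends (placed within
#' `coupling_dist` of a random bend with probability `coupling_p`) - the
#' generative knob the association test must detect.
#'
#' @param n_neurons Number of neurons.
#' @param main_length Main dendrite length, um.
#' @param bend_density Mean planted bends per um (day-8 wild-type dendrites
#'   show on the order of 0.1 per um).
#' @param bend_min_sep Minimum separation between planted bends, um.
#' @param bend_angle_range Range of planted interior angles, degrees.
#' @param outgrowth_mean Mean outgrowth count per neuron (Poisson).
#' @param outgrowth_length_meanlog,outgrowth_length_sdlog Log-normal
#'   parameters of outgrowth lengths, um.
#' @param coupling_p Probability that an outgrowth is planted next to a
#'   bend.
#' @param coupling_dist Maximum offset of a coupled outgrowth from its
#'   bend, um.
#' @param soma_radius Soma radius (um) or `NULL` (PLM-style).
#' @param node_spacing,coordinate_noise_sd Passed to [neuron_spec()].
#' @param seed RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_neurons = 19, main_length = 100,
                        bend_density = 0.1, bend_min_sep = 6,
                        bend_angle_range = c(100, 150), outgrowth_mean = 2,
                        outgrowth_length_meanlog = log(4),
                        outgrowth_length_sdlog = 0.5,
                        coupling_p = 0, coupling_dist = 0.5,
                        soma_radius = NULL, node_spacing = 0.25,
                        coordinate_noise_sd = 0.05, seed = 1) {
  stopifnot(n_neurons >= 1, coupling_p >= 0, coupling_p <= 1,
            bend_density >= 0, coupling_dist >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# Sample bend arclengths with a minimum separation by thinning.
sample_bend_positions <- function(n, main_length, min_sep, margin) {
  if (n == 0L) return(numeric(0))
  pos <- numeric(0)
  for (tries in seq_len(200L * n)) {
    cand <- stats::runif(1, margin, main_length - margin)
    if (!length(pos) || min(abs(pos - cand)) >= min_sep)
      pos <- c(pos, cand)
    if (length(pos) == n) break
  }
  sort(pos)
}

#' Generate a cohort of synthetic neurons
#'
#' @param spec A [cohort_spec()].
#' @return List of `list(tree, truth)` pairs as from [make_neuron()].
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_neurons), function(i) {
      n_b <- stats::rpois(1, spec$bend_density * spec$main_length)
      bp <- sample_bend_positions(n_b, spec$main_length, spec$bend_min_sep,
                                  margin = 5)
      bends <- if (length(bp))
        data.frame(arclength = bp,
                   angle = stats::runif(length(bp),
                                        spec$bend_angle_range[1L],
                                        spec$bend_angle_range[2L]))
      else NULL
      n_o <- stats::rpois(1, spec$outgrowth_mean)
      branches <- NULL
      if (n_o > 0L) {
        op <- vapply(seq_len(n_o), function(k) {
          if (length(bp) && stats::runif(1) < spec$coupling_p)
            min(max(bp[sample.int(length(bp), 1L)] +
                      stats::runif(1, -spec$coupling_dist,
                                   spec$coupling_dist), 2),
                spec$main_length - 2)
          else stats::runif(1, 2, spec$main_length - 2)
        }, numeric(1))
        branches <- data.frame(
          arclength = op,
          length = stats::rlnorm(n_o, spec$outgrowth_length_meanlog,
                                 spec$outgrowth_length_sdlog),
          label = "neuriteoutgrowth")
      }
      ns <- neuron_spec(main_length = spec$main_length,
                        node_spacing = spec$node_spacing,
                        bends = bends, branches = branches,
                        soma_radius = spec$soma_radius,
                        coordinate_noise_sd = spec$coordinate_noise_sd,
                        seed = stats::runif(1, 1, 2^30))
      make_neuron(ns)
    })
  })
}

#' Fast position-level cohort simulator
#'
#' Draws bend and outgrowth positions directly on the stretched 1D neuron,
#' skipping tree construction and detection. This is the efficient path
#' for calibration and power studies of the association test, where only
#' the point patterns matter; [make_cohort()] exercises the full pipeline.
#'
#' @param n_neurons Number of neurons.
#' @param main_length Neuron length, um.
#' @param bend_density Mean bends per um (minimum separation 4 um, the
#'   suppression radius of the bend detector).
#' @param outgrowth_mean Mean outgrowth count (Poisson, zero-truncated so
#'   every neuron enters the paired test).
#' @param coupling_p,coupling_dist As in [cohort_spec()].
#' @param seed RNG seed.
#' @return List of [event_positions()] objects.
#' @export
simulate_position_cohort <- function(n_neurons = 19, main_length = 100,
                                     bend_density = 0.1, outgrowth_mean = 2,
                                     coupling_p = 0, coupling_dist = 0.5,
                                     seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n_neurons), function(i) {
      n_b <- max(1L, stats::rpois(1, bend_density * main_length))
      bp <- sample_bend_positions(n_b, main_length, min_sep = 4, margin = 0)
      n_o <- max(1L, stats::rpois(1, outgrowth_mean))
      op <- vapply(seq_len(n_o), function(k) {
        if (stats::runif(1) < coupling_p)
          min(max(bp[sample.int(length(bp), 1L)] + stats::runif(1, -coupling_dist,
                                                coupling_dist), 0),
              main_length)
        else stats::runif(1, 0, main_length)
      }, numeric(1))
      event_positions(paste0("sim", i), bp, op, main_length)
    })
  })
}
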