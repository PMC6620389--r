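# ALM soma segmentation in 3D confocal stacks.
#
# The soma is segmented by seeded confidence-connected region growing:
# starting from the traced soma node, the region's intensity mean and SD
# are estimated, and a flood fill accepts voxels within mean +/-
# multiplier * SD; statistics and fill are iterated a few times. A
# morphological opening (ball structuring element in index space) removes
# thin attachments such as the dendrite, and the volume is the voxel count
# times the physical voxel volume.

#' Construct an image stack
#'
#' @param voxels 3D numeric array of intensities, indexed `[x, y, z]`.
#' @param voxel_dims Physical voxel size (dx, dy, dz), um.
#' @param origin Physical position (um) of the center of voxel (0,0,0);
#'   used to map tree coordinates into the stack.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_dims = c(0.223, 0.223, 0.3),
                        origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3L, all(voxel_dims > 0))
  structure(list(voxels = voxels,
                 voxel_dims = rep_len(as.numeric(voxel_dims), 3L),
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "image_stack")
}

#' Read a multi-page TIFF stack
#'
#' @param path Path to a grayscale multi-page TIFF (one page per z-slice).
#' @param voxel_dims Physical voxel size (dx, dy, dz), um.
#' @param origin Physical position of voxel (0,0,0), um.
#' @return An [image_stack()] indexed `[x, y, z]`.
#' @export
read_stack <- function(path, voxel_dims = c(0.223, 0.223, 0.3),
                       origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # readTIFF pages are [row = y, col = x]; stack as [x, y, z]
  vox <- array(0, dim = c(ncol(pages[[1L]]), nrow(pages[[1L]]),
                          length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- t(pages[[k]])
  image_stack(vox, voxel_dims, origin)
}

#' Write an image stack as multi-page TIFF
#'
#' Intensities are rescaled to the unit range and stored as 16-bit, so
#' absolute photon counts are not preserved (relative contrast is).
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  rng <- range(v)
  v <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0
  pages <- lapply(seq_len(dim(v)[3L]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

reflect_index <- function(idx, n) {
  # reflect-with-edge-repeat border handling: ... b a | a b c ... c | c b
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  # repeated reflection for kernels wider than the axis
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  }
  idx
}

convolve_axis <- function(a, kernel, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1L]
  m <- matrix(ap, nrow = n)
  out <- matrix(0, n, ncol(m))
  r <- (length(kernel) - 1L) %/% 2L
  for (t in seq_along(kernel)) {
    idx <- reflect_index(seq_len(n) + (t - r - 1L), n)
    out <- out + kernel[t] * m[idx, , drop = FALSE]
  }
  aperm(array(out, dim(ap)), order(perm))
}

#' Anisotropic Gaussian smoothing of a stack
#'
#' Separable Gaussian convolution with reflective borders; a per-axis sigma
#' of 0 leaves that axis untouched. The default sigma matches typical
#' pre-tracing denoising of confocal stacks.
#'
#' @param stack An [image_stack()].
#' @param sigma Per-axis Gaussian sigma in voxels.
#' @return A smoothed [image_stack()].
#' @export
gaussian_smooth <- function(stack, sigma = c(0.7, 0.7, 0.52)) {
  stopifnot(inherits(stack, "image_stack"))
  sigma <- rep_len(sigma, 3L)
  stopifnot(all(sigma >= 0))
  v <- stack$voxels
  for (axis in 1:3) {
    if (sigma[axis] == 0) next
    r <- max(1L, ceiling(4 * sigma[axis]))
    k <- stats::dnorm(-r:r, sd = sigma[axis])
    k <- k / sum(k)
    v <- convolve_axis(v, k, axis)
  }
  image_stack(v, stack$voxel_dims, stack$origin)
}

#' Segmentation parameters
#'
#' @param multiplier Acceptance half-width in region standard deviations.
#' @param iterations Number of mean/SD re-estimation passes.
#' @param init_radius Radius (voxels) of the initial seed neighbourhood.
#' @param opening_radius Radius (voxels) of the ball used for the
#'   morphological opening; 0 disables the opening.
#' @param blur_sigma Per-axis Gaussian pre-smoothing sigma, voxels.
#' @param boundary `"halfmax"` (default) refines the region-growing result
#'   to the connected half-intensity super-level set (midway between the
#'   region core and the background) before measuring volume. Because the
#'   point-spread function preserves an object's half-intensity surface,
#'   this removes the volume bias that a pure confidence band shows on
#'   blurred boundaries. `"confidence"` reports the raw region-growing
#'   mask.
#' @return A list of class `segment_config`.
#' @export
segment_config <- function(multiplier = 2.5, iterations = 4L,
                           init_radius = 1L, opening_radius = 1L,
                           blur_sigma = c(0.7, 0.7, 0.52),
                           boundary = c("halfmax", "confidence")) {
  stopifnot(multiplier > 0, iterations >= 1, init_radius >= 1,
            opening_radius >= 0, all(blur_sigma >= 0))
  structure(list(multiplier = multiplier, iterations = as.integer(iterations),
                 init_radius = as.integer(init_radius),
                 opening_radius = as.integer(opening_radius),
                 blur_sigma = rep_len(blur_sigma, 3L),
                 boundary = match.arg(boundary)),
            class = "segment_config")
}

# offsets (rows) within euclidean distance `r` in index space, center
# excluded when drop_center
ball_offsets <- function(r, drop_center = TRUE) {
  ri <- ceiling(r)
  g <- as.matrix(expand.grid(dx = -ri:ri, dy = -ri:ri, dz = -ri:ri))
  g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
  if (drop_center) g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g
}

# vectorized BFS flood fill over `accept` from seed voxel (1-based index
# triple), 26-connectivity
flood_fill <- function(accept, seed_idx, connectivity = 26L) {
  d <- dim(accept)
  offs <- if (connectivity == 26L) ball_offsets(1.8)
          else ball_offsets(1)
  visited <- array(FALSE, d)
  if (!accept[seed_idx[1L], seed_idx[2L], seed_idx[3L]]) return(visited)
  visited[seed_idx[1L], seed_idx[2L], seed_idx[3L]] <- TRUE
  frontier <- matrix(seed_idx, nrow = 1L)
  while (nrow(frontier)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
      sweep(frontier, 2L, offs[k, ], `+`)))
    ok <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
      cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
      cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
    cand <- cand[ok, , drop = FALSE]
    lin <- cand[, 1L] + d[1L] * (cand[, 2L] - 1L) +
      d[1L] * d[2L] * (cand[, 3L] - 1L)
    keep <- !visited[lin] & accept[lin]
    lin <- unique(lin[keep])
    visited[lin] <- TRUE
    frontier <- cbind(((lin - 1L) %% d[1L]) + 1L,
                      ((lin - 1L) %/% d[1L]) %% d[2L] + 1L,
                      (lin - 1L) %/% (d[1L] * d[2L]) + 1L)
  }
  visited
}

shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- list(seq_len(d[1L]) - off[1L], seq_len(d[2L]) - off[2L],
              seq_len(d[3L]) - off[3L])
  okx <- src[[1L]] >= 1L & src[[1L]] <= d[1L]
  oky <- src[[2L]] >= 1L & src[[2L]] <= d[2L]
  okz <- src[[3L]] >= 1L & src[[3L]] <= d[3L]
  out[okx, oky, okz] <- mask[src[[1L]][okx], src[[2L]][oky], src[[3L]][okz]]
  out
}

erode_mask <- function(mask, offs) {
  out <- mask
  for (k in seq_len(nrow(offs))) out <- out & shift_mask(mask, offs[k, ])
  out
}

dilate_mask <- function(mask, offs) {
  out <- mask
  for (k in seq_len(nrow(offs))) out <- out | shift_mask(mask, offs[k, ])
  out
}

open_mask <- function(mask, radius) {
  if (radius < 1L) return(mask)
  offs <- ball_offsets(radius)
  dilate_mask(erode_mask(mask, offs), offs)
}

#' Confidence-connected region growing
#'
#' Initializes the region as the seed neighbourhood, then iterates: compute
#' the region's intensity mean and SD, and flood-fill (26-connectivity)
#' from the seed accepting voxels within `multiplier` SDs of the mean.
#'
#' @param stack An [image_stack()].
#' @param seed 0-based voxel coordinates `c(x, y, z)` or a [seed_marker()].
#' @param cfg A [segment_config()].
#' @return Logical 3D mask.
#' @export
confidence_connected <- function(stack, seed, cfg = segment_config()) {
  stopifnot(inherits(stack, "image_stack"))
  if (inherits(seed, "seed_marker")) seed <- c(seed$x, seed$y, seed$z)
  d <- dim(stack$voxels)
  idx <- as.integer(round(seed)) + 1L
  if (any(idx < 1L) || any(idx > d))
    stop("seed lies outside the stack")
  v <- stack$voxels
  offs <- ball_offsets(cfg$init_radius, drop_center = FALSE)
  init <- sweep(offs, 2L, idx, `+`)
  ok <- init[, 1L] >= 1L & init[, 1L] <= d[1L] &
    init[, 2L] >= 1L & init[, 2L] <= d[2L] &
    init[, 3L] >= 1L & init[, 3L] <= d[3L]
  init <- init[ok, , drop = FALSE]
  lin <- init[, 1L] + d[1L] * (init[, 2L] - 1L) +
    d[1L] * d[2L] * (init[, 3L] - 1L)
  region_vals <- v[lin]
  mask <- NULL
  for (it in seq_len(cfg$iterations)) {
    mu <- mean(region_vals)
    sg <- stats::sd(region_vals)
    if (!is.finite(sg) || sg == 0) sg <- max(abs(mu), 1) * 1e-6
    accept <- v >= mu - cfg$multiplier * sg & v <= mu + cfg$multiplier * sg
    mask <- flood_fill(accept, idx)
    if (sum(mask) > 0.5 * prod(d))
      stop("segmentation overflow: region exceeds half the stack; ",
           "check the seed position and multiplier")
    region_vals <- v[mask]
    if (!length(region_vals)) region_vals <- v[lin]
  }
  mask
}

#' Segment the ALM soma and measure its volume
#'
#' Takes the soma node nearest the tree root as the seed, optionally
#' pre-smooths the stack, runs confidence-connected region growing,
#' applies a morphological opening to strip thin attachments (the
#' dendrite), and keeps the seed's connected component.
#'
#' @param stack An [image_stack()] covering the soma.
#' @param ct A `classified_tree` with soma-labelled nodes (from
#'   [classify_alm()]); may be `NULL` when `seed` is given directly.
#' @param cfg A [segment_config()].
#' @param smooth Apply `cfg$blur_sigma` Gaussian pre-smoothing (the default
#'   pipeline order)?
#' @param seed Optional explicit seed, 0-based voxel coordinates
#'   `c(x, y, z)`; overrides the soma-node lookup.
#' @return List of class `soma_segmentation`: `mask`, `seed` (0-based
#'   voxel), `voxel_count`, `volume` (um^3).
#' @export
segment_soma <- function(stack, ct = NULL, cfg = segment_config(),
                         smooth = TRUE, seed = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(seed)) {
    stopifnot(inherits(ct, "classified_tree"))
    soma_ids <- as.integer(names(ct$labels)[ct$labels == "soma"])
    if (!length(soma_ids)) stop("classified tree has no soma nodes")
    nd <- ct$tree$nodes
    root <- nd[match(ct$tree$root_id, nd$id), ]
    cand <- nd[match(soma_ids, nd$id), ]
    d2 <- (cand$x - root$x)^2 + (cand$y - root$y)^2 + (cand$z - root$z)^2
    seed_node <- cand[which.min(d2), ]
    seed_vox <- round((c(seed_node$x, seed_node$y, seed_node$z) -
                         stack$origin) / stack$voxel_dims)
  } else seed_vox <- round(seed)
  if (any(seed_vox < 0) || any(seed_vox > dim(stack$voxels) - 1L))
    stop("soma coordinates fall outside the stack")
  work <- if (smooth) gaussian_smooth(stack, cfg$blur_sigma) else stack
  mask <- confidence_connected(work, seed_vox, cfg)
  if (cfg$boundary == "halfmax") {
    # the confidence band tracks the statistically homogeneous core; the
    # unbiased boundary of a PSF-blurred object is its half-intensity
    # surface, so re-grow to the level midway between core and background
    v <- work$voxels
    idx0 <- as.integer(seed_vox) + 1L
    core <- if (any(mask)) stats::median(v[mask])
            else v[idx0[1L], idx0[2L], idx0[3L]]
    bg_zone <- !dilate_mask(mask, ball_offsets(3))
    bg <- if (any(bg_zone)) stats::median(v[bg_zone]) else 0
    accept <- v >= (core + bg) / 2
    idx <- as.integer(seed_vox) + 1L
    mask <- flood_fill(accept, idx)
  }
  mask <- open_mask(mask, cfg$opening_radius)
  idx <- as.integer(seed_vox) + 1L
  if (!mask[idx[1L], idx[2L], idx[3L]]) {
    # opening can nibble away the exact seed voxel; re-anchor at the
    # nearest surviving voxel
    on <- which(mask, arr.ind = TRUE)
    if (nrow(on) == 0L) stop("segmentation is empty after opening")
    dd <- rowSums(sweep(on, 2L, idx)^2)
    idx <- on[which.min(dd), ]
  }
  mask <- flood_fill(mask, idx)
  vol_voxel <- prod(stack$voxel_dims)
  structure(list(mask = mask, seed = as.integer(seed_vox),
                 voxel_count = sum(mask),
                 volume = sum(mask) * vol_voxel),
            class = "soma_segmentation")
}

#' @export
print.soma_segmentation <- function(x, ...) {
  cat(sprintf("<soma_segmentation> %d voxels, %.1f um^3, seed (%d, %d, %d)\n",
              x$voxel_count, x$volume, x$seed[1L], x$seed[2L], x$seed[3L]))
  invisible(x)
}

#' Brightest boundary voxel as a tracing seed
#'
#' Finds the maximal-intensity voxel among the six faces of the stack (the
#' location where a dendrite enters the imaging field of view) for use as
#' a tracing root; ties break towards the lexicographically smallest
#' (x, y, z).
#'
#' @param stack An [image_stack()].
#' @return A [seed_marker()] with 0-based voxel coordinates.
#' @export
find_boundary_seed <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  boundary <- array(FALSE, d)
  boundary[c(1L, d[1L]), , ] <- TRUE
  boundary[, c(1L, d[2L]), ] <- TRUE
  boundary[, , c(1L, d[3L])] <- TRUE
  vals <- v[boundary]
  mx <- max(vals)
  hits <- which(boundary & v == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L], hits[, 3L]), , drop = FALSE]
  seed_marker(unname(hits[1L, 1L]) - 1L, unname(hits[1L, 2L]) - 1L,
              unname(hits[1L, 3L]) - 1L, comment = "boundary seed")
}
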