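# Shared fixture builders and independent oracles.

# A straight chain tree along given points (n x 3 matrix), constant radius.
chain_tree <- function(pts, radius = 0.5) {
  n <- nrow(pts)
  neuron_tree(data.frame(id = seq_len(n), type = 3L,
                         x = pts[, 1], y = pts[, 2], z = pts[, 3],
                         radius = radius,
                         parent = c(-1L, seq_len(n - 1L))))
}

# Planar polyline with one corner of the given interior angle: two straight
# arms of `arm` um at `spacing` um node spacing, apex at the origin.
corner_polyline <- function(angle_deg, arm = 5, spacing = 0.2) {
  t1 <- seq(arm, spacing, by = -spacing)
  a <- angle_deg * pi / 180
  d2 <- c(cos(pi - a), sin(pi - a), 0)   # second arm direction
  t2 <- seq(spacing, arm, by = spacing)
  rbind(cbind(-t1, 0, 0), c(0, 0, 0),
        cbind(t2 * d2[1], t2 * d2[2], 0))
}

# Uniformly random 3D rotation matrix (caller controls the RNG state).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(pts, rot, shift = c(0, 0, 0)) {
  sweep(pts %*% t(rot), 2, shift, `+`)
}

rotate_tree <- function(tree, rot, shift = c(0, 0, 0)) {
  p <- apply_rigid(as.matrix(tree$nodes[, c("x", "y", "z")]), rot, shift)
  tree$nodes$x <- p[, 1]; tree$nodes$y <- p[, 2]; tree$nodes$z <- p[, 3]
  tree
}

# Independent NMS oracle: full greedy recomputation from scratch at every
# step (rescan all survivors, pick the strongest, drop its neighbourhood).
nms_oracle <- function(arclength, strength, window) {
  alive <- rep(TRUE, length(arclength))
  picked <- integer(0)
  repeat {
    cand <- which(alive)
    if (!length(cand)) break
    ord <- cand[order(-strength[cand], arclength[cand])]
    best <- ord[1L]
    picked <- c(picked, best)
    alive[abs(arclength - arclength[best]) <= window] <- FALSE
  }
  sort(picked)
}

# Exhaustive signed-rank null: enumerate all 2^n sign patterns.
signed_rank_enumerate <- function(d, w_obs) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    sum(r[signs])
  }, numeric(1))
  mean(ws >= w_obs)
}
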