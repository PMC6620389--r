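test_that("windowed angles: straight lines are 180, corners recover their angle", {
  straight <- cbind(seq(0, 10, by = 0.2), 0, 0)
  ang <- node_angles(straight, window = 2)
  defined <- ang[!is.na(ang)]
  expect_gt(length(defined), 10)
  expect_true(all(abs(defined - 180) < 1e-6))

  for (a in c(90, 120, 150)) {
    # spacing chosen off the window grid so no node sits exactly on the
    # 2 um window edge (floating-point knife edge under rotation)
    pts <- corner_polyline(a, arm = 5, spacing = 0.19)
    ang <- node_angles(pts, window = 2)
    apex <- which.min(ang)
    expect_equal(ang[apex], a, tolerance = 1)
    # rigid rotation leaves the angles unchanged
    set.seed(a)
    rpts <- apply_rigid(pts, random_rotation(), c(3, -7, 2))
    expect_equal(node_angles(rpts, window = 2), ang, tolerance = 1e-6)
  }
})

test_that("boundary and degenerate nodes get undefined angles", {
  pts <- cbind(seq(0, 10, by = 0.5), 0, 0)
  ang <- node_angles(pts, window = 2)
  s <- seq(0, 10, by = 0.5)
  expect_true(all(is.na(ang[s < 2 | s > 8])))
  expect_error(node_angles(pts[1:2, , drop = FALSE]), "at least 3")
})

test_that("bend detection applies threshold and suppression as specified", {
  straight <- cbind(seq(0, 20, by = 0.2), 0, 0)
  expect_equal(nrow(detect_bends(straight)), 0L)

  one <- corner_polyline(150, arm = 6, spacing = 0.2)
  expect_equal(nrow(detect_bends(one, morph_config(bend_threshold = 155))), 1L)
  expect_equal(nrow(detect_bends(one, morph_config(bend_threshold = 145))), 0L)

  # two 120-degree corners: 3 um apart -> one survives; 6 um apart -> both
  two_corners <- function(sep) {
    nt <- make_neuron(neuron_spec(
      main_length = 30, node_spacing = 0.2,
      bends = data.frame(arclength = c(12, 12 + sep), angle = 120),
      coordinate_noise_sd = 0, seed = 5))
    main_branch_geometry(classify_plm(nt$tree))
  }
  expect_equal(nrow(detect_bends(two_corners(3))), 1L)
  expect_equal(nrow(detect_bends(two_corners(6))), 2L)
})

test_that("sequential suppression equals the from-scratch greedy oracle", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    s <- sort(runif(n, 0, 60))
    strength <- runif(n)
    got <- neuritemorph:::nms_select(s, strength, window = 4)
    want <- nms_oracle(s, strength, window = 4)
    expect_identical(got, want)
  }
})

test_that("reported events are pairwise separated by more than the window", {
  for (seed in 1:5) {
    nt <- make_neuron(neuron_spec(
      main_length = 100,
      bends = data.frame(arclength = seq(10, 90, by = 8),
                         angle = runif(11, 100, 150)),
      seed = seed))
    ev <- detect_bends(main_branch_geometry(classify_plm(nt$tree)))
    if (nrow(ev) > 1L)
      expect_gt(min(diff(sort(ev$arclength))), 4)
  }
})

test_that("bend density and the threshold sweep behave as documented", {
  expect_equal(bend_density(data.frame(x = 1:5), 100), 0.05)
  expect_equal(bend_density(data.frame(), 100), 0)
  expect_error(bend_density(data.frame(), 0), "positive")

  # corners at exactly 150 degrees: zero density below, positive above
  nt <- make_neuron(neuron_spec(
    main_length = 60, bends = data.frame(arclength = c(20, 40), angle = 150),
    coordinate_noise_sd = 0, seed = 2))
  g <- main_branch_geometry(classify_plm(nt$tree))
  sw <- threshold_sweep(g, thresholds = c(135, 145, 149, 152, 160))
  expect_equal(sw$count, c(0, 0, 0, 2, 2))

  # monotonicity on noisy branches
  for (seed in 1:5) {
    nt <- make_neuron(neuron_spec(
      main_length = 80,
      bends = data.frame(arclength = c(15, 35, 55, 70),
                         angle = c(100, 130, 145, 158)),
      seed = seed))
    sw <- threshold_sweep(main_branch_geometry(classify_plm(nt$tree)),
                          thresholds = seq(135, 165, by = 5))
    expect_true(all(diff(sw$density) >= 0))
  }
  # straight branch: zero everywhere
  nt0 <- make_neuron(neuron_spec(main_length = 40, coordinate_noise_sd = 0,
                                 seed = 1))
  sw0 <- threshold_sweep(main_branch_geometry(classify_plm(nt0$tree)))
  expect_true(all(sw0$density == 0))
})

test_that("local thickness residual matches a brute-force windowed mean", {
  s <- seq(0, 50, by = 0.37)  # irregular-ish spacing via trig jitter
  s <- s + 0.08 * sin(seq_along(s))
  s <- sort(s)
  r <- 0.5 + 0.1 * cos(s / 3)
  res <- local_thickness_residual(r, s, window = 8)
  brute <- vapply(seq_along(s), function(i)
    r[i] - mean(r[abs(s - s[i]) <= 4]), numeric(1))
  expect_equal(res, brute, tolerance = 1e-12)

  # constant radius: zero residual
  expect_equal(local_thickness_residual(rep(0.5, 40), seq(0, 20, length = 40)),
               rep(0, 40))
  # single bump among dense constant neighbours
  s2 <- seq(0, 40, by = 0.2)
  r2 <- rep(0.5, length(s2))
  r2[101] <- 1.5
  res2 <- local_thickness_residual(r2, s2, window = 8)
  expect_equal(res2[101], 1 - 1 / 41, tolerance = 1e-10)
  # linear taper cancels in the symmetric interior window, up to one-node
  # window asymmetry at floating-point grid edges (slope * spacing / 2)
  r3 <- 0.8 - 0.01 * s2
  res3 <- local_thickness_residual(r3, s2, window = 8)
  interior <- s2 > 4 & s2 < 36
  expect_lt(max(abs(res3[interior])), 2e-3)
})

test_that("bead detection recovers planted bumps and respects suppression", {
  g_const <- data.frame(node_id = 1:60, x = (0:59) * 0.5, y = 0, z = 0,
                        radius = 0.5, arclength = (0:59) * 0.5)
  expect_equal(nrow(detect_beads(g_const)), 0L)
  expect_error(detect_beads(g_const[1:2, ]), "at least 3")

  total <- 0L
  for (seed in 1:10) {
    nt <- make_neuron(neuron_spec(
      main_length = 100,
      beads = data.frame(arclength = c(20, 50, 80), amplitude = 0.3,
                         width = 0.8),
      radius_noise_sd = 0.03, seed = seed))
    g <- main_branch_geometry(classify_plm(nt$tree))
    ev <- detect_beads(g)
    m <- match_events(ev$arclength, nt$truth$beads$arclength, tol = 1)
    total <- total + m$n_matched
    expect_equal(m$false_pos, 0L)
  }
  expect_gte(total / 30, 0.95)

  # two bumps 2 um apart with 4 um suppression merge into one event
  nt2 <- make_neuron(neuron_spec(
    main_length = 40,
    beads = data.frame(arclength = c(19, 21), amplitude = 0.4, width = 0.6),
    radius_noise_sd = 0.02, coordinate_noise_sd = 0, seed = 3))
  ev2 <- detect_beads(main_branch_geometry(classify_plm(nt2$tree)))
  expect_equal(nrow(ev2), 1L)
})

test_that("events are stable under rigid motion and orientation reversal", {
  nt <- make_neuron(neuron_spec(
    main_length = 60,
    bends = data.frame(arclength = c(15, 35, 50), angle = c(110, 130, 145)),
    beads = data.frame(arclength = 25, amplitude = 0.35, width = 0.8),
    seed = 12))
  g <- main_branch_geometry(classify_plm(nt$tree))
  bends <- detect_bends(g)
  beads <- detect_beads(g)

  set.seed(7)
  rot <- random_rotation()
  g2 <- g
  p2 <- apply_rigid(as.matrix(g[, c("x", "y", "z")]), rot, c(1, 2, 3))
  g2$x <- p2[, 1]; g2$y <- p2[, 2]; g2$z <- p2[, 3]
  expect_equal(detect_bends(g2)$arclength, bends$arclength,
               tolerance = 1e-9)
  expect_equal(detect_bends(g2)$angle, bends$angle, tolerance = 1e-6)

  # reversal: same events at mirrored arclengths
  L <- max(g$arclength)
  g3 <- g[rev(seq_len(nrow(g))), ]
  g3$arclength <- L - g3$arclength
  b3 <- detect_bends(g3)
  expect_equal(sort(L - b3$arclength), sort(bends$arclength),
               tolerance = 1e-9)
  bd3 <- detect_beads(g3)
  expect_equal(sort(L - bd3$arclength), sort(beads$arclength),
               tolerance = 1e-9)
})

test_that("spline curvature reproduces analytic geometry and smoothing damps it", {
  line <- cbind(seq(0, 10, by = 0.1), 0, 0)
  expect_lt(max(spline_curvature(line)$curvature), 1e-6)

  th <- seq(0, 1.5 * pi, length.out = 400)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  sc <- spline_curvature(circ, smoothing = 0)
  interior <- sc$arclength > 2 & sc$arclength < max(sc$arclength) - 2
  expect_equal(mean(sc$curvature[interior]), 0.1, tolerance = 0.005)

  nt <- make_neuron(neuron_spec(
    main_length = 40, bends = data.frame(arclength = 20, angle = 120),
    seed = 4))
  g <- main_branch_geometry(classify_plm(nt$tree))
  maxima <- vapply(c(0, 1e-4, 1e-2, 1), function(s)
    max(spline_curvature(g, smoothing = s)$curvature), numeric(1))
  expect_true(all(diff(maxima) <= 1e-6 + 0.05 * maxima[-length(maxima)]))
})
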