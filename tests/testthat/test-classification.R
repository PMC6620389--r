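test_that("endpoint path lengths are arclengths, matching a graph oracle", {
  expect_equal(unname(endpoint_path_lengths(chain_tree(cbind(0:2, 0, 0)))),
               2)
  bent <- chain_tree(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(unname(endpoint_path_lengths(bent)), 2)  # arclength, not chord

  skip_if_not_installed("igraph")
  nt <- make_neuron(neuron_spec(
    main_length = 40, node_spacing = 0.5,
    branches = data.frame(arclength = c(10, 25), length = c(5, 9),
                          label = "neuriteoutgrowth"),
    seed = 14))
  nd <- nt$tree$nodes
  epl <- endpoint_path_lengths(nt$tree)
  nonroot <- nd$parent != -1
  w <- sqrt((nd$x[nonroot] - nd$x[match(nd$parent[nonroot], nd$id)])^2 +
              (nd$y[nonroot] - nd$y[match(nd$parent[nonroot], nd$id)])^2 +
              (nd$z[nonroot] - nd$z[match(nd$parent[nonroot], nd$id)])^2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(nd$parent[nonroot]),
               to = as.character(nd$id[nonroot]), weight = w),
    directed = FALSE)
  d <- igraph::distances(g, v = as.character(nt$tree$root_id))
  expect_equal(unname(epl), unname(d[1, names(epl)]), tolerance = 1e-10)
})

test_that("main branch is the longest endpoint path with smallest-id tie-break", {
  # Y-tree: arms 10 um and 7 um
  nodes <- data.frame(
    id = 1:18, type = 3L,
    x = c(0:10, 1:7), y = c(rep(0, 11), 1:7), z = 0, radius = 0.5,
    parent = c(-1L, 1:10, 1L, 12:17))
  y <- neuron_tree(nodes)
  expect_equal(find_main_branch(y), 1:11)
  # equal 10 um arms: endpoints 11 and 21 tie, smaller id wins
  eq <- neuron_tree(data.frame(
    id = 1:21, type = 3L,
    x = c(0:10, -(1:10)), y = 0, z = 0, radius = 0.5,
    parent = c(-1L, 1:10, 1L, 12:20)))
  expect_equal(find_main_branch(eq), 1:11)
  expect_error(find_main_branch(chain_tree(cbind(0, 0, 0))), "single-node")
})

test_that("planted main path is recovered against short side branches", {
  nt <- make_neuron(neuron_spec(
    main_length = 120, node_spacing = 0.5,
    branches = data.frame(arclength = c(20, 50, 90),
                          length = c(20, 15, 10),
                          label = "neuriteoutgrowth"),
    seed = 31))
  mb <- find_main_branch(nt$tree)
  expect_equal(mb, seq_len(nt$truth$main_end_id))
})

test_that("ALM classification finds soma, soma outgrowths and neurite outgrowths", {
  nt <- make_neuron(neuron_spec(
    main_length = 15, soma_radius = 3,
    branches = data.frame(arclength = c(NA, NA, 8), length = c(4, 4, 3),
                          label = c("somaoutgrowth", "somaoutgrowth",
                                    "neuriteoutgrowth")),
    seed = 8))
  ct <- classify_alm(nt$tree)
  inv <- branch_inventory(ct)
  so <- inv[inv$label == "somaoutgrowth", ]
  expect_equal(nrow(so), 2L)
  expect_equal(sum(inv$label == "neuriteoutgrowth"), 1L)
  truth_so <- nt$truth$branches[nt$truth$branches$label == "somaoutgrowth", ]
  expect_equal(sort(so$length_um), sort(truth_so$length),
               tolerance = 0.13)  # half a node spacing on 0.25 um spacing
  # no side branches
  plain <- make_neuron(neuron_spec(main_length = 15, soma_radius = 3,
                                   seed = 9))
  inv0 <- branch_inventory(classify_alm(plain$tree))
  expect_equal(nrow(inv0), 0L)
  # all radii below threshold
  thin <- make_neuron(neuron_spec(main_length = 15, seed = 10))
  expect_error(classify_alm(thin$tree), "no soma found")
})

test_that("multi-node soma is a connected large-radius set containing the root", {
  # root + 2 more soma nodes + dendrite + stub off the last soma node
  nodes <- data.frame(
    id = 1:13, type = 3L,
    x = c(0, 1, 2, seq(1, 8, by = 1) + 2, 2.5, 3.0),
    y = c(0, 0, 0, rep(0, 8), 1, 2),
    z = 0,
    radius = c(3, 3, 3, rep(0.4, 8), 0.4, 0.4),
    parent = c(-1L, 1L, 2L, 3L, 4:10, 3L, 12L))
  ct <- classify_alm(neuron_tree(nodes))
  # soma nodes sit at the root end of the main branch and stay labelled soma
  expect_setequal(names(ct$labels)[ct$labels == "soma"], as.character(1:3))
  expect_equal(unname(ct$labels[["12"]]), "somaoutgrowth")
  expect_equal(unname(ct$labels[["13"]]), "somaoutgrowth")
})

test_that("PLM classification disambiguates PVM and honours manual labels", {
  nt <- make_neuron(neuron_spec(
    main_length = 100,
    branches = data.frame(
      arclength = c(30, 32, 50),
      length = c(8, 3, 5),
      label = c("pvm", "neuriteoutgrowth", "neuriteoutgrowth")),
    seed = 7))
  ct <- classify_plm(nt$tree)
  inv <- branch_inventory(ct)
  # the large-radius branch and its 2 um neighbour are pvm; the branch
  # 20 um away stays a neurite outgrowth
  expect_equal(sum(inv$label == "pvm"), 2L)
  expect_equal(sum(inv$label == "neuriteoutgrowth"), 1L)
  expect_equal(inv$attachment_um[inv$label == "neuriteoutgrowth"],
               nt$truth$branches$attachment_arclength[3], tolerance = 1e-6)

  # no large-radius side branch: everything is a neurite outgrowth
  nt2 <- make_neuron(neuron_spec(
    main_length = 60,
    branches = data.frame(arclength = c(20, 40), length = c(4, 6),
                          label = "neuriteoutgrowth"),
    seed = 17))
  inv2 <- branch_inventory(classify_plm(nt2$tree))
  expect_equal(inv2$label, rep("neuriteoutgrowth", 2))

  # reserved structure code 7 marks a manual VNC connection
  nt3 <- make_neuron(neuron_spec(
    main_length = 60,
    branches = data.frame(arclength = c(20, 40), length = c(4, 6),
                          label = "neuriteoutgrowth"),
    seed = 18))
  nd <- nt3$tree$nodes
  first_branch_ids <- nd$id[nd$id > nt3$truth$main_end_id][1:16]
  nd$type[nd$id %in% first_branch_ids[1]] <- 7L
  ct3 <- classify_plm(neuron_tree(nd))
  inv3 <- branch_inventory(ct3)
  expect_equal(sum(inv3$label == "vnc_connection"), 1L)
  expect_equal(sum(inv3$label == "neuriteoutgrowth"), 1L)
})

test_that("labels partition the nodes and are isometry invariant", {
  nt <- make_neuron(neuron_spec(
    main_length = 80,
    branches = data.frame(arclength = c(25, 27, 60), length = c(7, 3, 5),
                          label = c("pvm", "neuriteoutgrowth",
                                    "neuriteoutgrowth")),
    seed = 23))
  ct <- classify_plm(nt$tree)
  expect_equal(length(ct$labels), nrow(nt$tree$nodes))
  expect_true(all(ct$labels %in% c("mainbranch", "soma", "neuriteoutgrowth",
                                   "somaoutgrowth", "pvm", "vnc_connection",
                                   "blob_artifact")))
  set.seed(5)
  rot <- random_rotation()
  ct2 <- classify_plm(rotate_tree(nt$tree, rot, c(5, -3, 11)))
  expect_identical(ct2$labels, ct$labels)
  expect_equal(ct2$main_length, ct$main_length, tolerance = 1e-9)
  expect_equal(branch_inventory(ct2)$length_um,
               branch_inventory(ct)$length_um, tolerance = 1e-9)
})
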