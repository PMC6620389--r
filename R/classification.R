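# Compartment classification of traced ALM/PLM trees.
#
# Every node of a traced tree is assigned one of seven labels:
# mainbranch, soma, neuriteoutgrowth, somaoutgrowth, pvm, vnc_connection,
# blob_artifact. The main branch is the longest root-to-endpoint path
# (the sensory dendrite); the ALM soma is the connected set of
# large-radius nodes around the root; on PLM traces a large-radius side
# branch marks an accidentally co-traced PVM neuron. VNC connections and
# blob artifacts are carried as reserved SWC type codes written by manual
# editors and are never inferred automatically.

NODE_LABELS <- c("mainbranch", "soma", "neuriteoutgrowth", "somaoutgrowth",
                 "pvm", "vnc_connection", "blob_artifact")
VNC_TYPE_CODE <- 7L
BLOB_TYPE_CODE <- 8L

#' Classification thresholds
#'
#' @param soma_radius_threshold Radius (um) above which a traced node is
#'   considered somatic. Typical dendrite radii are 0.3-0.8 um and soma
#'   radii 2.5-4 um, so the default 2 separates them cleanly; re-tune per
#'   dataset if tracing radii are calibrated differently.
#' @param pvm_window Arclength half-window (um) around a detected PVM
#'   attachment point: side branches attaching within +/- this window are
#'   also labelled `pvm`.
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(soma_radius_threshold = 2, pvm_window = 4) {
  stopifnot(soma_radius_threshold > 0, pvm_window > 0)
  structure(list(soma_radius_threshold = soma_radius_threshold,
                 pvm_window = pvm_window),
            class = "classify_config")
}

# Internal geometry table: nodes in topological order with the edge length
# to the parent and cumulative path length from the root.
tree_geometry <- function(tree) {
  nd <- tree$nodes
  ord <- order_topological(tree)
  nd <- nd[ord, , drop = FALSE]
  pidx <- match(nd$parent, nd$id)  # position of parent within nd; NA for root
  edge <- numeric(nrow(nd))
  nonroot <- !is.na(pidx)
  edge[nonroot] <- sqrt((nd$x[nonroot] - nd$x[pidx[nonroot]])^2 +
                        (nd$y[nonroot] - nd$y[pidx[nonroot]])^2 +
                        (nd$z[nonroot] - nd$z[pidx[nonroot]])^2)
  plen <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))[-1L]) plen[i] <- plen[pidx[i]] + edge[i]
  nd$edge_length <- edge
  nd$path_length <- plen
  nd$parent_idx <- pidx
  nd
}

#' Root-to-endpoint path lengths
#'
#' For every endpoint (degree-1 non-root node) returns the arclength of the
#' unique path to the root, i.e. the sum of Euclidean distances between
#' consecutive nodes.
#'
#' @param tree A [neuron_tree()].
#' @return Named numeric vector (um), names are endpoint node ids.
#' @export
endpoint_path_lengths <- function(tree) {
  tree <- validate_neuron_tree(tree)
  g <- tree_geometry(tree)
  is_end <- !(g$id %in% g$parent) & g$parent != -1
  stats::setNames(g$path_length[is_end], g$id[is_end])
}

#' Find the main branch (sensory dendrite)
#'
#' The main branch is the root-to-endpoint path of maximal arclength; ties
#' are broken towards the smallest endpoint id.
#'
#' @param tree A [neuron_tree()].
#' @return Integer vector of node ids, ordered root to distal endpoint.
#' @export
find_main_branch <- function(tree) {
  tree <- validate_neuron_tree(tree)
  if (nrow(tree$nodes) < 2L)
    stop("main branch undefined for a single-node tree")
  lens <- endpoint_path_lengths(tree)
  ids <- as.integer(names(lens))
  best <- ids[lens == max(lens)]
  endpoint <- min(best)
  # walk parents back to the root
  nd <- tree$nodes
  path <- integer(0)
  cur <- endpoint
  while (cur != -1) {
    path <- c(path, cur)
    cur <- nd$parent[match(cur, nd$id)]
  }
  rev(path)
}

# Decompose the tree into side subtrees hanging off a backbone id set.
# Returns a list of lists(attachment_id, ids) where ids excludes the
# attachment node; each subtree is reported once, rooted at the child of a
# backbone node.
side_subtrees <- function(tree, backbone_ids) {
  nd <- tree$nodes
  kids <- split(nd$id, factor(nd$parent, levels = nd$id))
  out <- list()
  for (a in backbone_ids) {
    for (c0 in kids[[as.character(a)]]) {
      if (c0 %in% backbone_ids) next
      # BFS over the subtree rooted at c0
      ids <- c0
      frontier <- c0
      while (length(frontier)) {
        nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
        frontier <- nxt
        ids <- c(ids, nxt)
      }
      out[[length(out) + 1L]] <- list(attachment_id = a, ids = ids)
    }
  }
  out
}

# Shared branch bookkeeping: builds the per-branch table and per-node labels
# for a list of side subtrees with assigned labels.
build_classified <- function(tree, main_ids, soma_ids, subtrees, sub_labels,
                             neuron_class) {
  g <- tree_geometry(tree)
  labels <- stats::setNames(rep("mainbranch", nrow(g)), g$id)
  labels[as.character(intersect(soma_ids, g$id))] <- "soma"
  labels[as.character(main_ids)] <- "mainbranch"
  labels[as.character(intersect(main_ids, soma_ids))] <- "soma"
  main_arclen <- stats::setNames(g$path_length[match(main_ids, g$id)],
                                 main_ids)
  main_length <- sum(g$edge_length[match(main_ids[-1L], g$id)])
  branches <- data.frame(branch_id = integer(0), label = character(0),
                         length_um = numeric(0), attachment_id = integer(0),
                         attachment_um = numeric(0), n_nodes = integer(0))
  for (i in seq_along(subtrees)) {
    st <- subtrees[[i]]
    labels[as.character(st$ids)] <- sub_labels[i]
    # cable length: all subtree edges plus the edge joining the attachment
    len <- sum(g$edge_length[match(st$ids, g$id)])
    att_um <- if (st$attachment_id %in% main_ids)
      unname(main_arclen[as.character(st$attachment_id)]) else NA_real_
    branches <- rbind(branches, data.frame(
      branch_id = i, label = sub_labels[i], length_um = len,
      attachment_id = st$attachment_id, attachment_um = att_um,
      n_nodes = length(st$ids)))
  }
  structure(list(tree = tree, labels = labels, main_branch = main_ids,
                 neuron_class = neuron_class, branches = branches,
                 main_length = main_length),
            class = "classified_tree")
}

# Apply reserved manual-annotation type codes to side subtrees.
manual_label <- function(tree, subtree) {
  types <- tree$nodes$type[match(subtree$ids, tree$nodes$id)]
  if (any(types == VNC_TYPE_CODE)) return("vnc_connection")
  if (any(types == BLOB_TYPE_CODE)) return("blob_artifact")
  NA_character_
}

#' Classify an ALM neuron tree
#'
#' The soma is the maximal connected set of nodes containing the root whose
#' radii exceed the soma radius threshold (ALM traces are rooted inside the
#' soma by the tracer's soma detection). The main branch is the longest
#' root-to-endpoint path. Side branches attached to soma nodes are soma
#' outgrowths; side branches attached to main-branch nodes are neurite
#' outgrowths. Reserved SWC type codes 7/8 mark manually annotated VNC
#' connections and blob artifacts.
#'
#' @param tree A [neuron_tree()].
#' @param cfg A [classify_config()].
#' @return A `classified_tree`: the tree plus per-node labels, the main
#'   branch path, and a branch inventory table.
#' @export
classify_alm <- function(tree, cfg = classify_config()) {
  tree <- validate_neuron_tree(tree)
  nd <- tree$nodes
  if (!any(nd$radius > cfg$soma_radius_threshold))
    stop("no soma found: no node radius exceeds ",
         cfg$soma_radius_threshold, " um")
  # connected large-radius set containing the root
  big <- nd$id[nd$radius > cfg$soma_radius_threshold]
  adj <- adjacency_list(tree)
  soma_ids <- tree$root_id
  frontier <- tree$root_id
  while (length(frontier)) {
    nb <- setdiff(unlist(adj[as.character(frontier)], use.names = FALSE),
                  soma_ids)
    nb <- nb[nb %in% big]
    soma_ids <- c(soma_ids, nb)
    frontier <- nb
  }
  if (length(soma_ids) == 1L && !(tree$root_id %in% big))
    stop("no soma found: root is not connected to any large-radius node")
  main_ids <- find_main_branch(tree)
  backbone <- union(main_ids, soma_ids)
  subtrees <- side_subtrees(tree, backbone)
  labs <- vapply(subtrees, function(st) {
    ml <- manual_label(tree, st)
    if (!is.na(ml)) return(ml)
    if (st$attachment_id %in% soma_ids) "somaoutgrowth" else "neuriteoutgrowth"
  }, character(1))
  ct <- build_classified(tree, main_ids, soma_ids, subtrees, labs, "ALM")
  ct
}

#' Classify a PLM neuron tree
#'
#' The root is the dendrite's entry point into the field of view (from the
#' boundary seed marker); the main branch is the longest root-to-endpoint
#' path. PLM traces often accidentally include part of the crossing PVM
#' neuron: any side branch containing a node above the soma radius
#' threshold is taken as the PVM (its soma), and every side branch
#' attaching within the PVM arclength window of its attachment point is
#' labelled `pvm` too. If several side branches carry large-radius nodes,
#' the one with the single largest radius wins and the others fall through
#' to `neuriteoutgrowth` (with a message). Remaining side branches are
#' neurite outgrowths with recorded length and attachment position; type
#' codes 7/8 mark manual VNC-connection/blob annotations, which are
#' excluded from outgrowth counts.
#'
#' @inheritParams classify_alm
#' @return A `classified_tree`.
#' @export
classify_plm <- function(tree, cfg = classify_config()) {
  tree <- validate_neuron_tree(tree)
  main_ids <- find_main_branch(tree)
  subtrees <- side_subtrees(tree, main_ids)
  g <- tree_geometry(tree)
  main_arclen <- stats::setNames(g$path_length[match(main_ids, g$id)],
                                 main_ids)
  labs <- vapply(subtrees, function(st) {
    ml <- manual_label(tree, st)
    if (is.na(ml)) "neuriteoutgrowth" else ml
  }, character(1))
  # PVM: side branch holding the largest above-threshold radius
  max_r <- vapply(subtrees, function(st)
    max(g$radius[match(st$ids, g$id)]), numeric(1))
  eligible <- which(max_r > cfg$soma_radius_threshold &
                      labs == "neuriteoutgrowth")
  if (length(eligible)) {
    pvm_idx <- eligible[which.max(max_r[eligible])]
    if (length(eligible) > 1L)
      message("multiple large-radius side branches; only the largest ",
              "is labelled pvm")
    t0 <- main_arclen[as.character(subtrees[[pvm_idx]]$attachment_id)]
    att <- vapply(subtrees, function(st)
      unname(main_arclen[as.character(st$attachment_id)]), numeric(1))
    near <- which(abs(att - t0) <= cfg$pvm_window & labs == "neuriteoutgrowth")
    labs[union(pvm_idx, near)] <- "pvm"
  }
  build_classified(tree, main_ids, integer(0), subtrees, labs, "PLM")
}

adjacency_list <- function(tree) {
  nd <- tree$nodes
  nonroot <- nd$parent != -1
  edges <- data.frame(a = nd$id[nonroot], b = nd$parent[nonroot])
  both <- rbind(edges, data.frame(a = edges$b, b = edges$a))
  split(both$b, factor(both$a, levels = nd$id))
}

#' Branch inventory of a classified tree
#'
#' One row per side branch with its label, cable length and the arclength
#' of its attachment node along the main branch (measured from the root-side
#' end; `NA` for branches attached inside the soma). The total main-branch
#' length is attached as the `main_length` attribute.
#'
#' @param ct A `classified_tree` from [classify_alm()] or [classify_plm()].
#' @return Data frame with columns `branch_id`, `label`, `length_um`,
#'   `attachment_id`, `attachment_um`, `n_nodes`.
#' @export
branch_inventory <- function(ct) {
  stopifnot(inherits(ct, "classified_tree"))
  out <- ct$branches
  attr(out, "main_length") <- ct$main_length
  out
}

#' Geometry of the classified main branch
#'
#' @param ct A `classified_tree`.
#' @return Data frame (one row per main-branch node, root end first) with
#'   columns `node_id`, `x`, `y`, `z`, `radius`, `arclength` (um from the
#'   root-side end).
#' @export
main_branch_geometry <- function(ct) {
  stopifnot(inherits(ct, "classified_tree"))
  nd <- ct$tree$nodes
  i <- match(ct$main_branch, nd$id)
  p <- cbind(nd$x[i], nd$y[i], nd$z[i])
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  data.frame(node_id = ct$main_branch, x = p[, 1L], y = p[, 2L], z = p[, 3L],
             radius = nd$radius[i], arclength = c(0, cumsum(seg)))
}

#' @export
print.classified_tree <- function(x, ...) {
  tab <- table(factor(x$labels, levels = NODE_LABELS))
  cat(sprintf("<classified_tree> %s, %d nodes, main branch %.1f um\n",
              x$neuron_class, length(x$labels), x$main_length))
  print(tab)
  invisible(x)
}
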