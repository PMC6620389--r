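# SWC and Vaa3D .marker input/output.
#
# SWC is the plain-text neuron reconstruction format: one node per line with
# columns (id, type, x, y, z, radius, parent), '#' comments, parent -1 for
# the root. Tracing software (APP2/Vaa3D) typically emits coordinates in
# voxel units; all downstream thresholds here are physical, so coordinates
# and radii are converted to micrometres at read time via `unit_scale`.

#' Construct a neuron tree object
#'
#' A `neuron_tree` is a validated rooted tree of traced nodes with positions
#' and radii in micrometres, mirroring SWC semantics (single root with
#' parent -1, unique ids, acyclic and connected).
#'
#' @param nodes Data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @param unit_scale Per-axis micrometre-per-coordinate-unit factors already
#'   applied to the node table (kept for provenance).
#' @return An object of class `neuron_tree` with elements `nodes`,
#'   `root_id` and `unit_scale`.
#' @export
neuron_tree <- function(nodes, unit_scale = c(1, 1, 1)) {
  tree <- structure(
    list(nodes = nodes, root_id = NA_integer_,
         unit_scale = rep_len(as.numeric(unit_scale), 3L)),
    class = "neuron_tree")
  validate_neuron_tree(tree)
}

#' Validate a neuron tree
#'
#' Checks unique ids, non-negative radii, exactly one root (`parent == -1`),
#' resolvable parent references, and that the structure is a single
#' connected acyclic tree rooted at that node.
#'
#' @param tree A `neuron_tree` (or a bare list with a `nodes` data frame).
#' @return The validated tree (invisibly usable), with `root_id` filled in.
#' @export
validate_neuron_tree <- function(tree) {
  nd <- tree$nodes
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nd)))
    stop("neuron tree nodes must have columns: ", paste(req, collapse = ", "))
  if (nrow(nd) == 0L) stop("neuron tree has no nodes")
  if (anyDuplicated(nd$id))
    stop("structure error: duplicate node ids: ",
         paste(unique(nd$id[duplicated(nd$id)]), collapse = ", "))
  if (any(nd$radius < 0)) stop("structure error: negative radius")
  roots <- nd$id[nd$parent == -1]
  if (length(roots) == 0L) stop("structure error: no root (parent -1) found")
  if (length(roots) > 1L)
    stop("structure error: multiple roots (SWC forests are not supported): ",
         paste(roots, collapse = ", "))
  non_root <- nd$parent != -1
  if (!all(nd$parent[non_root] %in% nd$id))
    stop("structure error: dangling parent id(s): ",
         paste(setdiff(nd$parent[non_root], nd$id), collapse = ", "))
  # reachability from root; with unique ids and single root, unreached nodes
  # indicate a cycle or a disconnected component
  idx <- match(nd$parent, nd$id)  # NA for root
  reached <- logical(nrow(nd))
  reached[nd$parent == -1] <- TRUE
  repeat {
    newly <- !reached & reached[idx]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    reached[newly] <- TRUE
  }
  if (!all(reached))
    stop("structure error: cycle or disconnected component involving node(s): ",
         paste(utils::head(nd$id[!reached], 5L), collapse = ", "))
  tree$root_id <- roots
  tree
}

#' Read an SWC neuron trace
#'
#' Parses a 7-column whitespace-delimited SWC file (APP2/Vaa3D output) into
#' a validated [neuron_tree()]. Coordinates are multiplied per axis by
#' `unit_scale` and the radius by the x/y factor (tracing estimates radius
#' in-plane), so all downstream geometry is in micrometres.
#'
#' @param path Path to the SWC file.
#' @param unit_scale Micrometre-per-coordinate-unit factors, length 1 or 3.
#'   Use `c(0.223, 0.223, 0.300)` for voxel-unit traces at the default
#'   confocal voxel size; 1 if the file is already in micrometres.
#' @return A `neuron_tree`.
#' @export
read_swc <- function(path, unit_scale = c(1, 1, 1)) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  unit_scale <- rep_len(as.numeric(unit_scale), 3L)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("SWC parse error: no data lines in ", path)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("SWC parse error at line ", lineno[which(nf != 7L)[1L]],
         ": expected 7 columns, got ", nf[which(nf != 7L)[1L]])
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop("SWC parse error at line ", lineno[bad], ": non-numeric field")
  }
  nodes <- data.frame(
    id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
    x = m[, 3L] * unit_scale[1L], y = m[, 4L] * unit_scale[2L],
    z = m[, 5L] * unit_scale[3L],
    radius = m[, 6L] * unit_scale[1L],
    parent = as.integer(m[, 7L]))
  neuron_tree(nodes, unit_scale = unit_scale)
}

#' Write a neuron tree as SWC
#'
#' Writes the tree in topological order (every parent line precedes its
#' children). Coordinates are written as stored (micrometres), so
#' `read_swc(write_swc(tree), unit_scale = 1)` round-trips.
#'
#' @param tree A `neuron_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  tree <- validate_neuron_tree(tree)
  nd <- tree$nodes[order_topological(tree), , drop = FALSE]
  num <- function(v) sprintf("%.12g", v)
  lines <- paste(nd$id, nd$type, num(nd$x), num(nd$y), num(nd$z),
                 num(nd$radius), nd$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

# Node order with parents strictly before children (BFS from root).
order_topological <- function(tree) {
  nd <- tree$nodes
  kids <- split(seq_len(nrow(nd)), factor(nd$parent, levels = nd$id))
  out <- integer(nrow(nd))
  out[1L] <- which(nd$parent == -1)
  head_i <- 1L
  tail_i <- 1L
  while (head_i <= tail_i) {
    ch <- kids[[as.character(nd$id[out[head_i]])]]
    if (length(ch)) {
      out[(tail_i + 1L):(tail_i + length(ch))] <- ch
      tail_i <- tail_i + length(ch)
    }
    head_i <- head_i + 1L
  }
  out
}

#' Construct a tracing seed marker
#'
#' A seed marker is a single voxel position (0-based, x/y/z) used to
#' initialise neuron tracing, e.g. the brightest boundary voxel where the
#' PLM dendrite enters the imaging field of view.
#'
#' @param x,y,z 0-based voxel coordinates (non-negative).
#' @param comment Free-text annotation stored in the marker file.
#' @return An object of class `seed_marker`.
#' @export
seed_marker <- function(x, y, z, comment = "") {
  coords <- c(x = x, y = y, z = z)
  if (any(!is.finite(coords)) || any(coords < 0))
    stop("seed marker coordinates must be finite and non-negative")
  structure(list(x = x, y = y, z = z, comment = comment),
            class = "seed_marker")
}

#' Write a Vaa3D .marker seed file
#'
#' Emits the Vaa3D marker CSV dialect
#' `x,y,z,radius,shape,name,comment`, converting the internal 0-based voxel
#' coordinates to the 1-based convention of the file format.
#'
#' @param seed A [seed_marker()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker <- function(seed, path) {
  if (!inherits(seed, "seed_marker")) stop("`seed` must be a seed_marker")
  line <- paste(seed$x + 1, seed$y + 1, seed$z + 1, 0, 1, "seed",
                seed$comment, sep = ",")
  writeLines(c("#x,y,z,radius,shape,name,comment", line), path)
  invisible(path)
}

#' Read a Vaa3D .marker seed file
#'
#' @param path Path to the marker file (first marker line is used).
#' @return A [seed_marker()] with 0-based voxel coordinates.
#' @export
read_marker <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("marker parse error: no marker lines")
  f <- strsplit(lines[[1L]], ",")[[1L]]
  if (length(f) < 3L) stop("marker parse error: expected at least x,y,z")
  seed_marker(as.numeric(f[1L]) - 1, as.numeric(f[2L]) - 1,
              as.numeric(f[3L]) - 1,
              comment = if (length(f) >= 7L) f[7L] else "")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d nodes, root id %d, radius range [%.3g, %.3g] um\n",
              nrow(x$nodes), x$root_id, min(x$nodes$radius),
              max(x$nodes$radius)))
  invisible(x)
}
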