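#' Construct a neuron morphology from a node table
#'
#' A `neuron_morphology` wraps a tidy node table (one row per SWC node) plus
#' metadata. The node table must describe a single rooted tree: exactly one
#' node with `parent_id == -1`, every other parent referring to an existing
#' node, and no cycles.
#'
#' @param nodes Data frame with columns `node_id`, `type` (1 = soma,
#'   2 = axon, 3 = dendrite, 4 = apical), `x`, `y`, `z` (um), `radius` (um),
#'   `parent_id`.
#' @param neuron_id Identifier string.
#' @param metadata Named list (source, s-type if known, comments...).
#' @return A `neuron_morphology`.
#' @export
neuron_morphology <- function(nodes, neuron_id = "neuron", metadata = list()) {
  nodes <- tibble::as_tibble(nodes)
  req <- c("node_id", "type", "x", "y", "z", "radius", "parent_id")
  if (!all(req %in% names(nodes))) {
    abort(paste0("nodes must have columns: ", paste(req, collapse = ", ")))
  }
  nodes <- nodes[, req]
  validate_tree(nodes)
  structure(list(neuron_id = neuron_id, nodes = nodes, metadata = metadata),
            class = "neuron_morphology")
}

validate_tree <- function(nodes) {
  if (anyDuplicated(nodes$node_id)) {
    abort(paste0("duplicate node id: ",
                 nodes$node_id[anyDuplicated(nodes$node_id)]))
  }
  roots <- nodes$node_id[nodes$parent_id == -1]
  if (length(roots) != 1) {
    abort(paste0("tree must have exactly one root; found ", length(roots),
                 if (length(roots) > 0)
                   paste0(" (nodes ", paste(roots, collapse = ", "), ")")))
  }
  nonroot <- nodes$parent_id != -1
  missing <- !(nodes$parent_id[nonroot] %in% nodes$node_id)
  if (any(missing)) {
    bad <- nodes$node_id[nonroot][missing][1]
    abort(paste0("node ", bad, " references a missing parent"))
  }
  # cycle check: walk each node to the root with a visited budget
  parent_of <- setNames(nodes$parent_id, as.character(nodes$node_id))
  n <- nrow(nodes)
  depth_cache <- new.env(hash = TRUE)
  for (id in nodes$node_id) {
    cur <- id
    steps <- 0L
    while (cur != -1) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) abort(paste0("cycle detected at node ", id))
    }
  }
  invisible(TRUE)
}

#' @export
print.neuron_morphology <- function(x, ...) {
  n <- x$nodes
  cat("<neuron_morphology> ", x$neuron_id, ": ", nrow(n), " nodes (",
      sum(n$type == 1), " soma, ", sum(n$type == 2), " axon, ",
      sum(n$type %in% c(3, 4)), " dendrite)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.neuron_morphology <- function(x, ...) x$nodes

#' Read an SWC reconstruction file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments). The node table must form a single rooted tree; multiple
#' roots, dangling parents or cycles are hard errors naming the offending
#' node.
#'
#' @param path File path.
#' @param neuron_id Identifier; defaults to the file name without extension.
#' @return A [neuron_morphology()]. Comment lines are preserved in
#'   `metadata$comments`.
#' @export
read_swc <- function(path, neuron_id = NULL) {
  lines <- readLines(path)
  comments <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) == 0) abort(paste0("no data rows in ", path))
  m <- read.table(text = body, col.names = c("node_id", "type", "x", "y",
                                             "z", "radius", "parent_id"))
  neuron_morphology(
    m,
    neuron_id = neuron_id %||% sub("\\.swc$", "", basename(path)),
    metadata = list(source = path, comments = comments)
  )
}

#' Write a neuron to SWC
#'
#' @param n A [neuron_morphology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(n, path) {
  stopifnot(inherits(n, "neuron_morphology"))
  hdr <- c(paste0("# id type x y z radius parent"),
           paste0("# neuron_id: ", n$neuron_id))
  nd <- n$nodes
  rows <- sprintf("%d %d %.4f %.4f %.4f %.4f %d", nd$node_id, nd$type,
                  nd$x, nd$y, nd$z, nd$radius, nd$parent_id)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Mirror a neuron's coordinates across the atlas midplane
#'
#' @param n A [neuron_morphology()].
#' @param atlas An `annotation_volume` declaring the mirror plane.
#' @return A mirrored [neuron_morphology()] (id suffixed `_m`).
#' @export
mirror_neuron <- function(n, atlas) {
  xyz <- mirror_point(cbind(n$nodes$x, n$nodes$y, n$nodes$z), atlas)
  nd <- n$nodes
  nd$x <- xyz[, 1]
  nd$y <- xyz[, 2]
  nd$z <- xyz[, 3]
  neuron_morphology(nd, paste0(n$neuron_id, "_m"), n$metadata)
}

#' Soma position of a neuron
#' @param n A [neuron_morphology()].
#' @return Length-3 numeric (um) of the root node position.
#' @export
soma_position <- function(n) {
  r <- n$nodes[n$nodes$parent_id == -1, ]
  c(x = r$x, y = r$y, z = r$z)
}

# children list indexed by position in the node table
children_index <- function(nodes) {
  pos <- match(nodes$parent_id, nodes$node_id)  # NA for root
  split(seq_len(nrow(nodes))[!is.na(pos)], pos[!is.na(pos)])
}

# Euclidean length of each non-root node's edge to its parent
edge_lengths <- function(nodes) {
  pos <- match(nodes$parent_id, nodes$node_id)
  len <- numeric(nrow(nodes))
  has <- !is.na(pos)
  d <- cbind(nodes$x, nodes$y, nodes$z)[has, , drop = FALSE] -
    cbind(nodes$x, nodes$y, nodes$z)[pos[has], , drop = FALSE]
  len[has] <- sqrt(rowSums(d^2))
  len
}

# node table restricted to one compartment, keeping the soma root so the
# subtree stays a single tree. type 3 and 4 both count as dendrite.
compartment_nodes <- function(n, compartment = c("whole", "dendrite", "axon")) {
  compartment <- match.arg(compartment)
  nd <- n$nodes
  if (compartment == "whole") return(nd)
  keep_type <- if (compartment == "axon") 2 else c(3, 4)
  keep <- nd$type %in% keep_type | nd$parent_id == -1
  sub <- nd[keep, ]
  # drop nodes whose parent chain leaves the compartment (reattach not
  # attempted; generator and standard SWC emit compartment-contiguous trees)
  ok <- sub$parent_id %in% c(-1, sub$node_id)
  while (!all(ok)) {
    sub <- sub[ok, ]
    ok <- sub$parent_id %in% c(-1, sub$node_id)
  }
  sub
}
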