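#' Read a skeleton from an SWC file
#'
#' SWC is the standard whitespace-delimited neuron skeleton format:
#' `id type x y z radius parent`, one node per line, `parent = -1` for the
#' root, `#` comments. Coordinates are in µm. The node table is validated to
#' be a single rooted tree.
#'
#' @param path Path to an SWC file.
#' @param cell_id,cell_type Optional identity attached to the skeleton; by
#'   default the cell id is the file name without extension.
#' @return A skeleton tibble (class `opl_skeleton`) with columns `node_id`,
#'   `parent_id`, `x`, `y`, `z`, `radius`, `swc_type`, and attributes
#'   `cell_id`, `cell_type`.
#' @export
read_swc <- function(path, cell_id = NULL, cell_type = NA_character_) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad_len <- which(lengths(fields) != 7L)
  if (length(bad_len) > 0L) {
    abort(sprintf("SWC parse error in %s: line %d does not have 7 fields",
                  path, which(keep)[bad_len[1]]))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  nodes <- tibble(
    node_id = as.integer(m[, 1]), swc_type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent_id = as.integer(m[, 7])
  )
  new_skeleton(nodes,
               cell_id = cell_id %||% sub("\\.swc$", "", basename(path)),
               cell_type = cell_type, source = path)
}

#' Construct and validate a skeleton
#'
#' @param nodes Tibble with `node_id`, `parent_id`, `x`, `y`, `z`, `radius`
#'   (and optionally `swc_type`).
#' @param cell_id,cell_type Cell identity.
#' @param source Provenance string (for error messages).
#' @return A validated `opl_skeleton` tibble.
#' @export
new_skeleton <- function(nodes, cell_id, cell_type = NA_character_,
                         source = "<memory>") {
  nodes <- as_tibble(nodes)
  if (!"swc_type" %in% names(nodes)) nodes$swc_type <- 0L
  if (anyDuplicated(nodes$node_id)) {
    dup <- nodes$node_id[duplicated(nodes$node_id)][1]
    abort(sprintf("skeleton %s: duplicate node id %d", source, dup))
  }
  if (any(!is.finite(nodes$x) | !is.finite(nodes$y) | !is.finite(nodes$z))) {
    abort(sprintf("skeleton %s: non-finite coordinates", source))
  }
  roots <- which(nodes$parent_id == -1L)
  if (length(roots) != 1L) {
    abort(sprintf("skeleton %s: expected exactly one root, found %d",
                  source, length(roots)))
  }
  idx <- match(nodes$parent_id, nodes$node_id)
  orphan <- which(nodes$parent_id != -1L & is.na(idx))
  if (length(orphan) > 0L) {
    abort(sprintf("skeleton %s: node %d references missing parent %d",
                  source, nodes$node_id[orphan[1]], nodes$parent_id[orphan[1]]))
  }
  # cycle check: walk each node to the root, bounded by n steps
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[roots] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    chain <- i; j <- i; steps <- 0L
    while (is.na(depth[j])) {
      j <- idx[j]
      steps <- steps + 1L
      if (steps > n) {
        abort(sprintf("skeleton %s: cycle detected involving node %d",
                      source, nodes$node_id[i]))
      }
      chain <- c(chain, j)
    }
    depth[chain] <- depth[j] + rev(seq_along(chain)) - 1L
  }
  structure(nodes, class = c("opl_skeleton", class(nodes)),
            cell_id = cell_id, cell_type = cell_type)
}

#' Write a skeleton to an SWC file
#'
#' @param skel An `opl_skeleton` (or compatible node tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  hdr <- c("# SWC skeleton (units: um)",
           sprintf("# cell_id: %s", attr(skel, "cell_id") %||% NA),
           sprintf("# cell_type: %s", attr(skel, "cell_type") %||% NA),
           "# columns: id type x y z radius parent")
  body <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                  skel$node_id, skel$swc_type, skel$x, skel$y, skel$z,
                  skel$radius, skel$parent_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read all SWC skeletons in a directory
#'
#' @param dir Directory of `.swc` files.
#' @param cells Optional `cells` tibble (`cell_id`, `type`) used to attach
#'   cell types.
#' @return Named list of `opl_skeleton` objects, keyed by cell id.
#' @export
read_swc_dir <- function(dir, cells = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.swc$", full.names = TRUE))
  skels <- lapply(paths, read_swc)
  ids <- vapply(skels, function(s) attr(s, "cell_id"), character(1))
  names(skels) <- ids
  if (!is.null(cells)) {
    for (i in seq_along(skels)) {
      hit <- match(ids[i], cells$cell_id)
      if (!is.na(hit)) attr(skels[[i]], "cell_type") <- cells$type[hit]
    }
  }
  skels
}

# Local edge direction at a node: central difference over incident edges when
# a parent and at least one child exist, else the single incident edge.
node_direction <- function(skel, node_id) {
  i <- match(node_id, skel$node_id)
  if (is.na(i)) abort(sprintf("node %s not in skeleton", node_id))
  p <- match(skel$parent_id[i], skel$node_id)
  kids <- which(skel$parent_id == skel$node_id[i])
  here <- c(skel$x[i], skel$y[i], skel$z[i])
  at <- function(j) c(skel$x[j], skel$y[j], skel$z[j])
  if (!is.na(p) && length(kids) > 0L) {
    d <- at(kids[1]) - at(p)
  } else if (!is.na(p)) {
    d <- here - at(p)
  } else if (length(kids) > 0L) {
    d <- at(kids[1]) - here
  } else {
    abort(sprintf("node %s is isolated; no local direction", node_id))
  }
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) c(0, 0, 1) else d / nrm
}

# igraph tree with edge weights = Euclidean edge lengths.
skeleton_graph <- function(skel) {
  has_parent <- skel$parent_id != -1L
  pi <- match(skel$parent_id[has_parent], skel$node_id)
  ci <- which(has_parent)
  w <- sqrt((skel$x[ci] - skel$x[pi])^2 + (skel$y[ci] - skel$y[pi])^2 +
              (skel$z[ci] - skel$z[pi])^2)
  g <- igraph::graph_from_edgelist(
    cbind(as.character(skel$node_id[pi]), as.character(skel$node_id[ci])),
    directed = FALSE)
  igraph::E(g)$weight <- w
  if (nrow(skel) == 1L) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(as.character(skel$node_id))
  }
  g
}
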