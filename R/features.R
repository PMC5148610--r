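# Contact-set grouping and the geometric feature set used for classification:
#   a  total contact area (µm²)
#   b  eccentricity: distance from the terminal centre to the closest contact
#      point in the plane perpendicular to the optical axis (µm)
#   c  contact height: axial distance of the minimal-eccentricity point from
#      the terminal bottom, normalized by the terminal height
#   d  minimal along-dendrite distance to the closest branch point (µm)
#   e  minimal along-dendrite distance to the closest dendritic tip (µm)
#   f  smallest angle between the contacting dendrite and the optical axis
#   g  number of contact points in the set
#   h  (rod contacts of OFF-CBCs) minimum distance to the nearest synaptic
#      RBC contact on the same rod (µm)

#' Group contact points into contact-sets
#'
#' A contact-set is the collection of all contact points between one bipolar
#' cell and one photoreceptor terminal; sets are the unit of synaptic/
#' non-synaptic classification.
#'
#' @param points Contact-point tibble with at least `bc_id`, `terminal_id`.
#' @return Tibble with one row per (bc_id, terminal_id): list-column `points`
#'   and point count `g_n_points`.
#' @export
group_contact_sets <- function(points) {
  if (is.null(points) || nrow(points) == 0L) {
    return(tibble(bc_id = character(0), terminal_id = character(0),
                  points = list(), g_n_points = integer(0)))
  }
  points |>
    group_by(.data$bc_id, .data$terminal_id) |>
    tidyr::nest(points = -c("bc_id", "terminal_id")) |>
    ungroup() |>
    mutate(g_n_points = map_int(.data$points, nrow))
}

#' Total contact area of a set
#' @param set Tibble of contact points with an `area` column.
#' @return Sum of point areas (µm²).
#' @export
contact_area <- function(set) sum(set$area)

terminal_frame <- function(terminal) {
  if ("basal_z" %in% names(terminal)) {
    list(center = c(terminal$x, terminal$y, terminal$basal_z),
         axis = c(terminal$axis_x %||% 0, terminal$axis_y %||% 0,
                  terminal$axis_z %||% 1),
         height = terminal$height, radius = terminal$radius)
  } else {
    # rod spherule: invagination axis taken as the global optical axis,
    # bottom at centre - radius, height = diameter
    list(center = c(terminal$x, terminal$y, terminal$z - terminal$radius),
         axis = c(0, 0, 1), height = 2 * terminal$radius,
         radius = terminal$radius)
  }
}

planar_axial <- function(set, frame) {
  d <- cbind(set$x - frame$center[1], set$y - frame$center[2],
             set$z - frame$center[3])
  ax <- frame$axis / sqrt(sum(frame$axis^2))
  axial <- as.numeric(d %*% ax)
  perp <- d - outer(axial, ax)
  list(ecc = sqrt(rowSums(perp^2)), axial = axial)
}

#' Eccentricity of a contact-set
#'
#' Distance between the terminal centre and the closest contact point in the
#' plane perpendicular to the optical axis.
#'
#' @param set Contact-point tibble (`x`, `y`, `z`).
#' @param terminal One-row cone (or rod) tibble.
#' @return Minimum planar distance (µm).
#' @export
eccentricity <- function(set, terminal) {
  min(planar_axial(set, terminal_frame(terminal))$ecc)
}

#' Normalized contact height of a contact-set
#'
#' Axial distance of the minimal-eccentricity contact point from the bottom
#' of the terminal, divided by the terminal height. Ties in eccentricity are
#' broken by the smallest axial coordinate.
#'
#' @inheritParams eccentricity
#' @return Unitless height (0 = terminal bottom, 1 = top).
#' @export
contact_height <- function(set, terminal) {
  fr <- terminal_frame(terminal)
  pa <- planar_axial(set, fr)
  i <- order(pa$ecc, pa$axial)[1]
  pa$axial[i] / fr$height
}

#' Along-dendrite distances to the nearest branch point and dendritic tip
#'
#' Path-length distances along the skeleton tree from each contact point's
#' registered node to the closest branch node (graph degree >= 3) and the
#' closest leaf; the set feature is the minimum over points. A tree without
#' branch nodes uses the distance to the root.
#'
#' @param set Contact-point tibble with `node_id`.
#' @param skel An `opl_skeleton`.
#' @return Named numeric: `d_branch`, `e_tip` (µm).
#' @export
arc_distances <- function(set, skel) {
  miss <- setdiff(unique(set$node_id), skel$node_id)
  if (length(miss) > 0L) {
    abort(sprintf("contact node %s not in skeleton %s", miss[1],
                  attr(skel, "cell_id") %||% "?"))
  }
  g <- skeleton_graph(skel)
  deg <- igraph::degree(g)
  vn <- igraph::V(g)$name
  branch <- vn[deg >= 3]
  if (length(branch) == 0L) branch <- as.character(skel$node_id[skel$parent_id == -1L])
  leaves <- vn[deg <= 1]
  from <- as.character(unique(set$node_id))
  db <- igraph::distances(g, v = from, to = branch)
  dt <- igraph::distances(g, v = from, to = leaves)
  c(d_branch = min(db), e_tip = min(dt))
}

#' Smallest angle between the contacting dendrite and the optical axis
#'
#' Minimum over contact points of the acute angle between the local dendrite
#' direction at the registered node and the terminal's optical axis.
#'
#' @inheritParams arc_distances
#' @param terminal One-row terminal tibble.
#' @return Angle in radians, in \[0, pi/2\].
#' @export
axis_angle <- function(set, skel, terminal) {
  fr <- terminal_frame(terminal)
  ax <- fr$axis / sqrt(sum(fr$axis^2))
  ang <- vapply(unique(set$node_id), function(nid) {
    d <- node_direction(skel, nid)
    acos(pmin(1, abs(sum(d * ax))))
  }, numeric(1))
  min(ang)
}

#' Minimum distance to the nearest synaptic RBC contact on the same rod
#'
#' The extra classification feature for OFF-CBC-rod contacts: synaptic basal
#' OFF contacts sit close to the invaginating RBC dendrites of the rod.
#'
#' @param set Contact-point tibble (`x`, `y`, `z`).
#' @param rbc_points Matrix or tibble of synaptic RBC contact positions on
#'   the same rod (columns `x`, `y`, `z`).
#' @return Minimum Euclidean distance (µm); `NA` when `rbc_points` is empty.
#' @export
rod_extra_feature <- function(set, rbc_points) {
  if (is.null(rbc_points) || nrow(as.data.frame(rbc_points)) == 0L) {
    return(NA_real_)
  }
  rp <- as.matrix(as.data.frame(rbc_points)[, c("x", "y", "z")])
  sp <- cbind(set$x, set$y, set$z)
  d2 <- outer(rowSums(sp^2), rowSums(rp^2), "+") - 2 * sp %*% t(rp)
  sqrt(max(0, min(d2)))
}

#' Extract the feature vector of one contact-set
#'
#' @param set Contact-point tibble for one (BC, terminal) pair.
#' @param skel The BC's `opl_skeleton`.
#' @param terminal One-row cone or rod tibble.
#' @param rbc_points Optional synaptic RBC contact positions on the same rod
#'   (for the `h` feature).
#' @return One-row tibble with `a_area`, `b_ecc`, `c_height`, `d_branch`,
#'   `e_tip`, `f_angle`, `g_n_points` and, when `rbc_points` is given,
#'   `h_dist_rbc`.
#' @export
extract_features <- function(set, skel, terminal, rbc_points = NULL) {
  arc <- arc_distances(set, skel)
  out <- tibble(
    a_area = contact_area(set),
    b_ecc = eccentricity(set, terminal),
    c_height = contact_height(set, terminal),
    d_branch = unname(arc["d_branch"]),
    e_tip = unname(arc["e_tip"]),
    f_angle = axis_angle(set, skel, terminal),
    g_n_points = nrow(set)
  )
  if (!is.null(rbc_points)) out$h_dist_rbc <- rod_extra_feature(set, rbc_points)
  out
}

#' Extract features for every contact-set in a dataset
#'
#' Groups contact points into sets and computes the full feature table.
#' For rod contact-sets the `h` feature (distance to the nearest synaptic
#' RBC contact on the same rod) is filled in when `rbc_rod_contacts` is
#' supplied; rods without any synaptic RBC contact get `NA` there and are
#' excluded from OFF-CBC rod classification downstream.
#'
#' @param contacts Contact-point tibble (with `terminal_kind`, `node_id`).
#' @param skeletons Named list of `opl_skeleton`s.
#' @param cones,rods Terminal tibbles.
#' @param rbc_rod_contacts Optional tibble of synaptic RBC contact points on
#'   rods (`terminal_id`, `x`, `y`, `z`).
#' @return Feature tibble, one row per contact-set, keyed by
#'   (`bc_id`, `terminal_id`, `terminal_kind`).
#' @export
extract_contact_features <- function(contacts, skeletons, cones,
                                     rods = NULL, rbc_rod_contacts = NULL) {
  sets <- contacts |>
    group_by(.data$bc_id, .data$terminal_id, .data$terminal_kind) |>
    tidyr::nest(points = -c("bc_id", "terminal_id", "terminal_kind")) |>
    ungroup()
  if (nrow(sets) == 0L) {
    return(tibble(bc_id = character(0), terminal_id = character(0),
                  terminal_kind = character(0)))
  }
  rbc_by_rod <- if (!is.null(rbc_rod_contacts) && nrow(rbc_rod_contacts) > 0L) {
    split(rbc_rod_contacts[, c("x", "y", "z")], rbc_rod_contacts$terminal_id)
  } else list()
  # cache one graph (plus branch/leaf sets and local directions) per cell
  cache <- new.env(parent = emptyenv())
  cell_geom <- function(bc) {
    if (!is.null(cache[[bc]])) return(cache[[bc]])
    skel <- skeletons[[bc]]
    if (is.null(skel)) abort(sprintf("no skeleton for cell %s", bc))
    g <- skeleton_graph(skel)
    deg <- igraph::degree(g)
    vn <- igraph::V(g)$name
    branch <- vn[deg >= 3]
    if (length(branch) == 0L) {
      branch <- as.character(skel$node_id[skel$parent_id == -1L])
    }
    cache[[bc]] <- list(skel = skel, g = g, branch = branch,
                        leaves = vn[deg <= 1])
    cache[[bc]]
  }
  feats <- pmap(list(sets$points, sets$bc_id, sets$terminal_id,
                     sets$terminal_kind),
                function(pts, bc, tid, kind) {
    geo <- cell_geom(bc)
    term <- if (kind == "cone") cones[cones$cone_id == tid, ] else
      rods[rods$rod_id == tid, ]
    if (nrow(term) == 0L) abort(sprintf("unknown terminal %s", tid))
    term <- term[1, ]
    from <- as.character(unique(pts$node_id))
    if (!all(from %in% geo$skel$node_id)) {
      abort(sprintf("contact node not in skeleton %s", bc))
    }
    db <- min(igraph::distances(geo$g, v = from, to = geo$branch))
    dt <- min(igraph::distances(geo$g, v = from, to = geo$leaves))
    out <- tibble(
      a_area = contact_area(pts),
      b_ecc = eccentricity(pts, term),
      c_height = contact_height(pts, term),
      d_branch = db, e_tip = dt,
      f_angle = axis_angle(pts, geo$skel, term),
      g_n_points = nrow(pts)
    )
    if (kind == "rod") {
      out$h_dist_rbc <- rod_extra_feature(pts, rbc_by_rod[[tid]])
    } else {
      out$h_dist_rbc <- NA_real_
    }
    out
  })
  bind_cols(sets[, c("bc_id", "terminal_id", "terminal_kind")],
            bind_rows(feats))
}
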