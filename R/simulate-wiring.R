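# Contact wiring for the synthetic OPL.
#
# Synaptic contact archetypes (ground truth):
#   invaginating — ON-CBC / RBC / CBC9 contacts: low eccentricity, contact
#     height inside the pedicle body, dendritic branch terminating at the
#     terminal;
#   basal — OFF-CBC contacts: low eccentricity at the pedicle bottom;
#   tip — CBCX's atypical basal-like contacts at dendritic tips;
#   peripheral — non-synaptic touches at the side of the terminal or on
#     telodendria, registered on passing (internal) dendrite nodes.

sample_points_for_class <- function(class, cx, cy, basal_z, height, R, noise,
                                    n_pts) {
  rng <- switch(class,
                invaginating = list(e = noise$ecc_invag, h = noise$height_invag,
                                    ml = noise$area_meanlog_syn,
                                    sl = noise$area_sdlog_syn),
                basal = ,
                tip = list(e = noise$ecc_basal, h = noise$height_basal,
                           ml = noise$area_meanlog_syn - 0.7,
                           sl = noise$area_sdlog_syn),
                peripheral = list(e = noise$ecc_peri, h = noise$height_peri,
                                  ml = noise$area_meanlog_per,
                                  sl = noise$area_sdlog_per))
  ecc <- runif(n_pts, rng$e[1], rng$e[2]) * R
  phi <- runif(n_pts, 0, 2 * pi)
  hgt <- runif(n_pts, rng$h[1], rng$h[2])
  tibble(x = cx + ecc * cos(phi), y = cy + ecc * sin(phi),
         z = basal_z + hgt * height,
         area = rlnorm(n_pts, rng$ml, rng$sl))
}

# Append a three-node branch from the nearest primary-arbor node to a target,
# ending in a leaf just above `z_leaf` with a near-vertical terminal edge.
# `st` is a mutable per-cell state list(nodes=matrix, next_id).
grow_branch <- function(st, tx, ty, z_leaf) {
  nd <- st$nodes
  # attach only to passing (non-leaf) dendritic scaffold nodes, so earlier
  # terminal tips keep their leaf status (invaginating tips must stay tips)
  has_child <- nd[, 1] %in% nd[, 7]
  cand <- which(nd[, 2] == 3 & nd[, 5] >= 3 & nd[, 5] <= 6 & has_child)
  if (length(cand) == 0L) cand <- which(nd[, 2] == 3 & nd[, 5] <= 6)
  if (length(cand) == 0L) cand <- seq_len(nrow(nd))
  d2 <- (nd[cand, 3] - tx)^2 + (nd[cand, 4] - ty)^2
  from <- cand[which.min(d2)]
  id0 <- st$next_id
  mid <- c((nd[from, 3] + tx) / 2, (nd[from, 4] + ty) / 2)
  off <- runif(2, -0.2, 0.2)
  new <- rbind(
    c(id0,     3, mid[1], mid[2], 3.5, 0.4, nd[from, 1]),
    c(id0 + 1, 3, tx + off[1], ty + off[2], z_leaf + 1.5, 0.3, id0),
    c(id0 + 2, 3, tx + off[1] * 0.3, ty + off[2] * 0.3, z_leaf, 0.25, id0 + 1)
  )
  st$nodes <- rbind(nd, new)
  st$next_id <- id0 + 3L
  st$leaf <- id0 + 2L
  st
}

# Nearest internal (passing) node: has a parent and at least one child.
passing_node <- function(st, tx, ty) {
  nd <- st$nodes
  has_child <- nd[, 1] %in% nd[, 7]
  cand <- which(nd[, 7] != -1 & has_child & nd[, 2] == 3)
  if (length(cand) == 0L) cand <- seq_len(nrow(nd))
  d2 <- (nd[cand, 3] - tx)^2 + (nd[cand, 4] - ty)^2
  nd[cand[which.min(d2)], 1]
}

#' Wire synaptic and spurious contacts between BCs and photoreceptors
#'
#' Applies the generator's wiring rules: ON-CBCs and RBCs make invaginating
#' contacts (branch tips ending at the cone), OFF-CBCs basal contacts, CBC9
#' contacts every S-cone whose centre its dendritic hull covers, CBCX makes
#' mostly tip contacts on a small fraction of in-field cones, each rod is
#' invaginated by at most two distinct RBCs, and OFF-CBC types 3A/3B/4
#' contact rods close to an existing synaptic RBC contact. Non-synaptic
#' peripheral contacts are added at the configured spurious rates. Dendritic
#' branches are grown to every synaptic contact, so the returned skeletons
#' supersede the input ones.
#'
#' @param cones Cone tibble from [generate_cone_mosaic()].
#' @param rods Rod tibble from [generate_rod_field()] (may have zero rows).
#' @param bcs List with `cells` and `skeletons` (possibly several types
#'   combined).
#' @param config An [opl_config()].
#' @return List with `contacts` (one row per contact point: `contact_point_id`,
#'   `bc_id`, `terminal_id`, `terminal_kind`, `x`, `y`, `z`, `area`,
#'   `node_id`), `truth` (one row per contact-set: ground-truth `label`
#'   (`synaptic`/`non_synaptic`) and `contact_class`), and `skeletons`
#'   (updated).
#' @export
wire_contacts <- function(cones, rods, bcs, config) {
  set.seed(config$seed + 301L)
  noise <- config$contact_noise
  par <- config$bc_type_params
  cells <- bcs$cells
  states <- lapply(bcs$skeletons, function(s) {
    list(nodes = as.matrix(s[, c("node_id", "swc_type", "x", "y", "z",
                                 "radius", "parent_id")]),
         next_id = max(s$node_id) + 1L)
  })
  hulls <- lapply(bcs$skeletons, dendritic_hull)
  pts_out <- list(); truth_out <- list()
  set_counter <- 0L
  add_set <- function(bc_id, tid, kind, class, pts, node_id) {
    set_counter <<- set_counter + 1L
    pts_out[[set_counter]] <<- tibble(
      bc_id = bc_id, terminal_id = tid, terminal_kind = kind,
      x = pts$x, y = pts$y, z = pts$z, area = pts$area, node_id = node_id)
    truth_out[[set_counter]] <<- tibble(
      bc_id = bc_id, terminal_id = tid, terminal_kind = kind,
      label = if (class == "peripheral") "non_synaptic" else "synaptic",
      contact_class = class)
  }

  rbc_syn_points <- list()  # per rod: synaptic RBC contact positions
  have_cones <- !is.null(cones) && nrow(cones) > 0L

  for (ci in seq_len(nrow(cells))) {
    bc_id <- cells$cell_id[ci]; type <- cells$type[ci]
    p <- par[match(type, par$type), ]
    if (!have_cones) break
    infield <- cones[points_in_hull(hulls[[bc_id]],
                                    cbind(cones$x, cones$y)), ]
    if (nrow(infield) == 0L) next
    if (type == "CBC9") {
      syn <- infield[infield$spectral == "S", ]
    } else if (type == "RBC") {
      syn <- if (runif(1) < config$rbc_cone_fraction) {
        infield[sample.int(nrow(infield), min(nrow(infield), sample(1:2, 1))), ]
      } else infield[0, ]
    } else {
      syn <- infield[runif(nrow(infield)) < p$contact_fraction, ]
    }
    for (k in seq_len(nrow(syn))) {
      cone <- syn[k, ]
      class <- if (p$polarity == "OFF") "basal"
      else if (type == "CBCX") (if (runif(1) < 3 / 19) "invaginating" else "tip")
      else "invaginating"
      st <- grow_branch(states[[bc_id]], cone$x, cone$y,
                        z_leaf = cone$basal_z + 0.2)
      states[[bc_id]] <- st
      n_pts <- if (type == "CBC9") 2L + rbinom(1, 2, 0.5) else
        1L + rpois(1, noise$extra_points_lambda)
      pts <- sample_points_for_class(class, cone$x, cone$y, cone$basal_z,
                                     cone$height, cone$radius, noise, n_pts)
      add_set(bc_id, cone$cone_id, "cone", class, pts, st$leaf)
    }
    spur <- infield[!(infield$cone_id %in% syn$cone_id), ]
    spur <- spur[runif(nrow(spur)) < noise$spurious_rate, ]
    for (k in seq_len(nrow(spur))) {
      cone <- spur[k, ]
      node <- passing_node(states[[bc_id]], cone$x, cone$y)
      n_pts <- 1L + rbinom(1, 1, 0.3)
      pts <- sample_points_for_class("peripheral", cone$x, cone$y,
                                     cone$basal_z, cone$height, cone$radius,
                                     noise, n_pts)
      add_set(bc_id, cone$cone_id, "cone", "peripheral", pts, node)
    }
  }

  # --- rods ---
  if (!is.null(rods) && nrow(rods) > 0L) {
    rbc_ids <- cells$cell_id[cells$type == "RBC"]
    if (length(rbc_ids) > 0L) {
      rbc_polys <- lapply(hulls[rbc_ids], identity)
      cover <- matrix(FALSE, nrow(rods), length(rbc_ids))
      for (j in seq_along(rbc_ids)) {
        cover[, j] <- points_in_hull(rbc_polys[[j]], cbind(rods$x, rods$y))
      }
      rbc_contacted <- new.env(parent = emptyenv())
      for (ri in seq_len(nrow(rods))) {
        rod <- rods[ri, ]
        cands <- rbc_ids[cover[ri, ]]
        if (length(cands) == 0L) next
        cands <- sample(cands)[seq_len(min(2L, length(cands)))]
        cands <- cands[runif(length(cands)) < config$rod_accept]
        for (bc_id in cands) {
          rbc_contacted[[bc_id]] <- c(rbc_contacted[[bc_id]], rod$rod_id)
          st <- grow_branch(states[[bc_id]], rod$x, rod$y,
                            z_leaf = rod$z - rod$radius + 0.1)
          states[[bc_id]] <- st
          n_pts <- 1L + rpois(1, 0.6)
          pts <- sample_points_for_class("invaginating", rod$x, rod$y,
                                         rod$z - rod$radius, 2 * rod$radius,
                                         rod$radius, noise, n_pts)
          add_set(bc_id, rod$rod_id, "rod", "invaginating", pts, st$leaf)
          rbc_syn_points[[rod$rod_id]] <-
            rbind(rbc_syn_points[[rod$rod_id]],
                  cbind(pts$x, pts$y, pts$z))
        }
      }
    }
    rods_with_rbc <- names(rbc_syn_points)
    off_types <- intersect(names(config$off_rod_targets),
                           unique(cells$type))
    for (type in off_types) {
      lam <- config$off_rod_targets[[type]]
      for (bc_id in cells$cell_id[cells$type == type]) {
        inhull <- rods[points_in_hull(hulls[[bc_id]],
                                      cbind(rods$x, rods$y)), ]
        elig <- inhull[inhull$rod_id %in% rods_with_rbc, ]
        if (nrow(elig) == 0L) next
        n_draw <- min(rpois(1, lam), nrow(elig))
        if (n_draw == 0L) next
        chosen <- elig[sample.int(nrow(elig), n_draw), ]
        for (k in seq_len(n_draw)) {
          rod <- chosen[k, ]
          anchor <- rbc_syn_points[[rod$rod_id]][1, ]
          st <- grow_branch(states[[bc_id]], rod$x, rod$y,
                            z_leaf = rod$z - rod$radius + 0.1)
          states[[bc_id]] <- st
          d <- runif(1, 0.2, 1.2); phi <- runif(1, 0, 2 * pi)
          pts <- tibble(x = anchor[1] + d * cos(phi),
                        y = anchor[2] + d * sin(phi),
                        z = rod$z - rod$radius +
                          runif(1, noise$height_basal[1],
                                noise$height_basal[2]) * 2 * rod$radius,
                        area = rlnorm(1, noise$area_meanlog_syn - 0.7,
                                      noise$area_sdlog_syn))
          add_set(bc_id, rod$rod_id, "rod", "basal", pts, st$leaf)
        }
        # spurious rod contacts: far from the RBC invagination
        spur_rate <- noise$rod_spurious_rate %||% 0.05
        spur <- inhull[runif(nrow(inhull)) < spur_rate, ]
        spur <- spur[!(spur$rod_id %in% chosen$rod_id), ]
        for (k in seq_len(nrow(spur))) {
          rod <- spur[k, ]
          node <- passing_node(states[[bc_id]], rod$x, rod$y)
          d <- runif(1, 2.6, 5); phi <- runif(1, 0, 2 * pi)
          pts <- tibble(x = rod$x + d * cos(phi), y = rod$y + d * sin(phi),
                        z = rod$z + runif(1, -0.5, 0.5),
                        area = rlnorm(1, noise$area_meanlog_per,
                                      noise$area_sdlog_per))
          add_set(bc_id, rod$rod_id, "rod", "peripheral", pts, node)
        }
      }
    }
    # spurious RBC-rod contacts
    spur_rate <- noise$rod_spurious_rate %||% 0.05
    for (bc_id in cells$cell_id[cells$type == "RBC"]) {
      inhull <- rods[points_in_hull(hulls[[bc_id]], cbind(rods$x, rods$y)), ]
      inhull <- inhull[!(inhull$rod_id %in% rbc_contacted[[bc_id]]), ]
      spur <- inhull[runif(nrow(inhull)) < spur_rate, ]
      for (k in seq_len(nrow(spur))) {
        rod <- spur[k, ]
        node <- passing_node(states[[bc_id]], rod$x, rod$y)
        pts <- sample_points_for_class("peripheral", rod$x, rod$y,
                                       rod$z - rod$radius, 2 * rod$radius,
                                       rod$radius, noise, 1L)
        add_set(bc_id, rod$rod_id, "rod", "peripheral", pts, node)
      }
    }
  }

  skeletons <- lapply(names(states), function(bc_id) {
    nd <- states[[bc_id]]$nodes
    new_skeleton(
      tibble(node_id = as.integer(nd[, 1]), swc_type = as.integer(nd[, 2]),
             x = nd[, 3], y = nd[, 4], z = nd[, 5], radius = nd[, 6],
             parent_id = as.integer(nd[, 7])),
      cell_id = bc_id,
      cell_type = attr(bcs$skeletons[[bc_id]], "cell_type"))
  })
  names(skeletons) <- names(states)

  contacts <- if (set_counter > 0L) bind_rows(pts_out) else
    tibble(bc_id = character(0), terminal_id = character(0),
           terminal_kind = character(0), x = numeric(0), y = numeric(0),
           z = numeric(0), area = numeric(0), node_id = integer(0))
  truth <- if (set_counter > 0L) bind_rows(truth_out) else
    tibble(bc_id = character(0), terminal_id = character(0),
           terminal_kind = character(0), label = character(0),
           contact_class = character(0))
  if (nrow(contacts) > 0L) {
    contacts <- mutate(contacts,
                       contact_point_id = sprintf("cp_%06d", row_number())) |>
      select("contact_point_id", dplyr::everything())
  } else {
    contacts$contact_point_id <- character(0)
  }
  list(contacts = contacts, truth = truth, skeletons = skeletons)
}
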