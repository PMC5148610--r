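# Shared fixtures and independent oracles for the test suite.

# A small configuration that exercises every wiring rule in a few seconds.
small_config <- function(seed = 1, ...) {
  library(dplyr)
  params <- default_bc_type_params() |>
    filter(type %in% c("CBC2", "CBC6", "CBC9", "CBCX", "RBC", "CBC3B")) |>
    mutate(n_cells = c(6L, 4L, 10L, 3L, 3L, 20L)[match(type, c(
      "CBC2", "CBC3B", "CBC6", "CBCX", "CBC9", "RBC"))])
  opl_config(field_size = c(60, 50), bc_type_params = params, seed = seed,
             ...)
}

# Hand-built skeleton: a chain root(1)-a(2)-b(3)-leaf(4) with unit edges plus
# a side child c(5) of a, so a is a genuine branch node.
branch_chain_skeleton <- function() {
  new_skeleton(tibble::tibble(
    node_id = 1:5, parent_id = c(-1L, 1L, 2L, 3L, 2L),
    x = c(0, 1, 2, 3, 1), y = c(0, 0, 0, 0, 1), z = 0, radius = 0.5
  ), cell_id = "chain", cell_type = "test")
}

random_tree_skeleton <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  new_skeleton(tibble::tibble(
    node_id = seq_len(n), parent_id = parent,
    x = runif(n, 0, 20), y = runif(n, 0, 20), z = runif(n, 0, 5),
    radius = runif(n, 0.2, 1)
  ), cell_id = "rnd", cell_type = "test")
}

# Floyd-Warshall all-pairs shortest paths over the skeleton's weighted
# edges; independent of the igraph route used by the package.
oracle_tree_distances <- function(skel) {
  n <- nrow(skel)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  idx <- match(skel$parent_id, skel$node_id)
  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) next
    w <- sqrt((skel$x[i] - skel$x[j])^2 + (skel$y[i] - skel$y[j])^2 +
                (skel$z[i] - skel$z[j])^2)
    D[i, j] <- w; D[j, i] <- w
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  dimnames(D) <- list(skel$node_id, skel$node_id)
  D
}

oracle_node_degree <- function(skel) {
  idx <- match(skel$parent_id, skel$node_id)
  deg <- rep(0L, nrow(skel))
  for (i in seq_len(nrow(skel))) {
    j <- idx[i]
    if (is.na(j)) next
    deg[i] <- deg[i] + 1L
    deg[j] <- deg[j] + 1L
  }
  deg
}

# Ray-casting point-in-polygon, independent of mgcv::in.out.
oracle_in_polygon <- function(poly, px, py) {
  n <- nrow(poly)
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    cnt <- 0L
    on_edge <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
      # on-segment test
      d <- abs((x2 - x1) * (py[p] - y1) - (y2 - y1) * (px[p] - x1))
      if (d < 1e-9 && px[p] >= min(x1, x2) - 1e-9 &&
          px[p] <= max(x1, x2) + 1e-9 && py[p] >= min(y1, y2) - 1e-9 &&
          py[p] <= max(y1, y2) + 1e-9) on_edge <- TRUE
      if ((y1 > py[p]) != (y2 > py[p])) {
        xint <- x1 + (py[p] - y1) / (y2 - y1) * (x2 - x1)
        if (px[p] < xint) cnt <- cnt + 1L
      }
    }
    inside[p] <- on_edge || (cnt %% 2L == 1L)
  }
  inside
}

# Gift-wrapping convex hull area (independent of grDevices::chull).
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3L) return(0)
  start <- which.min(pts[, 1])
  hull <- start; cur <- start
  repeat {
    cand <- if (cur == 1L) 2L else 1L
    for (k in seq_len(n)) {
      if (k == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      if (cr < 0 || (abs(cr) < 1e-12 &&
                     sum((pts[k, ] - pts[cur, ])^2) >
                       sum((pts[cand, ] - pts[cur, ])^2))) cand <- k
    }
    cur <- cand
    if (cur == start) break
    hull <- c(hull, cur)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  h <- pts[hull, , drop = FALSE]
  m <- nrow(h)
  j <- c(m, seq_len(m - 1L))
  abs(sum(h[j, 1] * h[, 2] - h[, 1] * h[j, 2])) / 2
}

# Monte-Carlo union area of convex polygons.
oracle_union_area_mc <- function(polys, n_mc = 2e5, seed = 99) {
  set.seed(seed)
  xr <- range(unlist(lapply(polys, function(p) p[, 1])))
  yr <- range(unlist(lapply(polys, function(p) p[, 2])))
  px <- runif(n_mc, xr[1], xr[2]); py <- runif(n_mc, yr[1], yr[2])
  hit <- rep(FALSE, n_mc)
  for (p in polys) {
    todo <- which(!hit)
    if (length(todo) == 0L) break
    hit[todo] <- oracle_in_polygon(p, px[todo], py[todo])
  }
  mean(hit) * diff(xr) * diff(yr)
}

# A single-row cone for feature unit tests.
unit_cone <- function(x = 0, y = 0, basal_z = 0, height = 3, radius = 3.2,
                      axis = c(0, 0, 1)) {
  tibble::tibble(cone_id = "c1", x = x, y = y, basal_z = basal_z,
                 height = height, radius = radius,
                 axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
                 spectral = "M", complete = TRUE)
}

contact_pts <- function(x, y, z, area = 0.1, node_id = 1L,
                        bc_id = "b1", terminal_id = "c1") {
  tibble::tibble(bc_id = bc_id, terminal_id = terminal_id,
                 x = x, y = y, z = z,
                 area = rep_len(area, length(x)),
                 node_id = rep_len(node_id, length(x)))
}

# Separable two-cluster feature table for classifier tests.
separable_features <- function(n = 40, seed = 1, gap = 4) {
  set.seed(seed)
  half <- n %/% 2
  tibble::tibble(
    a_area = c(rnorm(half, 1 + gap / 4, 0.2), rnorm(n - half, 0.2, 0.1)),
    b_ecc = c(rnorm(half, 0.5, 0.3), rnorm(n - half, 0.5 + gap, 0.3)),
    c_height = c(rnorm(half, 0.3, 0.1), rnorm(n - half, 0.7, 0.1)),
    d_branch = rnorm(n, 3, 1),
    e_tip = c(abs(rnorm(half, 0, 0.2)), abs(rnorm(n - half, gap, 0.5))),
    f_angle = runif(n, 0, pi / 2),
    g_n_points = rpois(n, 2) + 1L,
    label = rep(c("synaptic", "non_synaptic"), c(half, n - half))
  )
}

# Labelled generator-realistic contact-set features (cone side only).
generator_features <- function(seed = 1, n = NULL, types = c("CBC5I", "CBC6",
                                                             "CBC7"),
                               n_cells = c(8L, 14L, 9L)) {
  library(dplyr)
  cfg <- opl_config(field_size = c(70, 55), seed = seed, rod_density = 0,
                    bc_type_params = default_bc_type_params() |>
                      filter(type %in% types) |>
                      mutate(n_cells = n_cells[match(type, types)]))
  sim <- simulate_opl(cfg, sac_cbc5 = FALSE)
  feats <- extract_contact_features(sim$contacts, sim$skeletons, sim$cones,
                                    sim$rods)
  lab <- feats |>
    inner_join(sim$truth |>
                 mutate(label = ifelse(label == "synaptic", "synaptic",
                                       "non_synaptic")) |>
                 select(bc_id, terminal_id, terminal_kind, label),
               by = c("bc_id", "terminal_id", "terminal_kind"))
  if (!is.null(n) && nrow(lab) > n) {
    set.seed(seed)
    lab <- lab[sample.int(nrow(lab), n), ]
  }
  lab
}
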