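# Contact-set grouping and the geometric feature set.

library(dplyr)

test_that("contact points group into one set per (BC, terminal) pair", {
  expect_equal(nrow(group_contact_sets(NULL)), 0L)
  pts <- bind_rows(
    contact_pts(1:3, 1:3, 0, bc_id = "b1", terminal_id = "c1"),
    contact_pts(0, 0, 0, bc_id = "b1", terminal_id = "c2"),
    contact_pts(0, 0, 0, bc_id = "b2", terminal_id = "c1"))
  g <- group_contact_sets(pts)
  expect_equal(nrow(g), 3L)
  expect_setequal(g$g_n_points, c(3L, 1L, 1L))
  expect_equal(sum(g$g_n_points), nrow(pts))
})

test_that("grouping matches a brute-force group-by oracle on random tables", {
  set.seed(7)
  pts <- contact_pts(runif(200), runif(200), runif(200),
                     bc_id = sample(paste0("b", 1:6), 200, TRUE),
                     terminal_id = sample(paste0("c", 1:9), 200, TRUE))
  g <- group_contact_sets(pts)
  oracle <- table(paste(pts$bc_id, pts$terminal_id))
  expect_equal(nrow(g), length(oracle))
  got <- setNames(g$g_n_points, paste(g$bc_id, g$terminal_id))
  expect_equal(as.integer(got[names(oracle)]), as.integer(oracle))
})

test_that("contact area is the sum of point areas", {
  expect_equal(contact_area(contact_pts(0:1, 0, 0, area = c(0.02, 0.03))),
               0.05)
  expect_equal(contact_area(contact_pts(0, 0, 0, area = 0.42)), 0.42)
  set.seed(1)
  areas <- runif(17)
  expect_equal(contact_area(contact_pts(runif(17), 0, 0, area = areas)),
               sum(areas))
})

test_that("eccentricity is the minimal planar distance to the cone centre", {
  cone <- unit_cone()
  expect_equal(eccentricity(contact_pts(0, 0, 2.5), cone), 0)
  expect_equal(eccentricity(contact_pts(c(3, 6), c(4, 8), c(1, 2)), cone), 5)
  # random sets against an exhaustive-minimum oracle with a tilted axis
  set.seed(11)
  ax <- c(1, 2, 3) / sqrt(14)
  cone_t <- unit_cone(x = 2, y = -1, basal_z = 0.5, axis = ax)
  for (i in 1:20) {
    pts <- contact_pts(rnorm(5, 2), rnorm(5, -1), rnorm(5, 1))
    d <- cbind(pts$x - 2, pts$y + 1, pts$z - 0.5)
    perp <- d - outer(as.numeric(d %*% ax), ax)
    expect_equal(eccentricity(pts, cone_t), min(sqrt(rowSums(perp^2))),
                 tolerance = 1e-12)
  }
})

test_that("contact height normalizes the minimal-eccentricity point's depth", {
  cone <- unit_cone(height = 3)
  expect_equal(contact_height(contact_pts(0.1, 0, 0), cone), 0)
  expect_equal(contact_height(contact_pts(0.1, 0, 3), cone), 1)
  # two-step oracle: argmin eccentricity (ties by smaller z), then project
  set.seed(5)
  for (i in 1:20) {
    pts <- contact_pts(rnorm(6), rnorm(6), runif(6, 0, 3))
    ecc <- sqrt(pts$x^2 + pts$y^2)
    j <- order(ecc, pts$z)[1]
    expect_equal(contact_height(pts, cone), pts$z[j] / 3)
  }
  # tie-break: identical eccentricity, different heights -> lower one
  tie <- contact_pts(c(1, -1), c(0, 0), c(2.4, 0.6))
  expect_equal(contact_height(tie, cone), 0.2)
})

test_that("arc distances to branch point and tip follow the dendrite", {
  skel <- branch_chain_skeleton()
  # contact at the leaf node 4: distance to tip 0
  expect_equal(unname(arc_distances(contact_pts(3, 0, 0, node_id = 4L),
                                    skel)["e_tip"]), 0)
  # contact at b (node 3): branch node a (2) is 1 away, leaf 4 is 1 away
  d <- arc_distances(contact_pts(2, 0, 0, node_id = 3L), skel)
  expect_equal(unname(d["d_branch"]), 1)
  expect_equal(unname(d["e_tip"]), 1)
  expect_error(arc_distances(contact_pts(0, 0, 0, node_id = 99L), skel),
               "not in skeleton")
})

test_that("arc distances agree with an all-pairs shortest-path oracle", {
  for (s in 1:8) {
    skel <- random_tree_skeleton(25, seed = s)
    D <- oracle_tree_distances(skel)
    deg <- oracle_node_degree(skel)
    branch <- which(deg >= 3)
    if (length(branch) == 0L) branch <- which(skel$parent_id == -1L)
    leaves <- which(deg <= 1)
    nid <- sample(skel$node_id, 3)
    got <- arc_distances(contact_pts(numeric(length(nid)), 0, 0, node_id = nid), skel)
    i <- match(nid, skel$node_id)
    expect_equal(unname(got["d_branch"]), min(D[i, branch]),
                 tolerance = 1e-9)
    expect_equal(unname(got["e_tip"]), min(D[i, leaves]), tolerance = 1e-9)
  }
})

test_that("axis angle is the acute angle to the optical axis", {
  vert <- new_skeleton(tibble::tibble(
    node_id = 1:2, parent_id = c(-1L, 1L), x = 0, y = 0, z = c(0, 2),
    radius = 0.5), cell_id = "v")
  horiz <- new_skeleton(tibble::tibble(
    node_id = 1:2, parent_id = c(-1L, 1L), x = c(0, 2), y = 0, z = 0,
    radius = 0.5), cell_id = "h")
  anti <- new_skeleton(tibble::tibble(
    node_id = 1:2, parent_id = c(-1L, 1L), x = 0, y = 0, z = c(2, 0),
    radius = 0.5), cell_id = "a")
  cone <- unit_cone()
  pt <- contact_pts(0, 0, 0, node_id = 2L)
  expect_equal(axis_angle(pt, vert, cone), 0, tolerance = 1e-9)
  expect_equal(axis_angle(pt, horiz, cone), pi / 2, tolerance = 1e-9)
  expect_equal(axis_angle(pt, anti, cone), 0, tolerance = 1e-9)
})

test_that("rod feature is the minimum distance to a synaptic RBC contact", {
  set <- contact_pts(0, 0, 0)
  expect_equal(rod_extra_feature(set, tibble::tibble(x = 0, y = 0, z = 0)), 0)
  rbc <- tibble::tibble(x = c(2, 0.7), y = 0, z = 0)
  expect_equal(rod_extra_feature(set, rbc), 0.7)
  expect_true(is.na(rod_extra_feature(set, NULL)))
  set.seed(3)
  for (i in 1:10) {
    s2 <- contact_pts(rnorm(4), rnorm(4), rnorm(4))
    r2 <- tibble::tibble(x = rnorm(6), y = rnorm(6), z = rnorm(6))
    brute <- min(sapply(1:4, function(a) sapply(1:6, function(b) {
      sqrt((s2$x[a] - r2$x[b])^2 + (s2$y[a] - r2$y[b])^2 +
             (s2$z[a] - r2$z[b])^2)
    })))
    expect_equal(rod_extra_feature(s2, r2), brute, tolerance = 1e-9)
  }
})

test_that("feature vectors are complete and g counts the points", {
  skel <- branch_chain_skeleton()
  cone <- unit_cone(x = 3, y = 0)
  set <- contact_pts(c(3, 3.1), c(0, 0.1), c(0.5, 1), node_id = 4L)
  f <- extract_features(set, skel, cone)
  expect_equal(f$g_n_points, 2L)
  expect_true(all(is.finite(unlist(f[, c("a_area", "b_ecc", "c_height",
                                         "d_branch", "e_tip", "f_angle")]))))
  expect_gte(f$f_angle, 0)
  expect_lte(f$f_angle, pi / 2 + 1e-12)
})

test_that("features are invariant under rigid translation and rotation about the axis", {
  skel <- branch_chain_skeleton()
  cone <- unit_cone(x = 3, y = 0)
  set <- contact_pts(c(3.4, 2.8), c(0.3, -0.2), c(0.5, 1.2), node_id = 3L)
  f0 <- extract_features(set, skel, cone)
  # translation of everything by (dx, dy, dz)
  dd <- c(5, -7, 2)
  skel_t <- new_skeleton(dplyr::mutate(tibble::as_tibble(skel),
                                       x = x + dd[1], y = y + dd[2],
                                       z = z + dd[3]),
                         cell_id = "t")
  cone_t <- unit_cone(x = 3 + dd[1], y = dd[2], basal_z = dd[3])
  set_t <- dplyr::mutate(set, x = x + dd[1], y = y + dd[2], z = z + dd[3])
  f1 <- extract_features(set_t, skel_t, cone_t)
  expect_equal(as.numeric(f1[1, 1:7]), as.numeric(f0[1, 1:7]),
               tolerance = 1e-9)
  # rotation about the pedicle axis leaves eccentricity and height unchanged
  th <- 0.83
  rot <- function(x, y, cx, cy) {
    cbind(cx + cos(th) * (x - cx) - sin(th) * (y - cy),
          cy + sin(th) * (x - cx) + cos(th) * (y - cy))
  }
  rs <- rot(set$x, set$y, 3, 0)
  set_r <- dplyr::mutate(set, x = rs[, 1], y = rs[, 2])
  expect_equal(eccentricity(set_r, cone), eccentricity(set, cone),
               tolerance = 1e-9)
  expect_equal(contact_height(set_r, cone), contact_height(set, cone),
               tolerance = 1e-9)
})

test_that("a threshold on eccentricity and height alone separates synthetic classes", {
  sim <- simulate_opl(small_config(seed = 21), sac_cbc5 = FALSE)
  feats <- extract_contact_features(sim$contacts, sim$skeletons, sim$cones,
                                    sim$rods)
  j <- inner_join(feats, sim$truth,
                  by = c("bc_id", "terminal_id", "terminal_kind")) |>
    filter(terminal_kind == "cone")
  pred <- ifelse(j$b_ecc < sim$config$pedicle_radius & j$c_height < 0.6,
                 "synaptic", "non_synaptic")
  truth <- ifelse(j$label == "synaptic", "synaptic", "non_synaptic")
  expect_gt(mean(pred == truth), 0.8)
})
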