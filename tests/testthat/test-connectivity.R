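# Convergence/divergence, coverage factors, KDEs, rod stats, bootstrap.

library(dplyr)

test_that("dendritic hulls match closed forms and a gift-wrapping oracle", {
  sq <- tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(dendritic_hull(sq)$area, 1)
  tri <- tibble(x = c(0, 4, 0), y = c(0, 0, 3))
  expect_equal(dendritic_hull(tri)$area, 6)
  degen <- dendritic_hull(tibble(x = c(0, 1), y = c(0, 0)))
  expect_true(degen$degenerate)
  expect_equal(degen$area, 0)
  set.seed(12)
  for (i in 1:25) {
    x <- runif(30, 0, 50); y <- runif(30, 0, 50)
    expect_equal(dendritic_hull(tibble(x = x, y = y))$area,
                 oracle_hull_area(x, y), tolerance = 1e-9)
  }
})

test_that("hull overlap and union agree with independent area oracles", {
  sq <- function(cx, cy, s) dendritic_hull(tibble(
    x = cx + c(0, s, s, 0), y = cy + c(0, 0, s, s)))
  a <- sq(0, 0, 4); b <- sq(2, 2, 4); c <- sq(10, 10, 2)
  expect_equal(hull_overlap_area(a, b), 4, tolerance = 1e-9)
  expect_equal(hull_overlap_area(a, c), 0)
  expect_equal(hull_overlap_area(a, a), 16, tolerance = 1e-9)
  u <- hull_union_area(list(a, b, c), resolution = 0.05)
  expect_equal(u, 16 + 16 - 4 + 4, tolerance = 0.3)
  # random mosaics vs Monte-Carlo union
  set.seed(3)
  polys <- lapply(1:6, function(i) {
    ang <- sort(runif(8, 0, 2 * pi))
    r <- runif(1, 3, 6)
    cx <- runif(1, 5, 25); cy <- runif(1, 5, 25)
    dendritic_hull(tibble(x = cx + r * cos(ang), y = cy + r * sin(ang)))
  })
  u1 <- hull_union_area(polys, resolution = 0.1)
  u2 <- oracle_union_area_mc(lapply(polys, `[[`, "poly"))
  expect_lt(abs(u1 - u2) / u2, 0.01)
})

test_that("cones in field use the inclusive boundary convention", {
  skel <- new_skeleton(tibble(
    node_id = 1:4, parent_id = c(-1L, 1L, 1L, 1L),
    x = c(0, 10, 10, 0), y = c(0, 0, 10, 10), z = 0, radius = 0.5),
    cell_id = "sq")
  empty <- unit_cone(x = 50, y = 50)
  expect_equal(cones_in_field(skel, empty[0, ]), character(0))
  cones <- bind_rows(unit_cone(5, 5), unit_cone(10, 5), unit_cone(11, 5)) |>
    mutate(cone_id = c("in", "edge", "out"))
  expect_setequal(cones_in_field(skel, cones), c("in", "edge"))
  # random layouts vs ray-casting oracle
  set.seed(9)
  for (i in 1:10) {
    pts <- tibble(x = runif(12, 0, 10), y = runif(12, 0, 10))
    h <- dendritic_hull(pts)
    qs <- tibble(x = runif(40, -2, 12), y = runif(40, -2, 12))
    got <- points_in_hull(h, cbind(qs$x, qs$y))
    want <- oracle_in_polygon(h$poly, qs$x, qs$y)
    expect_equal(got, want)
  }
})

make_toy_network <- function() {
  # two BC types, four cells, five cones with planted wiring
  cells <- tibble(cell_id = c("a1", "a2", "b1", "b2"),
                  type = c("T1", "T1", "T2", "T2"),
                  soma_x = c(2, 8, 2, 8), soma_y = 5, soma_z = 14)
  cones <- bind_rows(
    unit_cone(1, 1), unit_cone(4, 4), unit_cone(7, 7), unit_cone(9, 2),
    unit_cone(3, 8)) |>
    mutate(cone_id = paste0("c", 1:5), spectral = c("S", "M", "M", "M", "S"))
  sets <- tibble(
    bc_id = c("a1", "a1", "a2", "b1", "b2", "b2"),
    terminal_id = c("c1", "c2", "c3", "c2", "c4", "c5"),
    terminal_kind = "cone",
    label = c("synaptic", "synaptic", "synaptic", "synaptic", "synaptic",
              "non_synaptic"))
  list(cells = cells, cones = cones, sets = sets)
}

test_that("convergence and divergence reproduce planted wiring exactly", {
  toy <- make_toy_network()
  none <- convergence_divergence(mutate(toy$sets, label = "non_synaptic"),
                                 toy$cells, toy$cones, n_boot = 100)
  expect_true(all(none$convergence$mean_cones == 0))
  cd <- convergence_divergence(toy$sets, toy$cells, toy$cones, n_boot = 100)
  per_cell <- cd$per_cell
  expect_equal(per_cell$n_cones[per_cell$cell_id == "a1" &
                                  per_cell$spectral == "S"], 1L)
  expect_equal(per_cell$n_cones[per_cell$cell_id == "a1" &
                                  per_cell$spectral == "M"], 1L)
  expect_equal(per_cell$n_cones[per_cell$cell_id == "b2" &
                                  per_cell$spectral == "M"], 1L)
  # duality: total contacted cones per type == total contacting BCs per type
  for (ty in c("T1", "T2")) {
    lhs <- sum(per_cell$n_cones[per_cell$type == ty])
    rhs <- sum(cd$per_cone$n_bcs[cd$per_cone$type == ty])
    expect_equal(lhs, rhs)
  }
})

test_that("coverage factors hit the trivial cases", {
  skel <- function(id, cx) new_skeleton(tibble(
    node_id = 1:4, parent_id = c(-1L, 1L, 1L, 1L),
    x = cx + c(0, 4, 4, 0), y = c(0, 0, 4, 4), z = 0, radius = 0.5),
    cell_id = id)
  cones <- bind_rows(unit_cone(2, 2), unit_cone(12, 2)) |>
    mutate(cone_id = c("c1", "c2"))
  one <- coverage_factors(tibble(cell_id = "s1", type = "T"),
                          list(s1 = skel("s1", 0)), cones,
                          resolution = 0.05)
  expect_equal(one$hull_coverage, 1, tolerance = 0.02)
  expect_equal(one$cone_coverage, 1)
  two <- coverage_factors(tibble(cell_id = c("s1", "s2"), type = "T"),
                          list(s1 = skel("s1", 0), s2 = skel("s2", 10)),
                          cones, resolution = 0.05)
  expect_equal(two$hull_coverage, 1, tolerance = 0.02)
  expect_equal(two$cone_coverage, 1)
})

test_that("contact-distance KDEs are normalized with modes where planted", {
  toy <- make_toy_network()
  skels <- setNames(lapply(toy$cells$cell_id, function(id) {
    i <- match(id, toy$cells$cell_id)
    new_skeleton(tibble(
      node_id = 1:4, parent_id = c(-1L, 1L, 1L, 1L),
      x = toy$cells$soma_x[i] + c(0, 3, -3, 0),
      y = toy$cells$soma_y[i] + c(0, 3, 3, -4), z = 0, radius = 0.5),
      cell_id = id)
  }), toy$cells$cell_id)
  # ring wiring: contacted cones at planar distance ~5 from the soma
  set.seed(4)
  ring_cones <- bind_rows(lapply(1:8, function(k) {
    r <- 5 + runif(1, -0.2, 0.2)
    unit_cone(2 + r * cos(k), 5 + r * sin(k))
  })) |> mutate(cone_id = paste0("r", 1:8))
  ring_sets <- tibble(bc_id = "a1", terminal_id = ring_cones$cone_id,
                      terminal_kind = "cone", label = "synaptic")
  kde <- contact_distance_kde(ring_sets, toy$cells, skels, ring_cones)
  curve <- kde$kde
  expect_equal(sum(curve$density) * diff(curve$distance[1:2]), 1,
               tolerance = 1e-3)
  mode <- curve$distance[which.max(curve$density)]
  bw <- density(kde$distances$distance, bw = "nrd0")$bw
  expect_lt(abs(mode - 5), max(bw, 0.5))
})

test_that("rod connectivity respects the RBC-contact restriction", {
  cells <- tibble(cell_id = c("r1", "r2", "o1"),
                  type = c("RBC", "RBC", "CBC3B"),
                  soma_x = c(5, 6, 5), soma_y = 5, soma_z = 14)
  rods <- tibble(rod_id = paste0("rod", 1:4), x = c(2, 4, 6, 8), y = 5,
                 z = 6, radius = 0.9)
  sets <- tibble(
    bc_id = c("r1", "r2", "r1", "o1", "o1"),
    terminal_id = c("rod1", "rod1", "rod2", "rod2", "rod3"),
    terminal_kind = "rod",
    label = c("synaptic", "synaptic", "synaptic", "synaptic", "synaptic"))
  rc <- rod_connectivity(sets, rods, cells, n_boot = 100)
  hist <- setNames(rc$rbc_per_rod$n_rods, rc$rbc_per_rod$bin)
  expect_equal(unname(hist["2"]), 1L)  # rod1 has two distinct RBCs
  expect_equal(unname(hist["1"]), 1L)
  expect_equal(unname(hist["0"]), 2L)
  # rod3 has no RBC contact: o1's contact there is dropped from OFF counts
  off <- rc$rods_per_cell |> filter(bc_id == "o1")
  expect_equal(off$n_rods, 1L)
  expect_equal(rc$n_rods_excluded, 2L)
})

test_that("RBC group comparison flags degenerate splits and detects planted effects", {
  square_skel <- function(id, s) new_skeleton(tibble(
    node_id = 1:4, parent_id = c(-1L, 1L, 1L, 1L),
    x = c(0, s, s, 0), y = c(0, 0, s, s), z = 0, radius = 0.5),
    cell_id = id)
  build <- function(n, hull_mult = 1, cone_frac = 0.5, seed = 1) {
    set.seed(seed)
    ids <- paste0("r", seq_len(n))
    has_cone <- runif(n) < cone_frac
    sides <- sqrt(ifelse(has_cone, 100 * hull_mult, 100))
    cells <- tibble(cell_id = ids, type = "RBC", soma_x = 0, soma_y = 0,
                    soma_z = 14)
    skels <- setNames(lapply(seq_len(n), function(i) {
      square_skel(ids[i], sides[i])
    }), ids)
    rod_sets <- bind_rows(lapply(seq_len(n), function(i) {
      k <- rpois(1, 30)
      tibble(bc_id = ids[i], terminal_id = paste0("rod", i, "_", seq_len(k)),
             terminal_kind = "rod", label = "synaptic")
    }))
    cone_sets <- tibble(bc_id = ids[has_cone], terminal_id = "c1",
                        terminal_kind = "cone", label = "synaptic")
    list(cells = cells, skels = skels, sets = bind_rows(rod_sets, cone_sets))
  }
  rod_only <- build(10, cone_frac = 0)
  deg <- rbc_group_compare(rod_only$sets, rod_only$cells, rod_only$skels,
                           n_boot = 200)
  expect_true(deg$degenerate)
  # identical group parameters: the CI for the difference usually covers 0
  cover0 <- sapply(1:20, function(s) {
    d <- build(40, hull_mult = 1, seed = s)
    cmp <- rbc_group_compare(d$sets, d$cells, d$skels, n_boot = 300,
                             seed = s)
    diffs <- cmp$differences
    with(diffs[diffs$quantity == "hull_area", ],
         ci_low <= 0 && ci_high >= 0)
  })
  expect_gte(mean(cover0), 0.9)
  # a planted 2x hull-area difference is detected
  power <- sapply(1:20, function(s) {
    d <- build(40, hull_mult = 2, seed = 100 + s)
    cmp <- rbc_group_compare(d$sets, d$cells, d$skels, n_boot = 300,
                             seed = s)
    diffs <- cmp$differences
    with(diffs[diffs$quantity == "hull_area", ], ci_low > 0 | ci_high < 0)
  })
  expect_gte(mean(power), 0.9)
})

test_that("bootstrap CIs behave: degenerate width, coverage, determinism", {
  const <- bootstrap_ci(rep(3.5, 20), n_boot = 200)
  expect_equal(unname(const["low"]), 3.5)
  expect_equal(unname(const["high"]), 3.5)
  set.seed(77)
  covered <- sapply(1:500, function(i) {
    v <- rnorm(200)
    ci <- bootstrap_ci(v, n_boot = 200, seed = i)
    ci["low"] <= 0 && ci["high"] >= 0
  })
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.99)
  a <- bootstrap_ci(rnorm(50), n_boot = 500, seed = 5)
  b <- bootstrap_ci(rnorm(50), n_boot = 500, seed = 5)
  expect_false(identical(a, b))  # different samples
  v <- rnorm(50)
  expect_identical(bootstrap_ci(v, n_boot = 500, seed = 5),
                   bootstrap_ci(v, n_boot = 500, seed = 5))
  expect_error(bootstrap_ci(numeric(0)), "empty")
  expect_error(bootstrap_ci(1:10, n_boot = 10), "n_boot")
})

test_that("bootstrap CI width shrinks like 1/sqrt(n)", {
  set.seed(21)
  widths <- sapply(c(50, 200, 800), function(n) {
    mean(sapply(1:20, function(i) {
      ci <- bootstrap_ci(rnorm(n), n_boot = 300, seed = i)
      ci["high"] - ci["low"]
    }))
  })
  ratio <- widths[1] / widths[3]
  expect_gt(ratio, 2.5)  # exact scaling would be 4
  expect_lt(ratio, 6)
  slope <- coef(lm(log(widths) ~ log(c(50, 200, 800))))[2]
  expect_lt(abs(slope + 0.5), 0.12)
})

test_that("invaginating/tip tallies reproduce planted contingency tables", {
  cells <- tibble(cell_id = c(paste0("x", 1:7), paste0("o", 1:12)),
                  type = c(rep("CBCX", 7), rep("other_ON", 12)))
  # the reference counts: CBCX 3 invaginating of 19, others 71 of 81
  mk_sets <- function(ids, n, n_inv, type_seed) {
    set.seed(type_seed)
    tibble(bc_id = sample(ids, n, TRUE),
           terminal_id = paste0("c", seq_len(n)),
           subtype = rep(c("invaginating", "tip"), c(n_inv, n - n_inv)))
  }
  sets <- bind_rows(mk_sets(paste0("x", 1:7), 19, 3, 1),
                    mk_sets(paste0("o", 1:12), 81, 71, 2))
  tal <- contact_type_tally(sets, cells)
  tab <- tal$tally
  expect_equal(tab$n_invaginating[tab$type == "CBCX"], 3L)
  expect_equal(tab$n_tip[tab$type == "CBCX"], 16L)
  expect_equal(tab$n_invaginating[tab$type == "other_ON"], 71L)
  expect_equal(tab$n_tip[tab$type == "other_ON"], 10L)
  expect_equal(sum(tab$n_invaginating + tab$n_tip), nrow(sets))
  # threshold-based sub-labelling: all high invaginating -> tip column 0
  feat_sets <- tibble(bc_id = "x1", terminal_id = paste0("c", 1:5),
                      c_height = 0.4, b_ecc = 1)
  tal2 <- contact_type_tally(feat_sets, cells)
  expect_equal(tal2$tally$n_tip, 0L)
  expect_equal(tal2$tally$n_invaginating, 5L)
})
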