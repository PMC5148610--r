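# Population generators for the synthetic outer plexiform layer.
#
# Axis convention (documented in the dataset manifest): coordinates in µm;
# +z points from the inner retina toward the photoreceptors. Cone pedicle
# bases sit at z = 0 with the pedicle body in [0, height]; rod spherules
# float above at z ~ 6; BC somata below at z ~ 14; the IPL (SAC bands, BC
# axons) lies at negative z.

# Hexagonal lattice clipped to [0,w] x [0,h]; px/py shift the lattice phase
# (fractions of the spacing / row height).
hex_lattice <- function(w, h, spacing, px = 0, py = 0) {
  dy <- spacing * sqrt(3) / 2
  rows <- seq(spacing / 2 + py * dy, h, by = dy)
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    x0 <- if (i %% 2 == 0) spacing / 2 else spacing
    xs <- seq(x0 / 2 + px * spacing, w, by = spacing)
    cbind(xs, rows[i])
  }))
  pts[pts[, 1] >= 0 & pts[, 1] <= w & pts[, 2] >= 0 & pts[, 2] <= h, ,
      drop = FALSE]
}

#' Generate a jittered cone-pedicle mosaic
#'
#' Places cone pedicles on a jittered hexagonal lattice clipped to the field,
#' enforces a minimum centre-to-centre exclusion distance, and assigns each
#' pedicle an S spectral label with probability `s_cone_prob`. At the default
#' density and field size the mosaic holds ~163 pedicles.
#'
#' @param config An [opl_config()].
#' @return Tibble with columns `cone_id`, `x`, `y`, `basal_z`, `height`,
#'   `radius`, `axis_x/y/z`, `spectral`, `complete`.
#' @export
generate_cone_mosaic <- function(config) {
  set.seed(config$seed + 101L)
  w <- config$field_size[1]; h <- config$field_size[2]
  if (config$cone_density == 0) {
    return(tibble(cone_id = character(0), x = numeric(0), y = numeric(0),
                  basal_z = numeric(0), height = numeric(0),
                  radius = numeric(0), axis_x = numeric(0),
                  axis_y = numeric(0), axis_z = numeric(0),
                  spectral = character(0), complete = logical(0)))
  }
  spacing <- sqrt(2 / (sqrt(3) * config$cone_density / 1000))
  if (spacing < config$cone_exclusion) {
    abort("cone_density too high for the configured exclusion radius")
  }
  # correct for lattice clipping at the field border: small deterministic
  # search over spacing and lattice phase, count closest to the density
  # target wins
  n_target <- round(config$cone_density * w * h / 1000)
  best <- NULL
  for (f in seq(0.94, 1.04, by = 0.01)) {
    s <- max(spacing * f, config$cone_exclusion)
    for (px in c(0, 0.25, 0.5)) {
      for (py in c(0, 0.3, 0.6)) {
        n <- nrow(hex_lattice(w, h, s, px, py))
        if (is.null(best) || abs(n - n_target) < abs(best$n - n_target)) {
          best <- list(s = s, px = px, py = py, n = n)
        }
      }
    }
    if (!is.null(best) && best$n == n_target) break
  }
  spacing <- best$s
  base <- hex_lattice(w, h, spacing, best$px, best$py)
  jitter <- 0.22 * spacing
  # per-point rejection sampling of the jitter under the exclusion radius
  pts <- matrix(NA_real_, nrow(base), 2)
  for (i in seq_len(nrow(base))) {
    placed <- FALSE
    for (try in 1:40) {
      j <- jitter / (1 + (try - 1) / 8)  # shrink jitter if crowded
      cand <- base[i, ] + runif(2, -j, j)
      if (cand[1] < 0 || cand[1] > w || cand[2] < 0 || cand[2] > h) next
      if (i == 1L || all((pts[seq_len(i - 1L), 1] - cand[1])^2 +
                           (pts[seq_len(i - 1L), 2] - cand[2])^2 >=
                           config$cone_exclusion^2)) {
        pts[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) {
      abort("could not satisfy cone exclusion radius after bounded retries")
    }
  }
  n <- nrow(pts)
  margin <- config$pedicle_radius
  tibble(
    cone_id = sprintf("cone_%03d", seq_len(n)),
    x = pts[, 1], y = pts[, 2],
    basal_z = 0, height = config$pedicle_height,
    radius = config$pedicle_radius,
    axis_x = 0, axis_y = 0, axis_z = 1,
    spectral = if_else(runif(n) < config$s_cone_prob, "S", "M"),
    complete = pts[, 1] >= margin & pts[, 1] <= w - margin &
      pts[, 2] >= margin & pts[, 2] <= h - margin
  )
}

#' Generate the rod-spherule field
#'
#' Rod spherules are laid out on a dense jittered grid restricted to a
#' sub-rectangle covering `rod_field_fraction` of the x extent, mirroring a
#' half-field reconstruction.
#'
#' @param config An [opl_config()].
#' @return Tibble with `rod_id`, `x`, `y`, `z` (centre) and `radius`.
#' @export
generate_rod_field <- function(config) {
  set.seed(config$seed + 102L)
  w <- config$field_size[1] * config$rod_field_fraction
  h <- config$field_size[2]
  n_target <- round(config$rod_density * w * h / 1000)
  if (n_target <= 0) {
    return(tibble(rod_id = character(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), radius = numeric(0)))
  }
  spacing <- sqrt(w * h / n_target)
  nx <- max(1L, round(w / spacing)); ny <- max(1L, ceiling(n_target / nx))
  gx <- (seq_len(nx) - 0.5) * (w / nx)
  gy <- (seq_len(ny) - 0.5) * (h / ny)
  pts <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  pts <- pts + matrix(runif(2 * nrow(pts), -0.3 * spacing, 0.3 * spacing),
                      ncol = 2)
  pts <- pts[seq_len(min(n_target, nrow(pts))), , drop = FALSE]
  tibble(
    rod_id = sprintf("rod_%04d", seq_len(nrow(pts))),
    x = pmin(pmax(pts[, 1], 0), w), y = pmin(pmax(pts[, 2], 0), h),
    z = 6 + runif(nrow(pts), -0.5, 0.5),
    radius = config$rod_radius
  )
}

# Grow one BC dendritic arbor: soma -> hub -> 6 primary branches, each
# forking once into two tips. Planar coordinates are rescaled about the soma
# so the projected convex hull matches the per-cell target area exactly.
grow_bc_skeleton <- function(cell_id, type, soma, target_area) {
  n_primary <- 6L
  R <- sqrt(target_area / 2.598)  # circumradius of a regular hexagon of that area
  theta <- 2 * pi * (seq_len(n_primary) - 1) / n_primary +
    runif(1, 0, 2 * pi / n_primary) + runif(n_primary, -0.15, 0.15)
  nodes <- list(
    c(1, 1, soma[1], soma[2], 14, 2, -1),          # soma
    c(2, 3, soma[1], soma[2], 6, 1.2, 1)           # hub (primary branch point)
  )
  nid <- 2L
  for (k in seq_len(n_primary)) {
    rk <- R * runif(1, 0.92, 1.08)
    mid <- soma[1:2] + 0.55 * rk * c(cos(theta[k]), sin(theta[k]))
    nid <- nid + 1L; mid_id <- nid
    nodes[[length(nodes) + 1L]] <- c(mid_id, 3, mid[1], mid[2], 4, 0.6, 2)
    for (s in c(-1, 1)) {
      ang <- theta[k] + s * runif(1, 0.12, 0.3)
      tip <- soma[1:2] + rk * runif(1, 0.95, 1.05) * c(cos(ang), sin(ang))
      nid <- nid + 1L
      nodes[[length(nodes) + 1L]] <- c(nid, 3, tip[1], tip[2], 2.5, 0.3, mid_id)
    }
  }
  m <- do.call(rbind, nodes)
  nodes <- tibble(node_id = as.integer(m[, 1]), swc_type = as.integer(m[, 2]),
                  x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                  parent_id = as.integer(m[, 7]))
  a0 <- dendritic_hull(nodes)$area
  if (a0 > 0) {
    f <- sqrt(target_area / a0)
    nodes$x <- soma[1] + f * (nodes$x - soma[1])
    nodes$y <- soma[2] + f * (nodes$y - soma[2])
  }
  new_skeleton(nodes, cell_id = cell_id, cell_type = type)
}

#' Generate a bipolar-cell population of one type
#'
#' Somata are placed on a jittered grid over a centred sub-rectangle sized so
#' that the sum of dendritic hull areas divided by their union approximates
#' the configured coverage factor; each cell's arbor is grown by recursive
#' branching and rescaled so its projected convex hull matches a per-cell
#' area drawn around the configured type mean.
#'
#' @param config An [opl_config()].
#' @param type_name BC type label present in `config$bc_type_params`.
#' @return List with `cells` (tibble: `cell_id`, `type`, `soma_x/y/z`) and
#'   `skeletons` (named list of `opl_skeleton`).
#' @export
generate_bc_population <- function(config, type_name) {
  par <- config$bc_type_params
  i <- match(type_name, par$type)
  if (is.na(i)) abort(sprintf("unknown BC type '%s'", type_name))
  set.seed(config$seed + 200L + i)
  n <- par$n_cells[i]; A <- par$hull_area[i]; cov <- par$coverage[i]
  W <- config$field_size[1]; H <- config$field_size[2]
  R <- sqrt(A / 2.598)
  U <- n * A / cov  # union area implied by the coverage target
  rho <- W / H
  jit_u <- matrix(runif(2 * n, -1, 1), ncol = 2)  # fixed jitter draws
  place <- function(w_eff, h_eff) {
    if (n == 1L) return(cbind(W / 2, H / 2))
    x0 <- (W - w_eff) / 2; y0 <- (H - h_eff) / 2
    nx <- max(1L, round(sqrt(n * w_eff / max(h_eff, 1e-6))))
    ny <- ceiling(n / nx)
    gx <- x0 + (seq_len(nx) - 0.5) * (w_eff / nx)
    gy <- y0 + (seq_len(ny) - 0.5) * (h_eff / ny)
    s <- cbind(rep(gx, times = ny), rep(gy, each = nx))[seq_len(n), , drop = FALSE]
    s + 0.22 * min(w_eff / nx, h_eff / ny) * jit_u
  }
  # calibrate the placement rectangle so the measured union of (approximate
  # hexagonal) hulls matches the coverage target
  ang12 <- 2 * pi * (0:11) / 12
  approx_hull <- function(cx, cy) cbind(cx + R * cos(ang12), cy + R * sin(ang12))
  h_eff <- min(sqrt(U / rho), H); w_eff <- min(rho * h_eff, W)
  somata <- place(w_eff, h_eff)
  if (n > 1L) {
    for (it in 1:4) {
      hulls_est <- lapply(seq_len(n), function(j) {
        approx_hull(somata[j, 1], somata[j, 2])
      })
      u <- hull_union_area(hulls_est, resolution = max(0.5, R / 12))
      if (abs(u - U) / U < 0.03) break
      if (w_eff >= W && h_eff >= H && u < U) break  # field-limited
      s <- sqrt(U / u)
      w_eff <- min(w_eff * s, W); h_eff <- min(h_eff * s, H)
      somata <- place(w_eff, h_eff)
    }
  }
  ids <- sprintf("%s_%03d", tolower(type_name), seq_len(n))
  areas <- pmax(rnorm(n, A, 0.08 * A), 0.4 * A)
  skels <- lapply(seq_len(n), function(j) {
    grow_bc_skeleton(ids[j], type_name, somata[j, ], areas[j])
  })
  names(skels) <- ids
  list(
    cells = tibble(cell_id = ids, type = type_name,
                   soma_x = somata[, 1], soma_y = somata[, 2], soma_z = 14),
    skeletons = skels
  )
}
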