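# SAC (ChAT) band surfaces and CBC5 axonal point clouds.

sac_true_z <- function(cfg_sac, band, x, y) {
  z0 <- if (band == "ON") cfg_sac$z_on else cfg_sac$z_off
  ph <- if (band == "ON") 0 else pi / 3
  A <- cfg_sac$warp_amplitude
  L <- cfg_sac$warp_period
  z0 + A * sin(2 * pi * x / L + ph) * cos(2 * pi * y / L + ph / 2)
}

#' Generate starburst-amacrine (ChAT) band point clouds
#'
#' Samples two dense dendritic point clouds around smoothly warped,
#' non-intersecting surfaces in the IPL: the ON band below the OFF band
#' (`z_on < z_off` by convention). With `warp_amplitude = 0` both surfaces
#' are flat planes.
#'
#' @param config An [opl_config()].
#' @return List with `points` (tibble: `band`, `x`, `y`, `z`) and
#'   `true_surface`, a `function(band, x, y)` returning the noiseless band
#'   depth (generator ground truth).
#' @export
generate_sac_bands <- function(config) {
  set.seed(config$seed + 401L)
  w <- config$field_size[1]; h <- config$field_size[2]
  s <- config$sac
  one_band <- function(which_band) {
    n <- s$n_points
    x <- runif(n, 0, w); y <- runif(n, 0, h)
    z <- sac_true_z(s, which_band, x, y) + rnorm(n, 0, s$noise_sd)
    tibble(band = which_band, x = x, y = y, z = z)
  }
  list(points = bind_rows(one_band("ON"), one_band("OFF")),
       true_surface = function(band, x, y) sac_true_z(s, band, x, y))
}

#' Generate CBC5 axonal point clouds with planted subtypes
#'
#' Three CBC5 subtypes (by default 22/22/25 cells) are laid out as
#' approximately tiling mosaics; each cell's axonal arbor is a planar
#' Gaussian cloud whose depth follows the local warped SAC bands at the
#' subtype's planted corrected stratification depth (ON band = 0,
#' OFF band = 1). Dendritic (OPL) hull polygons are also generated so the
#' mosaic-overlap cost has both compartments to work with.
#'
#' @param config An [opl_config()].
#' @param sac Output of [generate_sac_bands()] (its true surfaces position
#'   the clouds); defaults to generating one.
#' @return List with `cells` (tibble: `cell_id`, `subtype_true`, `soma_x/y`,
#'   planted `depth_true`), `axon_points` (tibble: `cell_id`, `x`, `y`, `z`,
#'   `weight`), `opl_hulls` and `ipl_hulls` (named lists of `opl_hull`).
#' @export
generate_cbc5_axons <- function(config, sac = generate_sac_bands(config)) {
  set.seed(config$seed + 501L)
  w <- config$field_size[1]; h <- config$field_size[2]
  c5 <- config$cbc5
  par <- config$bc_type_params
  subtypes <- c("CBC5T", "CBC5O", "CBC5I")
  present <- subtypes[subtypes %in% par$type]
  cells_l <- list(); pts_l <- list(); opl_hulls <- list(); ipl_hulls <- list()
  for (si in seq_along(present)) {
    ty <- present[si]
    p <- par[match(ty, par$type), ]
    n <- p$n_cells
    nx <- max(1L, round(sqrt(n * w / h))); ny <- ceiling(n / nx)
    gx <- (seq_len(nx) - 0.5) * (w / nx); gy <- (seq_len(ny) - 0.5) * (h / ny)
    somata <- cbind(rep(gx, times = ny), rep(gy, each = nx))[seq_len(n), , drop = FALSE]
    somata <- somata + matrix(runif(2 * n, -0.18, 0.18) *
                                rep(c(w / nx, h / ny), each = n), ncol = 2)
    ids <- sprintf("%s_%03d", tolower(ty), seq_len(n))
    d0 <- c5$depths[si]
    depth_cell <- d0 + runif(n, -c5$cell_jitter, c5$cell_jitter)
    r_ipl <- sqrt((p$ipl_hull_area %||% 350) / pi)
    r_opl <- sqrt(p$hull_area / pi)
    for (j in seq_len(n)) {
      m <- c5$n_axon_points
      px <- pmin(pmax(rnorm(m, somata[j, 1], r_ipl / 2), 0), w)
      py <- pmin(pmax(rnorm(m, somata[j, 2], r_ipl / 2), 0), h)
      d <- rnorm(m, depth_cell[j], c5$profile_sd)
      zon <- sac$true_surface("ON", px, py)
      zoff <- sac$true_surface("OFF", px, py)
      pts_l[[ids[j]]] <- tibble(cell_id = ids[j], x = px, y = py,
                                z = zon + d * (zoff - zon),
                                weight = 1)
      ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
      opl_hulls[[ids[j]]] <- dendritic_hull(tibble(
        x = somata[j, 1] + r_opl * cos(ang) * runif(12, 0.9, 1.1),
        y = somata[j, 2] + r_opl * sin(ang) * runif(12, 0.9, 1.1)))
      ipl_hulls[[ids[j]]] <- dendritic_hull(pts_l[[ids[j]]])
    }
    cells_l[[ty]] <- tibble(cell_id = ids, subtype_true = ty,
                            soma_x = somata[, 1], soma_y = somata[, 2],
                            depth_true = depth_cell)
  }
  list(cells = bind_rows(cells_l), axon_points = bind_rows(pts_l),
       opl_hulls = opl_hulls, ipl_hulls = ipl_hulls)
}
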