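# Connectivity quantifications: convergence/divergence of cone-BC wiring,
# in-field vs contacted cone counts, coverage factors, contact-distance
# KDEs, rod connectivity, the RBC two-group comparison and percentile
# bootstrap confidence intervals.

#' Cones within a cell's dendritic field
#'
#' @param skel An `opl_skeleton` (dendritic nodes are used for the hull).
#' @param cones Cone tibble.
#' @return Character vector of cone ids whose centre projects inside or on
#'   the dendritic hull (boundary included).
#' @export
cones_in_field <- function(skel, cones) {
  if (nrow(cones) == 0L) return(character(0))
  h <- dendritic_hull(skel)
  cones$cone_id[points_in_hull(h, cbind(cones$x, cones$y))]
}

#' Percentile bootstrap confidence interval
#'
#' Case-resampling bootstrap of an arbitrary statistic; the interval is the
#' central `level` percentile range of the bootstrap distribution.
#'
#' @param values Sample vector (non-empty).
#' @param statistic Function of a vector (default [mean()]).
#' @param n_boot Number of resamples (>= 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  if (length(values) == 0L) abort("empty sample")
  if (n_boot < 100L) abort("n_boot must be >= 100")
  set.seed(seed)
  stats <- vapply(seq_len(n_boot), function(i) {
    statistic(sample(values, length(values), replace = TRUE))
  }, numeric(1))
  a <- (1 - level) / 2
  q <- quantile(stats, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

# Synaptic contact-sets joined with cell and cone metadata.
synaptic_cone_sets <- function(sets, cells, cones) {
  sets |>
    filter(.data$terminal_kind == "cone", .data$label == "synaptic") |>
    left_join(cells[, c("cell_id", "type")], by = c(bc_id = "cell_id")) |>
    left_join(cones[, c("cone_id", "spectral", "complete")],
              by = c(terminal_id = "cone_id"))
}

#' Convergence and divergence of cone-to-BC connectivity
#'
#' Convergence: per (BC type, spectral class), the mean number of cones a
#' cell synaptically contacts. Divergence: per (spectral class, BC type),
#' the mean number of BCs of that type contacted by a cone. Restricted to
#' complete cones; per-cell and per-cone records are returned alongside the
#' bootstrapped means so the duality (sum of per-cell counts = sum of
#' per-cone counts within a type) is checkable.
#'
#' @param sets Classified contact-set tibble (`bc_id`, `terminal_id`,
#'   `terminal_kind`, `label`).
#' @param cells Cell metadata (`cell_id`, `type`).
#' @param cones Cone tibble with `spectral` and `complete`.
#' @param n_boot,seed Bootstrap parameters.
#' @return List of tibbles: `convergence`, `divergence`, `per_cell`,
#'   `per_cone`, `contacted_fraction` (contacted vs in-field cones requires
#'   skeletons; see [contacted_fraction()]).
#' @export
convergence_divergence <- function(sets, cells, cones, n_boot = 500L,
                                   seed = 1L) {
  syn <- synaptic_cone_sets(sets, cells, cones) |>
    filter(.data$complete %in% c(TRUE, NA))
  spectra <- c("S", "M")
  grid_cells <- tidyr::expand_grid(cell_id = cells$cell_id,
                                   spectral = spectra) |>
    left_join(cells[, c("cell_id", "type")], by = "cell_id")
  per_cell <- syn |>
    count(.data$bc_id, .data$spectral, name = "n_cones") |>
    rename(cell_id = "bc_id") |>
    dplyr::right_join(grid_cells, by = c("cell_id", "spectral")) |>
    mutate(n_cones = dplyr::coalesce(.data$n_cones, 0L))
  convergence <- per_cell |>
    group_by(.data$type, .data$spectral) |>
    summarise(n_cells = n(), mean_cones = mean(.data$n_cones),
              ci = list(bootstrap_ci(.data$n_cones, n_boot = n_boot,
                                     seed = seed)),
              .groups = "drop") |>
    mutate(ci_low = map_dbl(.data$ci, 1), ci_high = map_dbl(.data$ci, 2)) |>
    select(-"ci")
  complete_cones <- cones |> filter(.data$complete %in% c(TRUE, NA))
  grid_cones <- tidyr::expand_grid(cone_id = complete_cones$cone_id,
                                   type = unique(cells$type)) |>
    left_join(complete_cones[, c("cone_id", "spectral")], by = "cone_id")
  per_cone <- syn |>
    count(.data$terminal_id, .data$type, name = "n_bcs") |>
    rename(cone_id = "terminal_id") |>
    dplyr::right_join(grid_cones, by = c("cone_id", "type")) |>
    mutate(n_bcs = dplyr::coalesce(.data$n_bcs, 0L))
  divergence <- per_cone |>
    group_by(.data$spectral, .data$type) |>
    summarise(n_cones = n(), mean_bcs = mean(.data$n_bcs),
              ci = list(bootstrap_ci(.data$n_bcs, n_boot = n_boot,
                                     seed = seed)),
              .groups = "drop") |>
    mutate(ci_low = map_dbl(.data$ci, 1), ci_high = map_dbl(.data$ci, 2)) |>
    select(-"ci")
  list(convergence = convergence, divergence = divergence,
       per_cell = per_cell, per_cone = per_cone)
}

#' Contacted fraction of in-field cones
#'
#' For each cell: the number of (complete) cones within the dendritic hull,
#' the number synaptically contacted, and per type the mean counts and
#' contacted fraction.
#'
#' @param sets Classified contact-set tibble.
#' @param cells Cell metadata.
#' @param skeletons Named skeleton list.
#' @param cones Cone tibble.
#' @return List with `per_cell` and `per_type` tibbles.
#' @export
contacted_fraction <- function(sets, cells, skeletons, cones) {
  cones_c <- cones |> filter(.data$complete %in% c(TRUE, NA))
  syn <- sets |>
    filter(.data$terminal_kind == "cone", .data$label == "synaptic")
  per_cell <- map(cells$cell_id, function(id) {
    infield <- cones_in_field(skeletons[[id]], cones_c)
    contacted <- intersect(syn$terminal_id[syn$bc_id == id], cones_c$cone_id)
    tibble(cell_id = id, n_in_field = length(infield),
           n_contacted = length(intersect(contacted, infield)))
  }) |>
    bind_rows() |>
    left_join(cells[, c("cell_id", "type")], by = "cell_id")
  per_type <- per_cell |>
    group_by(.data$type) |>
    summarise(n_cells = n(), mean_in_field = mean(.data$n_in_field),
              mean_contacted = mean(.data$n_contacted),
              fraction = sum(.data$n_contacted) / max(1, sum(.data$n_in_field)),
              .groups = "drop")
  list(per_cell = per_cell, per_type = per_type)
}

#' Coverage factors of one BC type's mosaic
#'
#' Hull coverage: sum of convex-hull areas divided by the area of their
#' union. Cone coverage: sum over cells of the number of (complete) cones in
#' the dendritic field, divided by the number of cones in the joint field.
#'
#' @param cells Cell metadata of a single type.
#' @param skeletons Named skeleton list.
#' @param cones Cone tibble.
#' @param resolution Grid resolution for the union area (µm).
#' @return One-row tibble: `type`, `n_cells`, `hull_area_mean`,
#'   `hull_area_sd`, `hull_coverage`, `cone_coverage`.
#' @export
coverage_factors <- function(cells, skeletons, cones, resolution = 0.25) {
  if (nrow(cells) == 0L) abort("no cells")
  hulls <- lapply(cells$cell_id, function(id) dendritic_hull(skeletons[[id]]))
  areas <- vapply(hulls, `[[`, numeric(1), "area")
  u <- hull_union_area(hulls, resolution = resolution)
  if (u <= 0) abort("union of hulls has zero area")
  cones_c <- cones |> filter(.data$complete %in% c(TRUE, NA))
  infield <- lapply(cells$cell_id, function(id) {
    cones_in_field(skeletons[[id]], cones_c)
  })
  joint <- unique(unlist(infield))
  cone_cov <- if (length(joint) > 0L) {
    sum(lengths(infield)) / length(joint)
  } else NA_real_
  tibble(type = cells$type[1], n_cells = nrow(cells),
         hull_area_mean = mean(areas), hull_area_sd = sd(areas),
         hull_coverage = sum(areas) / u, cone_coverage = cone_cov)
}

#' Kernel density estimate of contact distance from the soma
#'
#' Planar distances from each cell's soma to the centres of its synaptically
#' contacted cones, optionally normalized by the cell's equivalent dendritic
#' field radius sqrt(A/pi); one Gaussian KDE per BC type (Silverman's
#' bandwidth by default). Curves are normalized to unit integral.
#'
#' @param sets Classified contact-set tibble.
#' @param cells Cell metadata with `soma_x`, `soma_y`.
#' @param skeletons Named skeleton list (for hull areas when normalizing).
#' @param cones Cone tibble.
#' @param normalize Divide distances by the equivalent hull radius?
#' @param bw Bandwidth ("nrd0" = Silverman, or numeric).
#' @param n Grid size of the returned curve.
#' @return List with `distances` (per-contact tibble) and `kde` (tibble
#'   `type`, `distance`, `density`).
#' @export
contact_distance_kde <- function(sets, cells, skeletons, cones,
                                 normalize = FALSE, bw = "nrd0", n = 256L) {
  cone_xy <- cones[, c("cone_id", "x", "y")] |>
    rename(cone_x = "x", cone_y = "y")
  syn <- synaptic_cone_sets(sets, cells, cones) |>
    left_join(cells[, c("cell_id", "soma_x", "soma_y")],
              by = c(bc_id = "cell_id")) |>
    left_join(cone_xy, by = c(terminal_id = "cone_id"))
  d <- sqrt((syn$cone_x - syn$soma_x)^2 + (syn$cone_y - syn$soma_y)^2)
  if (normalize) {
    r_eq <- vapply(syn$bc_id, function(id) {
      sqrt(dendritic_hull(skeletons[[id]])$area / pi)
    }, numeric(1))
    d <- d / r_eq
  }
  distances <- tibble(bc_id = syn$bc_id, type = syn$type, distance = d)
  kde <- distances |>
    group_by(.data$type) |>
    tidyr::nest(.key = "data") |>
    mutate(kde = map(.data$data, function(df) {
      bw_use <- bw
      if (nrow(df) < 2L || sd(df$distance) == 0) {
        # degenerate sample: Silverman's rule collapses, use a fixed narrow
        # kernel so the curve still integrates to 1 with its mode at d
        bw_use <- max(1e-3, 0.05 * max(abs(df$distance), 1))
      }
      k <- density(df$distance, bw = bw_use, n = n)
      tibble(distance = k$x, density = k$y)
    })) |>
    select("type", "kde") |>
    tidyr::unnest("kde") |>
    ungroup()
  list(distances = distances, kde = kde)
}

#' Rod-to-BC connectivity summaries
#'
#' Rods per RBC, the per-rod histogram of distinct invaginating RBC partners
#' (0 / 1 / 2 / >2), and rods per OFF-CBC type. OFF-CBC counts are
#' restricted to rods with at least one synaptic RBC contact (the number of
#' excluded rods is reported).
#'
#' @param sets Classified contact-set tibble (rod rows used).
#' @param rods Rod tibble.
#' @param cells Cell metadata (with `soma_x`, `soma_y` when restricting to
#'   the rod field).
#' @param rod_field Optional numeric `c(xmin, xmax, ymin, ymax)` of the
#'   reconstructed rod area; per-cell statistics are restricted to cells
#'   with their soma inside it (default: bounding box of `rods` plus a 2 µm
#'   margin, `NULL`-able by passing `FALSE`).
#' @param n_boot,seed Bootstrap parameters for the per-type means.
#' @return List: `rods_per_cell` (per-cell records + per-type mean with CI),
#'   `rbc_per_rod` (histogram tibble), `n_rods_excluded`.
#' @export
rod_connectivity <- function(sets, rods, cells, rod_field = NULL,
                             n_boot = 500L, seed = 1L) {
  if (is.null(rod_field)) {
    rod_field <- c(min(rods$x) - 2, max(rods$x) + 2,
                   min(rods$y) - 2, max(rods$y) + 2)
  }
  if (!identical(rod_field, FALSE) && all(c("soma_x", "soma_y") %in%
                                          names(cells))) {
    cells <- cells |>
      filter(.data$soma_x >= rod_field[1], .data$soma_x <= rod_field[2],
             .data$soma_y >= rod_field[3], .data$soma_y <= rod_field[4])
  }
  rs <- sets |>
    filter(.data$bc_id %in% cells$cell_id) |>
    filter(.data$terminal_kind == "rod", .data$label == "synaptic") |>
    left_join(cells[, c("cell_id", "type")], by = c(bc_id = "cell_id"))
  rbc_sets <- rs |> filter(.data$type == "RBC")
  rods_with_rbc <- unique(rbc_sets$terminal_id)
  n_excluded <- nrow(rods) - length(rods_with_rbc)
  rbc_counts <- rbc_sets |>
    distinct(.data$terminal_id, .data$bc_id) |>
    count(.data$terminal_id, name = "n_rbc")
  all_rods <- tibble(rod_id = rods$rod_id) |>
    left_join(rbc_counts, by = c(rod_id = "terminal_id")) |>
    mutate(n_rbc = dplyr::coalesce(.data$n_rbc, 0L))
  rbc_per_rod <- all_rods |>
    mutate(bin = dplyr::case_when(.data$n_rbc == 0L ~ "0",
                                  .data$n_rbc == 1L ~ "1",
                                  .data$n_rbc == 2L ~ "2",
                                  TRUE ~ ">2")) |>
    count(.data$bin, name = "n_rods")
  off_ok <- rs |>
    filter(.data$type == "RBC" | .data$terminal_id %in% rods_with_rbc)
  per_cell <- off_ok |>
    distinct(.data$bc_id, .data$terminal_id, .data$type) |>
    count(.data$bc_id, .data$type, name = "n_rods") |>
    dplyr::right_join(cells[, c("cell_id", "type")],
                      by = c(bc_id = "cell_id", "type")) |>
    mutate(n_rods = dplyr::coalesce(.data$n_rods, 0L))
  per_type <- per_cell |>
    group_by(.data$type) |>
    summarise(n_cells = n(), mean_rods = mean(.data$n_rods),
              ci = list(bootstrap_ci(.data$n_rods, n_boot = n_boot,
                                     seed = seed)),
              .groups = "drop") |>
    mutate(ci_low = map_dbl(.data$ci, 1), ci_high = map_dbl(.data$ci, 2)) |>
    select(-"ci")
  list(rods_per_cell = per_cell, rods_per_type = per_type,
       rbc_per_rod = rbc_per_rod, n_rods_excluded = n_excluded)
}

#' Compare rod-only and rod-plus-cone RBC groups
#'
#' Splits RBCs by presence of at least one synaptic cone contact and
#' compares rod-contact counts and dendritic hull areas between the groups
#' with a bootstrap CI of the difference in means.
#'
#' @param sets Classified contact-set tibble.
#' @param cells Cell metadata (RBC rows used).
#' @param skeletons Named skeleton list.
#' @param n_boot,seed Bootstrap parameters.
#' @return List with `per_cell`, `summary` (per group), `differences`
#'   (tibble of mean differences with CIs), `degenerate` flag.
#' @export
rbc_group_compare <- function(sets, cells, skeletons, n_boot = 1000L,
                              seed = 1L) {
  rbcs <- cells |> filter(.data$type == "RBC")
  syn <- sets |> filter(.data$label == "synaptic",
                        .data$bc_id %in% rbcs$cell_id)
  cone_bcs <- unique(syn$bc_id[syn$terminal_kind == "cone"])
  rod_counts <- syn |>
    filter(.data$terminal_kind == "rod") |>
    count(.data$bc_id, name = "n_rods")
  per_cell <- rbcs |>
    left_join(rod_counts, by = c(cell_id = "bc_id")) |>
    mutate(n_rods = dplyr::coalesce(.data$n_rods, 0L),
           group = if_else(.data$cell_id %in% cone_bcs, "rod_and_cone",
                           "rod_only"),
           hull_area = map_dbl(.data$cell_id, function(id) {
             dendritic_hull(skeletons[[id]])$area
           }))
  degenerate <- length(unique(per_cell$group)) < 2L
  summary <- per_cell |>
    group_by(.data$group) |>
    summarise(n = n(), mean_rods = mean(.data$n_rods),
              mean_hull_area = mean(.data$hull_area), .groups = "drop")
  differences <- NULL
  if (!degenerate) {
    set.seed(seed)
    boot_diff <- function(v, g) {
      reps <- vapply(seq_len(n_boot), function(i) {
        idx <- sample(length(v), replace = TRUE)
        vi <- v[idx]; gi <- g[idx]
        if (length(unique(gi)) < 2L) return(NA_real_)
        mean(vi[gi == "rod_and_cone"]) - mean(vi[gi == "rod_only"])
      }, numeric(1))
      quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    }
    q1 <- boot_diff(per_cell$n_rods, per_cell$group)
    q2 <- boot_diff(per_cell$hull_area, per_cell$group)
    differences <- tibble(
      quantity = c("n_rods", "hull_area"),
      diff = c(mean(per_cell$n_rods[per_cell$group == "rod_and_cone"]) -
                 mean(per_cell$n_rods[per_cell$group == "rod_only"]),
               mean(per_cell$hull_area[per_cell$group == "rod_and_cone"]) -
                 mean(per_cell$hull_area[per_cell$group == "rod_only"])),
      ci_low = c(q1[1], q2[1]), ci_high = c(q1[2], q2[2]))
  }
  list(per_cell = per_cell, summary = summary, differences = differences,
       degenerate = degenerate)
}

#' Tally invaginating vs tip contacts of ON-CBCs
#'
#' Sub-labels each synaptic ON-CBC cone contact-set as invaginating
#' (contact height above `height_threshold` and eccentricity within the
#' pedicle radius) or tip, and returns per-type contingency counts with the
#' per-cell records needed for external model fitting.
#'
#' @param sets Synaptic ON-CBC contact-sets with features (`c_height`,
#'   `b_ecc`) and `bc_id`; a `subtype` column may already be present, in
#'   which case it is used as-is.
#' @param cells Cell metadata.
#' @param pedicle_radius Pedicle planar radius (µm).
#' @param height_threshold Normalized height separating tip/basal from
#'   invaginating (default 0.15).
#' @return List with `tally` (per type: `n_invaginating`, `n_tip`) and
#'   `per_set`.
#' @export
contact_type_tally <- function(sets, cells, pedicle_radius = 3.2,
                               height_threshold = 0.15) {
  per_set <- sets |>
    left_join(cells[, c("cell_id", "type")], by = c(bc_id = "cell_id"))
  if (!"subtype" %in% names(per_set)) {
    per_set <- per_set |>
      mutate(subtype = if_else(.data$c_height > height_threshold &
                                 .data$b_ecc <= pedicle_radius,
                               "invaginating", "tip"))
  }
  tally <- per_set |>
    count(.data$type, .data$subtype) |>
    tidyr::pivot_wider(names_from = "subtype", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (col in c("n_invaginating", "n_tip")) {
    if (!col %in% names(tally)) tally[[col]] <- 0L
  }
  list(tally = tally[, c("type", "n_invaginating", "n_tip")],
       per_set = per_set)
}
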