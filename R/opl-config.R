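#' Default bipolar-cell type parameters
#'
#' Per-type cell counts, mean dendritic (OPL) convex-hull areas, OPL hull
#' coverage targets and mean axonal (IPL) hull areas used by the synthetic
#' generator. Values follow the reconstructed population of the e2006-style
#' outer-retina volume the analysis is designed for; `contact_fraction` is the
#' fraction of in-field cones a cell of that type synaptically contacts
#' (OFF types and CBC5I/6/7 sample most cones in their field, CBC5T/5O/8 fewer
#' than half, CBCX ~20%).
#'
#' @return A tibble with one row per BC type.
#' @export
default_bc_type_params <- function() {
  tibble(
    type = c("CBC1", "CBC2", "CBC3A", "CBC3B", "CBC4", "CBC5T", "CBC5O",
             "CBC5I", "CBCX", "CBC6", "CBC7", "CBC8", "CBC9", "RBC"),
    n_cells = c(26L, 34L, 22L, 32L, 30L, 22L, 22L, 25L, 7L, 45L, 29L, 8L,
                6L, 141L),
    hull_area = c(175, 204, 273, 292, 302, 256, 380, 459, 433, 125, 254,
                  1249, 2223, 128),
    coverage = c(1.17, 1.18, 1.17, 1.41, 1.32, 1.13, 1.35, 1.55, 1.02, 1.14,
                 1.22, 1.14, 1.84, 2.17),
    ipl_hull_area = c(376, 353, 308, 224, 274, 402, 359, 276, 899, 165, 274,
                      699, 1605, 65),
    polarity = c("OFF", "OFF", "OFF", "OFF", "OFF", "ON", "ON", "ON", "ON",
                 "ON", "ON", "ON", "ON", "RBC"),
    contact_fraction = c(0.70, 0.70, 0.65, 0.75, 0.70, 0.45, 0.45, 0.70,
                         0.20, 0.70, 0.60, 0.40, NA, NA)
  )
}

#' Configuration for the synthetic outer-plexiform-layer generator
#'
#' Builds a validated configuration for [simulate_opl()]. Defaults emulate the
#' study conditions of the mouse outer-retina volume: a 114 x 80 µm field with
#' 163 cone pedicles (about 17.9 per 1000 µm²), 5% S-cones, a dense rod field
#' over half the field (2177 spherules over 57 x 80 µm), per-type BC mosaics
#' with the dendritic-field areas and coverage factors of the reconstructed
#' population, and three CBC5 subtypes (22/22/25 cells) stratifying between
#' the two starburst (ChAT) bands.
#'
#' @param field_size Numeric length-2, (x, y) extent in µm.
#' @param cone_density Cone pedicles per 1000 µm².
#' @param s_cone_prob Probability that a cone is an S-cone, in \[0, 1\].
#' @param rod_density Rod spherules per 1000 µm² (within the rod
#'   sub-rectangle).
#' @param rod_field_fraction Fraction of the x extent covered by the rod
#'   field (the study reconstructed rods over half the field).
#' @param bc_type_params Tibble as produced by [default_bc_type_params()];
#'   rows may be dropped or altered to simulate a subset of types.
#' @param cone_exclusion Minimum distance between cone pedicle centres (µm).
#' @param pedicle_radius,pedicle_height Cone pedicle planar radius and axial
#'   height (µm).
#' @param rod_radius Rod spherule radius (µm).
#' @param contact_noise Named list of contact-geometry distribution
#'   parameters; see Details.
#' @param rbc_cone_fraction Fraction of RBCs that receive at least one
#'   (invaginating) cone contact.
#' @param rod_accept Per-(rod, covering-RBC) acceptance probability; tuned so
#'   that an RBC dendritic field of ~128 µm² in the default rod density
#'   collects on the order of 35 rods.
#' @param off_rod_targets Named mean rod-contact counts per OFF-CBC type.
#' @param sac Named list of SAC band parameters: `z_on`, `z_off` (mean band
#'   depths, µm; ON < OFF by the axis convention used here), `warp_amplitude`
#'   (µm), `warp_period` (µm), `noise_sd` (µm), `n_points` per band.
#' @param cbc5 Named list: `depths` (planted corrected stratification depths
#'   of the three subtypes, ON band = 0, OFF band = 1), `profile_sd`
#'   (within-cell spread of corrected depth), `cell_jitter` (between-cell
#'   spread), `n_axon_points` per cell.
#' @param seed Integer RNG seed; a fixed seed makes the full dataset
#'   reproducible.
#'
#' @details `contact_noise` fields (all configurable): `area_meanlog_syn`,
#'   `area_sdlog_syn`, `area_meanlog_per`, `area_sdlog_per` (log-normal
#'   per-point contact areas, µm²); `ecc_invag`, `ecc_basal`, `ecc_peri`
#'   (eccentricity ranges as fractions of the pedicle radius — synaptic
#'   contacts fall inside the pedicle, peripheral ones in an annulus outside
#'   it); `height_invag`, `height_basal`, `height_peri` (normalized contact
#'   height ranges); `spurious_rate` (probability that an in-reach,
#'   non-synaptic BC-cone pair leaves a peripheral contact);
#'   `extra_points_lambda` (Poisson mean of contact points beyond the first
#'   in a synaptic set).
#'
#' @return An object of class `opl_config` (a named list).
#' @export
opl_config <- function(field_size = c(114, 80),
                       cone_density = 163 / (114 * 80) * 1000,
                       s_cone_prob = 0.05,
                       rod_density = 2177 / (57 * 80) * 1000,
                       rod_field_fraction = 0.5,
                       bc_type_params = default_bc_type_params(),
                       cone_exclusion = 5.5,
                       pedicle_radius = 3.2,
                       pedicle_height = 3,
                       rod_radius = 0.9,
                       contact_noise = list(),
                       rbc_cone_fraction = 0.75,
                       rod_accept = 0.70,
                       off_rod_targets = c(CBC1 = 0.3, CBC2 = 0.3, CBC3A = 5,
                                           CBC3B = 10, CBC4 = 5),
                       sac = list(),
                       cbc5 = list(),
                       seed = 1L) {
  noise_def <- list(
    area_meanlog_syn = log(0.35), area_sdlog_syn = 0.45,
    area_meanlog_per = log(0.05), area_sdlog_per = 0.55,
    ecc_invag = c(0, 0.35), ecc_basal = c(0, 0.45), ecc_peri = c(1.05, 1.55),
    height_invag = c(0.20, 0.55), height_basal = c(0, 0.12),
    height_peri = c(0.2, 1.0),
    spurious_rate = 0.5, rod_spurious_rate = 0.05, extra_points_lambda = 1.5
  )
  sac_def <- list(z_on = -42, z_off = -34, warp_amplitude = 2,
                  warp_period = 60, noise_sd = 0.3, n_points = 3000L)
  cbc5_def <- list(depths = c(0.30, 0.52, 0.74), profile_sd = 0.08,
                   cell_jitter = 0.05, n_axon_points = 150L)
  cfg <- list(
    field_size = as.numeric(field_size),
    cone_density = cone_density,
    s_cone_prob = s_cone_prob,
    rod_density = rod_density,
    rod_field_fraction = rod_field_fraction,
    bc_type_params = as_tibble(bc_type_params),
    cone_exclusion = cone_exclusion,
    pedicle_radius = pedicle_radius,
    pedicle_height = pedicle_height,
    rod_radius = rod_radius,
    contact_noise = utils::modifyList(noise_def, contact_noise),
    rbc_cone_fraction = rbc_cone_fraction,
    rod_accept = rod_accept,
    off_rod_targets = off_rod_targets,
    sac = utils::modifyList(sac_def, sac),
    cbc5 = utils::modifyList(cbc5_def, cbc5),
    seed = as.integer(seed)
  )
  validate_opl_config(cfg)
  structure(cfg, class = "opl_config")
}

validate_opl_config <- function(cfg) {
  stopifnot(length(cfg$field_size) == 2L)
  if (any(cfg$field_size <= 0)) abort("field_size must be positive")
  if (cfg$cone_density < 0 || cfg$rod_density < 0) {
    abort("densities must be non-negative")
  }
  if (cfg$s_cone_prob < 0 || cfg$s_cone_prob > 1) {
    abort("s_cone_prob must be in [0, 1]")
  }
  req <- c("type", "n_cells", "hull_area", "coverage", "polarity")
  miss <- setdiff(req, names(cfg$bc_type_params))
  if (length(miss) > 0L) {
    abort(paste("bc_type_params missing columns:", paste(miss, collapse = ", ")))
  }
  if (cfg$sac$z_on >= cfg$sac$z_off) {
    abort("SAC band convention requires z_on < z_off")
  }
  invisible(cfg)
}

#' @export
print.opl_config <- function(x, ...) {
  cat(sprintf("<opl_config> field %g x %g um, %.1f cones / 1000 um^2 (P[S] = %.2f), %d BC types, seed %d\n",
              x$field_size[1], x$field_size[2], x$cone_density,
              x$s_cone_prob, nrow(x$bc_type_params), x$seed))
  invisible(x)
}
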