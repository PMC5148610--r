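#' Simulate a fully labelled synthetic outer-retina dataset
#'
#' Runs the whole generator: cone-pedicle mosaic, rod field, per-type BC
#' mosaics with grown dendritic arbors, synaptic and spurious contact wiring,
#' SAC band point clouds and CBC5 axonal arbors. Everything is deterministic
#' given `config$seed`.
#'
#' @param config An [opl_config()].
#' @param types Character vector of BC types to generate; default all types
#'   in `config$bc_type_params`.
#' @param sac_cbc5 Logical; also generate SAC bands and CBC5 axon clouds.
#' @return A list of class `opl_sim`: `cones`, `rods`, `cells`, `skeletons`,
#'   `contacts`, `truth`, and (if requested) `sac`, `cbc5`, plus the `config`.
#' @export
simulate_opl <- function(config = opl_config(), types = NULL,
                         sac_cbc5 = TRUE) {
  types <- types %||% config$bc_type_params$type
  cones <- generate_cone_mosaic(config)
  rods <- generate_rod_field(config)
  pops <- lapply(types, function(ty) generate_bc_population(config, ty))
  bcs <- list(cells = bind_rows(lapply(pops, `[[`, "cells")),
              skeletons = do.call(c, lapply(pops, `[[`, "skeletons")))
  wired <- wire_contacts(cones, rods, bcs, config)
  out <- list(config = config, cones = cones, rods = rods,
              cells = bcs$cells, skeletons = wired$skeletons,
              contacts = wired$contacts, truth = wired$truth)
  if (sac_cbc5) {
    sac <- generate_sac_bands(config)
    out$sac <- sac
    if (any(c("CBC5T", "CBC5O", "CBC5I") %in% config$bc_type_params$type)) {
      out$cbc5 <- generate_cbc5_axons(config, sac)
    }
  }
  structure(out, class = "opl_sim")
}

#' @export
print.opl_sim <- function(x, ...) {
  cat(sprintf("<opl_sim> %d cones (%d S), %d rods, %d BCs, %d contact points in %d contact-sets\n",
              nrow(x$cones), sum(x$cones$spectral == "S"), nrow(x$rods),
              nrow(x$cells), nrow(x$contacts), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the analysis-facing files (`cones.csv`, `rods.csv`, `cells.csv`,
#' `contacts.csv`, one SWC skeleton per cell under `skeletons/`,
#' `sac_points.csv`, `cbc5_axon_points.csv`, and `manifest.json` with the
#' config echo and file inventory). Ground-truth labels are only written
#' (`truth.csv`, plus the spectral column of `cones.csv`) when
#' `emit_truth = TRUE`.
#'
#' @param sim An `opl_sim`.
#' @param dir Output directory (created if needed).
#' @param emit_truth Write ground-truth labels too?
#' @return `dir`, invisibly.
#' @export
write_opl_dataset <- function(sim, dir, emit_truth = FALSE) {
  dir.create(file.path(dir, "skeletons"), recursive = TRUE,
             showWarnings = FALSE)
  cones <- sim$cones
  if (!emit_truth) cones$spectral <- "unknown"
  readr::write_csv(cones, file.path(dir, "cones.csv"))
  readr::write_csv(sim$rods, file.path(dir, "rods.csv"))
  readr::write_csv(sim$cells, file.path(dir, "cells.csv"))
  readr::write_csv(sim$contacts, file.path(dir, "contacts.csv"))
  for (id in names(sim$skeletons)) {
    write_swc(sim$skeletons[[id]],
              file.path(dir, "skeletons", paste0(id, ".swc")))
  }
  if (!is.null(sim$sac)) {
    readr::write_csv(sim$sac$points, file.path(dir, "sac_points.csv"))
  }
  if (!is.null(sim$cbc5)) {
    readr::write_csv(sim$cbc5$axon_points,
                     file.path(dir, "cbc5_axon_points.csv"))
  }
  if (emit_truth) {
    readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
    readr::write_csv(sim$cones, file.path(dir, "cones_truth.csv"))
  }
  manifest <- list(
    generator = "oplconnect synthetic OPL",
    units = "um; +z from inner retina toward photoreceptors; IPL at negative z",
    seed = sim$config$seed,
    config = unclass(sim$config)[setdiff(names(sim$config), "bc_type_params")],
    bc_type_params = sim$config$bc_type_params,
    files = list.files(dir, recursive = TRUE),
    emitted_truth = emit_truth
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_opl_dataset()]
#'
#' The same layout accepts real exported data: CSV tables plus one SWC file
#' per cell.
#'
#' @param dir Dataset directory.
#' @return List with `cones`, `rods`, `cells`, `skeletons`, `contacts` and,
#'   when present, `truth`, `sac_points`, `cbc5_axon_points`, `manifest`.
#' @export
read_opl_dataset <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  }
  cells <- rd("cells.csv")
  out <- list(
    cones = rd("cones.csv"), rods = rd("rods.csv"), cells = cells,
    contacts = rd("contacts.csv"), truth = rd("truth.csv"),
    sac_points = rd("sac_points.csv"),
    cbc5_axon_points = rd("cbc5_axon_points.csv"),
    skeletons = read_swc_dir(file.path(dir, "skeletons"), cells = cells)
  )
  mp <- file.path(dir, "manifest.json")
  if (file.exists(mp)) out$manifest <- jsonlite::read_json(mp)
  out
}
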