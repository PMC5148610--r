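# End-to-end orchestration: simulate/ingest -> features -> classify ->
# S-cone identification -> CBC5 typing -> connectivity.

#' Default classifier training-set sizes
#'
#' Contact-set counts used to draw labelled training data in the pipeline,
#' mirroring the reference analysis: 50 OFF-CBC, 108 ON-CBC and 67 RBC
#' cone contact-sets, and 100 RBC rod contact-sets plus the per-type OFF
#' rod sets.
#' @return Named integer vector.
#' @export
default_train_sizes <- function() {
  c(OFF_CBC_cone = 50L, ON_CBC_cone = 108L, RBC_cone = 67L,
    OFF_CBC_rod = 97L, RBC_rod = 100L)
}

group_membership <- function(sets_meta, cells, bc_params) {
  polarity <- setNames(bc_params$polarity, bc_params$type)
  sets_meta |>
    left_join(cells[, c("cell_id", "type")], by = c(bc_id = "cell_id")) |>
    mutate(pol = unname(polarity[.data$type]),
           group = dplyr::case_when(
             .data$terminal_kind == "cone" & .data$pol == "OFF" ~ "OFF_CBC_cone",
             .data$terminal_kind == "cone" & .data$pol == "ON" ~ "ON_CBC_cone",
             .data$terminal_kind == "cone" & .data$pol == "RBC" ~ "RBC_cone",
             .data$terminal_kind == "rod" & .data$pol == "OFF" ~ "OFF_CBC_rod",
             .data$terminal_kind == "rod" & .data$pol == "RBC" ~ "RBC_rod",
             TRUE ~ NA_character_))
}

#' Classify all contact-sets of a dataset
#'
#' Trains one RBF-SVM per classifier group on a labelled training subsample
#' (ground-truth labels in simulation; manual labels for real data) and
#' predicts synaptic/non-synaptic for every contact-set. CBCX sets are
#' excluded from ON-CBC training (their contacts are atypical) but are still
#' predicted. OFF-CBC rod sets are restricted to rods with an identified
#' synaptic RBC contact (those with no `h` feature are dropped from that
#' group, mirroring the analysis restriction).
#'
#' @param features Feature tibble from [extract_contact_features()].
#' @param labels Tibble (`bc_id`, `terminal_id`, `terminal_kind`, `label`)
#'   of ground-truth or manual labels covering at least the training draws.
#' @param cells Cell metadata.
#' @param bc_params BC type parameter tibble (for polarities).
#' @param train_sizes Named vector of per-group training sizes
#'   (see [default_train_sizes()]); capped at availability.
#' @param seed Integer seed for the training draws.
#' @return List: `sets` (features + predicted `label`), `models`,
#'   `cv_reports` (per-group [loo_cross_validate()] results on the training
#'   draws).
#' @export
classify_dataset <- function(features, labels, cells, bc_params,
                             train_sizes = default_train_sizes(),
                             seed = 1L) {
  feats <- group_membership(features, cells, bc_params)
  lab <- labels |>
    mutate(label = if_else(.data$label %in% c("synaptic", "invaginating",
                                              "basal", "tip"),
                           "synaptic", "non_synaptic"))
  feats <- feats |>
    left_join(lab[, c("bc_id", "terminal_id", "terminal_kind", "label")] |>
                rename(truth_label = "label"),
              by = c("bc_id", "terminal_id", "terminal_kind"))
  set.seed(seed)
  out_sets <- list(); models <- list(); cv_reports <- list()
  for (grp in intersect(names(train_sizes), unique(feats$group))) {
    g <- feats |> filter(.data$group == grp)
    if (grp == "OFF_CBC_rod") g <- g |> filter(!is.na(.data$h_dist_rbc))
    if (nrow(g) == 0L) next
    train_pool <- g |> filter(!is.na(.data$truth_label))
    if (grp == "ON_CBC_cone") {
      train_pool <- train_pool |> filter(.data$type != "CBCX")
    }
    n_tr <- min(train_sizes[[grp]], nrow(train_pool))
    tr <- train_pool[sample.int(nrow(train_pool), n_tr), ]
    tr$label <- tr$truth_label
    if (length(unique(tr$label)) < 2L) {
      # degenerate group (e.g. no spurious contacts generated): constant label
      g$label <- tr$label[1] %||% "synaptic"
      out_sets[[grp]] <- g
      next
    }
    fit <- train_contact_classifier(tr, grp, seed = seed)
    models[[grp]] <- fit
    cv_reports[[grp]] <- loo_cross_validate(tr, grp, seed = seed)
    out_sets[[grp]] <- predict(fit, g)
  }
  sets <- bind_rows(out_sets) |>
    select(-dplyr::any_of(c("pol", "type", "truth_label")))
  list(sets = sets, models = models, cv_reports = cv_reports)
}

#' Run the full outer-retina connectivity pipeline
#'
#' Simulates (or ingests) a dataset, extracts contact-set features,
#' classifies contacts, identifies S-cones from CBC9 connectivity, types
#' CBC5 cells, and computes the connectivity statistics. Stages can be
#' toggled; later stages error if a required earlier stage is disabled.
#'
#' @param config An [opl_config()] (used when `dataset` is `NULL`).
#' @param dataset Optional pre-built dataset (an `opl_sim` or the result of
#'   [read_opl_dataset()]); when given, `config` supplies parameters only.
#' @param stages Character vector of stages to run, a subset of
#'   `c("features", "classify", "scones", "cbc5", "connectivity")`.
#' @param train_sizes Per-group training sizes for [classify_dataset()].
#' @param tip_threshold Along-dendrite distance (µm) below which a CBC9
#'   contact counts as made by a branch terminating at the cone.
#' @param out_dir Optional directory; the dataset and result tables are
#'   written there.
#' @param seed Overrides `config$seed` when given.
#' @return List of class `opl_run` with the per-stage results.
#' @export
run_opl_pipeline <- function(config = opl_config(), dataset = NULL,
                             stages = c("features", "classify", "scones",
                                        "cbc5", "connectivity"),
                             train_sizes = default_train_sizes(),
                             tip_threshold = 1, out_dir = NULL,
                             seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- dataset %||% simulate_opl(config)
  run <- list(config = config, sim = sim)
  need <- function(stage, value, what) {
    if (is.null(value)) {
      abort(sprintf("stage '%s' requires disabled/missing upstream stage '%s'",
                    stage, what))
    }
    value
  }
  if ("features" %in% stages) {
    rbc_rod <- sim$contacts |>
      inner_join(sim$truth |>
                   filter(.data$terminal_kind == "rod",
                          .data$label == "synaptic") |>
                   inner_join(sim$cells |> filter(.data$type == "RBC"),
                              by = c(bc_id = "cell_id")) |>
                   select("bc_id", "terminal_id"),
                 by = c("bc_id", "terminal_id"))
    run$features <- extract_contact_features(
      sim$contacts, sim$skeletons, sim$cones, sim$rods,
      rbc_rod_contacts = rbc_rod)
  }
  if ("classify" %in% stages) {
    feats <- need("classify", run$features, "features")
    cls <- classify_dataset(feats, sim$truth, sim$cells,
                            config$bc_type_params,
                            train_sizes = train_sizes, seed = config$seed)
    run$classified <- cls$sets
    run$models <- cls$models
    run$cv_reports <- cls$cv_reports
  }
  if ("scones" %in% stages) {
    cls <- need("scones", run$classified, "classify")
    cbc9_ids <- sim$cells$cell_id[sim$cells$type == "CBC9"]
    cbc9_sets <- cls |>
      filter(.data$bc_id %in% cbc9_ids, .data$terminal_kind == "cone") |>
      mutate(cone_id = .data$terminal_id, cbc9_id = .data$bc_id,
             n_points = .data$g_n_points,
             terminates_at_cone = .data$e_tip < tip_threshold)
    in_reach <- unique(unlist(lapply(cbc9_ids, function(id) {
      cones_in_field(sim$skeletons[[id]], sim$cones)
    })))
    cand <- find_scone_candidates(cbc9_sets)
    strict <- classify_scones(cand, cone_ids = in_reach, rule = "strict")
    liberal <- classify_scones(cand, cone_ids = in_reach, rule = "liberal")
    run$scones <- list(
      candidates = cand, strict = strict, liberal = liberal,
      in_reach = in_reach,
      fraction_strict = if (length(in_reach) > 0)
        scone_fraction(strict, length(in_reach)) else NA_real_,
      fraction_liberal = if (length(in_reach) > 0)
        scone_fraction(liberal, length(in_reach)) else NA_real_,
      binomial_p = if (length(in_reach) > 0)
        binomial_test_exact(sum(liberal$spectral == "S"),
                            length(in_reach), 0.05) else NA_real_)
  }
  if ("cbc5" %in% stages && !is.null(sim$cbc5)) {
    run$cbc5_fit <- classify_cbc5(
      sim$cbc5$axon_points, sim$sac$points,
      sim$cbc5$opl_hulls, sim$cbc5$ipl_hulls, seed = config$seed)
  }
  if ("connectivity" %in% stages) {
    cls <- need("connectivity", run$classified, "classify")
    run$connectivity <- convergence_divergence(cls, sim$cells, sim$cones,
                                               seed = config$seed)
    run$contacted <- contacted_fraction(cls, sim$cells, sim$skeletons,
                                        sim$cones)
    types_present <- unique(sim$cells$type)
    run$coverage <- bind_rows(lapply(types_present, function(ty) {
      coverage_factors(sim$cells |> filter(.data$type == ty),
                       sim$skeletons, sim$cones)
    }))
    if (nrow(sim$rods) > 0L) {
      run$rods <- rod_connectivity(cls, sim$rods, sim$cells,
                                   seed = config$seed)
      if ("RBC" %in% types_present) {
        run$rbc_groups <- rbc_group_compare(cls, sim$cells, sim$skeletons,
                                            seed = config$seed)
      }
    }
  }
  run <- structure(run, class = "opl_run")
  if (!is.null(out_dir)) write_opl_run(run, out_dir)
  run
}

#' @export
print.opl_run <- function(x, ...) {
  cat("<opl_run> stages:",
      paste(intersect(c("features", "classified", "scones", "cbc5_fit",
                        "connectivity"), names(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' @param run An `opl_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_opl_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) if (!is.null(df)) readr::write_csv(df, file.path(dir, f))
  wr(run$features, "features.csv")
  wr(run$classified, "predictions.csv")
  if (!is.null(run$scones)) {
    wr(run$scones$strict, "cone_labels_strict.csv")
    wr(run$scones$liberal, "cone_labels_liberal.csv")
    summary <- list(n_candidates = nrow(run$scones$candidates),
                    n_in_reach = length(run$scones$in_reach),
                    fraction_strict_pct = run$scones$fraction_strict,
                    fraction_liberal_pct = run$scones$fraction_liberal,
                    binomial_p = run$scones$binomial_p)
    jsonlite::write_json(summary, file.path(dir, "scone_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$cbc5_fit)) wr(tidy(run$cbc5_fit), "cbc5_assignments.csv")
  if (!is.null(run$connectivity)) {
    wr(run$connectivity$convergence, "convergence.csv")
    wr(run$connectivity$divergence, "divergence.csv")
  }
  wr(run$coverage, "coverage.csv")
  if (!is.null(run$rods)) wr(run$rods$rods_per_type, "rods_per_type.csv")
  invisible(dir)
}
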