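# CBC5 subtype classification.
#
# Axonal depth profiles are corrected by mapping the two warped SAC (ChAT)
# band surfaces to parallel planes (ON band -> 0, OFF band -> 1), reduced by
# PCA, clustered with a 3-component Gaussian mixture, and refined by a
# shift/swap heuristic minimising a cost that combines the mixture penalty
# with same-cluster convex-hull overlap in both OPL and IPL:
#
#   L = lambda1 * sum_i (x_i - mu_ci)' Sigma_ci^{-1} (x_i - mu_ci)
#     + lambda2 * sum_{i != j} delta(ci, cj) O_ij,OPL / sum_i A_i,OPL
#     + lambda2 * sum_{i != j} delta(ci, cj) O_ij,IPL / sum_i A_i,IPL
#
# (the inverse covariance makes the first term a proper Mahalanobis/GMM
# penalty; the literal form without the inverse is available via
# `literal_cost = TRUE`).

#' Fit a SAC band surface from a dendritic point cloud
#'
#' Bins the point cloud on an (x, y) grid, extracts the modal depth per bin
#' (the mean z inside the highest-count depth bin, so a two-mode bin returns
#' the denser mode), and fits a smooth tensor-product cubic B-spline surface
#' to the per-bin peak depths. Grid cells without points are interpolated by
#' the smooth.
#'
#' @param points Tibble with `x`, `y`, `z` (one SAC band's dendritic points).
#' @param grid List with `nx`, `ny` (planar bins) and `dz` (depth bin height,
#'   µm).
#' @return Object of class `sac_surface` with a [predict()] method taking
#'   `x`, `y`.
#' @export
sac_band_surface <- function(points, grid = list(nx = 14, ny = 10, dz = 0.5)) {
  if (is.null(points) || nrow(points) == 0L) abort("empty SAC point cloud")
  xb <- seq(min(points$x), max(points$x), length.out = grid$nx + 1L)
  yb <- seq(min(points$y), max(points$y), length.out = grid$ny + 1L)
  ix <- pmin(pmax(findInterval(points$x, xb, all.inside = TRUE), 1L), grid$nx)
  iy <- pmin(pmax(findInterval(points$y, yb, all.inside = TRUE), 1L), grid$ny)
  peaks <- points |>
    mutate(ix = ix, iy = iy) |>
    group_by(.data$ix, .data$iy) |>
    summarise(peak = {
      zb <- floor(.data$z / grid$dz)
      mode_bin <- as.numeric(names(which.max(table(zb))))
      mean(.data$z[zb == mode_bin])
    }, .groups = "drop") |>
    mutate(x = (xb[.data$ix] + xb[.data$ix + 1L]) / 2,
           y = (yb[.data$iy] + yb[.data$iy + 1L]) / 2)
  kx <- max(4L, min(9L, grid$nx - 2L))
  ky <- max(4L, min(9L, grid$ny - 2L))
  while (kx * ky >= nrow(peaks) && (kx > 4L || ky > 4L)) {
    if (kx >= ky) kx <- kx - 1L else ky <- ky - 1L
  }
  fit <- mgcv::gam(peak ~ te(x, y, bs = "bs", k = c(kx, ky)), data = peaks)
  structure(list(fit = fit, xlim = range(points$x), ylim = range(points$y)),
            class = "sac_surface")
}

#' @export
predict.sac_surface <- function(object, x, y, ...) {
  as.numeric(predict(object$fit, newdata = data.frame(x = x, y = y)))
}

#' @export
print.sac_surface <- function(x, ...) {
  cat(sprintf("<sac_surface> x in [%.1f, %.1f], y in [%.1f, %.1f]\n",
              x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2]))
  invisible(x)
}

#' Map depths to SAC-band-corrected (flattened) coordinates
#'
#' Per (x, y) column, an affine map sends the ON band surface to 0 and the
#' OFF band surface to 1; values outside \[0, 1\] are legitimate
#' extrapolation.
#'
#' @param x,y,z Point coordinates (µm; recycled to a common length).
#' @param on_surface,off_surface `sac_surface` objects.
#' @return Corrected depths (unitless).
#' @export
flatten_depth <- function(x, y, z, on_surface, off_surface) {
  zon <- predict(on_surface, x, y)
  zoff <- predict(off_surface, x, y)
  gap <- zoff - zon
  if (any(abs(gap) < 1e-9)) {
    abort("SAC surfaces are coincident at a queried (x, y)")
  }
  (z - zon) / gap
}

#' SAC-corrected axonal depth profiles
#'
#' Histograms the corrected depths of each cell's axonal points
#' (length-weighted via the `weight` column when present) over `bins` equal
#' bins spanning `range`, normalized to unit sum per cell.
#'
#' @param axon_points Tibble `cell_id`, `x`, `y`, `z` (and optional
#'   `weight`).
#' @param on_surface,off_surface `sac_surface` objects.
#' @param bins Number of depth bins (default 50).
#' @param range Corrected-depth range covered (default c(-0.5, 1.5)).
#' @return Tibble `cell_id`, `depth` (bin centre), `density`.
#' @export
axon_depth_profiles <- function(axon_points, on_surface, off_surface,
                                bins = 50L, range = c(-0.5, 1.5)) {
  w <- if ("weight" %in% names(axon_points)) axon_points$weight else
    rep(1, nrow(axon_points))
  d <- flatten_depth(axon_points$x, axon_points$y, axon_points$z,
                     on_surface, off_surface)
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= bins
  df <- tibble(cell_id = axon_points$cell_id[keep], bin = bin[keep],
               w = w[keep])
  df |>
    group_by(.data$cell_id, .data$bin) |>
    summarise(w = sum(.data$w), .groups = "drop") |>
    tidyr::complete(cell_id = unique(df$cell_id), bin = seq_len(bins),
                    fill = list(w = 0)) |>
    group_by(.data$cell_id) |>
    mutate(density = .data$w / sum(.data$w)) |>
    ungroup() |>
    mutate(depth = centres[.data$bin]) |>
    select("cell_id", "depth", "density")
}

profiles_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(profiles, id_cols = "cell_id",
                             names_from = "depth", values_from = "density")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$cell_id
  m
}

safe_inverse <- function(S, ridge = 1e-8) {
  tryCatch(solve(S), error = function(e) {
    solve(S + diag(ridge * mean(diag(S)) + 1e-12, nrow(S)))
  })
}

#' Initial CBC5 clustering: PCA + 3-component Gaussian mixture
#'
#' Mean-centres the depth profiles, projects onto the first three principal
#' components, and fits a three-component full-covariance Gaussian mixture
#' by EM with 20 seeded restarts (one k-means start plus random starts),
#' keeping the best log-likelihood. Degenerate covariances are
#' ridge-regularised when inverted (constant `1e-8` times the mean diagonal).
#'
#' @param profiles Long profile tibble from [axon_depth_profiles()].
#' @param seed Integer seed.
#' @param n_restarts Number of seeded EM restarts (default 20).
#' @return List (class `cbc5_state`): `cell_id`, `scores` (n x 3), `assign`
#'   (integer in 1..3), `means`, `covs`, `pca`.
#' @export
cbc5_init <- function(profiles, seed = 1L, n_restarts = 20L) {
  m <- profiles_matrix(profiles)
  if (nrow(m) < 3L) abort("need at least 3 cells")
  set.seed(seed)
  pca <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pca$x))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  if (k < 3L) scores <- cbind(scores, matrix(0, nrow(scores), 3L - k))
  colnames(scores) <- paste0("PC", 1:3)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cl0 <- if (r == 1L) {
      stats::kmeans(scores, 3L, nstart = 5L)$cluster
    } else {
      sample.int(3L, nrow(scores), replace = TRUE)
    }
    if (length(unique(cl0)) < 3L) next
    fit <- tryCatch(
      mclust::meVVV(data = scores, z = mclust::unmap(cl0)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$loglik %||% NA) &&
        (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) abort("Gaussian mixture fit failed in all restarts")
  covs <- lapply(1:3, function(c) best$parameters$variance$sigma[, , c])
  structure(list(cell_id = rownames(m), scores = scores,
                 assign = as.integer(apply(best$z, 1, which.max)),
                 means = t(best$parameters$mean), covs = covs, pca = pca,
                 loglik = best$loglik),
            class = "cbc5_state")
}

# Pairwise hull overlap matrix (O_ii = A_i) for a named hull list, ordered
# by cell_id.
overlap_matrix <- function(hulls, cell_id) {
  n <- length(cell_id)
  O <- matrix(0, n, n, dimnames = list(cell_id, cell_id))
  for (i in seq_len(n)) {
    O[i, i] <- hulls[[cell_id[i]]]$area
    for (j in seq_len(i - 1L)) {
      o <- hull_overlap_area(hulls[[cell_id[i]]], hulls[[cell_id[j]]])
      O[i, j] <- o; O[j, i] <- o
    }
  }
  O
}

#' Assemble the full cluster state for the overlap-penalised cost
#'
#' @param state A `cbc5_state` from [cbc5_init()].
#' @param opl_hulls,ipl_hulls Named lists of `opl_hull` objects (dendritic /
#'   axonal convex hulls), keyed by cell id.
#' @param lambda1 Weight of the mixture (Mahalanobis) term (default 1).
#' @param lambda2 Weight of the overlap terms (default: number of cells,
#'   balancing a per-cell sum against field-level overlap ratios).
#' @param literal_cost Use the literal printed quadratic form without the
#'   covariance inverse (default `FALSE`: proper Mahalanobis form).
#' @return The state augmented with overlap matrices and cost weights.
#' @export
cbc5_attach_overlaps <- function(state, opl_hulls, ipl_hulls,
                                 lambda1 = 1, lambda2 = NULL,
                                 literal_cost = FALSE) {
  n <- length(state$cell_id)
  state$O_opl <- overlap_matrix(opl_hulls, state$cell_id)
  state$O_ipl <- overlap_matrix(ipl_hulls, state$cell_id)
  state$lambda1 <- lambda1
  state$lambda2 <- lambda2 %||% n
  state$literal_cost <- literal_cost
  # per-cell, per-component quadratic penalties
  D <- matrix(0, n, 3L)
  for (c in 1:3) {
    M <- if (literal_cost) state$covs[[c]] else safe_inverse(state$covs[[c]])
    dx <- sweep(state$scores, 2, state$means[c, ])
    D[, c] <- rowSums((dx %*% M) * dx)
  }
  state$D <- D
  state
}

#' Cost of a CBC5 cluster state
#'
#' Mixture penalty plus same-cluster hull-overlap ratios (OPL and IPL),
#' summed symmetrically over ordered pairs i != j.
#'
#' @param state A `cbc5_state` with overlaps attached
#'   ([cbc5_attach_overlaps()]).
#' @return The scalar cost.
#' @export
cluster_cost <- function(state) {
  same <- outer(state$assign, state$assign, "==")
  diag(same) <- FALSE
  term1 <- state$lambda1 * sum(state$D[cbind(seq_along(state$assign),
                                             state$assign)])
  ov <- state$lambda2 * (sum(state$O_opl[same]) / sum(diag(state$O_opl)) +
                           sum(state$O_ipl[same]) / sum(diag(state$O_ipl)))
  term1 + ov
}

#' Refine cluster assignments by greedy shifts and swaps
#'
#' Greedy descent over single-cell reassignments and pairwise swaps: in each
#' iteration the best strictly cost-decreasing move is applied; terminates at
#' a local minimum (or `max_iter`). The returned cost is never above the
#' input cost.
#'
#' @param state A `cbc5_state` with overlaps attached.
#' @param max_iter Maximum accepted moves.
#' @return The refined state, with `cost` and `cost_trace` fields.
#' @export
refine_assignments <- function(state, max_iter = 200L) {
  n <- length(state$assign)
  A_opl <- sum(diag(state$O_opl)); A_ipl <- sum(diag(state$O_ipl))
  Oo <- state$O_opl; Oi <- state$O_ipl
  diag(Oo) <- 0; diag(Oi) <- 0
  # S[i, c]: summed overlap of cell i with current members of cluster c
  Sm <- function(O) sapply(1:3, function(c) rowSums(O[, state$assign == c,
                                                      drop = FALSE]))
  So <- Sm(Oo); Si <- Sm(Oi)
  ov_w <- 2 * state$lambda2
  cost <- cluster_cost(state)
  trace <- cost
  for (it in seq_len(max_iter)) {
    best_delta <- -1e-12; best_move <- NULL
    a <- state$assign
    # single reassignments
    for (i in seq_len(n)) {
      for (b in setdiff(1:3, a[i])) {
        delta <- state$lambda1 * (state$D[i, b] - state$D[i, a[i]]) +
          ov_w * ((So[i, b] - So[i, a[i]]) / A_opl +
                    (Si[i, b] - Si[i, a[i]]) / A_ipl)
        if (delta < best_delta) {
          best_delta <- delta; best_move <- list(kind = "shift", i = i, b = b)
        }
      }
    }
    # swaps between different clusters
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (a[i] == a[j]) next
        delta <- state$lambda1 * (state$D[i, a[j]] + state$D[j, a[i]] -
                                    state$D[i, a[i]] - state$D[j, a[j]]) +
          ov_w * ((So[i, a[j]] - Oo[i, j] + So[j, a[i]] - Oo[i, j] -
                     So[i, a[i]] - So[j, a[j]]) / A_opl +
                    (Si[i, a[j]] - Oi[i, j] + Si[j, a[i]] - Oi[i, j] -
                       Si[i, a[i]] - Si[j, a[j]]) / A_ipl)
        if (delta < best_delta) {
          best_delta <- delta; best_move <- list(kind = "swap", i = i, j = j)
        }
      }
    }
    if (is.null(best_move)) break
    apply_shift <- function(i, b) {
      old <- state$assign[i]
      So[, old] <<- So[, old] - Oo[, i]; So[, b] <<- So[, b] + Oo[, i]
      Si[, old] <<- Si[, old] - Oi[, i]; Si[, b] <<- Si[, b] + Oi[, i]
      state$assign[i] <<- b
    }
    if (best_move$kind == "shift") {
      apply_shift(best_move$i, best_move$b)
    } else {
      bi <- state$assign[best_move$i]; bj <- state$assign[best_move$j]
      apply_shift(best_move$i, bj)
      apply_shift(best_move$j, bi)
    }
    cost <- cost + best_delta
    trace <- c(trace, cost)
  }
  state$cost <- cluster_cost(state)
  state$cost_trace <- trace
  state
}

#' Classify CBC5 cells into subtypes 5T / 5O / 5I
#'
#' The end-to-end subtype pipeline: fit the two SAC band surfaces, compute
#' SAC-corrected axonal depth profiles, cluster by PCA + Gaussian mixture,
#' refine with the shift/swap overlap heuristic, and name the clusters by
#' ascending mean profile peak (5T stratifies closest to the ON band).
#'
#' @param axon_points Tibble `cell_id`, `x`, `y`, `z` (+ optional `weight`).
#' @param sac_points Tibble `band` (`"ON"`/`"OFF"`), `x`, `y`, `z`.
#' @param opl_hulls,ipl_hulls Named lists of `opl_hull`s per cell.
#' @param bins,range Depth histogram spec (see [axon_depth_profiles()]).
#' @param lambda1,lambda2,literal_cost Cost weights (see
#'   [cbc5_attach_overlaps()]).
#' @param refine Run the shift/swap refinement?
#' @param seed Integer seed.
#' @return Object of class `cbc5_fit`; see [tidy.cbc5_fit()] and
#'   [glance.cbc5_fit()].
#' @export
classify_cbc5 <- function(axon_points, sac_points, opl_hulls, ipl_hulls,
                          bins = 50L, range = c(-0.5, 1.5),
                          lambda1 = 1, lambda2 = NULL, literal_cost = FALSE,
                          refine = TRUE, seed = 1L) {
  on_surf <- sac_band_surface(sac_points[sac_points$band == "ON", ])
  off_surf <- sac_band_surface(sac_points[sac_points$band == "OFF", ])
  profiles <- axon_depth_profiles(axon_points, on_surf, off_surf,
                                  bins = bins, range = range)
  state <- cbc5_init(profiles, seed = seed)
  state <- cbc5_attach_overlaps(state, opl_hulls, ipl_hulls,
                                lambda1 = lambda1, lambda2 = lambda2,
                                literal_cost = literal_cost)
  state$cost <- cluster_cost(state)
  if (refine) state <- refine_assignments(state)
  peaks <- profiles |>
    mutate(cluster = state$assign[match(.data$cell_id, state$cell_id)]) |>
    group_by(.data$cluster, .data$depth) |>
    summarise(density = mean(.data$density), .groups = "drop_last") |>
    summarise(peak = .data$depth[which.max(.data$density)], .groups = "drop")
  ord <- order(peaks$peak)
  subtype_names <- c("CBC5T", "CBC5O", "CBC5I")
  name_of <- setNames(subtype_names, peaks$cluster[ord])
  structure(list(state = state, profiles = profiles,
                 on_surface = on_surf, off_surface = off_surf,
                 subtype = unname(name_of[as.character(state$assign)]),
                 cluster_names = name_of),
            class = "cbc5_fit")
}

#' @export
print.cbc5_fit <- function(x, ...) {
  tab <- table(x$subtype)
  cat(sprintf("<cbc5_fit> %d cells: %s; cost %.3f\n",
              length(x$subtype),
              paste(names(tab), tab, sep = " = ", collapse = ", "),
              x$state$cost))
  invisible(x)
}

#' @rdname classify_cbc5
#' @param x A `cbc5_fit`.
#' @param ... Unused.
#' @export
tidy.cbc5_fit <- function(x, ...) {
  tibble(cell_id = x$state$cell_id,
         subtype = x$subtype,
         cluster = x$state$assign,
         PC1 = x$state$scores[, 1], PC2 = x$state$scores[, 2],
         PC3 = x$state$scores[, 3])
}

#' @rdname classify_cbc5
#' @export
glance.cbc5_fit <- function(x, ...) {
  tibble(n_cells = length(x$subtype), cost = x$state$cost,
         lambda1 = x$state$lambda1, lambda2 = x$state$lambda2,
         n_refine_moves = length(x$state$cost_trace %||% 1) - 1L,
         loglik = x$state$loglik)
}
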