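# Per-group RBF-SVM classification of contact-sets (synaptic vs not).
#
# Separate classifiers are trained for OFF-CBC, ON-CBC and RBC contacts onto
# cones, and for OFF-CBC and RBC contacts onto rods; the OFF-CBC rod group
# additionally uses the distance to the nearest synaptic RBC contact.
# Hyperparameters (cost C and kernel width gamma) are selected on a fixed
# logarithmic grid by leave-one-out accuracy, with feature standardisation
# recomputed inside every fold.

#' Feature names and hyperparameter grid of a classifier group
#'
#' @param group One of `"OFF_CBC_cone"`, `"ON_CBC_cone"`, `"RBC_cone"`,
#'   `"OFF_CBC_rod"`, `"RBC_rod"`.
#' @return List with `group`, `features`, `cost_grid`, `gamma_grid`.
#' @export
classifier_group <- function(group = c("OFF_CBC_cone", "ON_CBC_cone",
                                       "RBC_cone", "OFF_CBC_rod", "RBC_rod")) {
  group <- match.arg(group)
  base <- c("a_area", "b_ecc", "c_height", "d_branch", "e_tip", "f_angle",
            "g_n_points")
  feats <- if (group == "OFF_CBC_rod") c(base, "h_dist_rbc") else base
  list(group = group, features = feats,
       cost_grid = 10^(-1:2), gamma_grid = c(0.01, 0.03, 0.1, 0.3, 1))
}

scale_apply <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

fit_fold <- function(xtr, ytr, xte, cost, gamma) {
  ctr <- colMeans(xtr)
  sc <- apply(xtr, 2, sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  m <- e1071::svm(scale_apply(xtr, ctr, sc), ytr, type = "C-classification",
                  kernel = "radial", cost = cost, gamma = gamma,
                  scale = FALSE)
  predict(m, scale_apply(xte, ctr, sc))
}

loo_predictions <- function(x, y, cost, gamma) {
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L) {
      pred[i] <- levels(ytr)  # degenerate fold: majority (only) class
    } else {
      pred[i] <- fit_fold(x[-i, , drop = FALSE], ytr,
                          x[i, , drop = FALSE], cost, gamma)
    }
  }
  pred
}

check_features <- function(labeled, feats) {
  miss <- setdiff(feats, names(labeled))
  if (length(miss) > 0L) {
    abort(paste("missing features:", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(labeled[, feats])
  if (anyNA(x)) abort("features contain missing values")
  x
}

#' Train a contact-set classifier
#'
#' Selects `(C, gamma)` on the group's logarithmic grid by leave-one-out
#' accuracy (standardisation recomputed within each fold), then fits the
#' final RBF C-SVM on the full standardized training set.
#'
#' @param labeled Feature tibble with a `label` column
#'   (`"synaptic"`/`"non_synaptic"`).
#' @param group A group name or [classifier_group()] list.
#' @param seed Integer seed (the fit is deterministic; the seed guards any
#'   tie-breaking randomness in the backend).
#' @return Object of class `contact_svm`.
#' @export
train_contact_classifier <- function(labeled, group = "ON_CBC_cone",
                                     seed = 1L) {
  if (is.character(group)) group <- classifier_group(group)
  x <- check_features(labeled, group$features)
  y <- factor(labeled$label, levels = c("non_synaptic", "synaptic"))
  if (nlevels(droplevels(y)) < 2L) {
    abort("training set contains a single class")
  }
  set.seed(seed)
  grid <- expand.grid(cost = group$cost_grid, gamma = group$gamma_grid)
  acc <- numeric(nrow(grid))
  preds <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    preds[[k]] <- loo_predictions(x, y, grid$cost[k], grid$gamma[k])
    acc[k] <- mean(preds[[k]] == y)
  }
  best <- which.max(acc)  # first maximum: deterministic tie-break
  ctr <- colMeans(x)
  sc <- apply(x, 2, sd); sc[sc == 0 | !is.finite(sc)] <- 1
  model <- e1071::svm(scale_apply(x, ctr, sc), y, type = "C-classification",
                      kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], scale = FALSE)
  structure(list(model = model, center = ctr, scale = sc,
                 group = group, cost = grid$cost[best],
                 gamma = grid$gamma[best], loo_accuracy = acc[best],
                 loo_pred = preds[[best]], y = y, n_train = nrow(x)),
            class = "contact_svm")
}

#' @export
print.contact_svm <- function(x, ...) {
  cat(sprintf("<contact_svm> group %s, n = %d, C = %g, gamma = %g, LOO accuracy %.3f\n",
              x$group$group, x$n_train, x$cost, x$gamma, x$loo_accuracy))
  invisible(x)
}

#' Leave-one-out cross-validation report
#'
#' Evaluates a classifier group by leave-one-out cross-validation at the
#' grid-selected hyperparameters and reports the false-positive rate
#' FP/(FP+TN), false-negative rate FN/(FN+TP) and total score (accuracy),
#' with synaptic as the positive class.
#'
#' @inheritParams train_contact_classifier
#' @return Object of class `cv_report`: list with `predictions` tibble and
#'   the three rates; see [tidy.cv_report()] / [glance.cv_report()].
#' @export
loo_cross_validate <- function(labeled, group = "ON_CBC_cone", seed = 1L) {
  if (nrow(labeled) < 3L) abort("need at least 3 labeled contact-sets")
  fit <- train_contact_classifier(labeled, group, seed)
  y <- fit$y; pred <- fit$loo_pred
  tp <- sum(pred == "synaptic" & y == "synaptic")
  tn <- sum(pred == "non_synaptic" & y == "non_synaptic")
  fp <- sum(pred == "synaptic" & y == "non_synaptic")
  fn <- sum(pred == "non_synaptic" & y == "synaptic")
  structure(list(
    predictions = tibble(truth = as.character(y),
                         prediction = as.character(pred)),
    group = fit$group$group, n_train = length(y),
    false_positive_rate = if (fp + tn > 0) fp / (fp + tn) else 0,
    false_negative_rate = if (fn + tp > 0) fn / (fn + tp) else 0,
    total_score = (tp + tn) / length(y),
    confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
    cost = fit$cost, gamma = fit$gamma
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: n = %d, FPR %.1f%%, FNR %.1f%%, total score %.2f\n",
              x$group, x$n_train, 100 * x$false_positive_rate,
              100 * x$false_negative_rate, x$total_score))
  invisible(x)
}

#' @rdname loo_cross_validate
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) x$predictions

#' @rdname loo_cross_validate
#' @export
glance.cv_report <- function(x, ...) {
  tibble(group = x$group, n_train = x$n_train,
         false_positive_rate = x$false_positive_rate,
         false_negative_rate = x$false_negative_rate,
         total_score = x$total_score, cost = x$cost, gamma = x$gamma)
}

#' Predict synaptic labels for contact-sets
#'
#' @param object A `contact_svm`.
#' @param newdata Feature tibble containing the group's features.
#' @param ... Unused.
#' @return `newdata` with a `label` column added (input order preserved).
#' @export
predict.contact_svm <- function(object, newdata, ...) {
  if (nrow(newdata) == 0L) {
    newdata$label <- character(0)
    return(newdata)
  }
  x <- check_features(newdata, object$group$features)
  p <- predict(object$model, scale_apply(x, object$center, object$scale))
  newdata$label <- as.character(p)
  newdata
}
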