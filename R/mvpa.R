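feature_names_68 <- function() {
  combos <- c("tmean_epochs.mean_channels", "tmean_epochs.sd_channels",
              "sd_epochs.mean_channels", "sd_epochs.sd_channels")
  as.vector(t(outer(marker_ids, combos, paste, sep = ".")))
}

#' Build the 68-feature summary of one subject/session
#'
#' Condenses the seventeen marker maps into all four combinations of central
#' tendency and fluctuation over time and space: 80% trimmed mean or SD
#' across epochs, crossed with mean or SD across channels — 17 x 4 = 68
#' named, deterministically ordered features. With multi-iteration resting
#' epoching the summaries are averaged over iterations. wSMI contributes via
#' its per-channel degree reduction so all markers share the epoch x channel
#' shape.
#'
#' @param markers Output of [compute_markers()] (its `per_iteration`
#'   attribute is used), or a single list of epochs x channels marker
#'   matrices.
#' @return Named numeric vector of length 68.
#' @export
build_features <- function(markers) {
  iters <- if (!is.null(attr(markers, "per_iteration"))) {
    attr(markers, "per_iteration")
  } else if (is.list(markers) && !is.null(markers[[1]]) && is.matrix(markers[[1]])) {
    list(markers)
  } else if (is.list(markers) && is.list(markers[[1]]) &&
             is.matrix(markers[[1]][[1]])) {
    markers # a list of per-iteration marker lists
  } else {
    stop("unrecognized marker input", call. = FALSE)
  }
  missing <- setdiff(marker_ids, names(iters[[1]]))
  if (length(missing)) {
    stop("missing markers: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  acc <- numeric(68)
  for (mv in iters) {
    v <- unlist(lapply(marker_ids, function(id) {
      m <- mv[[id]]
      tm <- apply(m, 2, trimmed_mean80)   # per-channel trimmed mean over epochs
      sde <- apply(m, 2, stats::sd)       # per-channel SD over epochs
      c(mean(tm), stats::sd(tm), mean(sde), stats::sd(sde))
    }), use.names = FALSE)
    acc <- acc + v
  }
  stats::setNames(acc / length(iters), feature_names_68())
}

auc_score <- function(labels_pos, scores) {
  # labels_pos: logical (TRUE = positive class); rank-based AUC
  n1 <- sum(labels_pos); n0 <- sum(!labels_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

select_features_f <- function(X, y, frac = 0.2) {
  # univariate F-score (equivalent to squared two-sample t on 2 classes)
  n_keep <- ceiling(frac * ncol(X))
  g1 <- X[y == levels(y)[1], , drop = FALSE]
  g2 <- X[y == levels(y)[2], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  gm <- colMeans(X)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- (n1 - 1) * v1 + (n2 - 1) * v2
  f <- (ssb / 1) / (ssw / (n1 + n2 - 2))
  f[!is.finite(f)] <- 0
  sort(order(f, decreasing = TRUE)[seq_len(n_keep)])
}

fit_svm_pipeline <- function(X, y, cost, probability = FALSE) {
  sel <- select_features_f(X, y)
  model <- suppressWarnings(
    e1071::svm(X[, sel, drop = FALSE], y, kernel = "linear",
               cost = cost, probability = probability, scale = TRUE)
  )
  list(selected = sel, model = model)
}

decision_scores <- function(fit, X, positive) {
  pr <- stats::predict(fit$model, X[, fit$selected, drop = FALSE],
                       decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lab <- colnames(dv)[1] # "A/B": positive decision value means class A
  s <- as.numeric(dv[, 1])
  if (!startsWith(lab, paste0(positive, "/"))) s <- -s
  s
}

inner_choose_cost <- function(X, y, cost_grid, k = 5, positive = "MCS") {
  fold <- stratified_folds(y, k)
  perf <- vapply(cost_grid, function(cc) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) return(NA_real_)
      fit <- fit_svm_pipeline(X[tr, , drop = FALSE], droplevels(y[tr]), cc)
      s <- decision_scores(fit, X[!tr, , drop = FALSE], positive)
      auc_score(y[!tr] == positive, s)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  # ties (common on separable data, where AUC is scale-invariant) break
  # toward the least-penalized model, which keeps Platt calibration sharp
  cost_grid[max(which(perf >= max(perf) - 1e-12))]
}

#' Train the linear-SVM predictor of minimally conscious state
#'
#' Fits the study's diagnostic pipeline on a labeled reference database of
#' 68-feature vectors: 20% univariate-F feature selection (14 of 68
#' features), a linear support-vector classifier with the penalty C chosen
#' by nested stratified cross-validation over the grid
#' `{1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1}`, and Platt scaling for calibrated
#' probabilities. Feature selection and C search run inside training folds
#' only; the reported `cv_auc` is the outer 5-fold estimate.
#'
#' @param features Subjects x 68 matrix (or data frame) of [build_features()]
#'   vectors.
#' @param labels Character/factor with two classes, `"VS"` and `"MCS"`.
#' @param cost_grid Candidate C values.
#' @param n_folds Outer/inner fold count.
#' @param seed Integer seed (fold assignment).
#' @return An object of class `mcs_classifier`: selected features, fitted
#'   SVM with Platt calibration, chosen cost, `cv_auc`, configuration.
#' @export
train_mcs_classifier <- function(features, labels,
                                 cost_grid = 10^(-6:-1),
                                 n_folds = 5, seed = 1L) {
  X <- as.matrix(features)
  y <- factor(labels, levels = c("VS", "MCS"))
  if (nlevels(droplevels(y)) < 2) stop("need two classes", call. = FALSE)
  if (nrow(X) < 10) stop("need >= 10 subjects", call. = FALSE)
  cost_grid <- sort(unique(cost_grid))
  set.seed(as.integer(seed) %% 2147483629)

  fold <- stratified_folds(y, n_folds)
  outer_auc <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    cc <- inner_choose_cost(X[tr, , drop = FALSE], droplevels(y[tr]), cost_grid)
    fit <- fit_svm_pipeline(X[tr, , drop = FALSE], droplevels(y[tr]), cc)
    s <- decision_scores(fit, X[!tr, , drop = FALSE], "MCS")
    auc_score(y[!tr] == "MCS", s)
  }, numeric(1))

  cost <- inner_choose_cost(X, y, cost_grid)
  final <- fit_svm_pipeline(X, y, cost, probability = TRUE)
  structure(list(
    selected = final$selected,
    feature_names = colnames(X) %||% feature_names_68(),
    model = final$model, cost = cost,
    cv_auc = mean(outer_auc, na.rm = TRUE),
    n_folds = n_folds, seed = seed, n_train = nrow(X)
  ), class = "mcs_classifier")
}

#' @export
print.mcs_classifier <- function(x, ...) {
  cat(sprintf("<mcs_classifier> linear SVM, C = %g, %d/%d features, CV AUC = %.3f\n",
              x$cost, length(x$selected), length(x$feature_names), x$cv_auc))
  invisible(x)
}

#' Predict the probability of being MCS
#'
#' Platt-calibrated probability that a feature vector comes from a minimally
#' conscious (rather than VS/UWS) recording.
#'
#' @param clf An `mcs_classifier`.
#' @param fv Named 68-feature vector (or matrix of rows).
#' @return Numeric probability/ies in \[0, 1\].
#' @export
predict_mcs <- function(clf, fv) {
  X <- if (is.matrix(fv)) fv else matrix(fv, 1, dimnames = list(NULL, names(fv)))
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), clf$feature_names)) {
    if (!all(clf$feature_names %in% colnames(X))) {
      stop("feature names do not match the classifier", call. = FALSE)
    }
    X <- X[, clf$feature_names, drop = FALSE]
  }
  pr <- stats::predict(clf$model, X[, clf$selected, drop = FALSE],
                       probability = TRUE)
  unname(attr(pr, "probabilities")[, "MCS"])
}

#' Pre/post change in the MCS prediction
#'
#' The tDCS-induced change: probability on the post-stimulation resting EEG
#' minus the probability on the pre-stimulation one.
#'
#' @param clf An `mcs_classifier`.
#' @param pre_fv,post_fv Feature vectors for the two sessions.
#' @return Signed scalar in \[-1, 1\].
#' @export
delta_prediction <- function(clf, pre_fv, post_fv) {
  predict_mcs(clf, post_fv) - predict_mcs(clf, pre_fv)
}
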