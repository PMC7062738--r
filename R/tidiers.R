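#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster-permutation result
#'
#' One row per cluster: sign, size, mass and permutation p-value.
#' @param x An `eeg_cluster_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eeg_cluster_result <- function(x, ...) {
  tibble::tibble(cluster = x$cluster, sign = x$sign,
                 n_elements = x$n_elements, mass = x$mass,
                 p_value = x$p_value)
}

#' One-row summary of a cluster-permutation result
#' @param x An `eeg_cluster_result`.
#' @param ... Unused.
#' @return A tibble with test configuration and the smallest cluster p.
#' @export
glance.eeg_cluster_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_clusters = nrow(x),
    n_significant = sum(x$p_value < 0.05),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_,
    first_step = p$first_step, paired = p$paired,
    threshold_p = p$threshold_p, n_perm = p$n_perm
  )
}

#' Tidy an MCS classifier: selected features and linear weights
#' @param x An `mcs_classifier`.
#' @param ... Unused.
#' @return A tibble `feature`, `weight` (weights in the scaled feature
#'   space; positive pushes toward MCS).
#' @export
tidy.mcs_classifier <- function(x, ...) {
  w <- as.numeric(crossprod(x$model$coefs, x$model$SV))
  if (identical(x$model$levels[1], "MCS")) w <- w else w <- -w
  tibble::tibble(feature = x$feature_names[x$selected], weight = w)
}

#' One-row summary of an MCS classifier
#' @param x An `mcs_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.mcs_classifier <- function(x, ...) {
  tibble::tibble(cv_auc = x$cv_auc, cost = x$cost,
                 n_features = length(x$selected),
                 n_train = x$n_train, n_folds = x$n_folds)
}

#' Plot a marker topography over the scalp
#'
#' Channels at their 2-D scalp positions, colored by marker value; channels
#' belonging to a significant cluster can be highlighted.
#'
#' @param layout An `eeg_layout`.
#' @param values Per-channel numeric vector.
#' @param highlight Optional integer vector of channels to ring.
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_topography <- function(layout, values, highlight = NULL, title = NULL) {
  df <- tibble::tibble(x = layout$positions_2d[, 1],
                       y = layout$positions_2d[, 2],
                       value = values)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, color = .data$value)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, color = "value")
  if (length(highlight)) {
    p <- p + ggplot2::geom_point(data = df[highlight, , drop = FALSE],
                                 shape = 21, size = 6, stroke = 1,
                                 color = "white", fill = NA)
  }
  p
}

#' Heatmap of a temporal-generalization matrix
#'
#' Train time on the y axis, test time on the x axis, AUC as fill; the
#' diagonal marks classifiers tested at their training time. A sustained
#' square of above-chance AUC off the diagonal indicates metastable activity.
#'
#' @param object A `tg_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tg_matrix <- function(object, ...) {
  df <- expand.grid(train = object$time_ms, test = object$time_ms)
  df$auc <- as.numeric(object$auc)
  ggplot2::ggplot(df, ggplot2::aes(.data$test, .data$train, fill = .data$auc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "navy",
                                  mid = "white", high = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "test time (ms)", y = "train time (ms)", fill = "AUC") +
    ggplot2::theme_minimal()
}

#' Butterfly plot of an event-related potential
#'
#' All channels overlaid against time.
#' @param object An `erp_wave`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.erp_wave <- function(object, ...) {
  df <- tibble::tibble(
    channel = rep(seq_len(nrow(object$data)), each = ncol(object$data)),
    time_ms = rep(object$time_ms, nrow(object$data)),
    uV = as.numeric(t(object$data))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uV,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)",
                  title = object$condition) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
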