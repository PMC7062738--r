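#' Condition-wise event-related potential
#'
#' Per channel and timepoint, the 80% trimmed mean across the retained trials
#' of one condition — robust to occasional extreme trials.
#'
#' @param ep A task `eeg_epochs` (from [epoch_task()]).
#' @param condition `"standard"` or `"deviant"`.
#' @param min_trials Minimum trial count below which the wave is flagged.
#' @return A list of class `erp_wave`: `data` (channels x timepoints, uV),
#'   `time_ms`, `n_trials`, `condition`, `flagged`.
#' @export
erp_average <- function(ep, condition, min_trials = 5) {
  keep <- !ep$rejected_epochs & ep$labels == condition
  n <- sum(keep)
  d <- dim(ep$data)
  w <- matrix(NA_real_, d[2], d[3])
  if (n > 0) {
    for (ch in seq_len(d[2])) {
      w[ch, ] <- tm80_cols(matrix(ep$data[keep, ch, ], n, d[3]))
    }
  }
  structure(list(data = w, time_ms = ep$time_ms %||% (seq_len(d[3]) - 1),
                 n_trials = n, condition = condition,
                 flagged = n < min_trials), class = "erp_wave")
}

#' Per-subject oddball interaction contrast
#'
#' The double difference
#' `[Deviant - Standard]_post - [Deviant - Standard]_pre` per subject,
#' flattened to the element order of [spacetime_adjacency()]
#' (`(t - 1) * n_channels + ch`), ready for [cluster_perm()] between groups.
#' Subjects missing any of the four cells are excluded and listed.
#'
#' @param erps A list per subject: `list(pre = list(standard=, deviant=),
#'   post = ...)` of `erp_wave`s.
#' @return A list: `contrast` (subjects x elements matrix), `n_channels`,
#'   `n_time`, `excluded` (integer indices).
#' @export
interaction_contrast <- function(erps) {
  rows <- list(); excluded <- integer()
  for (i in seq_along(erps)) {
    s <- erps[[i]]
    ok <- !is.null(s$pre$standard) && !is.null(s$pre$deviant) &&
      !is.null(s$post$standard) && !is.null(s$post$deviant) &&
      !s$pre$standard$flagged && !s$pre$deviant$flagged &&
      !s$post$standard$flagged && !s$post$deviant$flagged
    if (!ok) { excluded <- c(excluded, i); next }
    dd <- (s$post$deviant$data - s$post$standard$data) -
      (s$pre$deviant$data - s$pre$standard$data)
    rows[[length(rows) + 1L]] <- as.numeric(dd) # column-major: ch fastest
  }
  if (!length(rows)) stop("no complete subject", call. = FALSE)
  m <- do.call(rbind, rows)
  list(contrast = m, n_channels = nrow(erps[[which(!seq_along(erps) %in% excluded)[1]]]$pre$standard$data),
       n_time = ncol(m) / nrow(erps[[which(!seq_along(erps) %in% excluded)[1]]]$pre$standard$data),
       excluded = excluded)
}

#' Temporal-generalization decoding of deviant vs standard trials
#'
#' Trains a linear SVM at each (decimated) timepoint on the channel voltages
#' of that sample, and tests it at every other timepoint, under repeated
#' stratified cross-validation. Performance is the AUC of the decision
#' values, averaged across all fold-iteration estimates.
#'
#' @param ep A task `eeg_epochs`.
#' @param seed Integer seed (fold assignment).
#' @param n_iter CV repetitions (study default 10).
#' @param n_folds Stratified folds (5).
#' @param decim Keep every `decim`-th timepoint.
#' @param cost SVM penalty.
#' @return A list of class `tg_matrix`: `auc` (train x test times),
#'   `time_ms`, `flagged` (too few trials in a class).
#' @export
tg_decode <- function(ep, seed = 1L, n_iter = 10, n_folds = 5, decim = 1,
                      cost = 1) {
  keep <- !ep$rejected_epochs & ep$labels %in% c("standard", "deviant")
  y <- factor(ep$labels[keep], levels = c("standard", "deviant"))
  d <- dim(ep$data)
  tsel <- seq(1, d[3], by = decim)
  nt <- length(tsel)
  n <- sum(keep)
  flagged <- min(table(y)) < 5
  auc <- matrix(NA_real_, nt, nt)
  if (!flagged) {
    X <- ep$data[keep, , tsel, drop = FALSE] # trials x channels x times
    set.seed(as.integer(seed) %% 2147483629)
    acc <- matrix(0, nt, nt); cnt <- 0L
    for (it in seq_len(n_iter)) {
      fold <- stratified_folds(y, n_folds)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
        ytr <- y[tr]
        pos <- y[!tr] == "deviant"
        n_te <- sum(!tr)
        # unfold test trials to (trials * times) x channels for one GEMM
        # per trained classifier
        Mte <- matrix(aperm(X[!tr, , , drop = FALSE], c(1, 3, 2)),
                      n_te * nt, d[2])
        for (ti in seq_len(nt)) {
          Xtr <- matrix(X[tr, , ti], sum(tr), d[2])
          mu <- colMeans(Xtr); sg <- sqrt(col_vars(Xtr))
          sg[sg == 0] <- 1
          Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
          model <- suppressWarnings(e1071::svm(Xtr, ytr, kernel = "linear",
                                               cost = cost, scale = FALSE))
          w <- as.numeric(crossprod(model$coefs, model$SV))
          b <- model$rho
          # orient the hyperplane so positive scores mean "deviant"
          str <- as.numeric(Xtr %*% w) - b
          sgn <- sign(mean(str[ytr == "deviant"]) - mean(str[ytr == "standard"]))
          if (sgn == 0) sgn <- 1
          v <- w / sg
          S <- matrix(Mte %*% v, n_te, nt) # scores per test trial x time
          S <- sgn * (S - sum(mu * v) - b)
          for (tj in seq_len(nt)) {
            acc[ti, tj] <- acc[ti, tj] + auc_score(pos, S[, tj])
          }
        }
        cnt <- cnt + 1L
      }
    }
    auc <- acc / cnt
  }
  structure(list(auc = auc, time_ms = (ep$time_ms %||% tsel)[tsel],
                 n_trials = n, flagged = flagged,
                 cv = list(n_iter = n_iter, n_folds = n_folds, seed = seed)),
            class = "tg_matrix")
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat(sprintf("<tg_matrix> %d x %d timepoints, mean AUC %.3f%s\n",
              nrow(x$auc), ncol(x$auc), mean(x$auc, na.rm = TRUE),
              if (x$flagged) " (FLAGGED: too few trials)" else ""))
  invisible(x)
}
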