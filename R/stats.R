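#' Adjacency graph over analysis elements
#'
#' Thin container tying an element count to a neighbor relation, consumed by
#' [cluster_perm()]. Constructed by the geometry helpers
#' ([channel_adjacency()], [pair_adjacency()], [spacetime_adjacency()],
#' [matrix_adjacency()]).
#'
#' @param neighbors List of integer vectors, `neighbors[[i]]` giving the
#'   elements adjacent to element `i` (symmetric).
#' @param geometry Label for printing.
#' @return An object of class `eeg_adjacency`.
#' @export
adjacency_graph <- function(neighbors, geometry = "custom") {
  structure(list(n = length(neighbors), neighbors = neighbors,
                 geometry = geometry), class = "eeg_adjacency")
}

#' @export
print.eeg_adjacency <- function(x, ...) {
  cat(sprintf("<eeg_adjacency> %s, %d elements, %d edges\n", x$geometry, x$n,
              sum(lengths(x$neighbors)) / 2))
  invisible(x)
}

adj_from_matrix <- function(m, geometry) {
  adjacency_graph(lapply(seq_len(nrow(m)), function(i) which(m[i, ])), geometry)
}

#' Channel-topography adjacency
#' @param layout An `eeg_layout`.
#' @return An `eeg_adjacency` over channels.
#' @export
channel_adjacency <- function(layout) {
  adj_from_matrix(layout$adjacency, "channels")
}

#' Electrode-pair adjacency for pairwise connectivity statistics
#'
#' Elements are the `n (n - 1) / 2` unordered electrode pairs in
#' lexicographic order. Two pairs are neighbors when they share one electrode
#' and their non-shared electrodes are layout neighbors, or when they share
#' none but one of the two cross-assignments maps both endpoints onto layout
#' neighbors.
#'
#' @param layout An `eeg_layout`.
#' @return An `eeg_adjacency` over pairs, with the pair index matrix in
#'   attribute `pairs`.
#' @export
pair_adjacency <- function(layout) {
  A <- layout$adjacency
  nc <- nrow(A)
  pairs <- electrode_pairs(layout)
  np <- nrow(pairs)
  # index pairs by electrode for fast candidate lookup
  by_elec <- lapply(seq_len(nc), function(e) which(pairs[, 1] == e | pairs[, 2] == e))
  nb <- vector("list", np)
  for (p in seq_len(np)) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    cand <- unique(c(by_elec[[a]], by_elec[[b]],
                     unlist(by_elec[which(A[a, ] | A[b, ])], use.names = FALSE)))
    cand <- cand[cand != p]
    keep <- vapply(cand, function(q) {
      cc <- pairs[q, 1]; dd <- pairs[q, 2]
      shared <- c(a, b)[c(a, b) %in% c(cc, dd)]
      if (length(shared) == 1) {
        u <- setdiff(c(a, b), shared); v <- setdiff(c(cc, dd), shared)
        A[u, v]
      } else if (length(shared) == 0) {
        (A[a, cc] && A[b, dd]) || (A[a, dd] && A[b, cc])
      } else FALSE
    }, logical(1))
    nb[[p]] <- sort(cand[keep])
  }
  g <- adjacency_graph(nb, "channel-pairs")
  attr(g, "pairs") <- pairs
  g
}

#' Enumerate the unordered electrode pairs of a layout
#'
#' All `n (n - 1) / 2` pairs in lexicographic order — the element order used
#' by [wsmi()] and [pair_adjacency()].
#' @param layout An `eeg_layout` (or a channel count).
#' @return Two-column integer matrix.
#' @export
electrode_pairs <- function(layout) {
  nc <- if (inherits(layout, "eeg_layout")) nrow(layout$adjacency) else as.integer(layout)
  pairs <- which(upper.tri(diag(nc)), arr.ind = TRUE)
  unname(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
}

#' Channel-by-time adjacency for spatiotemporal clustering
#'
#' Element `(t - 1) * n_channels + ch` for time index t and channel ch.
#' Neighbors: the same channel at adjacent samples, plus layout-neighbor
#' channels at the same sample.
#'
#' @param layout An `eeg_layout`.
#' @param n_time Number of timepoints.
#' @return An `eeg_adjacency`.
#' @export
spacetime_adjacency <- function(layout, n_time) {
  A <- layout$adjacency
  nc <- nrow(A)
  nb <- vector("list", nc * n_time)
  ch_nb <- lapply(seq_len(nc), function(i) which(A[i, ]))
  for (t in seq_len(n_time)) for (ch in seq_len(nc)) {
    i <- (t - 1) * nc + ch
    v <- (t - 1) * nc + ch_nb[[ch]]
    if (t > 1) v <- c(v, i - nc)
    if (t < n_time) v <- c(v, i + nc)
    nb[[i]] <- v
  }
  adjacency_graph(nb, "channel-time")
}

#' Lattice adjacency over a train-time x test-time matrix
#'
#' 4-neighborhood over the cells of a square generalization matrix, element
#' `(j - 1) * n + i` for train time i, test time j.
#'
#' @param n Matrix side length.
#' @return An `eeg_adjacency`.
#' @export
matrix_adjacency <- function(n) {
  nb <- vector("list", n * n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    id <- (j - 1) * n + i
    v <- integer()
    if (i > 1) v <- c(v, id - 1L)
    if (i < n) v <- c(v, id + 1L)
    if (j > 1) v <- c(v, id - n)
    if (j < n) v <- c(v, id + n)
    nb[[id]] <- v
  }
  adjacency_graph(nb, "time-time")
}

# ---- first-step statistics (vectorized over elements) --------------------

col_vars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

welch_t_stat <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- col_vars(A); vb <- col_vars(B)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(stat = t, p = p)
}

mann_whitney_z_stat <- function(A, B) {
  z <- vapply(seq_len(ncol(A)), function(j) {
    mann_whitney_z(A[, j], B[, j])
  }, numeric(1))
  list(stat = z, p = 2 * stats::pnorm(-abs(z)))
}

dependent_t_stat <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(col_vars(D))
  t <- m / (s / sqrt(n))
  list(stat = t, p = 2 * stats::pt(-abs(t), n - 1))
}

wilcoxon_z_stat <- function(D) {
  z <- apply(D, 2, wilcoxon_signed_z)
  list(stat = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Mann-Whitney U z-statistic
#'
#' Normal-approximation z with tie correction and continuity correction,
#' signed so that larger values in `a` give positive z.
#' @param a,b Numeric samples.
#' @return Scalar z.
#' @export
mann_whitney_z <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  tie <- rle(sort(r))$lengths
  sig <- sqrt(na * nb / 12 * ((na + nb + 1) -
                sum(tie^3 - tie) / ((na + nb) * (na + nb - 1))))
  if (sig == 0) return(0)
  (U - mu - sign(U - mu) * 0.5 * (U != mu)) / sig
}

#' Wilcoxon signed-rank z-statistic
#'
#' z of the signed-rank statistic of `x` (or `x - y`), normal approximation
#' with continuity correction; zeros dropped, midranks for ties.
#' @param x Numeric vector (differences if `y` is `NULL`).
#' @param y Optional paired sample.
#' @return Scalar z.
#' @export
wilcoxon_signed_z <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(0)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- rle(sort(r))$lengths
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48)
  if (sig == 0) return(0)
  (W - mu - sign(W - mu) * 0.5 * (W != mu)) / sig
}

# connected components among suprathreshold elements; returns list of
# integer vectors
supra_clusters <- function(mask, neighbors) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  in_mask <- logical(length(mask)); in_mask[idx] <- TRUE
  seen <- logical(length(mask))
  out <- list()
  for (s in idx) {
    if (seen[s]) next
    comp <- integer(); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in neighbors[[v]]) {
        if (in_mask[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

max_cluster_mass <- function(stat, p, threshold_p, neighbors) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- p < threshold_p & sign(stat) == sgn
    for (cl in supra_clusters(mask, neighbors)) {
      best <- max(best, abs(sum(stat[cl])))
    }
  }
  best
}

#' Two-step cluster-based permutation test
#'
#' First step: an elementwise statistic between the two groups (Welch t or
#' Mann-Whitney z unpaired; dependent t or signed-rank z paired), thresholded
#' two-sided at `threshold_p`. Suprathreshold elements are clustered by the
#' adjacency graph, separately for positive and negative signs, and each
#' cluster's mass is the sum of its statistics. Second step: group labels
#' (unpaired) or within-subject signs (paired) are permuted `n_perm` times;
#' each cluster's p-value is the proportion of permutations whose maximum
#' absolute cluster mass reaches the observed mass (max-statistic control of
#' the family-wise error over all elements).
#'
#' @param data_a Subjects x elements matrix (group A, or condition A when
#'   paired).
#' @param data_b Subjects x elements matrix (group B / condition B; paired
#'   data must have equal row counts).
#' @param adjacency An `eeg_adjacency` matching the element count.
#' @param first_step `"welch_t"` or `"mann_whitney_z"`; in paired mode these
#'   select the dependent t-test and the Wilcoxon signed-rank z.
#' @param paired Logical.
#' @param threshold_p First-step inclusion p-value.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param exhaustive If `TRUE`, enumerate every relabeling (all
#'   `choose(n, n_a)` group assignments, or all `2^n` sign patterns when
#'   paired) instead of random sampling; the p-value is then the exact
#'   proportion of relabelings — including the observed one — whose maximum
#'   cluster mass reaches the observed mass.
#' @return A tibble of clusters (`cluster`, `sign`, `n_elements`, `mass`,
#'   `p_value`, list-column `members`) of class `eeg_cluster_result`, with
#'   the null max-mass distribution, the elementwise statistic and the
#'   parameters in attributes.
#' @export
cluster_perm <- function(data_a, data_b, adjacency,
                         first_step = c("welch_t", "mann_whitney_z"),
                         paired = FALSE, threshold_p = 0.05,
                         n_perm = 10000, seed = 1L, exhaustive = FALSE) {
  first_step <- match.arg(first_step)
  data_a <- as.matrix(data_a); data_b <- as.matrix(data_b)
  m <- ncol(data_a)
  if (ncol(data_b) != m) stop("element counts differ", call. = FALSE)
  if (adjacency$n != m) stop("adjacency does not match element count", call. = FALSE)
  if (paired && nrow(data_a) != nrow(data_b)) {
    stop("paired data require equal subject counts", call. = FALSE)
  }
  if (min(nrow(data_a), nrow(data_b)) < 2) stop("need >= 2 subjects per group", call. = FALSE)
  nbrs <- adjacency$neighbors

  statfun <- if (!paired) {
    if (first_step == "welch_t") welch_t_stat else mann_whitney_z_stat
  } else {
    if (first_step == "welch_t") {
      function(A, B) dependent_t_stat(A - B)
    } else {
      function(A, B) wilcoxon_z_stat(A - B)
    }
  }

  obs <- statfun(data_a, data_b)
  clusters <- list(); signs <- integer(); masses <- numeric()
  for (sgn in c(1, -1)) {
    mask <- obs$p < threshold_p & sign(obs$stat) == sgn
    for (cl in supra_clusters(mask, nbrs)) {
      clusters[[length(clusters) + 1L]] <- cl
      signs <- c(signs, sgn)
      masses <- c(masses, sum(obs$stat[cl]))
    }
  }

  set.seed(as.integer(seed) %% 2147483629)
  if (exhaustive) {
    if (!paired) {
      pool <- rbind(data_a, data_b)
      na <- nrow(data_a); n <- nrow(pool)
      combos <- utils::combn(n, na)
      null_max <- apply(combos, 2, function(idx) {
        st <- statfun(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE])
        max_cluster_mass(st$stat, st$p, threshold_p, nbrs)
      })
    } else {
      n <- nrow(data_a)
      null_max <- vapply(seq_len(2^n) - 1L, function(bits) {
        flip <- bitwAnd(bits, 2L^(seq_len(n) - 1L)) > 0
        A <- data_a; B <- data_b
        A[flip, ] <- data_b[flip, , drop = FALSE]
        B[flip, ] <- data_a[flip, , drop = FALSE]
        st <- statfun(A, B)
        max_cluster_mass(st$stat, st$p, threshold_p, nbrs)
      }, numeric(1))
    }
    pvals <- vapply(masses, function(ms) {
      mean(null_max >= abs(ms) - 1e-12)
    }, numeric(1))
    n_perm <- length(null_max)
  } else {
    null_max <- numeric(n_perm)
    if (!paired) {
      pool <- rbind(data_a, data_b)
      na <- nrow(data_a); n <- nrow(pool)
      for (k in seq_len(n_perm)) {
        idx <- sample.int(n, na)
        st <- statfun(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE])
        null_max[k] <- max_cluster_mass(st$stat, st$p, threshold_p, nbrs)
      }
    } else {
      n <- nrow(data_a)
      for (k in seq_len(n_perm)) {
        flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
        A <- data_a; B <- data_b
        A[flip, ] <- data_b[flip, , drop = FALSE]
        B[flip, ] <- data_a[flip, , drop = FALSE]
        st <- statfun(A, B)
        null_max[k] <- max_cluster_mass(st$stat, st$p, threshold_p, nbrs)
      }
    }
    pvals <- vapply(masses, function(ms) {
      (1 + sum(null_max >= abs(ms))) / (n_perm + 1)
    }, numeric(1))
  }

  out <- tibble::tibble(
    cluster = seq_along(clusters),
    sign = signs,
    n_elements = lengths(clusters),
    mass = masses,
    p_value = pvals,
    members = clusters
  )
  class(out) <- c("eeg_cluster_result", class(out))
  attr(out, "null_max") <- null_max
  attr(out, "elementwise") <- obs
  attr(out, "params") <- list(first_step = first_step, paired = paired,
                              threshold_p = threshold_p, n_perm = n_perm,
                              seed = seed)
  out
}

#' Hedges' g with bootstrap confidence interval
#'
#' Pooled-SD standardized mean difference with the small-sample correction
#' `J = 1 - 3 / (4 (n1 + n2) - 9)`; percentile bootstrap CI by resampling
#' subjects within groups.
#'
#' @param group_a,group_b Numeric vectors.
#' @param n_boot Bootstrap iterations (study default 10000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return A tibble `kind`, `value`, `ci_low`, `ci_high`, `n_boot`.
#' @export
hedges_g <- function(group_a, group_b, n_boot = 10000, conf = 0.95, seed = 1L) {
  g_of <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
    if (sp == 0) return(NA_real_)
    (mean(a) - mean(b)) / sp * (1 - 3 / (4 * (n1 + n2) - 9))
  }
  g <- g_of(group_a, group_b)
  if (is.na(g)) stop("zero pooled SD: Hedges' g undefined", call. = FALSE)
  set.seed(as.integer(seed) %% 2147483629)
  bt <- vapply(seq_len(n_boot), function(i) {
    g_of(sample(group_a, replace = TRUE), sample(group_b, replace = TRUE))
  }, numeric(1))
  qs <- stats::quantile(bt, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  tibble::tibble(kind = "hedges_g", value = g,
                 ci_low = qs[[1]], ci_high = qs[[2]], n_boot = n_boot)
}

#' Rank-based effect size r = z / sqrt(N)
#'
#' Effect size of a Mann-Whitney or Wilcoxon z-statistic.
#' @param z z-statistic.
#' @param n Population size.
#' @return A tibble `kind`, `value`.
#' @export
rank_effect_r <- function(z, n) {
  stopifnot(n >= 1)
  tibble::tibble(kind = "rank_r", value = z / sqrt(n))
}

#' Aligned-rank-transform factorial ANOVA (2 x 2 mixed design)
#'
#' Nonparametric factorial analysis of a mixed design with one
#' between-subjects factor (`group`) and one within-subjects factor
#' (`session`): for each effect, responses are aligned (all other effects'
#' cell-mean contributions removed), midranked, and submitted to a
#' repeated-measures ANOVA on the ranks; only the aligned effect's row is
#' retained. This gives a valid nonparametric interaction test, unlike plain
#' rank transformation.
#'
#' @param data Data frame with columns `subject`, `group`, `session`,
#'   `value`; every subject must have both sessions.
#' @return A tibble `effect`, `F`, `df1`, `df2`, `p_value`.
#' @export
art_anova <- function(data) {
  d <- as.data.frame(data)
  need <- c("subject", "group", "session", "value")
  if (!all(need %in% names(d))) stop("need columns subject, group, session, value", call. = FALSE)
  d$group <- factor(d$group); d$session <- factor(d$session)
  d$subject <- factor(d$subject)
  if (nlevels(d$group) != 2 || nlevels(d$session) != 2) {
    stop("art_anova implements the 2 x 2 mixed design", call. = FALSE)
  }
  tab <- table(d$subject, d$session)
  if (any(tab != 1)) stop("every subject needs exactly one value per session", call. = FALSE)

  grand <- mean(d$value)
  mg <- tapply(d$value, d$group, mean)[d$group]
  ms <- tapply(d$value, d$session, mean)[d$session]
  cellkey <- interaction(d$group, d$session)
  mc <- tapply(d$value, cellkey, mean)[cellkey]
  resid <- d$value - mc

  effects <- list(
    group = as.numeric(mg - grand),
    session = as.numeric(ms - grand),
    `group:session` = as.numeric(mc - mg - ms + grand)
  )
  rows <- lapply(names(effects), function(eff) {
    aligned <- resid + effects[[eff]]
    r <- rank(aligned)
    dd <- d; dd$r <- r
    fit <- stats::aov(r ~ group * session + Error(subject), data = dd)
    s <- summary(fit)
    # between-subject stratum holds `group`; within holds session and interaction
    find_row <- function(su, term) {
      for (stratum in su) {
        tb <- stratum[[1]]
        rn <- trimws(rownames(tb))
        hit <- which(rn == term)
        if (length(hit)) {
          err <- which(rn == "Residuals")
          return(list(F = tb[hit, "F value"], df1 = tb[hit, "Df"],
                      df2 = tb[err, "Df"], p = tb[hit, "Pr(>F)"]))
        }
      }
      NULL
    }
    res <- find_row(s, eff)
    tibble::tibble(effect = eff, F = res$F, df1 = res$df1, df2 = res$df2,
                   p_value = res$p)
  })
  dplyr::bind_rows(rows)
}

#' Continuity-corrected chi-square comparison of two proportions
#'
#' 2 x 2 chi-square test with Yates correction (df = 1).
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return A tibble `statistic`, `df`, `p_value`, `prop1`, `prop2`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    stop("degenerate margin: proportion test undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, prop1 = k1 / n1, prop2 = k2 / n2)
}
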