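chain_adjacency <- function(m) {
  adjacency_graph(lapply(seq_len(m), function(i) {
    intersect(c(i - 1L, i + 1L), seq_len(m))
  }), "chain")
}

test_that("cluster permutation p-values match exhaustive enumeration exactly", {
  set.seed(31)
  # 4 + 4 subjects, 3 elements in a chain; group A elevated on elements 1-2
  A <- cbind(rnorm(4, 3), rnorm(4, 3), rnorm(4, 0))
  B <- cbind(rnorm(4, 0), rnorm(4, 0), rnorm(4, 0))
  res <- cluster_perm(A, B, chain_adjacency(3), "welch_t", exhaustive = TRUE)
  expect_gt(nrow(res), 0)

  # independent brute-force oracle over all C(8,4) = 70 relabelings
  pool <- rbind(A, B)
  oracle_stats <- function(ia) {
    vapply(1:3, function(j) {
      tt <- t.test(pool[ia, j], pool[-ia, j])
      c(tt$statistic, tt$p.value)
    }, numeric(2))
  }
  oracle_clusters <- function(st) {
    out <- list()
    for (sgn in c(1, -1)) {
      mask <- st[2, ] < 0.05 & sign(st[1, ]) == sgn
      runs <- rle(mask)
      pos <- cumsum(c(1, runs$lengths))
      for (k in seq_along(runs$values)) {
        if (runs$values[k]) out[[length(out) + 1]] <- pos[k]:(pos[k + 1] - 1)
      }
    }
    out
  }
  combos <- combn(8, 4)
  null_max <- apply(combos, 2, function(ia) {
    st <- oracle_stats(ia)
    cl <- oracle_clusters(st)
    if (!length(cl)) 0 else max(vapply(cl, function(m) abs(sum(st[1, m])), 0))
  })
  obs <- oracle_stats(1:4)
  ocl <- oracle_clusters(obs)
  expect_equal(length(ocl), nrow(res))
  for (k in seq_along(ocl)) {
    expect_equal(sort(res$members[[k]]), sort(ocl[[k]]))
    expect_equal(res$mass[k], sum(obs[1, ocl[[k]]]), tolerance = 1e-9)
    expect_equal(res$p_value[k],
                 mean(null_max >= abs(sum(obs[1, ocl[[k]]])) - 1e-12))
  }
})

test_that("paired cluster permutation uses the dependent t and sign flips", {
  set.seed(32)
  base <- matrix(rnorm(6 * 3), 6, 3)
  A <- base + cbind(rnorm(6, 2, 0.5), rnorm(6, 2, 0.5), rnorm(6, 0, 0.5))
  res <- cluster_perm(A, base, chain_adjacency(3), "welch_t", paired = TRUE,
                      exhaustive = TRUE)
  expect_gt(nrow(res), 0)
  big <- res[which.max(abs(res$mass)), ]
  expect_true(all(big$members[[1]] %in% 1:2))
  expect_lt(big$p_value, 0.1) # floor 4/64 with 6 paired subjects
  # observed first-step statistic equals the classical dependent t
  st <- attr(res, "elementwise")
  expect_equal(unname(st$stat[1]),
               unname(t.test(A[, 1], base[, 1], paired = TRUE)$statistic),
               tolerance = 1e-9)
})

test_that("cluster p-values shrink monotonically with planted amplitude", {
  lay <- make_layout(32, "spherical-cap", "delaunay")
  adj <- channel_adjacency(lay)
  target <- which(lay$adjacency[1, ])[1:3]
  target <- unique(c(1L, target))
  set.seed(33)
  noise_a <- matrix(rnorm(10 * 32), 10, 32)
  noise_b <- matrix(rnorm(10 * 32), 10, 32)
  ps <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(amp) {
    A <- noise_a; A[, target] <- A[, target] + amp
    res <- cluster_perm(A, noise_b, adj, "welch_t", n_perm = 300, seed = 5)
    if (nrow(res)) min(res$p_value) else 1
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_lt(ps[5], 0.05)
})

test_that("planted broad effects are recovered as one cluster covering them", {
  lay <- make_layout(32, "grid", "k-nearest", k = 4)
  adj <- channel_adjacency(lay)
  target <- 1:10 # grid order: contiguous block
  set.seed(34)
  A <- matrix(rnorm(10 * 32), 10, 32); A[, target] <- A[, target] + 3
  B <- matrix(rnorm(10 * 32), 10, 32)
  res <- cluster_perm(A, B, adj, "welch_t", n_perm = 500, seed = 9)
  sig <- res[res$p_value < 0.05 & res$sign > 0, ]
  expect_gte(nrow(sig), 1)
  covered <- unique(unlist(sig$members))
  expect_gte(length(intersect(covered, target)), 8)
})

test_that("pair adjacency matches hand enumeration on a 4-channel ring", {
  lay <- make_layout(4, "ring", "k-nearest", k = 2)
  g <- pair_adjacency(lay)
  pairs <- attr(g, "pairs")
  expect_equal(nrow(pairs), 6)
  key <- apply(pairs, 1, paste, collapse = "-")
  nb_named <- lapply(seq_len(6), function(i) sort(key[g$neighbors[[i]]]))
  names(nb_named) <- key
  # ring edges: 1-2, 2-3, 3-4, 1-4; non-edges: 1-3, 2-4
  # (a,b)~(c,d): share one electrode & others adjacent, or both cross-pairs adjacent
  expect_true("1-3" %in% nb_named[["1-2"]]) # share 1; 2~3 adjacent
  expect_true("2-4" %in% nb_named[["1-2"]]) # share 2; 1~4 adjacent
  expect_true("3-4" %in% nb_named[["1-2"]]) # no shared: 1~4 & 2~3 adjacent
  # symmetry of the relation
  for (i in 1:6) for (j in g$neighbors[[i]]) {
    expect_true(i %in% g$neighbors[[j]])
  }
  # on a 6-ring, pairs with no shared and no neighbouring endpoints are
  # not adjacent
  lay6 <- make_layout(6, "ring", "k-nearest", k = 2)
  g6 <- pair_adjacency(lay6)
  p6 <- attr(g6, "pairs")
  id <- function(a, b) which(p6[, 1] == a & p6[, 2] == b)
  expect_false(id(4, 5) %in% g6$neighbors[[id(1, 2)]])
})

test_that("pair enumeration yields n(n-1)/2 pairs", {
  expect_equal(nrow(electrode_pairs(make_layout(10, "ring", "k-nearest"))), 45)
  expect_equal(nrow(electrode_pairs(5)), 10)
})

test_that("Hedges g matches the closed-form small-sample-corrected value", {
  a <- c(0, 0, 1, 1); b <- c(1, 1, 2, 2)
  g <- hedges_g(a, b, n_boot = 200, seed = 2)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expected <- (mean(a) - mean(b)) / sp * (1 - 3 / (4 * 8 - 9))
  expect_equal(g$value, expected, tolerance = 1e-12)
  expect_lt(g$ci_low, g$ci_high)
  g2 <- hedges_g(b, a, n_boot = 200, seed = 2)
  expect_equal(g2$value, -g$value)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3), n_boot = 50)$value, 0)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("rank effect size r = z / sqrt(N)", {
  expect_equal(rank_effect_r(3, 36)$value, 0.5)
  expect_equal(rank_effect_r(0, 10)$value, 0)
})

test_that("rank z-statistics agree with the classical test implementations", {
  a <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.3)
  b <- c(6.1, 5.9, 7.2, 4.9, 8.8, 7.7)
  z <- mann_whitney_z(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE, exact = FALSE))
  expect_equal(2 * pnorm(-abs(z)), ref$p.value, tolerance = 1e-9)
  expect_lt(z, 0) # a smaller than b
  # signed-rank z vs the exact distribution at n = 6
  d <- c(1.5, 2.2, -0.4, 3.1, 0.9, 1.7)
  zs <- wilcoxon_signed_z(d)
  exact_p <- wilcox.test(d, exact = TRUE)$p.value
  expect_lt(abs(2 * pnorm(-abs(zs)) - exact_p), 0.08)
  expect_gt(zs, 0)
})

test_that("ART ANOVA detects a pure crossover interaction and not the mains", {
  n_sig_int <- 0; n_sig_main <- 0
  for (s in 1:10) {
    set.seed(40 + s)
    n <- 20
    d <- expand.grid(subject = sprintf("s%02d", 1:(2 * n)),
                     session = c("pre", "post"))
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n, "A", "B")
    cross <- ifelse(d$group == "A", 1, -1) * ifelse(d$session == "pre", 1, -1)
    d$value <- cross + rnorm(nrow(d), 0, 0.8)
    res <- art_anova(d)
    if (res$p_value[res$effect == "group:session"] < 0.05) n_sig_int <- n_sig_int + 1
    n_sig_main <- n_sig_main +
      sum(res$p_value[res$effect %in% c("group", "session")] < 0.05)
  }
  expect_gte(n_sig_int, 9)
  expect_lte(n_sig_main, 4) # ~ nominal false-positive rate over 20 main tests
})

test_that("ART ANOVA on constant data reports nothing significant", {
  d <- expand.grid(subject = sprintf("s%d", 1:6), session = c("pre", "post"))
  d$group <- rep(c("A", "B"), each = 3)
  d$value <- 1
  res <- art_anova(d)
  expect_false(any(res$p_value < 0.05, na.rm = TRUE))
})

test_that("proportion comparison reproduces the chi-square convention", {
  res <- compare_proportions(5, 10, 5, 10)
  expect_equal(res$statistic, 0) # identical proportions, Yates floor
  # agrees with stats::prop.test
  ref <- prop.test(c(9, 3), c(14, 11))
  res2 <- compare_proportions(9, 14, 3, 11)
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-12)
  # on tiny tables the corrected chi-square p tracks the exact test
  f <- fisher.test(matrix(c(6, 2, 2, 6), 2))$p.value
  res3 <- compare_proportions(6, 8, 2, 8)
  expect_lt(abs(res3$p_value - f), 0.15)
  expect_error(compare_proportions(0, 5, 0, 5), "margin")
})
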