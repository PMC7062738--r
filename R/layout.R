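#' Build a synthetic sensor layout
#'
#' Constructs an electrode layout with 2-D scalp-projection coordinates, 3-D
#' head-surface coordinates and a symmetric channel adjacency, standing in for
#' a high-density geodesic sensor net at a configurable channel count.
#'
#' @param n_channels Number of electrodes (>= 3).
#' @param geometry Spatial arrangement: `"ring"` (circle), `"grid"` (square
#'   lattice) or `"spherical-cap"` (Fibonacci spiral on the upper cap of a
#'   unit sphere, the closest analogue of a scalp net).
#' @param neighbor_rule How adjacency is derived from the 2-D positions:
#'   `"delaunay"` (edges of the Delaunay triangulation), `"k-nearest"`
#'   (mutualized k-nearest-neighbour graph) or `"radius"` (all pairs closer
#'   than `radius`).
#' @param k Neighbour count for `"k-nearest"`.
#' @param radius Distance threshold for `"radius"`. Defaults to 1.05 times the
#'   largest nearest-neighbour distance so that no channel is isolated.
#' @return An object of class `eeg_layout`: a list with `channel_ids`,
#'   `positions_2d` (n x 2), `positions_3d` (n x 3) and `adjacency`
#'   (symmetric, irreflexive logical matrix).
#' @examples
#' lay <- make_layout(16, "grid", "k-nearest", k = 4)
#' rowSums(lay$adjacency)
#' @export
make_layout <- function(n_channels,
                        geometry = c("spherical-cap", "ring", "grid"),
                        neighbor_rule = c("delaunay", "k-nearest", "radius"),
                        k = 4, radius = NULL) {
  geometry <- match.arg(geometry)
  neighbor_rule <- match.arg(neighbor_rule)
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 3) {
    stop("`n_channels` must be a single number >= 3", call. = FALSE)
  }
  n <- as.integer(n_channels)

  pos <- switch(geometry,
    "ring" = {
      theta <- 2 * pi * (seq_len(n) - 1) / n
      p2 <- cbind(cos(theta), sin(theta))
      list(p2 = p2, p3 = cbind(p2 * sin(pi / 3), cos(pi / 3)))
    },
    "grid" = {
      side <- ceiling(sqrt(n))
      ij <- cbind((seq_len(n) - 1) %% side, (seq_len(n) - 1) %/% side)
      p2 <- scale(ij, scale = FALSE)
      attr(p2, "scaled:center") <- NULL
      r2 <- sqrt(rowSums(p2^2)); rmax <- max(r2, 1e-9)
      # project the flat grid onto the upper hemisphere for 3-D coordinates
      phi <- r2 / rmax * pi / 2.5
      az <- atan2(p2[, 2], p2[, 1])
      list(p2 = p2, p3 = cbind(sin(phi) * cos(az), sin(phi) * sin(az), cos(phi)))
    },
    "spherical-cap" = {
      # Fibonacci spiral over the cap z in [cos(70 deg), 1]
      i <- seq_len(n) - 0.5
      z <- 1 - (1 - cos(70 * pi / 180)) * i / n
      az <- pi * (1 + sqrt(5)) * i
      s <- sqrt(pmax(0, 1 - z^2))
      p3 <- cbind(s * cos(az), s * sin(az), z)
      # azimuthal equidistant projection for the 2-D scalp view
      phi <- acos(pmin(1, z))
      list(p2 = cbind(phi * cos(az), phi * sin(az)), p3 = p3)
    }
  )

  d2 <- as.matrix(stats::dist(pos$p2))
  adj <- switch(neighbor_rule,
    "k-nearest" = {
      kk <- max(1L, min(as.integer(k), n - 1L))
      a <- matrix(FALSE, n, n)
      for (i in seq_len(n)) {
        nb <- order(d2[i, ])[2:(kk + 1L)]
        a[i, nb] <- TRUE
      }
      a | t(a) # symmetrize: neighbourhood is mutual
    },
    "radius" = {
      if (is.null(radius)) {
        nearest <- apply(d2 + diag(Inf, n), 1, min)
        radius <- 1.05 * max(nearest)
      }
      a <- d2 <= radius & d2 > 0
      a | t(a)
    },
    "delaunay" = delaunay_adjacency(pos$p2)
  )
  diag(adj) <- FALSE
  dimnames(adj) <- NULL

  structure(list(
    channel_ids = sprintf("E%03d", seq_len(n)),
    positions_2d = unname(pos$p2),
    positions_3d = unname(pos$p3),
    adjacency = adj
  ), class = "eeg_layout")
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat(sprintf("<eeg_layout> %d channels, %d adjacency edges\n",
              length(x$channel_ids), sum(x$adjacency) / 2))
  invisible(x)
}

# ---- Delaunay triangulation (Bowyer-Watson, 2-D) -------------------------
# No triangulation library ships with the environment, so the incremental
# algorithm is implemented directly; O(n^2), ample for layouts of a few
# hundred electrodes.

delaunay_adjacency <- function(p) {
  n <- nrow(p)
  if (n < 3) stop("need >= 3 points")
  # jitter-free: break exact cocircularity by a deterministic tiny perturbation
  eps <- 1e-9 * max(apply(p, 2, function(v) diff(range(v))), 1)
  set_p <- p + eps * outer(seq_len(n), c(1, 2), function(i, j) sin(i * j * 1.7))

  # super-triangle enclosing all points
  cx <- mean(range(set_p[, 1])); cy <- mean(range(set_p[, 2]))
  r <- max(sqrt((set_p[, 1] - cx)^2 + (set_p[, 2] - cy)^2)) * 10 + 1
  sp <- rbind(c(cx - 2 * r, cy - r), c(cx + 2 * r, cy - r), c(cx, cy + 2 * r))
  pts <- rbind(set_p, sp)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tris <- list(c(s1, s2, s3))
  circ <- list(circumcircle(pts[s1, ], pts[s2, ], pts[s3, ]))

  for (ip in seq_len(n)) {
    px <- pts[ip, 1]; py <- pts[ip, 2]
    bad <- vapply(circ, function(cc) {
      (px - cc[1])^2 + (py - cc[2])^2 <= cc[3]
    }, logical(1))
    # boundary polygon = edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    tris <- tris[!bad]; circ <- circ[!bad]
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    keep <- key %in% names(which(table(key) == 1))
    for (ie in which(keep)) {
      a <- edges[ie, 1]; b <- edges[ie, 2]
      tris[[length(tris) + 1L]] <- c(a, b, ip)
      circ[[length(circ) + 1L]] <- circumcircle(pts[a, ], pts[b, ], pts[ip, ])
    }
  }

  adj <- matrix(FALSE, n, n)
  for (tr in tris) {
    v <- tr[tr <= n]
    if (length(v) >= 2) {
      for (i in seq_along(v)) for (j in seq_along(v)) {
        if (i != j) adj[v[i], v[j]] <- TRUE
      }
    }
  }
  adj
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
  ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
           (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
  uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
           (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}
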