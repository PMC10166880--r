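# Independent oracles and fixture builders. The ray-casting oracle shares no
# code with the package's crossing-number implementation: it shoots a ray at
# a random angle, counts parametric segment intersections, and re-draws the
# angle whenever the ray grazes a vertex or runs parallel to an edge.

# Even-odd membership of points (n x 2) in the closed ring `verts` (m x 2),
# by randomized-angle ray casting.
oracle_pip <- function(points, verts, max_tries = 50L) {
  n <- nrow(points)
  m <- nrow(verts)
  ax <- verts[, 1]; ay <- verts[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  out <- rep(NA, n)
  for (i in seq_len(n)) {
    px <- points[i, 1]; py <- points[i, 2]
    for (try in seq_len(max_tries)) {
      th <- stats::runif(1, 0, 2 * pi)
      dx <- cos(th); dy <- sin(th)
      crossings <- 0L
      ok <- TRUE
      for (e in seq_len(m)) {
        ex <- bx[e] - ax[e]; ey <- by[e] - ay[e]
        denom <- dx * ey - dy * ex
        if (abs(denom) < 1e-12) {
          # parallel: if collinear and overlapping this is ambiguous
          next
        }
        # solve p + t*d == a + s*e
        qx <- ax[e] - px; qy <- ay[e] - py
        t <- (qx * ey - qy * ex) / denom
        s <- (qx * dy - qy * dx) / denom
        if (t > 0 && s >= 0 && s <= 1) {
          if (s < 1e-9 || s > 1 - 1e-9 || t < 1e-9) {
            ok <- FALSE  # grazes a vertex or starts on the edge: re-cast
            break
          }
          crossings <- crossings + 1L
        }
      }
      if (ok) {
        out[i] <- (crossings %% 2L) == 1L
        break
      }
    }
  }
  out
}

# Minimum distance from each point to the polygon boundary, used to exclude
# near-boundary points from oracle comparisons (edge behaviour is a
# convention, not a correctness question).
dist_to_boundary <- function(points, verts) {
  m <- nrow(verts)
  ax <- verts[, 1]; ay <- verts[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  px <- points[, 1]; py <- points[, 2]
  d2 <- rep(Inf, nrow(points))
  for (e in seq_len(m)) {
    ex <- bx[e] - ax[e]; ey <- by[e] - ay[e]
    len2 <- ex^2 + ey^2
    t <- if (len2 == 0) 0 else
      pmin(1, pmax(0, ((px - ax[e]) * ex + (py - ay[e]) * ey) / len2))
    d2 <- pmin(d2, (px - (ax[e] + t * ex))^2 + (py - (ay[e] + t * ey))^2)
  }
  sqrt(d2)
}

# Random polygon with n_v vertices; simple star-shaped when jitter = 0,
# increasingly self-intersecting as the radius jitters and vertex order is
# shuffled.
random_polygon <- function(n_v = 8L, self_intersecting = FALSE) {
  th <- sort(stats::runif(n_v, 0, 2 * pi))
  r <- stats::runif(n_v, 0.5, 2)
  v <- cbind(r * cos(th), r * sin(th))
  if (self_intersecting) {
    v <- v[sample(n_v), ]
  }
  v
}

# Dense by-hand TPM: entry-by-entry double loop over the region, no matrix
# algebra shared with the implementation.
oracle_tpm <- function(counts_dense, mask, gene_col) {
  g_sum <- 0
  total <- 0
  for (i in which(mask)) {
    for (j in seq_len(ncol(counts_dense))) {
      total <- total + counts_dense[i, j]
      if (j == gene_col) g_sum <- g_sum + counts_dense[i, j]
    }
  }
  g_sum / total * 1e6
}

# Best label permutation matching estimated to true component means.
match_components <- function(est_means, true_means) {
  K <- nrow(true_means)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(K))) {
    cost <- sum((est_means[p, , drop = FALSE] - true_means)^2)
    if (cost < best_cost) {
      best_cost <- cost
      best <- p
    }
  }
  best
}

# Small deterministic dataset with hand-set counts for statistics tests.
toy_dataset <- function(counts, ...) {
  CellDataset(counts, ...)
}

unit_square <- function(name = NULL) {
  gate_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), name = name)
}
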