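# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the edge-graph Dijkstra ignores Steiner
# subdivision and straightening, the ICC oracle goes through stats::aov,
# the projection oracle through numerical optimization.

# Upper-bound oracle: shortest path along mesh edges only (no Steiner
# points, no straightening). Always >= the true polyhedral geodesic.
edge_dijkstra_oracle <- function(mesh, vid_from, vid_to) {
  f <- mesh$faces
  e <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
                    f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)]))
  e <- e[e[, 1] < e[, 2], , drop = FALSE]
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  d <- igraph::distances(g, v = vid_from, to = vid_to)
  if (length(vid_from) == 1L && length(vid_to) == 1L) as.numeric(d) else diag(d)
}

nearest_vertex <- function(mesh, p) {
  which.min(colSums((t(mesh$vertices) - as.numeric(p))^2))
}

# Two-way mean squares via stats::aov on the long-format matrix.
aov_icc_oracle <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                  rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  list(consistency = (msr - mse) / (msr + (k - 1) * mse),
       agreement = (msr - mse) /
         (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# Brute-force tolerance agreement: enumerate every subject x column pair.
agreement_oracle <- function(m, tol) {
  hits <- 0L; total <- 0L
  for (i in seq_len(ncol(m) - 1L)) for (j in (i + 1L):ncol(m)) {
    for (s in seq_len(nrow(m))) {
      d <- abs(m[s, i] - m[s, j])
      if (!is.na(d)) {
        total <- total + 1L
        if (d <= tol) hits <- hits + 1L
      }
    }
  }
  100 * hits / total
}

# Closest point on a mesh by per-triangle numerical optimization over
# barycentric coordinates (L-BFGS-B on the simplex).
projection_oracle <- function(mesh, p) {
  p <- as.numeric(p)
  best <- Inf
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    obj <- function(uv) {
      u <- uv[1]; v <- uv[2]
      if (u + v > 1) { w <- u + v; u <- u / w; v <- v / w }
      q <- (1 - u - v) * tri[1, ] + u * tri[2, ] + v * tri[3, ]
      sum((q - p)^2)
    }
    r <- stats::optim(c(1 / 3, 1 / 3), obj, method = "L-BFGS-B",
                      lower = 0, upper = 1)
    if (r$value < best) best <- r$value
  }
  sqrt(best)
}

# A small closed cube mesh built in code (canonical 8-vertex, 12-face PLY
# fixture when written out).
cube_mesh <- function(side = 10) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  colnames(v) <- NULL
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  triangle_mesh(v, f)
}

expect_equal_tol <- function(a, b, tol) testthat::expect_lt(abs(a - b), tol)
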