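#' Build the geodesic graph of a mesh
#'
#' Discretizes the surface metric for shortest-path queries: graph nodes are
#' the mesh vertices plus `n_steiner` evenly spaced Steiner points on every
#' edge; every pair of nodes lying on a common face is joined by an edge
#' weighted with its straight-line length. Dijkstra on this graph gives an
#' upper bound on the true polyhedral geodesic which [geodesic_curve()]
#' tightens by unfolding-based straightening.
#'
#' Building the graph is the expensive step; pass the result to repeated
#' [geodesic_curve()] calls on the same mesh.
#'
#' @param mesh A `naso_mesh`.
#' @param n_steiner Extra points per edge (default 3).
#' @return A `naso_geograph` (list: igraph, node coordinates, node host
#'   edges, face-to-node index).
#' @export
geodesic_graph <- function(mesh, n_steiner = 3) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  # unique undirected edges
  e_all <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e_key <- pmin(e_all[, 1], e_all[, 2]) * (nv + 1) + pmax(e_all[, 1], e_all[, 2])
  keep <- !duplicated(e_key)
  edges <- cbind(pmin(e_all[keep, 1], e_all[keep, 2]),
                 pmax(e_all[keep, 1], e_all[keep, 2]))
  ne <- nrow(edges)
  face_edge <- matrix(match(e_key, e_key[keep]), ncol = 3)  # F x 3

  k <- as.integer(n_steiner)
  if (k > 0) {
    tpar <- seq_len(k) / (k + 1)
    p0 <- v[edges[, 1], , drop = FALSE]
    dvec <- v[edges[, 2], , drop = FALSE] - p0
    st <- do.call(rbind, lapply(tpar, function(t_) p0 + t_ * dvec))
    coords <- rbind(v, st)
    # node ids of steiner points: edge e, level j -> nv + (j-1)*ne + e
    host_edge <- c(rep(NA_integer_, nv), rep(seq_len(ne), times = k))
  } else {
    coords <- v
    host_edge <- rep(NA_integer_, nv)
  }
  nn <- nrow(coords)

  # nodes per face: 3 vertices + k steiner per edge
  npf <- 3L + 3L * k
  face_nodes <- matrix(0L, nrow(f), npf)
  face_nodes[, 1:3] <- f
  if (k > 0)
    for (j in seq_len(k))
      face_nodes[, 3L + (j - 1L) * 3L + 1:3] <-
        nv + (j - 1L) * ne + face_edge
  pair_t <- utils::combn(npf, 2)
  from <- as.vector(face_nodes[, pair_t[1, ]])
  to <- as.vector(face_nodes[, pair_t[2, ]])
  pk <- pmin(from, to) * (nn + 1) + pmax(from, to)
  keep2 <- !duplicated(pk)
  from <- from[keep2]; to <- to[keep2]
  w <- sqrt(rowSums((coords[from, , drop = FALSE] -
                     coords[to, , drop = FALSE])^2))
  g <- igraph::make_graph(rbind(from, to), n = nn, directed = FALSE)
  igraph::E(g)$weight <- w
  structure(list(graph = g, coords = coords, host_edge = host_edge,
                 edges = edges,
                 edge_key = edges[, 1] * (nv + 1) + edges[, 2],
                 face_nodes = face_nodes, mesh = mesh,
                 n_steiner = k, cache = new.env(parent = emptyenv())),
            class = "naso_geograph")
}

#' @export
print.naso_geograph <- function(x, ...) {
  cat(sprintf("<naso_geograph> %d nodes (%d steiner/edge), %d graph edges\n",
              nrow(x$coords), x$n_steiner, igraph::ecount(x$graph)))
  invisible(x)
}

#' Surface curve through ordered waypoints
#'
#' The on-surface curve between consecutive waypoints is the shortest
#' geodesic found in three stages: Dijkstra on the Steiner-subdivision
#' graph (a corridor and upper bound), closed-form unfolding straightening,
#' and a geodesic-shortening flow (midpoint over-relaxation with local
#' re-projection, in C++) whose fixed point no longer depends on the
#' corridor. Segments are solved from both endpoints and the shorter
#' refined result kept, and each is probed for saddle configurations along
#' ridge lines (see `probe_saddles`). The total length is additive over
#' segments; a closed curve adds the last-to-first segment.
#'
#' @param mesh A `naso_mesh`.
#' @param waypoints An m x 3 matrix of ordered control points (m >= 2), or a
#'   `naso_landmarks` subset (rows used in order).
#' @param closed Close the curve back to the first waypoint?
#' @param graph Optional precomputed [geodesic_graph()] of `mesh`.
#' @param n_steiner Steiner points per edge if `graph` is NULL.
#' @param straighten Refine the Dijkstra corridor (closed-form
#'   straightening plus the geodesic-shortening flow; default TRUE).
#' @param probe_saddles Probe sideways basins of each refined segment and
#'   keep the shortest stable geodesic (default TRUE); disable for faster,
#'   slightly less tight curves.
#' @param tol_project Maximum allowed waypoint-to-surface distance in mm
#'   (default 0.5, the scanner-noise scale).
#' @return A `naso_curve`: list with `points` (polyline on the surface),
#'   `length` (mm), `segment_lengths`, `waypoints`, `closed`.
#' @export
geodesic_curve <- function(mesh, waypoints, closed = FALSE, graph = NULL,
                           n_steiner = 3, straighten = TRUE,
                           probe_saddles = TRUE, tol_project = 0.5) {
  wp_ids <- if (inherits(waypoints, "naso_landmarks")) rownames(waypoints)
            else NULL
  wp <- as.matrix(unclass(waypoints))
  if (ncol(wp) != 3L || nrow(wp) < 2L)
    stop("waypoints must be an m x 3 matrix with m >= 2")
  if (is.null(graph)) graph <- geodesic_graph(mesh, n_steiner = n_steiner)

  # project waypoints to the surface
  proj <- lapply(seq_len(nrow(wp)), function(i) project_to_surface(mesh, wp[i, ]))
  pd <- vapply(proj, `[[`, 0, "distance")
  if (any(pd > tol_project))
    stop(sprintf("projection error: waypoint %d is %.3f mm off the surface (tol %.3f)",
                 which.max(pd), max(pd), tol_project))
  wp_on <- do.call(rbind, lapply(proj, `[[`, "point"))
  wp_face <- vapply(proj, `[[`, 0L, "face")

  idx <- seq_len(nrow(wp))
  pairs <- cbind(idx[-length(idx)], idx[-1])
  if (closed) pairs <- rbind(pairs, c(nrow(wp), 1L))

  seg <- vector("list", nrow(pairs))
  for (s in seq_len(nrow(pairs))) {
    i <- pairs[s, 1]; j <- pairs[s, 2]
    seg[[s]] <- geodesic_segment(graph, wp_on[i, ], wp_face[i],
                                 wp_on[j, ], wp_face[j],
                                 straighten = straighten,
                                 probe_saddles = probe_saddles)
  }
  seg_len <- vapply(seg, attr, 0, "length")
  pts <- seg[[1]]
  if (length(seg) > 1)
    for (s in 2:length(seg)) pts <- rbind(pts, seg[[s]][-1, , drop = FALSE])
  structure(list(points = pts, length = sum(seg_len),
                 segment_lengths = seg_len, waypoints = wp_ids,
                 closed = closed),
            class = "naso_curve")
}

#' @export
print.naso_curve <- function(x, ...) {
  cat(sprintf("<naso_curve> length %.4f mm, %d polyline points%s%s\n",
              x$length, nrow(x$points), if (x$closed) ", closed" else "",
              if (is.null(x$waypoints)) "" else
                paste0(" [", paste(x$waypoints, collapse = "-"), "]")))
  invisible(x)
}

# Shortest on-surface path between two projected points. The Dijkstra
# corridor can depend on the search direction when near-equal routes exist;
# both directions are refined and the shorter geodesic kept, which also
# makes the result direction- and mirror-consistent.
geodesic_segment <- function(graph, p1, f1, p2, f2, straighten = TRUE,
                             probe_saddles = TRUE) {
  d12 <- sqrt(sum((p1 - p2)^2))
  if (d12 == 0 || f1 == f2) {
    # same face: straight segment lies on the surface
    out <- rbind(p1, p2)
    attr(out, "length") <- d12
    return(out)
  }
  fwd <- geodesic_segment_dir(graph, p1, f1, p2, f2, straighten)
  rev_ <- geodesic_segment_dir(graph, p2, f2, p1, f1, straighten)
  if (attr(rev_, "length") < attr(fwd, "length")) {
    len <- attr(rev_, "length"); fc <- attr(rev_, "faces")
    fwd <- rev_[rev(seq_len(nrow(rev_))), , drop = FALSE]
    attr(fwd, "length") <- len
    attr(fwd, "faces") <- rev(fc)
  }
  if (straighten && probe_saddles && !is.null(attr(fwd, "faces")))
    fwd <- kick_probe(graph, fwd)
  fwd
}

# A refined path running along a ridge line can be a saddle of the length
# functional: probe both sideways basins with a tangent-normal kick and
# keep the shortest stable geodesic. The kick frame is built from the
# geometry, so the probe is equivariant under rigid motion and mirroring.
kick_probe <- function(graph, pts) {
  faces <- attr(pts, "faces")
  len0 <- attr(pts, "length")
  if (nrow(pts) < 5L || is.null(faces)) return(pts)
  kick <- kick_directions(pts, faces, graph)
  if (is.null(kick)) return(pts)
  adj <- face_adjacency(graph)
  delta <- min(0.08 * len0, 1.5 * mean_edge_length(graph))
  best <- pts
  for (sgn in c(1, -1)) {
    p2 <- unclass(pts)
    idx <- 2:(nrow(pts) - 1L)
    p2[idx, ] <- p2[idx, ] + sgn * delta * kick[idx, , drop = FALSE]
    alt <- smooth_path_cpp(p2, faces - 1L, graph$mesh$vertices,
                           graph$mesh$faces - 1L, adj$ptr, adj$idx,
                           omega = 1.7, maxSweeps = 50000L,
                           tol = max(1e-10, 1e-9 * len0))
    alt_len <- polyline_length(alt$points)
    if (alt_len < attr(best, "length") * (1 - 1e-12)) {
      out <- alt$points
      attr(out, "length") <- alt_len
      attr(out, "faces") <- alt$faces + 1L
      best <- out
    }
  }
  best
}

geodesic_segment_dir <- function(graph, p1, f1, p2, f2, straighten = TRUE) {
  coords <- graph$coords
  att1 <- attach_node(graph, p1, f1)
  att2 <- attach_node(graph, p2, f2)
  if (!is.na(att1$node) && !is.na(att2$node)) {
    sp <- igraph::shortest_paths(graph$graph, from = att1$node, to = att2$node,
                                 output = "vpath")
    vp <- as.integer(sp$vpath[[1]])
    if (length(vp) == 0) stop("no-path error: waypoints on disconnected surface components")
    node_path <- vp
    head_pt <- NULL; tail_pt <- NULL
  } else {
    src <- att1$cand; tgt <- att2$cand
    dmat <- igraph::distances(graph$graph, v = src, to = tgt)
    dsrc <- sqrt(colSums((t(coords[src, , drop = FALSE]) - p1)^2))
    dtgt <- sqrt(colSums((t(coords[tgt, , drop = FALSE]) - p2)^2))
    tot <- dmat + matrix(dsrc, length(src), length(tgt)) +
      matrix(dtgt, length(src), length(tgt), byrow = TRUE)
    if (!any(is.finite(tot))) stop("no-path error: waypoints on disconnected surface components")
    best <- arrayInd(which.min(tot), dim(tot))
    sp <- igraph::shortest_paths(graph$graph, from = src[best[1]],
                                 to = tgt[best[2]], output = "vpath")
    node_path <- as.integer(sp$vpath[[1]])
    head_pt <- p1
    tail_pt <- p2
  }
  pts <- coords[node_path, , drop = FALSE]
  host <- graph$host_edge[node_path]
  maps <- edge_vertex_face_maps(graph)
  nv <- nrow(graph$mesh$vertices)
  face_of <- ifelse(is.na(host), ifelse(node_path <= nv,
                                        maps$vertex_face[pmin(node_path, nv)], 1L),
                    maps$edge_face[ifelse(is.na(host), 1L, host)])
  if (!is.null(head_pt)) { pts <- rbind(head_pt, pts); host <- c(NA, host); face_of <- c(f1, face_of) }
  if (!is.null(tail_pt)) { pts <- rbind(pts, tail_pt); host <- c(host, NA); face_of <- c(face_of, f2) }
  fc <- NULL
  if (straighten && nrow(pts) > 2) {
    r <- refine_path(pts, host, graph, face_of)
    pts <- r$pts
    fc <- r$faces
  }
  # drop consecutive duplicates
  if (nrow(pts) > 1) {
    dd <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2) > 0)
    pts <- pts[dd, , drop = FALSE]
    if (!is.null(fc)) fc <- fc[dd]
  }
  attr(pts, "length") <- polyline_length(pts)
  attr(pts, "faces") <- fc
  pts
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Map a projected point to a graph node (if it coincides with one) or to the
# candidate node set of its containing face.
attach_node <- function(graph, p, face) {
  cand <- graph$face_nodes[face, ]
  d2 <- colSums((t(graph$coords[cand, , drop = FALSE]) - p)^2)
  i <- which.min(d2)
  if (d2[i] < 1e-18) list(node = cand[i], cand = cand)
  else list(node = NA_integer_, cand = cand)
}

# Iterative closed-form straightening ("string pulling"): each interior point
# hosted on a mesh edge is moved to the crossing parameter obtained by
# unfolding its neighbours about that edge; converges to the geodesic
# restricted to the crossed-edge sequence. Over-relaxed Gauss-Seidel
# (omega ~ 1.8) keeps long paths converging in few sweeps.
straighten_path <- function(pts, host, graph, max_sweeps = 3000, tol = 1e-11,
                            omega = 1.8) {
  v <- graph$mesh$vertices
  n <- nrow(pts)
  movable <- which(!is.na(host))
  movable <- movable[movable > 1 & movable < n]
  if (!length(movable)) return(pts)
  e0 <- v[graph$edges[host[movable], 1], , drop = FALSE]
  e1 <- v[graph$edges[host[movable], 2], , drop = FALSE]
  ed <- e1 - e0
  elen <- sqrt(rowSums(ed * ed))
  eu <- ed / elen
  scale <- max(elen)
  # red-black ordering: update alternating interleaved subsets so each
  # vectorized half-sweep uses its neighbours' freshest positions
  groups <- split(seq_along(movable), movable %% 2L)
  update <- function(sel) {
    idx <- movable[sel]
    A <- pts[idx - 1L, , drop = FALSE]
    B <- pts[idx + 1L, , drop = FALSE]
    o <- e0[sel, , drop = FALSE]; u <- eu[sel, , drop = FALSE]
    ra <- A - o; rb <- B - o
    aal <- rowSums(ra * u); bal <- rowSums(rb * u)
    ape <- sqrt(pmax(0, rowSums(ra * ra) - aal^2))
    bpe <- sqrt(pmax(0, rowSums(rb * rb) - bal^2))
    tl <- ifelse(ape + bpe < 1e-14 * scale, (aal + bal) / 2,
                 aal + ape * (bal - aal) / (ape + bpe))
    tl_old <- rowSums((pts[idx, , drop = FALSE] - o) * u)
    tl <- pmin(pmax(tl_old + omega * (tl - tl_old), 0), elen[sel])
    newp <- o + tl * u
    moved <- max((tl - tl_old)^2)
    pts[idx, ] <<- newp
    moved
  }
  for (sweep in seq_len(max_sweeps)) {
    moved <- max(vapply(groups, update, 0))
    if (moved < (tol * scale)^2) break
  }
  pts
}

# Refine a Dijkstra corridor into a geodesic: closed-form straightening
# gives a good initial path quickly; the C++ geodesic-shortening flow
# (midpoint over-relaxation with local re-projection onto the mesh) then
# converges to a discrete geodesic whose length no longer depends on which
# equal-length corridor Dijkstra happened to return.
refine_path <- function(pts, host, graph, face_of, n_points = 64L) {
  pts <- straighten_path(pts, host, graph, max_sweeps = 400, tol = 1e-9)
  adj <- face_adjacency(graph)
  len0 <- polyline_length(pts)
  # fixed-count arc-length resampling: the discretization of every segment
  # is then independent of the Dijkstra corridor it came from (and
  # equivariant under rigid motion, mirroring and scaling)
  rs <- resample_polyline(pts, face_of, n_points)
  flow <- function(p, fo) smooth_path_cpp(p, fo - 1L, graph$mesh$vertices,
                                          graph$mesh$faces - 1L,
                                          adj$ptr, adj$idx,
                                          omega = 1.7, maxSweeps = 50000L,
                                          tol = max(1e-10, 1e-9 * len0))
  out <- flow(rs$pts, rs$face_of)
  list(pts = out$points, faces = out$faces + 1L)
}

# Unit sideways directions (tangent x surface normal) along a path.
kick_directions <- function(pts, face_of, graph) {
  n <- nrow(pts)
  if (n < 3L) return(NULL)
  f <- graph$mesh$faces
  v <- graph$mesh$vertices
  a <- v[f[face_of, 1], , drop = FALSE]
  b <- v[f[face_of, 2], , drop = FALSE]
  c_ <- v[f[face_of, 3], , drop = FALSE]
  nrm <- cross3_rows(b - a, c_ - a)
  tang <- rbind(pts[2, ] - pts[1, ],
                pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
                pts[n, ] - pts[n - 1, ])
  side <- cross3_rows(tang, nrm)
  len <- sqrt(rowSums(side * side))
  len[len < 1e-300] <- 1
  side / len
}

mean_edge_length <- function(graph) {
  if (is.null(graph$cache$medge)) {
    v <- graph$mesh$vertices
    e <- graph$edges
    graph$cache$medge <- mean(sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                                            v[e[, 2], , drop = FALSE])^2)))
  }
  graph$cache$medge
}

# Even arc-length resampling of a polyline; each new point inherits the
# hosting face of the original point preceding it (a starting guess the
# smoothing flow refines by local projection).
resample_polyline <- function(pts, face_of, n_points) {
  n <- nrow(pts)
  if (n < 3L || n >= n_points) return(list(pts = pts, face_of = face_of))
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[n]
  if (total == 0) return(list(pts = pts, face_of = face_of))
  tgt <- seq(0, total, length.out = n_points)
  j <- pmin(findInterval(tgt, cum, rightmost.closed = TRUE), n - 1L)
  w <- (tgt - cum[j]) / pmax(seg[j], 1e-300)
  new_pts <- pts[j, , drop = FALSE] * (1 - w) + pts[j + 1L, , drop = FALSE] * w
  new_pts[1, ] <- pts[1, ]
  new_pts[n_points, ] <- pts[n, ]
  list(pts = new_pts, face_of = face_of[j])
}

vertex_incidence <- function(graph) {
  if (is.null(graph$cache$vf)) {
    f <- graph$mesh$faces
    graph$cache$vf <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  }
  graph$cache$vf
}

# One incident face per mesh edge and per mesh vertex.
edge_vertex_face_maps <- function(graph) {
  if (is.null(graph$cache$maps)) {
    f <- graph$mesh$faces
    nv <- nrow(graph$mesh$vertices)
    e_all <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(e_all[, 1], e_all[, 2]) * (nv + 1) + pmax(e_all[, 1], e_all[, 2])
    fid <- rep(seq_len(nrow(f)), 3)
    first <- !duplicated(key)
    edge_face <- fid[first][match(graph$edge_key, key[first])]
    vertex_face <- integer(nv)
    vertex_face[as.integer(names(vertex_incidence(graph)))] <-
      vapply(vertex_incidence(graph), `[[`, 0L, 1L)
    graph$cache$maps <- list(edge_face = edge_face, vertex_face = vertex_face)
  }
  graph$cache$maps
}

# CSR adjacency: for each face, the faces sharing at least one vertex.
face_adjacency <- function(graph) {
  if (is.null(graph$cache$adj)) {
    vf <- vertex_incidence(graph)
    f <- graph$mesh$faces
    nb <- lapply(seq_len(nrow(f)), function(fi)
      sort(unique(unlist(vf[as.character(f[fi, ])], use.names = FALSE))))
    lens <- lengths(nb)
    graph$cache$adj <- list(ptr = c(0L, cumsum(lens)),
                            idx = unlist(nb, use.names = FALSE) - 1L)
  }
  graph$cache$adj
}

#' Geodesic distance between two surface points
#'
#' @inheritParams geodesic_curve
#' @param p,q 3D points on (or near) the surface.
#' @return Length in mm.
#' @export
geodesic_distance <- function(mesh, p, q, graph = NULL, ...) {
  geodesic_curve(mesh, rbind(as.numeric(p), as.numeric(q)), graph = graph,
                 ...)$length
}
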