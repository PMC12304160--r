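#' Euclidean distance between two 3D points
#'
#' @param p,q Numeric length-3 vectors (mm).
#' @return Distance in mm.
#' @export
euclidean_distance <- function(p, q) {
  stopifnot(all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

#' Perpendicular length from a point to a line
#'
#' Distance from `x` to the infinite line through `a` and `b` (the
#' construction behind effective nasal length, dimple depth and vermillion
#' convexity). The infinite line is used rather than the segment: the foot
#' point may fall slightly outside the chord on infant anatomy.
#'
#' @param x Query point.
#' @param a,b Two distinct points defining the line.
#' @return Distance in mm; 0 iff `x` is collinear with `a`, `b`.
#' @export
perpendicular_length <- function(x, a, b) {
  x <- as.numeric(x); a <- as.numeric(a); b <- as.numeric(b)
  d <- b - a
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("degenerate line: a == b")
  v <- x - a
  cr <- c(v[2] * d[3] - v[3] * d[2],
          v[3] * d[1] - v[1] * d[3],
          v[1] * d[2] - v[2] * d[1])
  sqrt(sum(cr^2)) / nd
}

#' Three-point angle
#'
#' Angle at `vertex` between the rays towards `a` and `b`, in degrees
#' within \[0, 180\] (e.g. the vermillion angle chR-ls-chL).
#'
#' @param a,vertex,b 3D points; `a` and `b` distinct from `vertex`.
#' @return Angle in degrees.
#' @export
three_point_angle <- function(a, vertex, b) {
  u <- as.numeric(a) - as.numeric(vertex)
  v <- as.numeric(b) - as.numeric(vertex)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate angle: ray endpoint coincides with vertex")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Two-directional angle
#'
#' Unsigned angle between two undirected lines, folded into \[0, 90\]
#' degrees (e.g. the columellar angle between the cM-sn direction and the
#' commissure line chR-chL). Folding means a symmetric columella
#' perpendicular to the commissure line reads exactly 90 degrees.
#'
#' @param d1,d2 Nonzero direction vectors.
#' @return Angle in degrees within \[0, 90\].
#' @export
two_direction_angle <- function(d1, d2) {
  d1 <- as.numeric(d1); d2 <- as.numeric(d2)
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  if (n1 == 0 || n2 == 0) stop("degenerate direction: zero vector")
  cosang <- abs(sum(d1 * d2)) / (n1 * n2)
  acos(min(1, cosang)) * 180 / pi
}

#' Construct a plane
#' @param point A point on the plane.
#' @param normal Plane normal (any nonzero vector; stored unit-length).
#' @return A `naso_plane` (list: point, normal).
#' @export
plane3 <- function(point, normal) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("degenerate plane: zero normal")
  structure(list(point = as.numeric(point), normal = normal / nn),
            class = "naso_plane")
}

#' @export
print.naso_plane <- function(x, ...) {
  cat(sprintf("<naso_plane> point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed offset of a point from a plane
#'
#' For the morphological midsagittal plane the sign convention is
#' right = positive (enforced by [midsagittal_plane()]); "more lateral"
#' means larger absolute offset.
#'
#' @param plane A `naso_plane`.
#' @param p 3D point (or n x 3 matrix).
#' @return Signed distance(s) in mm.
#' @export
lateral_offset <- function(plane, p) {
  if (is.matrix(p))
    as.numeric((p - matrix(plane$point, nrow(p), 3, byrow = TRUE)) %*% plane$normal)
  else
    sum((as.numeric(p) - plane$point) * plane$normal)
}

reflect_points <- function(pts, plane) {
  off <- lateral_offset(plane, pts)
  pts - 2 * outer(off, plane$normal)
}

#' Morphological midsagittal plane
#'
#' Plane through nasion (n), subnasale (sn) and pronasale (prn), with the
#' normal oriented so that the right cheilion (chR), when present, has a
#' positive lateral offset.
#'
#' @param lm A `naso_landmarks` containing n, sn, prn (chR used for
#'   orientation when present).
#' @return A `naso_plane`.
#' @export
midsagittal_plane <- function(lm) {
  need <- c("n", "sn", "prn")
  miss <- setdiff(need, rownames(lm))
  if (length(miss)) stop("missing landmark(s) for midsagittal plane: ",
                         paste(miss, collapse = ", "))
  a <- lm_pt(lm, "n"); b <- lm_pt(lm, "sn"); c_ <- lm_pt(lm, "prn")
  u <- b - a; v <- c_ - a
  nrm <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(nrm^2))
  scale <- max(sqrt(sum(u^2)), sqrt(sum(v^2)))
  if (nn <= 1e-12 * scale^2)
    stop("degenerate midsagittal plane: n, sn, prn are collinear")
  pl <- plane3(a, nrm)
  if (lm_has(lm, "chR") && lateral_offset(pl, lm_pt(lm, "chR")) < 0)
    pl$normal <- -pl$normal
  pl
}

#' Project a point onto a mesh surface
#'
#' Nearest point on any triangle of the mesh, found by an exact per-triangle
#' closest-point computation over all faces.
#'
#' @param mesh A `naso_mesh`.
#' @param p 3D point.
#' @return List: `point` (foot point on the surface), `distance` (mm),
#'   `face` (1-based face index).
#' @export
project_to_surface <- function(mesh, p) {
  p <- as.numeric(p)
  cp <- closest_point_triangles(mesh, p)
  i <- which.min(cp$d2)
  list(point = cp$pts[i, ], distance = sqrt(cp$d2[i]), face = i)
}

# Vectorized closest point on each triangle (Ericson's region method).
closest_point_triangles <- function(mesh, p) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  pm <- matrix(p, nrow(f), 3, byrow = TRUE)
  ab <- b - a; ac <- c_ - a; ap <- pm - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp_ <- pm - c_
  d5 <- rowSums(ab * cp_); d6 <- rowSums(ac * cp_)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  res <- a  # default: vertex a
  done <- d1 <= 0 & d2 <= 0
  sel <- !done & d3 >= 0 & d4 <= d3
  res[sel, ] <- b[sel, ]; done <- done | sel
  sel <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(sel)) {
    t_ <- d1[sel] / (d1[sel] - d3[sel])
    res[sel, ] <- a[sel, , drop = FALSE] + t_ * ab[sel, , drop = FALSE]
  }
  done <- done | sel
  sel <- !done & d6 >= 0 & d5 <= d6
  res[sel, ] <- c_[sel, ]; done <- done | sel
  sel <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(sel)) {
    t_ <- d2[sel] / (d2[sel] - d6[sel])
    res[sel, ] <- a[sel, , drop = FALSE] + t_ * ac[sel, , drop = FALSE]
  }
  done <- done | sel
  sel <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(sel)) {
    t_ <- (d4[sel] - d3[sel]) / ((d4[sel] - d3[sel]) + (d5[sel] - d6[sel]))
    res[sel, ] <- b[sel, , drop = FALSE] +
      t_ * (c_[sel, , drop = FALSE] - b[sel, , drop = FALSE])
  }
  done <- done | sel
  if (any(!done)) {
    denom <- va + vb + vc
    vv <- vb / denom; ww <- vc / denom
    sel <- !done
    res[sel, ] <- a[sel, , drop = FALSE] + vv[sel] * ab[sel, , drop = FALSE] +
      ww[sel] * ac[sel, , drop = FALSE]
  }
  list(pts = res, d2 = rowSums((res - pm)^2))
}

#' Apply a rigid motion (or similarity) to points
#'
#' @param pts n x 3 matrix or length-3 vector.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 vector.
#' @param scale Scalar scale factor (default 1: rigid).
#' @return Transformed points, same shape as input.
#' @export
transform_points <- function(pts, rotation = diag(3), translation = c(0, 0, 0),
                             scale = 1) {
  vec <- !is.matrix(pts)
  if (vec) pts <- matrix(pts, 1, 3)
  out <- scale * pts %*% t(rotation) +
    matrix(translation, nrow(pts), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Random rotation matrix
#' @param seed Optional integer seed.
#' @return A 3 x 3 rotation matrix drawn uniformly (QR of Gaussian matrix).
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Apply a transform to a mesh and/or landmark set
#' @param mesh A `naso_mesh` (or NULL).
#' @param lm A `naso_landmarks` (or NULL).
#' @inheritParams transform_points
#' @return List with transformed `mesh` and `landmarks`.
#' @export
transform_scene <- function(mesh = NULL, lm = NULL, rotation = diag(3),
                            translation = c(0, 0, 0), scale = 1) {
  out <- list(mesh = NULL, landmarks = NULL)
  if (!is.null(mesh))
    out$mesh <- triangle_mesh(transform_points(mesh$vertices, rotation,
                                               translation, scale),
                              mesh$faces, mesh$colors)
  if (!is.null(lm)) {
    pts <- transform_points(unclass(lm)[, , drop = FALSE], rotation,
                            translation, scale)
    rownames(pts) <- rownames(lm)
    out$landmarks <- landmark_set(pts, virtual = attr(lm, "virtual"))
  }
  out
}

#' Mirror a mesh across a plane
#' @param mesh A `naso_mesh`.
#' @param plane A `naso_plane`; default x = 0.
#' @return The reflected mesh (face orientation re-flipped).
#' @export
mirror_mesh <- function(mesh, plane = plane3(c(0, 0, 0), c(1, 0, 0))) {
  v <- reflect_points(mesh$vertices, plane)
  triangle_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE], mesh$colors)
}
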