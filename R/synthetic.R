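#' Analytic geodesic fixtures
#'
#' Meshes with closed-form geodesic lengths, used to validate the surface
#' curve engine: a planar grid (geodesic = chord), a sphere (great-circle
#' arc R*theta), an open cylinder (unrolled-plane formula
#' sqrt((R*dtheta)^2 + dz^2)) and a hemispherical "nose" whose rim-to-rim
#' curve over the pole has length pi*R against a chord of 2R.
#'
#' Refinement levels are nested: each level doubles the linear mesh
#' resolution (sphere: one extra icosphere subdivision).
#'
#' @param kind One of "plane", "sphere", "cylinder", "hemisphere-nose".
#' @param size Characteristic size in mm: plane side length (default 50),
#'   sphere/hemisphere radius (default 10), cylinder radius (default 5).
#' @param refine Refinement level 1, 2 or 3 (default 2).
#' @return List: `mesh` (`naso_mesh`), `points` (named matrix of analytic
#'   surface points), `pairs` (data.frame: from, to, chord, geodesic in mm).
#' @export
make_fixture <- function(kind = c("plane", "sphere", "cylinder",
                                  "hemisphere-nose"),
                         size = NULL, refine = 2) {
  kind <- match.arg(kind)
  refine <- as.integer(refine)
  if (refine < 1 || refine > 6) stop("fixture spec error: refine must be in 1..6")
  switch(kind,
         plane = fixture_plane(if (is.null(size)) 50 else size, refine),
         sphere = fixture_sphere(if (is.null(size)) 10 else size, refine),
         cylinder = fixture_cylinder(if (is.null(size)) 5 else size, refine),
         `hemisphere-nose` = fixture_hemisphere(if (is.null(size)) 10 else size,
                                                refine))
}

grid_mesh <- function(xs, ys, zfun, sym_split = FALSE) {
  nx <- length(xs); ny <- length(ys)
  xx <- rep(xs, times = ny); yy <- rep(ys, each = nx)
  zz <- zfun(xx, yy)
  v <- cbind(xx, yy, zz)
  id <- function(i, j) (j - 1L) * nx + i
  fs <- vector("list", (nx - 1L) * (ny - 1L))
  k <- 0L
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    k <- k + 1L
    a <- id(i, j); b <- id(i + 1L, j); c_ <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
    # mirror-symmetric diagonal pattern: flip orientation on the x<0 side
    flip <- sym_split && (xs[i] + xs[i + 1L] < 0)
    fs[[k]] <- if (!flip) rbind(c(a, b, c_), c(a, c_, d))
               else rbind(c(b, c_, d), c(b, d, a))
  }
  triangle_mesh(v, do.call(rbind, fs))
}

fixture_plane <- function(L, refine) {
  n <- 12L * 2L^(refine - 1L)
  xs <- seq(0, L, length.out = n + 1L)
  mesh <- grid_mesh(xs, xs, function(x, y) rep(0, length(x)))
  snap <- function(p) {
    g <- vapply(p, function(q) xs[which.min(abs(xs - q))], 0)
    c(g, 0)
  }
  pts <- rbind(A = snap(c(0.2 * L, 0.25 * L)), B = snap(c(0.75 * L, 0.7 * L)),
               C = snap(c(0.3 * L, 0.8 * L)))
  ch <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  pairs <- data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                      chord = c(ch(1, 2), ch(1, 3), ch(2, 3)))
  pairs$geodesic <- pairs$chord
  list(mesh = mesh, points = pts, pairs = pairs)
}

#' Icosphere mesh
#' @param radius Sphere radius in mm.
#' @param subdivisions Number of 4-to-1 triangle subdivisions of the
#'   icosahedron (each adds one refinement level).
#' @return A `naso_mesh` with all vertices on the sphere.
#' @export
icosphere <- function(radius = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    e_all <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(e_all[, 1], e_all[, 2]) * (nv + 1) + pmax(e_all[, 1], e_all[, 2])
    uk <- !duplicated(key)
    mids <- (v[e_all[uk, 1], , drop = FALSE] + v[e_all[uk, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    mid_id <- nv + match(key, key[uk])
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nrow(f))]
    m23 <- mid_id[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_id[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  triangle_mesh(radius * v, f)
}

fixture_sphere <- function(R, refine) {
  mesh <- icosphere(R, subdivisions = refine + 1L)
  pts <- rbind(P0 = c(R, 0, 0), P90 = c(0, R, 0), P45 = R * c(1, 1, 0) / sqrt(2),
               PN = c(0, 0, R))
  ang <- function(i, j) acos(min(1, sum(pts[i, ] * pts[j, ]) / R^2))
  combs <- utils::combn(rownames(pts), 2)
  pairs <- data.frame(from = combs[1, ], to = combs[2, ])
  th <- mapply(function(a, b) ang(match(a, rownames(pts)), match(b, rownames(pts))),
               pairs$from, pairs$to)
  pairs$chord <- 2 * R * sin(th / 2)
  pairs$geodesic <- R * th
  list(mesh = mesh, points = pts, pairs = pairs)
}

fixture_cylinder <- function(R, refine) {
  h <- 4 * R
  ntheta <- 16L * 2L^(refine - 1L)
  nz <- 12L * 2L^(refine - 1L)
  th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  zs <- seq(0, h, length.out = nz + 1L)
  id <- function(i, j) (j - 1L) * ntheta + i
  v <- cbind(R * cos(rep(th, times = nz + 1L)), R * sin(rep(th, times = nz + 1L)),
             rep(zs, each = ntheta))
  fs <- vector("list", ntheta * nz)
  k <- 0L
  for (j in seq_len(nz)) for (i in seq_len(ntheta)) {
    k <- k + 1L
    i2 <- if (i == ntheta) 1L else i + 1L
    a <- id(i, j); b <- id(i2, j); c_ <- id(i2, j + 1L); d <- id(i, j + 1L)
    fs[[k]] <- rbind(c(a, b, c_), c(a, c_, d))
  }
  mesh <- triangle_mesh(v, do.call(rbind, fs))
  pts <- rbind(A = c(R, 0, h / 4),
               B = c(R * cos(pi / 2), R * sin(pi / 2), 3 * h / 4),
               C = c(R * cos(pi / 4), R * sin(pi / 4), h / 2))
  unroll <- function(p, q) {
    t1 <- atan2(p[2], p[1]); t2 <- atan2(q[2], q[1])
    dth <- abs(t2 - t1); dth <- min(dth, 2 * pi - dth)
    sqrt((R * dth)^2 + (q[3] - p[3])^2)
  }
  combs <- utils::combn(rownames(pts), 2)
  pairs <- data.frame(from = combs[1, ], to = combs[2, ])
  pairs$chord <- apply(combs, 2, function(ft)
    sqrt(sum((pts[ft[1], ] - pts[ft[2], ])^2)))
  pairs$geodesic <- apply(combs, 2, function(ft) unroll(pts[ft[1], ], pts[ft[2], ]))
  list(mesh = mesh, points = pts, pairs = pairs)
}

fixture_hemisphere <- function(R, refine) {
  nphi <- 10L * 2L^(refine - 1L)
  ntheta <- 4L * nphi
  phis <- seq(0, pi / 2, length.out = nphi + 1L)[-1L]  # pole handled apart
  th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  v <- rbind(c(0, 0, R))
  for (p in phis)
    v <- rbind(v, cbind(R * sin(p) * cos(th), R * sin(p) * sin(th),
                        R * cos(p)))
  id <- function(ring, i) 1L + (ring - 1L) * ntheta + ((i - 1L) %% ntheta) + 1L
  fs <- list()
  for (i in seq_len(ntheta))  # pole fan
    fs[[length(fs) + 1L]] <- c(1L, id(1L, i), id(1L, i + 1L))
  for (ring in seq_len(length(phis) - 1L)) for (i in seq_len(ntheta)) {
    a <- id(ring, i); b <- id(ring, i + 1L)
    c_ <- id(ring + 1L, i + 1L); d <- id(ring + 1L, i)
    fs[[length(fs) + 1L]] <- c(a, b, c_)
    fs[[length(fs) + 1L]] <- c(a, c_, d)
  }
  mesh <- triangle_mesh(v, do.call(rbind, fs))
  pts <- rbind(n = c(R, 0, 0), sn = c(-R, 0, 0), prn = c(0, 0, R))
  pairs <- data.frame(from = c("n", "prn", "n"), to = c("prn", "sn", "sn"),
                      chord = c(R * sqrt(2), R * sqrt(2), 2 * R),
                      geodesic = c(pi * R / 2, pi * R / 2, pi * R))
  list(mesh = mesh, points = pts, pairs = pairs)
}

# Template (x, y) positions of the 33 landmarks for the parametric face,
# in mm at scale 1. mab depends on the alar-base type target.
face_template <- function(alar_type = "I") {
  x_mab <- switch(alar_type, I = 6.5, II = 0.8, III = 2.2,
                  stop("face spec error: alar_type must be I, II or III"))
  t <- rbind(
    n = c(0, 18), sn = c(0, 0), prn = c(0, 5.5), cM = c(0, 3.2),
    acbR = c(9.5, 1.2), acbL = c(-9.5, 1.2),
    alR = c(10.5, 3.5), alL = c(-10.5, 3.5),
    cR = c(1.6, 2.8), cL = c(-1.6, 2.8),
    aliR = c(5.0, 2.0), aliL = c(-5.0, 2.0),
    aloR = c(8.0, 2.6), aloL = c(-8.0, 2.6),
    sbalR = c(7.0, -0.6), sbalL = c(-7.0, -0.6),
    mabR = c(x_mab, -0.8), mabL = c(-x_mab, -0.8),
    cbR = c(2.2, -0.8), cbL = c(-2.2, -0.8),
    chR = c(16.5, -16), chL = c(-16.5, -16),
    cphR = c(3.8, -10.2), cphL = c(-3.8, -10.2),
    ls = c(0, -11.5), sto = c(0, -17),
    vmjR = c(3.8, -13), vmjL = c(-3.8, -13), vmjM = c(0, -14),
    prl = c(0, -8.5), sls = c(0, -4.5),
    lvR = c(8, -13.5), lvL = c(-8, -13.5))
  t[landmark_ids(), , drop = FALSE]
}

#' Generate a stylized nasolabial face with ground-truth landmarks
#'
#' Builds a smooth height-field surface (gentle facial dome, superelliptic
#' nose bump, alar and columellar ridges, vermillion lip ridge, philtrum
#' dimple) sampled on a grid whose lines pass through every landmark, so all
#' 33 landmarks are exact mesh vertices lying on the surface. With
#' `asymmetry = 0` the mesh and landmark set are exactly mirror-symmetric
#' about the plane x = 0 (symmetric triangulation pattern included). The
#' generator is stylized rather than photorealistic: the measurement battery
#' needs correct differential geometry, not portraiture.
#'
#' @param scale Global scale factor (1 = infant-sized, mm).
#' @param alar_type Target alar-base type "I", "II" or "III" (controls the
#'   medial alar base position relative to the columella high point: well
#'   lateral of it, medial of it, or coincident with the columella base).
#' @param asymmetry SD in mm of seeded left-side landmark/surface
#'   perturbations; 0 gives an exactly symmetric face.
#' @param noise_sd SD in mm of smooth random surface bumps (symmetrized when
#'   `asymmetry = 0`).
#' @param resolution Target grid spacing in mm (default 1.5).
#' @param nose_height Nose bump height in mm (default 9).
#' @param lip_height Vermillion ridge height in mm (default 3).
#' @param seed Integer seed for the stochastic components.
#' @param mesh Build the mesh? (FALSE returns landmarks/truth only, e.g.
#'   for typing studies that need no surface.)
#' @return List: `mesh`, `landmarks` (`naso_landmarks`), `truth` (list with
#'   `alar_type`, laterality `margin_mm`, and the exact chord distances of
#'   all 29 two-point D-parameters).
#' @export
make_face <- function(scale = 1, alar_type = "I", asymmetry = 0,
                      noise_sd = 0, resolution = 1.5, nose_height = 9,
                      lip_height = 3, seed = NULL, mesh = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- face_template(alar_type)

  # seeded smooth noise bumps (width >= 4 mm keeps the field smooth)
  nb <- 14L
  bumps <- NULL
  if (noise_sd > 0 || asymmetry > 0) {
    bumps <- list(cx = stats::runif(nb, -20, 20), cy = stats::runif(nb, -22, 22),
                  w = stats::runif(nb, 4, 9),
                  a = stats::rnorm(nb, 0, max(noise_sd, 1e-12)),
                  asym_a = stats::rnorm(nb, 0, max(asymmetry, 1e-12)))
  }
  zfun <- function(x, y) {
    z <- 6 * (1 - (x / 40)^2 - (y / 50)^2) +
      nose_height * exp(-(((x / 7)^2 + ((y - 7) / 9)^2)^1.6)) +
      2.0 * exp(-(((abs(x) - 7.5) / 3)^2 + ((y - 1.5) / 3)^2)) +
      1.5 * exp(-((x / 1.2)^2 + ((y - 2.5) / 2.5)^2)) +
      lip_height * exp(-(((y + 13 + 0.008 * x^2) / 2.5)^2)) * exp(-((x / 14)^2)) -
      0.8 * exp(-((x / 2)^2 + ((y + 5) / 3)^2))
    if (!is.null(bumps)) {
      for (i in seq_along(bumps$cx)) {
        g <- function(xx) exp(-(((xx - bumps$cx[i]) / bumps$w[i])^2 +
                                ((y - bumps$cy[i]) / bumps$w[i])^2))
        if (noise_sd > 0) z <- z + bumps$a[i] * (g(x) + g(-x)) / 2
        if (asymmetry > 0) z <- z + bumps$asym_a[i] * g(x)
      }
    }
    z
  }

  # left-side landmark perturbation for asymmetric faces; the alar-typing
  # triplet (mab, c, cb) keeps its lateral (x) template positions so the
  # declared alar-base type remains a generator invariant
  lm_xy <- tpl
  if (asymmetry > 0) {
    left <- grepl("L$", rownames(tpl))
    lm_xy[left, ] <- lm_xy[left, ] +
      matrix(stats::rnorm(2 * sum(left), 0, asymmetry), ncol = 2)
    typing <- c("mabL", "cL", "cbL")
    lm_xy[typing, 1] <- tpl[typing, 1]
    if (alar_type == "III") lm_xy["mabL", ] <- lm_xy["cbL", ]
  }

  xmax <- 22; ymax <- 24
  xs_half <- sort(unique(c(seq(resolution, xmax, by = resolution),
                           round(abs(lm_xy[abs(lm_xy[, 1]) > 1e-9, 1]), 10), xmax)))
  if (asymmetry > 0) {
    xs <- sort(unique(c(-xs_half, 0, xs_half, round(lm_xy[, 1], 10))))
  } else xs <- c(-rev(xs_half), 0, xs_half)
  ys <- sort(unique(c(seq(-ymax, ymax, by = resolution),
                      round(lm_xy[, 2], 10), ymax)))

  lm3 <- cbind(lm_xy, zfun(lm_xy[, 1], lm_xy[, 2]))
  rownames(lm3) <- rownames(tpl)

  m <- NULL
  if (mesh) {
    m <- grid_mesh(xs, ys, zfun, sym_split = TRUE)
    if (scale != 1) m <- triangle_mesh(scale * m$vertices, m$faces)
  }
  lm <- landmark_set(scale * lm3)

  dist_defs <- registry_distance_pairs()
  truth_d <- vapply(names(dist_defs), function(id) {
    p <- dist_defs[[id]]
    euclidean_distance(lm[p[1], ], lm[p[2], ])
  }, 0)
  margin <- abs(lm_xy["mabR", 1]) - abs(lm_xy["cR", 1])
  list(mesh = m, landmarks = lm,
       truth = list(alar_type = alar_type, margin_mm = scale * margin,
                    distances = truth_d))
}

#' Simulate a measurement cohort
#'
#' Generates subjects aged 3 to 9 months with sex, birth weight and
#' parameter values following per-parameter linear growth
#' `value = intercept + slope * age + sex_offset + N(0, sd)`. Default
#' growth truths are calibrated to the packaged reference-table magnitudes
#' (e.g. right vermillion length about 19.8 +/- 2 mm mid-range), so that
#' simulated cohorts are clinically plausible in scale.
#'
#' @param n Number of subjects.
#' @param params Data.frame with columns `param` (registry id), `intercept`
#'   (mm at age 0), `slope` (mm/month), `sd` (residual SD mm), `sex_offset`
#'   (added for males, subtracted for females). Default:
#'   [default_growth_truth()].
#' @param sex_ratio Proportion male (default 13/25).
#' @param age_range Age range in months (default c(3, 9)).
#' @param seed Integer seed; fixed seed gives identical cohorts.
#' @return Data.frame: subject, sex ("M"/"F"), age_months, birth_weight_g,
#'   one column per parameter. Attribute `truth` keeps the generating table.
#' @export
simulate_cohort <- function(n, params = default_growth_truth(),
                            sex_ratio = 13 / 25, age_range = c(3, 9),
                            seed = NULL) {
  if (n < 1) stop("cohort spec error: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sex <- ifelse(stats::runif(n) < sex_ratio, "M", "F")
  age <- stats::runif(n, age_range[1], age_range[2])
  bw <- round(stats::rnorm(n, 3400, 450))
  out <- data.frame(subject = sprintf("S%03d", seq_len(n)), sex = sex,
                    age_months = age, birth_weight_g = bw,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    val <- p$intercept + p$slope * age + ifelse(sex == "M", 1, -1) * p$sex_offset +
      stats::rnorm(n, 0, p$sd)
    out[[p$param]] <- pmax(val, 0.1)  # lengths are positive
  }
  attr(out, "truth") <- params
  out
}

#' Default growth truths for simulation
#'
#' One row per reference-table parameter; intercepts are chosen so the
#' expected value at the mid-range age of 4.6 months matches the packaged
#' observed means, slopes default to 0.3 mm/month and residual SDs to the
#' observed SDs.
#'
#' @return Data.frame with columns param, intercept, slope, sd, sex_offset.
#' @export
default_growth_truth <- function() {
  ref <- load_reference_table()
  data.frame(param = ref$param_id,
             intercept = ref$observed_mean - 0.3 * 4.6,
             slope = 0.3, sd = ref$observed_sd, sex_offset = 0.15,
             stringsAsFactors = FALSE)
}

#' Inject missing values into a cohort table
#'
#' Blanks parameter cells (never the covariates) completely at random
#' (MCAR) or with probability increasing in age (MAR-on-age), emulating the
#' age-dependent dropout pattern of infant scanning.
#'
#' @param cohort Cohort data.frame as from [simulate_cohort()].
#' @param rate Target missingness fraction, 0 <= rate < 1.
#' @param mechanism "MCAR" or "MAR-age".
#' @param seed Integer seed; fixed seed gives an identical mask.
#' @return The cohort with NA holes; the input is not modified.
#' @export
inject_missingness <- function(cohort, rate, mechanism = c("MCAR", "MAR-age"),
                               seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("missingness spec error: rate must be in [0, 1)")
  if (rate == 0) return(cohort)
  if (!is.null(seed)) set.seed(seed)
  pcols <- setdiff(names(cohort), c("subject", "sex", "age_months",
                                    "birth_weight_g"))
  p_row <- if (mechanism == "MCAR") rep(rate, nrow(cohort)) else {
    w <- stats::plogis(0.8 * (cohort$age_months - mean(cohort$age_months)))
    pmin(rate * w / mean(w), 0.95)
  }
  for (cl in pcols) {
    hit <- stats::runif(nrow(cohort)) < p_row
    cohort[[cl]][hit] <- NA_real_
  }
  cohort
}
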