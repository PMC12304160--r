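test_that("planar geodesics equal straight chords", {
  fx <- make_fixture("plane", refine = 2)
  g <- geodesic_graph(fx$mesh)
  # grid-aligned pair: representable exactly
  for (i in seq_len(nrow(fx$pairs))) {
    p <- fx$points[fx$pairs$from[i], ]; q <- fx$points[fx$pairs$to[i], ]
    len <- geodesic_distance(fx$mesh, p, q, graph = g)
    expect_lt(abs(len - fx$pairs$geodesic[i]), 1e-6)
  }
  # random on-grid pairs: never below the chord, within mesh tolerance above
  set.seed(21)
  v <- fx$mesh$vertices
  for (i in 1:5) {
    ids <- sample(nrow(v), 2)
    chord <- euclidean_distance(v[ids[1], ], v[ids[2], ])
    if (chord < 5) next
    len <- geodesic_distance(fx$mesh, v[ids[1], ], v[ids[2], ], graph = g)
    expect_gte(len, chord - 1e-9)
    expect_lt(len, chord * 1.005)
  }
})

test_that("sphere and cylinder geodesics match closed forms within 1%", {
  for (kind in c("sphere", "cylinder", "hemisphere-nose")) {
    fx <- make_fixture(kind, refine = 2)
    g <- geodesic_graph(fx$mesh)
    for (i in seq_len(nrow(fx$pairs))) {
      p <- fx$points[fx$pairs$from[i], ]; q <- fx$points[fx$pairs$to[i], ]
      len <- geodesic_distance(fx$mesh, p, q, graph = g)
      expect_lt(abs(len - fx$pairs$geodesic[i]) / fx$pairs$geodesic[i], 0.01,
                label = paste(kind, fx$pairs$from[i], fx$pairs$to[i]))
    }
  }
})

test_that("geodesic error decreases monotonically with mesh refinement", {
  for (kind in c("sphere", "cylinder")) {
    errs <- vapply(1:3, function(lev) {
      fx <- make_fixture(kind, refine = lev)
      g <- geodesic_graph(fx$mesh)
      max(vapply(seq_len(nrow(fx$pairs)), function(i) {
        len <- geodesic_distance(fx$mesh, fx$points[fx$pairs$from[i], ],
                                 fx$points[fx$pairs$to[i], ], graph = g)
        abs(len - fx$pairs$geodesic[i]) / fx$pairs$geodesic[i]
      }, 0))
    }, 0)
    expect_true(all(diff(errs) < 0), label = paste(kind, toString(errs)))
  }
})

test_that("multi-waypoint curves concatenate additively; closed curves close", {
  fx <- make_fixture("sphere", refine = 2)
  g <- geodesic_graph(fx$mesh)
  A <- fx$points["P0", ]; B <- fx$points["P45", ]; C <- fx$points["P90", ]
  abc <- geodesic_curve(fx$mesh, rbind(A, B, C), graph = g)
  ab <- geodesic_curve(fx$mesh, rbind(A, B), graph = g)
  bc <- geodesic_curve(fx$mesh, rbind(B, C), graph = g)
  expect_equal(abc$length, ab$length + bc$length, tolerance = 1e-12)
  expect_equal(abc$segment_lengths, c(ab$length, bc$length))

  loop <- geodesic_curve(fx$mesh, rbind(A, B, fx$points["PN", ]),
                         closed = TRUE, graph = g)
  expect_true(loop$closed)
  expect_equal(loop$points[1, ], loop$points[nrow(loop$points), ],
               tolerance = 1e-9)
  expect_length(loop$segment_lengths, 3)
})

test_that("curve length always dominates the endpoint chord", {
  fx <- make_fixture("sphere", refine = 1)
  g <- geodesic_graph(fx$mesh)
  set.seed(22)
  v <- fx$mesh$vertices
  for (i in 1:20) {
    ids <- sample(nrow(v), 2)
    chord <- euclidean_distance(v[ids[1], ], v[ids[2], ])
    len <- geodesic_distance(fx$mesh, v[ids[1], ], v[ids[2], ], graph = g)
    expect_gte(len, chord - 1e-9)
  }
})

test_that("edge-graph Dijkstra oracle upper-bounds the geodesic", {
  fx <- make_fixture("sphere", refine = 2)
  g <- geodesic_graph(fx$mesh)
  set.seed(23)
  v <- fx$mesh$vertices
  for (i in 1:15) {
    ids <- sample(nrow(v), 2)
    len <- geodesic_distance(fx$mesh, v[ids[1], ], v[ids[2], ], graph = g)
    oracle <- edge_dijkstra_oracle(fx$mesh, ids[1], ids[2])
    expect_lte(len, oracle + 1e-9)
    # the edge graph overshoots by at most the worst lattice anisotropy
    expect_lt(oracle / max(len, 1e-12), 1.35)
  }
})

test_that("surface curves are invariant under joint rigid motion", {
  fx <- make_fixture("sphere", refine = 2)
  g <- geodesic_graph(fx$mesh)
  p <- fx$points["P0", ]; q <- fx$points["PN", ]
  len0 <- geodesic_distance(fx$mesh, p, q, graph = g)
  set.seed(24)
  for (i in 1:3) {
    R <- random_rotation(); tr <- rnorm(3, 0, 40)
    m2 <- triangle_mesh(transform_points(fx$mesh$vertices, R, tr), fx$mesh$faces)
    len1 <- geodesic_distance(m2, transform_points(p, R, tr),
                              transform_points(q, R, tr))
    expect_lt(abs(len1 - len0), 1e-6)
  }
})

test_that("off-surface waypoints and disconnected surfaces raise errors", {
  fx <- make_fixture("plane", refine = 1)
  g <- geodesic_graph(fx$mesh)
  expect_error(geodesic_curve(fx$mesh, rbind(c(10, 10, 8), c(30, 30, 0)),
                              graph = g, tol_project = 0.5), "projection error")
  # two disjoint triangles
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(100, 0, 0), c(101, 0, 0), c(100, 1, 0))
  m <- triangle_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(geodesic_curve(m, rbind(c(0.2, 0.2, 0), c(100.5, 0.2, 0))),
               "no-path")
})

test_that("curve polyline stays on the mesh surface", {
  fx <- make_fixture("sphere", refine = 2)
  g <- geodesic_graph(fx$mesh)
  cv <- geodesic_curve(fx$mesh, rbind(fx$points["P0", ], fx$points["PN", ]),
                       graph = g)
  offs <- apply(cv$points, 1, function(p)
    project_to_surface(fx$mesh, p)$distance)
  expect_lt(max(offs), 1e-7)
})
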