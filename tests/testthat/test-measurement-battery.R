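test_that("registry enumerates the full battery with correct cardinalities", {
  reg <- registry()
  kinds <- vapply(reg, `[[`, "", "kind")
  expect_length(reg, 84)
  expect_equal(sum(kinds %in% c("distance", "perpendicular")), 32)
  expect_equal(sum(kinds == "surface_curve"), 32)
  expect_equal(sum(kinds %in% c("angle3", "angle2dir")), 2)
  expect_equal(sum(kinds == "index"), 18)
  expect_length(landmark_ids(), 33)

  expect_equal(reg$D1$name, "Nasal height")
  expect_equal(reg$D15$inputs, c("chR", "chL"))
  expect_equal(reg$D4$line, c("n", "sn"))
  expect_equal(reg$D16$point, "sls")
  expect_equal(reg$S6$waypoints, c("cbR", "mabR", "aliR"))
  expect_true(reg$S6$closed)
  expect_equal(reg$A2$vertex, "ls")
  expect_equal(reg$I18$den_rule, "max")
  expect_equal(reg$I17$of, c("I15", "I16"))
  # index formulas reference only measured parameters
  for (id in names(reg)[kinds == "index"])
    expect_true(all(grepl("^[DSI]", c(reg[[id]]$num, reg[[id]]$den, reg[[id]]$of))))

  tab <- registry_table()
  expect_equal(nrow(tab), 84)
  expect_false(anyDuplicated(tab$id) > 0)
})

test_that("distance engine reproduces axis-aligned constructions", {
  lm <- landmark_set(rbind(n = c(0, 20, 0), sn = c(0, 0, 0), prn = c(0, 10, 8),
                           chR = c(20, 0, 0), chL = c(-20, 0, 0),
                           ls = c(0, -8, 0)))
  d <- compute_distances(lm)
  vals <- setNames(d$value, d$id)
  expect_equal(vals[["D1"]], 20)
  expect_equal(vals[["D4"]], 8)  # prn offset perpendicular to the n-sn axis
  expect_equal(vals[["D15"]], 40)
  expect_equal(sum(d$status == "computed"), 6)  # D1 D4 D15 D22 D23 D24
  expect_match(d$reason[d$id == "D2"], "missing")
})

test_that("angle engine matches planar trigonometry", {
  lm <- landmark_set(rbind(chR = c(20, 0, 0), ls = c(0, -8, 0),
                           chL = c(-20, 0, 0), cM = c(0, 5, 0),
                           sn = c(0, 2, 0)))
  a <- compute_angles(lm)
  vals <- setNames(a$value, a$id)
  expect_equal(vals[["A2"]], 2 * atan(20 / 8) * 180 / pi, tolerance = 1e-9)
  expect_equal(vals[["A1"]], 90)  # columella vertical, commissure horizontal
  lm2 <- landmark_set(rbind(chR = c(20, 0, 0), ls = c(5, 0, 0),
                            chL = c(-20, 0, 0)))
  a2 <- compute_angles(lm2)
  expect_equal(a2$value[a2$id == "A2"], 180)
})

test_that("flat limit: on a plane every curve equals its chord", {
  fx <- make_fixture("plane", refine = 1)
  # collinear n / prn / sn down a grid column
  lm <- landmark_set(rbind(n = c(25, 50 * 10 / 12, 0), prn = c(25, 25, 0),
                           sn = c(25, 50 * 2 / 12, 0)))
  b <- compute_battery(fx$mesh, lm)
  vals <- setNames(b$value, b$id)
  expect_equal(vals[["S3"]], vals[["D1"]], tolerance = 1e-9)
  expect_equal(vals[["S1"]] + vals[["S2"]], vals[["S3"]], tolerance = 1e-12)
  expect_equal(vals[["I1"]], 1, tolerance = 1e-9)  # vertical nasal convexity
})

test_that("hemispherical nose: curve over the pole vs rim diameter gives pi/2", {
  fx <- make_fixture("hemisphere-nose", refine = 2)
  lm <- landmark_set(fx$points)
  g <- geodesic_graph(fx$mesh)
  s <- compute_surface_curves(fx$mesh, lm, graph = g)
  d <- compute_distances(lm)
  s3 <- s$value[s$id == "S3"]; d1 <- d$value[d$id == "D1"]
  expect_lt(abs(s3 / d1 - pi / 2) / (pi / 2), 0.01)
})

test_that("composite curves are exactly additive over their segments", {
  f <- make_face(resolution = 2.5)
  g <- geodesic_graph(f$mesh)
  s <- compute_surface_curves(f$mesh, f$landmarks, graph = g)
  vals <- setNames(s$value, s$id)
  expect_equal(vals[["S3"]], vals[["S1"]] + vals[["S2"]], tolerance = 1e-12)
  expect_equal(vals[["S12"]], vals[["S10"]] + vals[["S11"]], tolerance = 1e-12)
})

test_that("missing landmarks propagate as skipped parameters, never errors", {
  f <- make_face(resolution = 3)
  keep <- setdiff(landmark_ids(), c("sto", "vmjR", "vmjL", "vmjM"))
  lm <- landmark_set(unclass(f$landmarks)[keep, ])
  b <- compute_battery(f$mesh, lm)
  reg <- registry()
  dropped <- c("sto", "vmjR", "vmjL", "vmjM")
  for (id in b$id[b$kind %in% c("distance", "perpendicular", "surface_curve")]) {
    needs_dropped <- length(intersect(reg[[id]]$inputs, dropped)) > 0
    expect_equal(b$status[b$id == id] == "skipped-missing-input", needs_dropped,
                 label = id)
  }
  # indices only present when every input is present
  expect_equal(b$status[b$id == "I11"], "skipped-missing-input")  # needs S18/D21
  expect_equal(b$status[b$id == "I1"], "computed")
})

test_that("zero denominators flag indices as undefined, not NaN", {
  f <- make_face(resolution = 3)
  b <- compute_battery(f$mesh, f$landmarks)
  tweaked <- as.data.frame(b)
  tweaked$value[tweaked$id == "D1"] <- 0
  i <- compute_indices(naso3d:::as_battery(tweaked))
  expect_equal(i$status[i$id == "I1"], "undefined-index")
  expect_true(is.na(i$value[i$id == "I1"]))
})

test_that("symmetric face: equal R/L pairs and unit symmetry indices", {
  f <- make_face()
  b <- compute_battery(f$mesh, f$landmarks)
  vals <- setNames(b$value, b$id)
  dpairs <- rbind(c("D5", "D6"), c("D7", "D8"), c("D10", "D11"),
                  c("D12", "D13"), c("D17", "D18"), c("D23", "D24"),
                  c("D29", "D30"), c("D31", "D32"))
  for (r in seq_len(nrow(dpairs)))
    expect_lt(abs(vals[dpairs[r, 1]] - vals[dpairs[r, 2]]), 1e-9)
  spairs <- rbind(c("S4", "S5"), c("S6", "S7"), c("S8", "S9"),
                  c("S10", "S11"), c("S25", "S26"), c("S31", "S32"))
  for (r in seq_len(nrow(spairs)))
    expect_lt(abs(vals[spairs[r, 1]] - vals[spairs[r, 2]]), 1e-9)
  for (id in c("I8", "I15", "I16", "I17"))
    expect_lt(abs(vals[id] - 1), 1e-6)
})

test_that("mirroring the scene swaps R/L values and inverts symmetry ratios", {
  f <- make_face(asymmetry = 0.5, noise_sd = 0.3, seed = 31, resolution = 2.5)
  b0 <- compute_battery(f$mesh, f$landmarks)
  v0 <- setNames(b0$value, b0$id)
  mm <- mirror_mesh(f$mesh)
  ml <- mirror_landmarks(f$landmarks)
  b1 <- compute_battery(mm, ml)
  v1 <- setNames(b1$value, b1$id)
  reg <- registry()
  for (id in names(reg)) {
    if (!reg[[id]]$kind %in% c("distance", "perpendicular", "surface_curve"))
      next
    partner <- names(reg)[vapply(names(reg), function(j)
      reg[[j]]$kind == reg[[id]]$kind &&
        identical(sort(naso3d:::swap_side_ids(reg[[id]]$inputs)),
                  sort(reg[[j]]$inputs)), TRUE)][1]
    expect_lt(abs(v1[id] - v0[partner]) / max(v0[partner], 1e-9), 1e-9,
              label = paste(id, "vs", partner))
  }
  expect_equal(v1[["I15"]], 1 / v0[["I15"]], tolerance = 1e-12)
  expect_equal(v1[["I16"]], 1 / v0[["I16"]], tolerance = 1e-12)
  expect_equal(v1[["I8"]], 1 / v0[["I8"]], tolerance = 1e-9)
})

test_that("uniform scaling scales lengths and leaves angles and indices fixed", {
  f <- make_face(resolution = 2.5)
  b0 <- compute_battery(f$mesh, f$landmarks)
  k <- 2.5
  sc <- transform_scene(f$mesh, f$landmarks, scale = k)
  b1 <- compute_battery(sc$mesh, sc$landmarks)
  v0 <- setNames(b0$value, b0$id); v1 <- setNames(b1$value, b1$id)
  len_ids <- b0$id[b0$units == "mm"]
  expect_lt(max(abs(v1[len_ids] - k * v0[len_ids]) / (k * v0[len_ids])), 1e-6)
  expect_lt(max(abs(v1[c("A1", "A2")] - v0[c("A1", "A2")])), 1e-6)
  idx <- b0$id[b0$kind == "index"]
  expect_lt(max(abs(v1[idx] - v0[idx])), 1e-6)
})

test_that("constructive landmark derivation finds extremal points and reports QC", {
  # hemispherical nose: the curve over the pole is everywhere radius R from
  # the rim diameter; the derived pronasale must sit at that height
  fx <- make_fixture("hemisphere-nose", refine = 2)
  lm <- landmark_set(fx$points[c("n", "sn"), ])
  d <- derive_constructive_landmarks(fx$mesh, lm)
  expect_true("prn" %in% rownames(d$landmarks))
  h <- perpendicular_length(d$landmarks["prn", ], lm["n", ], lm["sn", ])
  expect_lt(abs(h - 10) / 10, 0.01)

  # flat philtrum: no dimple to find
  pl <- make_fixture("plane", refine = 1)
  lm2 <- landmark_set(rbind(sn = c(25, 37.5, 0), prl = c(25, 12.5, 0)))
  d2 <- derive_constructive_landmarks(pl$mesh, lm2)
  expect_match(d2$qc$note[d2$qc$id == "sls"], "no dimple")

  # full face: all five derivable points, discrepancies reported in mm
  f <- make_face(resolution = 2.5)
  d3 <- derive_constructive_landmarks(f$mesh, f$landmarks)
  expect_setequal(d3$qc$id, c("prn", "sls", "lvR", "lvL", "cM"))
  expect_true(all(is.finite(d3$qc$user_discrepancy_mm)))
})
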