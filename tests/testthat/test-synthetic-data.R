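test_that("fixture tables carry correct closed-form lengths", {
  sph <- make_fixture("sphere", refine = 1)
  R <- 10
  for (i in seq_len(nrow(sph$pairs))) {
    p <- sph$points[sph$pairs$from[i], ]; q <- sph$points[sph$pairs$to[i], ]
    th <- acos(min(1, sum(p * q) / R^2))
    expect_equal(sph$pairs$geodesic[i], R * th, tolerance = 1e-12)
    expect_equal(sph$pairs$chord[i], euclidean_distance(p, q), tolerance = 1e-12)
  }
  cyl <- make_fixture("cylinder", refine = 1)
  i <- which(cyl$pairs$from == "A" & cyl$pairs$to == "B")
  expect_equal(cyl$pairs$geodesic[i], sqrt((5 * pi / 2)^2 + 10^2),
               tolerance = 1e-12)
  hemi <- make_fixture("hemisphere-nose", refine = 1)
  expect_equal(hemi$pairs$geodesic[hemi$pairs$to == "sn" &
                                   hemi$pairs$from == "n"], pi * 10)
  expect_error(make_fixture("sphere", refine = 9), "refine")
})

test_that("fixture landmark points lie on (or sag-close to) their meshes", {
  for (kind in c("plane", "sphere", "cylinder", "hemisphere-nose")) {
    fx <- make_fixture(kind, refine = 2)
    offs <- apply(fx$points, 1, function(p)
      project_to_surface(fx$mesh, p)$distance)
    expect_lt(max(offs), 0.1, label = kind)  # within faceting sag
  }
})

test_that("symmetric faces are exactly mirror-symmetric", {
  f <- make_face()
  lm <- unclass(f$landmarks)
  for (id in grep("R$", rownames(lm), value = TRUE)) {
    lid <- sub("R$", "L", id)
    expect_identical(lm[id, "x"], -lm[lid, "x"], label = id)
    expect_identical(lm[id, c("y", "z")], lm[lid, c("y", "z")], label = id)
  }
  # mesh is its own mirror image: reflected vertex set equals the original
  v <- f$mesh$vertices
  key <- paste(round(-v[, 1], 9), round(v[, 2], 9), round(v[, 3], 9))
  key0 <- paste(round(v[, 1], 9), round(v[, 2], 9), round(v[, 3], 9))
  expect_setequal(key, key0)
})

test_that("all 33 landmarks sit on the generated surface", {
  f <- make_face(asymmetry = 0.4, noise_sd = 0.3, seed = 81, resolution = 2)
  expect_true(is_complete(f$landmarks))
  offs <- apply(unclass(f$landmarks), 1, function(p)
    project_to_surface(f$mesh, p)$distance)
  expect_lt(max(offs), 1e-9)
})

test_that("alar-type targets are built into the landmark geometry", {
  f1 <- make_face(alar_type = "I", mesh = FALSE)
  expect_gt(f1$truth$margin_mm, 0.1)
  f2 <- make_face(alar_type = "II", mesh = FALSE)
  expect_lt(f2$truth$margin_mm, -0.1)
  f3 <- make_face(alar_type = "III", mesh = FALSE)
  expect_identical(unclass(f3$landmarks)["mabR", ],
                   unclass(f3$landmarks)["cbR", ])
  expect_error(make_face(alar_type = "IV"), "alar_type")
})

test_that("generator ground truth matches the measured battery distances", {
  f <- make_face(resolution = 2.5)
  d <- compute_distances(f$landmarks)
  vals <- setNames(d$value, d$id)
  for (id in names(f$truth$distances))
    expect_equal(vals[[id]], f$truth$distances[[id]], tolerance = 1e-12)
})

test_that("generators are pure functions of spec and seed", {
  f1 <- make_face(asymmetry = 0.3, noise_sd = 0.2, seed = 9, resolution = 3)
  f2 <- make_face(asymmetry = 0.3, noise_sd = 0.2, seed = 9, resolution = 3)
  expect_identical(f1$mesh$vertices, f2$mesh$vertices)
  expect_identical(unclass(f1$landmarks), unclass(f2$landmarks))
  c1 <- simulate_cohort(40, seed = 10)
  c2 <- simulate_cohort(40, seed = 10)
  expect_identical(c1, c2)
})

test_that("simulated cohorts follow their growth truths", {
  truth <- data.frame(param = "D23", intercept = 18.4, slope = 0.3, sd = 0,
                      sex_offset = 0.15)
  co <- simulate_cohort(50, params = truth, seed = 91)
  male <- co$sex == "M"
  expect_equal(co$D23[male], 18.4 + 0.3 * co$age_months[male] + 0.15,
               tolerance = 1e-12)
  truth$sd <- 1
  co2 <- simulate_cohort(1000, params = truth, seed = 92)
  fit <- lm(D23 ~ age_months, data = co2[co2$sex == "F", ])
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(coef(fit)[2] - 0.3), 3 * se)
  expect_true(all(co2$age_months >= 3 & co2$age_months <= 9))
  expect_error(simulate_cohort(0), "n must be")
})

test_that("missingness injection honours rate, mechanism and seed", {
  co <- simulate_cohort(250, seed = 93)
  expect_identical(inject_missingness(co, 0), co)
  mis <- inject_missingness(co, 0.2, "MCAR", seed = 94)
  pcols <- setdiff(names(co), c("subject", "sex", "age_months", "birth_weight_g"))
  frac <- mean(is.na(as.matrix(mis[, pcols])))
  ncell <- nrow(co) * length(pcols)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / ncell))
  mis2 <- inject_missingness(co, 0.2, "MCAR", seed = 94)
  expect_identical(mis, mis2)
  expect_error(inject_missingness(co, 1), "rate")
  # MAR-on-age: missingness rises with age
  mar <- inject_missingness(co, 0.3, "MAR-age", seed = 95)
  miss_rate <- rowMeans(is.na(mar[, pcols]))
  expect_gt(cor(co$age_months, miss_rate), 0.2)
  expect_false(anyNA(mar$age_months))
})
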