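line_cohort <- function(n = 20, intercept = 10, slope = 0.8, sd = 0) {
  age <- seq(3, 9, length.out = n)
  data.frame(subject = sprintf("S%02d", 1:n),
             sex = rep(c("M", "F"), length.out = n),
             age_months = age, birth_weight_g = 3400,
             D23 = intercept + slope * age + rnorm(n, 0, sd))
}

test_that("growth model recovers a noiseless line exactly", {
  co <- line_cohort()
  for (s in c("M", "F")) {
    m <- fit_growth_model(co, "D23", s)
    expect_equal(unname(coef(m)), c(10, 0.8), tolerance = 1e-9)
    expect_equal(m$residual_sd, 0, tolerance = 1e-9)
    expect_equal(as.numeric(predict(m, 5)), 14, tolerance = 1e-9)
  }
  expect_error(fit_growth_model(co[1, ], "D23", "M"), "n = ")
})

test_that("growth model is unbiased on noisy cohorts (3 SE)", {
  truth <- data.frame(param = "D23", intercept = 18.4, slope = 0.3, sd = 0.5,
                      sex_offset = 0)
  co <- simulate_cohort(200, params = truth, seed = 51)
  m <- fit_growth_model(co, "D23", "M")
  se <- sqrt(diag(vcov(m$fit)))[2]
  expect_lt(abs(coef(m)[2] - 0.3), 3 * se)
  # least-squares identity: prediction at the mean age equals the mean value
  sub <- co[co$sex == "M", ]
  expect_equal(as.numeric(predict(m, mean(sub$age_months))), mean(sub$D23),
               tolerance = 1e-9)
})

test_that("prediction flags extrapolation and rejects negative ages", {
  co <- line_cohort()
  m <- fit_growth_model(co, "D23", "M")
  p <- predict(m, c(5, 12))
  expect_equal(attr(p, "extrapolated"), c(FALSE, TRUE))
  expect_error(predict(m, -1), "age")
  expect_equal(predict_value(m, 5), predict(m, 5))
})

test_that("z-scores are centred and scaled by the residual SD", {
  set.seed(52)
  co <- line_cohort(n = 200, sd = 0.5)
  m <- fit_growth_model(co, "D23", "M")
  expect_equal(zscore(m, as.numeric(predict(m, 6)), 6), 0)
  expect_equal(zscore(m, as.numeric(predict(m, 6)) + 2 * m$residual_sd, 6), 2)
  m0 <- fit_growth_model(line_cohort(sd = 0), "D23", "M")
  expect_warning(z <- zscore(m0, 14, 5), "zero")
  expect_true(is.na(z))
  # calibration: z of fresh draws from the model ~ N(0, 1)
  co2 <- line_cohort(n = 400, sd = 0.5)
  z <- zscore(m, co2$D23[co2$sex == "M"], co2$age_months[co2$sex == "M"])
  expect_lt(abs(mean(z)), 0.25)   # sampling + model-fit error
  expect_lt(abs(sd(z) - 1), 0.25)
})

test_that("ICC consistency vs agreement: identical and shifted raters", {
  m <- cbind(a = c(10, 12, 14, 16, 18), b = c(10, 12, 14, 16, 18))
  expect_equal(icc_consistency(m), 1)
  expect_equal(icc_agreement(m), 1)
  shifted <- cbind(a = m[, 1], b = m[, 1] + 0.5)
  expect_equal(icc_consistency(shifted), 1)
  expect_lt(icc_agreement(shifted), 1)
  expect_lt(icc_agreement(shifted), icc_consistency(shifted))
  flat <- matrix(5, 4, 3)
  expect_warning(expect_true(is.na(icc_consistency(flat))), "degenerate")
})

test_that("ICCs match the ANOVA mean-squares oracle to 1e-9", {
  set.seed(53)
  for (i in 1:5) {
    n <- sample(5:9, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 15, 2), n, k) +
      matrix(rnorm(k, 0, 0.5), n, k, byrow = TRUE)
    o <- aov_icc_oracle(m)
    expect_lt(abs(icc_consistency(m) - o$consistency), 1e-9)
    expect_lt(abs(icc_agreement(m) - o$agreement), 1e-9)
  }
})

test_that("ICC interpretation bands honour the published cut-points", {
  expect_equal(interpret_icc(0.39), "poor")
  expect_equal(interpret_icc(0.40), "substantial")
  expect_equal(interpret_icc(0.75), "substantial")
  expect_equal(interpret_icc(0.76), "excellent")
  expect_equal(interpret_icc(c(-0.2, 0.5, 0.99)),
               c("poor", "substantial", "excellent"))
  expect_error(interpret_icc(1.2), "exceed")
})

test_that("percentage agreement matches brute-force pair enumeration", {
  m <- cbind(c(10, 12, 14), c(10, 12, 14))
  expect_equal(percent_agreement(m, 1), 100)
  m2 <- cbind(c(10, 12, 14), c(12, 14, 16))
  expect_equal(percent_agreement(m2, 1), 0)
  set.seed(54)
  m3 <- matrix(rnorm(18, 15, 1), 6, 3)
  expect_equal(percent_agreement(m3, 1), agreement_oracle(m3, 1))
  expect_equal(percent_agreement(m3, 0.3), agreement_oracle(m3, 0.3))
})

test_that("pearson r: exact lines and covariance-formula agreement", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(55)
  a <- rnorm(30); b <- rnorm(30)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_lt(abs(pearson_r(a, b) - oracle), 1e-12)
  expect_warning(expect_true(is.na(pearson_r(x, rep(3, 5)))), "variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("PMM imputation: identity, donor property, calibration, determinism", {
  co <- simulate_cohort(120, seed = 61)
  # complete data: returned unchanged
  imp0 <- impute_pmm(co, m = 2, seed = 1)
  expect_identical(imp0$imputations[[1]], co)

  mis <- inject_missingness(co, 0.2, "MAR-age", seed = 62)
  imp <- impute_pmm(mis, m = 5, k = 5, maxit = 5, seed = 63)
  expect_length(imp$imputations, 5)
  pcols <- setdiff(names(co), c("subject", "sex", "age_months", "birth_weight_g"))
  for (d in imp$imputations) {
    expect_false(anyNA(d[, pcols]))
    for (cl in pcols) {
      holes <- is.na(mis[[cl]])
      if (!any(holes)) next
      # every imputed value is an observed value of its own column
      expect_true(all(d[[cl]][holes] %in% mis[[cl]][!holes]), label = cl)
      # observed cells preserved bit-exactly
      expect_identical(d[[cl]][!holes], mis[[cl]][!holes])
    }
  }
  # completed means close to the complete-data means
  pm <- pool_means(imp)
  for (cl in pcols) {
    se <- sd(co[[cl]]) / sqrt(nrow(co))
    expect_lt(abs(pm[cl] - mean(co[[cl]])), 3 * se, label = cl)
  }
  # fixed seed: bit-reproducible
  imp2 <- impute_pmm(mis, m = 5, k = 5, maxit = 5, seed = 63)
  expect_identical(imp$imputations, imp2$imputations)

  # too few donors
  tiny <- mis[1:6, ]
  tiny$D23[1:5] <- NA
  expect_error(impute_pmm(tiny, k = 5, seed = 1), "donors")
})

test_that("cohort tables validate and round-trip through CSV", {
  co <- simulate_cohort(15, seed = 71)
  co$D23[3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- load_cohort(path)
  expect_equal(co2$D23, co$D23)
  expect_true(is.na(co2$D23[3]))

  bad <- co; bad$sex[1] <- "x"
  expect_error(naso3d:::validate_cohort(bad), "sex")
  bad2 <- co; names(bad2)[5] <- "Q99"
  expect_error(naso3d:::validate_cohort(bad2), "Q99")
  expect_equal(age_months(4, 18), 4.6)
})
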