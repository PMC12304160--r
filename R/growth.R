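#' Read / write cohort tables
#'
#' Cohort CSV: columns subject, sex (M/F), age_months (decimal months with
#' the 30-day-month convention), birth_weight_g, one column per battery
#' parameter; empty cell = missing.
#'
#' @param path CSV path.
#' @return Validated cohort data.frame.
#' @export
load_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(tab)
}

#' @rdname load_cohort
#' @param cohort Cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_cohort <- function(tab) {
  need <- c("subject", "sex", "age_months")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(tab$sex %in% c("M", "F")))
    stop("cohort sex must be 'M' or 'F'")
  if (any(tab$age_months < 0, na.rm = TRUE)) stop("cohort age must be >= 0")
  pcols <- cohort_param_cols(tab)
  bad <- setdiff(pcols, names(registry()))
  if (length(bad)) stop("unknown parameter column(s): ",
                        paste(bad, collapse = ", "))
  tab
}

cohort_param_cols <- function(tab)
  setdiff(names(tab), c("subject", "sex", "age_months", "birth_weight_g"))

#' Convert an age in months and days to decimal months
#'
#' Uses the 30-day-month convention: age = months + days/30.
#'
#' @param months Completed months.
#' @param days Additional days.
#' @return Decimal age in months.
#' @export
age_months <- function(months, days = 0) months + days / 30

#' Fit a per-parameter, per-sex growth model
#'
#' Least-squares polynomial regression (default linear) of a parameter on
#' age in months, fitted separately by sex as in reference growth charts
#' (female and male curves drawn separately). The residual SD feeds
#' [zscore()]; predictions outside the fitted age range are flagged as
#' extrapolation.
#'
#' @param cohort Cohort data.frame (see [load_cohort()]).
#' @param param Registry parameter id (a column of `cohort`).
#' @param sex "M" or "F".
#' @param degree Polynomial degree in age (default 1).
#' @return A `naso_growth` model object.
#' @export
fit_growth_model <- function(cohort, param, sex, degree = 1) {
  cohort <- validate_cohort(cohort)
  if (!param %in% names(cohort)) stop("parameter column not in cohort: ", param)
  sub <- cohort[cohort$sex == sex & !is.na(cohort[[param]]), ]
  n <- nrow(sub)
  if (n < 3L) stop(sprintf("insufficient data for %s/%s: n = %d (need >= 3)",
                           param, sex, n))
  fit <- stats::lm(sub[[param]] ~ poly(age_months, degree, raw = TRUE),
                   data = sub)
  p <- degree + 1L
  sigma <- if (n > p) sqrt(sum(stats::residuals(fit)^2) / (n - p)) else 0
  # an exact fit leaves only float-noise residuals; report a true zero
  if (sigma < 1e-10 * max(abs(sub[[param]]))) sigma <- 0
  structure(list(param = param, sex = sex, degree = degree,
                 coefficients = stats::setNames(as.numeric(stats::coef(fit)),
                                                paste0("age^", 0:degree)),
                 residual_sd = sigma, n = n,
                 age_range = range(sub$age_months), fit = fit),
            class = "naso_growth")
}

#' @export
print.naso_growth <- function(x, ...) {
  cat(sprintf("<naso_growth> %s, sex %s, n = %d\n", x$param, x$sex, x$n))
  eq <- paste(sprintf("%.4g", x$coefficients),
              c("", sprintf("*age^%d", seq_len(x$degree))), sep = "",
              collapse = " + ")
  cat("  value [mm] =", eq, "\n")
  cat(sprintf("  residual SD %.3f mm, fitted ages %.1f..%.1f months\n",
              x$residual_sd, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' @export
coef.naso_growth <- function(object, ...) object$coefficients

#' @export
residuals.naso_growth <- function(object, ...) stats::residuals(object$fit)

#' Predict the expected value at an age
#'
#' @param object A `naso_growth` model.
#' @param age Age(s) in decimal months (>= 0).
#' @param ... Unused.
#' @return Predicted value(s) in mm, with attribute `extrapolated`
#'   (logical per age) set outside the fitted 3-9 month range.
#' @export
predict.naso_growth <- function(object, age, ...) {
  if (any(age < 0)) stop("domain error: age must be >= 0")
  X <- outer(age, 0:object$degree, `^`)
  out <- as.numeric(X %*% object$coefficients)
  attr(out, "extrapolated") <- age < object$age_range[1] |
    age > object$age_range[2]
  out
}

#' @rdname predict.naso_growth
#' @param model A `naso_growth` model.
#' @export
predict_value <- function(model, age) predict(model, age)

#' Z-score of an observation against a growth model
#'
#' (observed - predicted at age) / residual SD.
#'
#' @param model A `naso_growth` model.
#' @param observed Observed value in mm.
#' @param age Age in decimal months.
#' @return Dimensionless z-score(s); NA with a warning when the model has
#'   zero residual SD.
#' @export
zscore <- function(model, observed, age) {
  if (model$residual_sd <= 0) {
    warning("undefined z-score: residual SD is zero")
    return(NA_real_ * observed)
  }
  pred <- predict(model, age)
  as.numeric((observed - pred) / model$residual_sd)
}

#' Fit growth models for every parameter and sex
#'
#' @param cohort Cohort data.frame.
#' @param params Parameter columns (default: all in the cohort).
#' @param degree Polynomial degree.
#' @return Data.frame: param, sex, one column per coefficient,
#'   residual_sd, n — the serializable reference-model table.
#' @export
fit_growth_models <- function(cohort, params = cohort_param_cols(cohort),
                              degree = 1) {
  rows <- list()
  for (p in params) for (s in c("F", "M")) {
    m <- tryCatch(fit_growth_model(cohort, p, s, degree), error = function(e) NULL)
    if (is.null(m)) next
    rows[[paste(p, s)]] <- data.frame(param = p, sex = s,
      t(m$coefficients), residual_sd = m$residual_sd, n = m$n,
      age_min = m$age_range[1], age_max = m$age_range[2],
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
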