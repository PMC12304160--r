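#' Predictive-mean-matching imputation by chained equations
#'
#' Fills missing parameter values by iterated chained regressions with
#' predictive mean matching (PMM): each incomplete variable is regressed on
#' the covariates (sex, age, birth weight) and all other quantitative
#' variables at their current fill-in; regression coefficients are drawn
#' from their Bayesian posterior; each missing cell then receives the
#' observed value of a donor sampled from the `k` cases whose predicted
#' means are closest to the cell's prediction. Imputed values are therefore
#' always observed values of the same column (no out-of-support
#' fabrication), which is robust to nonlinearity and outliers. Correlated
#' parameters can be grouped into blocks that are visited together.
#'
#' @param cohort Cohort data.frame with NA holes (see [simulate_cohort()],
#'   [inject_missingness()]).
#' @param m Number of imputed datasets (default 5).
#' @param k PMM donor pool size (default 5).
#' @param maxit Chained-equation iterations per dataset (default 10).
#' @param seed Integer seed; a fixed seed makes the output bit-reproducible.
#' @param blocks Optional list of character vectors grouping parameter
#'   columns; block members are visited consecutively (default: all
#'   parameter columns as one length-measurement block).
#' @return A `naso_imputations`: list with `imputations` (list of `m`
#'   completed data.frames), `m`, `k`, `maxit`, `seed`.
#' @export
impute_pmm <- function(cohort, m = 5, k = 5, maxit = 10, seed = NULL,
                       blocks = NULL) {
  cohort <- validate_cohort(cohort)
  if (m < 1 || k < 1) stop("imputation spec error: m and k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pcols <- cohort_param_cols(cohort)
  if (is.null(blocks)) blocks <- list(pcols)
  visit <- intersect(unlist(blocks), pcols)
  targets <- visit[vapply(visit, function(cl) anyNA(cohort[[cl]]), TRUE)]
  for (cl in targets) {
    n_donor <- sum(!is.na(cohort[[cl]]))
    if (n_donor < k)
      stop(sprintf("imputation error: variable %s has %d complete donors (< k = %d)",
                   cl, n_donor, k))
  }
  if (!length(targets))
    return(structure(list(imputations = rep(list(cohort), m), m = m, k = k,
                          maxit = maxit, seed = seed),
                     class = "naso_imputations"))

  covars <- cbind(sexM = as.numeric(cohort$sex == "M"),
                  age = cohort$age_months,
                  bw = if ("birth_weight_g" %in% names(cohort))
                    cohort$birth_weight_g else NULL)
  miss_idx <- lapply(targets, function(cl) which(is.na(cohort[[cl]])))
  names(miss_idx) <- targets

  imps <- vector("list", m)
  for (im in seq_len(m)) {
    cur <- cohort
    # initialize holes with random observed draws
    for (cl in targets) {
      obs <- cur[[cl]][!is.na(cur[[cl]])]
      cur[[cl]][miss_idx[[cl]]] <- sample(obs, length(miss_idx[[cl]]),
                                          replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (cl in targets) {
        mis <- miss_idx[[cl]]
        obs <- setdiff(seq_len(nrow(cur)), mis)
        X <- cbind(1, covars,
                   as.matrix(cur[, setdiff(pcols, cl), drop = FALSE]))
        storage.mode(X) <- "double"
        y <- cohort[[cl]]
        d <- pmm_draw(X[obs, , drop = FALSE], y[obs], X[mis, , drop = FALSE])
        for (j in seq_along(mis)) {
          dist <- abs(d$yhat_obs - d$yhat_mis[j])
          pool <- order(dist)[seq_len(min(k, length(dist)))]
          donor <- pool[sample.int(length(pool), 1L)]
          cur[[cl]][mis[j]] <- y[obs][donor]
        }
      }
    }
    imps[[im]] <- cur
  }
  structure(list(imputations = imps, m = m, k = k, maxit = maxit,
                 seed = seed),
            class = "naso_imputations")
}

# Posterior draw of regression coefficients (ridge-stabilized), returning
# predicted means for observed (at beta-hat) and missing (at beta-star) rows.
pmm_draw <- function(Xo, yo, Xm) {
  p <- ncol(Xo); n <- length(yo)
  xtx <- crossprod(Xo)
  ridge <- diag(1e-8 * (diag(xtx) + 1), p)
  V <- solve(xtx + ridge)
  beta_hat <- V %*% crossprod(Xo, yo)
  res <- yo - Xo %*% beta_hat
  df <- max(n - p, 1)
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  R <- chol((V + t(V)) / 2)
  beta_star <- beta_hat + sqrt(sigma2_star) * t(R) %*% stats::rnorm(p)
  list(yhat_obs = as.numeric(Xo %*% beta_hat),
       yhat_mis = as.numeric(Xm %*% beta_star))
}

#' @export
print.naso_imputations <- function(x, ...) {
  nmis <- sum(is.na(x$imputations[[1]][0, ]))
  cat(sprintf("<naso_imputations> m = %d completed datasets (PMM, k = %d, %d iterations)\n",
              x$m, x$k, x$maxit))
  invisible(x)
}

#' Pool completed-data column means across imputations
#' @param imp A `naso_imputations`.
#' @param cols Columns to average (default all parameter columns).
#' @return Named vector of across-imputation mean column means.
#' @export
pool_means <- function(imp, cols = NULL) {
  if (is.null(cols)) cols <- cohort_param_cols(imp$imputations[[1]])
  mm <- sapply(imp$imputations, function(d) colMeans(d[, cols, drop = FALSE]))
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1, dimnames = list(cols, NULL))
  rowMeans(mm)
}
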