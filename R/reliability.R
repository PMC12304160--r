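#' Load a rating matrix
#'
#' Subjects x raters (or occasions) CSV of one parameter's values; header
#' row names the raters, empty cells are missing.
#'
#' @param path CSV path.
#' @return Numeric matrix with rater columns; rows with any missing cell
#'   are kept and flagged via the `incomplete` attribute.
#' @export
load_rating_matrix <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  validate_rating_matrix(m)
}

validate_rating_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("rating matrix needs >= 2 subjects and >= 2 raters/occasions")
  attr(m, "incomplete") <- which(rowSums(is.na(m)) > 0)
  m
}

# Two-way mean squares of a complete subjects x raters matrix.
twoway_ms <- function(m) {
  m <- validate_rating_matrix(m)
  cc <- stats::complete.cases(m)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("fewer than 2 complete subjects")
  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation, two-way consistency, single measure
#'
#' ICC(C,1) from the two-way mean-square decomposition:
#' (MSR - MSE) / (MSR + (k-1) MSE). Rater offsets that are constant across
#' subjects do not reduce consistency. Used for intra-rater reliability
#' across measurement occasions.
#'
#' @param m Subjects x occasions numeric matrix (rows with missing cells
#'   are dropped).
#' @return ICC value; NA with a warning when between-subject variance is
#'   degenerate (MSR = MSE = 0).
#' @export
icc_consistency <- function(m) {
  ms <- twoway_ms(m)
  den <- ms$msr + (ms$k - 1) * ms$mse
  if (den == 0) { warning("degenerate rating matrix: no variance"); return(NA_real_) }
  (ms$msr - ms$mse) / den
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' ICC(A,1): (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)). Systematic
#' rater offsets count against agreement, so ICC(A,1) <= ICC(C,1) whenever
#' raters differ by a shift. Used for inter-rater reliability.
#'
#' @inheritParams icc_consistency
#' @return ICC value, or NA when degenerate.
#' @export
icc_agreement <- function(m) {
  ms <- twoway_ms(m)
  den <- ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse)
  if (den == 0) { warning("degenerate rating matrix: no variance"); return(NA_real_) }
  (ms$msr - ms$mse) / den
}

#' Interpret an ICC value
#'
#' Bands: below 0.40 poor, 0.40 to 0.75 inclusive substantial, above 0.75
#' excellent.
#'
#' @param icc ICC value(s), each <= 1.
#' @return Character vector in {"poor", "substantial", "excellent"}.
#' @export
interpret_icc <- function(icc) {
  if (any(icc > 1 + 1e-12, na.rm = TRUE)) stop("ICC cannot exceed 1")
  ifelse(icc < 0.40, "poor", ifelse(icc <= 0.75, "substantial", "excellent"))
}

#' Percentage agreement at a tolerance
#'
#' Share of subject-wise rater pairs whose absolute difference is within
#' `tol`, averaged over all unordered column pairs, in percent.
#'
#' @param m Subjects x raters matrix.
#' @param tol Agreement tolerance in mm (default 1).
#' @return Percentage in 0..100.
#' @export
percent_agreement <- function(m, tol = 1.0) {
  m <- validate_rating_matrix(m)
  cmb <- utils::combn(ncol(m), 2)
  diffs <- abs(m[, cmb[1, ], drop = FALSE] - m[, cmb[2, ], drop = FALSE])
  100 * mean(diffs <= tol, na.rm = TRUE)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in -1..1; NA with a warning for zero variance.
#' @export
pearson_r <- function(x, y) {
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (length(x) < 3L) stop("pearson_r needs n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("undefined correlation: zero variance")
    return(NA_real_)
  }
  stats::cor(x, y)
}
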