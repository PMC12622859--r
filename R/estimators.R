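complete_pairs <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Pearson product-moment correlation
#'
#' Complete-case Pearson correlation between a digital measure and a
#' reference measure. Requires at least 3 complete pairs and refuses
#' constant input rather than returning a silent zero, since an undefined
#' correlation usually signals a data problem in an agreement study.
#'
#' @param x,y Paired numeric vectors; pairs with any `NA` are dropped.
#' @return List with `r` and `n` (complete pairs used).
#' @export
pearson_r <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 3L)
    stop("need at least 3 complete pairs, got ", cp$n, call. = FALSE)
  if (stats::sd(cp$x) == 0 || stats::sd(cp$y) == 0)
    stop("correlation undefined: an input vector is constant", call. = FALSE)
  list(r = stats::cor(cp$x, cp$y), n = cp$n)
}

#' Simple linear regression of a DM on one RM
#'
#' Ordinary least squares with the digital measure as the response. The
#' coefficient of determination equals the squared Pearson correlation.
#'
#' @inheritParams pearson_r
#' @return List with `slope`, `intercept`, `r2` and `n`.
#' @export
fit_slr <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 3L)
    stop("need at least 3 complete pairs, got ", cp$n, call. = FALSE)
  if (stats::sd(cp$x) == 0 || stats::sd(cp$y) == 0)
    stop("regression undefined: an input vector is constant", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = cp$x, y = cp$y))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = summary(fit)$r.squared, n = cp$n)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`. Unlike R-squared it penalises
#' uninformative predictors and can be negative.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of complete cases.
#' @param p Number of predictors.
#' @return Adjusted R-squared (may be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Multiple linear regression of a DM on a set of RMs
#'
#' Ordinary least squares of the digital measure on one or more reference
#' measures, complete cases per model (a row is dropped if any predictor or
#' the response is missing, so different predictor sets may use different
#' `n`). Reports both R-squared and adjusted R-squared.
#'
#' @param X Numeric matrix or data frame of predictors (one column per RM).
#' @param y Response vector (the digital measure).
#' @return List with `coefficients`, `r2`, `adj_r2`, `n` and `p`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1)
    stop("need more complete cases (n = ", n, ") than predictors + 1 (p = ",
         p, ")", call. = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    drop_idx <- qrX$pivot[(qrX$rank + 1L):(p + 1L)] - 1L
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[drop_idx[drop_idx > 0]], collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(y ~ ., data = data.frame(X, y = y, check.names = FALSE))
  sm <- summary(fit)
  list(coefficients = stats::coef(fit), r2 = sm$r.squared,
       adj_r2 = adjusted_r2(sm$r.squared, n, p), n = n, p = p)
}
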