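#' Sample covariance of aligned indicator data
#'
#' Computes the unbiased sample covariance matrix of the indicator columns
#' used by the CFA. `listwise` (the default) keeps only rows with every
#' indicator observed; `pairwise` uses all overlapping pairs, which can
#' yield an indefinite matrix, so positive definiteness is verified and a
#' violation is an error advising listwise deletion.
#'
#' @param data Numeric matrix or data frame, one column per indicator.
#' @param strategy `"listwise"` or `"pairwise"` missing-data handling.
#' @return List with `S` (covariance matrix) and `n_used` (rows behind it;
#'   for pairwise, the smallest pairwise count).
#' @export
compute_sample_cov <- function(data, strategy = c("listwise", "pairwise")) {
  strategy <- match.arg(strategy)
  X <- as.matrix(data)
  p <- ncol(X)
  if (strategy == "listwise") {
    cc <- stats::complete.cases(X)
    n_used <- sum(cc)
    if (n_used < p + 1L)
      stop(sprintf("listwise covariance needs >= %d complete rows, got %d",
                   p + 1L, n_used), call. = FALSE)
    S <- stats::cov(X[cc, , drop = FALSE])
  } else {
    npair <- crossprod(!is.na(X))
    if (any(npair < 3L))
      stop("pairwise covariance needs >= 3 overlapping rows per pair; minimum is ",
           min(npair), call. = FALSE)
    S <- stats::cov(X, use = "pairwise.complete.obs")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("pairwise covariance matrix is not positive definite; ",
           "use listwise deletion", call. = FALSE)
    n_used <- as.integer(min(npair))
  }
  list(S = S, n_used = n_used)
}

#' Specify a two-factor measurement model
#'
#' Simple-structure specification: the DM factor is measured by the
#' individual window-day DM values and the RM factor by the COA items; no
#' cross-loadings. Identification is by unit factor variances, so the
#' factor covariance is directly the factor correlation. Each factor needs
#' at least 3 indicators for the model to be identified.
#'
#' @param dm_indicators,rm_indicators Character vectors naming the columns
#'   loading on the DM factor and the RM factor.
#' @return An object of class `avtk_cfa_spec`.
#' @export
cfa_model_spec <- function(dm_indicators, rm_indicators) {
  if (length(dm_indicators) < 3L || length(rm_indicators) < 3L)
    stop("each factor needs at least 3 indicators", call. = FALSE)
  if (length(intersect(dm_indicators, rm_indicators)))
    stop("an indicator cannot load on both factors", call. = FALSE)
  structure(list(dm_indicators = dm_indicators, rm_indicators = rm_indicators),
            class = "avtk_cfa_spec")
}

# Model-implied covariance: Sigma = Lambda Phi Lambda' + diag(psi),
# Lambda simple-structure with p1 loadings on factor 1 and p2 on factor 2.
cfa_implied_cov <- function(lambda, phi, psi, p1) {
  p <- length(lambda)
  f <- rep(1:2, c(p1, p - p1))
  L <- matrix(0, p, 2)
  L[cbind(seq_len(p), f)] <- lambda
  Phi <- matrix(c(1, phi, phi, 1), 2)
  L %*% Phi %*% t(L) + diag(psi, p)
}

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p and its
# analytic gradient wrt theta = (lambda, atanh(phi), log(psi - floor)).
cfa_objective <- function(theta, S, p1, logdetS, psi_floor) {
  p <- ncol(S)
  lambda <- theta[seq_len(p)]
  phi <- tanh(theta[p + 1L])
  psi <- psi_floor + exp(theta[(p + 2L):(2L * p + 1L)])
  Sigma <- cfa_implied_cov(lambda, phi, psi, p1)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = rep(0, length(theta))))
  Sinv <- chol2inv(ch)
  val <- 2 * sum(log(diag(ch))) + sum(Sinv * S) - logdetS - p
  # dF/dSigma = Sigma^-1 - Sigma^-1 S Sigma^-1
  A <- Sinv - Sinv %*% S %*% Sinv
  f <- rep(1:2, c(p1, p - p1))
  L <- matrix(0, p, 2)
  L[cbind(seq_len(p), f)] <- lambda
  Phi <- matrix(c(1, phi, phi, 1), 2)
  ALP <- A %*% L %*% Phi
  g_lambda <- 2 * ALP[cbind(seq_len(p), f)]
  g_phi_raw <- 2 * (t(L) %*% A %*% L)[1L, 2L] * (1 - phi^2)
  g_psi_raw <- diag(A) * (psi - psi_floor)
  list(value = val, gradient = c(g_lambda, g_phi_raw, g_psi_raw))
}

cfa_starts <- function(S, p1) {
  p <- ncol(S)
  R <- stats::cov2cor(S)
  sdv <- sqrt(diag(S))
  i1 <- seq_len(p1); i2 <- (p1 + 1L):p
  mean_offdiag <- function(M) {
    if (nrow(M) < 2L) return(0.49)
    mean(M[upper.tri(M)])
  }
  l1 <- sqrt(max(mean_offdiag(R[i1, i1, drop = FALSE]), 0.04))
  l2 <- sqrt(max(mean_offdiag(R[i2, i2, drop = FALSE]), 0.04))
  phi0 <- mean(R[i1, i2]) / (l1 * l2)
  phi0 <- max(min(phi0, 0.95), -0.95)
  base_lambda <- c(rep(l1, p1), rep(l2, p - p1)) * sdv
  base_psi <- pmax(diag(S) - base_lambda^2, 0.05 * diag(S))
  mk <- function(lmult, phival) {
    lam <- base_lambda * lmult
    psi <- pmax(diag(S) - lam^2, 0.05 * diag(S))
    c(lam, atanh(max(min(phival, 0.95), -0.95)), log(psi))
  }
  list(mk(1, phi0), mk(0.75, phi0), mk(1.2, phi0), mk(1, phi0 / 2), mk(0.9, 0))
}

#' Fit a two-factor correlated-factor CFA by maximum likelihood
#'
#' Minimises the normal-theory maximum-likelihood discrepancy
#' \deqn{F(\theta) = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) -
#'   \ln|S| - p} over loadings, the factor correlation and the diagonal
#' uniquenesses, with both factor variances fixed to 1 so the factor
#' covariance is the factor correlation itself. The factor correlation is
#' parameterised through `tanh` and uniquenesses through a positivity
#' transform; optimisation uses `stats::nlminb` with analytic gradients
#' from 5 deterministic starting points, keeping the best solution.
#'
#' The model chi-square is `(n_used - 1) * F` at the minimum. A uniqueness
#' estimate on its lower bound (a Heywood case) is flagged and floored at
#' `psi_floor` with a warning rather than failing, so batch analyses run to
#' completion. Non-convergence is likewise reported through the `converged`
#' flag, not raised.
#'
#' @param S Sample covariance matrix of the indicators (DM-day columns
#'   first, then RM items, matching `spec`).
#' @param n_used Number of observations behind `S`.
#' @param spec A [cfa_model_spec()]; its indicator names must match
#'   `colnames(S)` in order (DM block then RM block).
#' @param control List of optimiser settings: `rel_tol` (default `1e-10`),
#'   `iter_max` (default 1000), `psi_floor` (default `1e-6`).
#' @return An object of class `avtk_cfa` with the factor correlation `phi`,
#'   raw and standardised loadings, uniquenesses, `chisq`, `df`, baseline
#'   chi-square and df, discrepancy value, and flags `converged` /
#'   `heywood`. Fit indices are added by [compute_fit_indices()].
#' @export
fit_two_factor_cfa <- function(S, n_used, spec, control = list()) {
  stopifnot(inherits(spec, "avtk_cfa_spec"))
  p1 <- length(spec$dm_indicators)
  p2 <- length(spec$rm_indicators)
  p <- p1 + p2
  S <- as.matrix(S)
  if (!is.null(colnames(S))) {
    want <- c(spec$dm_indicators, spec$rm_indicators)
    if (!all(want %in% colnames(S)))
      stop("covariance matrix lacks indicator(s): ",
           paste(setdiff(want, colnames(S)), collapse = ", "), call. = FALSE)
    S <- S[want, want]
  } else if (ncol(S) != p) {
    stop("covariance dimension does not match the model specification",
         call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("sample covariance matrix is not positive definite", call. = FALSE)
  rel_tol <- control$rel_tol %||% 1e-10
  iter_max <- control$iter_max %||% 1000L
  psi_floor <- control$psi_floor %||% 1e-6
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1L]

  best <- NULL
  for (start in cfa_starts(S, p1)) {
    opt <- stats::nlminb(
      start,
      objective = function(th) cfa_objective(th, S, p1, logdetS, psi_floor)$value,
      gradient = function(th) cfa_objective(th, S, p1, logdetS, psi_floor)$gradient,
      control = list(iter.max = iter_max, eval.max = 4L * iter_max,
                     rel.tol = rel_tol))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  lambda <- unname(best$par[seq_len(p)])
  phi <- unname(tanh(best$par[p + 1L]))
  psi <- unname(psi_floor + exp(best$par[(p + 2L):(2L * p + 1L)]))

  # sign convention: average loading positive within each factor;
  # flipping one factor's loadings flips the factor correlation
  s1 <- sign(sum(lambda[seq_len(p1)]))
  s2 <- sign(sum(lambda[(p1 + 1L):p]))
  if (s1 < 0) { lambda[seq_len(p1)] <- -lambda[seq_len(p1)]; phi <- -phi }
  if (s2 < 0) { lambda[(p1 + 1L):p] <- -lambda[(p1 + 1L):p]; phi <- -phi }

  heywood <- any(psi <= psi_floor * (1 + 1e-3))
  if (heywood)
    warning("Heywood case: uniqueness estimate(s) at the lower bound ",
            "were floored at ", psi_floor, call. = FALSE)
  Sigma <- cfa_implied_cov(lambda, phi, psi, p1)
  F_min <- max(best$objective, 0)
  free <- 2L * p + 1L
  structure(list(
    phi = phi,
    loadings = lambda,
    loadings_std = lambda / sqrt(diag(Sigma)),
    uniquenesses = psi,
    implied_cov = Sigma,
    sample_cov = S,
    discrepancy = F_min,
    chisq = (n_used - 1) * F_min,
    df = (p * (p + 1L)) %/% 2L - free,
    baseline_chisq = (n_used - 1) *
      (-determinant(stats::cov2cor(S), logarithm = TRUE)$modulus[1L]),
    baseline_df = (p * (p - 1L)) %/% 2L,
    n_used = n_used,
    p1 = p1, p2 = p2,
    converged = best$convergence == 0L,
    heywood = heywood,
    spec = spec), class = "avtk_cfa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.avtk_cfa <- function(x, ...) {
  cat("<avtk_cfa> two-factor correlated-factor model (ML)\n")
  cat(sprintf("  factor correlation: %.4f\n", x$phi))
  cat(sprintf("  chi-square %.3f on %d df (n = %d)%s%s\n", x$chisq, x$df,
              x$n_used, if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$heywood) " [Heywood]" else ""))
  if (!is.null(x$cfi))
    cat(sprintf("  CFI %.3f  TLI %.3f  RMSEA %.3f  SRMR %.3f\n",
                x$cfi, x$tli, x$rmsea, x$srmr))
  invisible(x)
}

#' Compute CFI, TLI, RMSEA and SRMR for a fitted CFA
#'
#' The incremental indices compare the fitted model with the independence
#' baseline (diagonal covariance, `df_b = p(p-1)/2`):
#' `CFI = 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)` and
#' `TLI = (chisq_b/df_b - chisq/df) / (chisq_b/df_b - 1)` (TLI may exceed 1).
#' `RMSEA = sqrt(max(chisq - df, 0) / (df (n - 1)))` and SRMR is the root
#' mean square of the correlation-scale residuals over the lower triangle
#' including the diagonal. With `df = 0` the indices are undefined and
#' returned as `NA` with a warning.
#'
#' @param fit An `avtk_cfa` from [fit_two_factor_cfa()].
#' @return The fit with `cfi`, `tli`, `rmsea`, `srmr` filled in.
#' @export
compute_fit_indices <- function(fit) {
  stopifnot(inherits(fit, "avtk_cfa"))
  if (fit$df == 0L) {
    warning("saturated model (df = 0): fit indices undefined", call. = FALSE)
    fit$cfi <- fit$tli <- fit$rmsea <- NA_real_
  } else {
    num <- max(fit$chisq - fit$df, 0)
    den <- max(fit$baseline_chisq - fit$baseline_df, fit$chisq - fit$df, 0)
    fit$cfi <- if (den == 0) 1 else 1 - num / den
    rb <- fit$baseline_chisq / fit$baseline_df
    fit$tli <- (rb - fit$chisq / fit$df) / (rb - 1)
    fit$rmsea <- sqrt(max(fit$chisq - fit$df, 0) / (fit$df * (fit$n_used - 1)))
  }
  dS <- sqrt(diag(fit$sample_cov))
  res <- (fit$sample_cov - fit$implied_cov) / outer(dS, dS)
  fit$srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  fit
}

#' Fit-evaluation thresholds
#'
#' Default acceptability thresholds for the four fit statistics: CFI and
#' TLI acceptable at values >= 0.9, RMSEA and SRMR acceptable at values
#' < 0.08.
#'
#' @param cfi_min,tli_min Lower bounds for CFI/TLI (pass when `>=`).
#' @param rmsea_max,srmr_max Upper bounds for RMSEA/SRMR (pass when
#'   strictly `<`).
#' @return An object of class `avtk_thresholds`.
#' @export
fit_thresholds <- function(cfi_min = 0.90, tli_min = 0.90,
                           rmsea_max = 0.08, srmr_max = 0.08) {
  stopifnot(cfi_min > 0, cfi_min < 1, tli_min > 0, tli_min < 1,
            rmsea_max > 0, rmsea_max < 1, srmr_max > 0, srmr_max < 1)
  structure(list(cfi_min = cfi_min, tli_min = tli_min,
                 rmsea_max = rmsea_max, srmr_max = srmr_max),
            class = "avtk_thresholds")
}

#' Evaluate model fit against acceptability thresholds
#'
#' CFI and TLI pass when at or above their threshold (a TLI above 1 counts
#' as passing); RMSEA and SRMR pass when strictly below theirs. The overall
#' verdict follows the majority of the four statistics: `"acceptable"`,
#' `"unacceptable"`, or `"mixed"` on a 2-2 split.
#'
#' @param fit An `avtk_cfa` with fit indices (see [compute_fit_indices()]),
#'   or a list/one-row data frame with elements `cfi`, `tli`, `rmsea`,
#'   `srmr`.
#' @param thresholds An [fit_thresholds()] object.
#' @return List with logical `cfi_pass`, `tli_pass`, `rmsea_pass`,
#'   `srmr_pass` and character `verdict`.
#' @export
evaluate_fit <- function(fit, thresholds = fit_thresholds()) {
  stopifnot(inherits(thresholds, "avtk_thresholds"))
  idx <- vapply(c("cfi", "tli", "rmsea", "srmr"),
                function(k) as.numeric(fit[[k]]), numeric(1))
  if (anyNA(idx))
    stop("fit indices missing; run compute_fit_indices() first", call. = FALSE)
  flags <- c(cfi_pass = idx[["cfi"]] >= thresholds$cfi_min,
             tli_pass = idx[["tli"]] >= thresholds$tli_min,
             rmsea_pass = idx[["rmsea"]] < thresholds$rmsea_max,
             srmr_pass = idx[["srmr"]] < thresholds$srmr_max)
  n_pass <- sum(flags)
  verdict <- if (n_pass > 2L) "acceptable" else if (n_pass < 2L) "unacceptable" else "mixed"
  c(as.list(flags), list(verdict = verdict))
}
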