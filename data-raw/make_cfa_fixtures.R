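# Generates the committed CFA oracle fixtures under
# tests/testthat/fixtures/ by fitting each synthetic covariance matrix with
# the independent SEM package `lava` (ML, two correlated factors with unit
# factor variances) and freezing its estimates.
#
# chi-square convention: lava's LR statistic is n * F_ML; CFI/TLI are
# derived from lava's model and independence chi-squares via the standard
# formulas; RMSEA is lava's own; SRMR is computed from lava's fitted
# moments. Fixture data are synthetic draws from a two-factor model with
# unequal loadings and (for two fixtures) Likert-discretised items, so the
# sample covariances carry realistic sampling misfit.
#
# Run from the package root: Rscript data-raw/make_cfa_fixtures.R

suppressMessages(library(lava))

make_data <- function(seed, n, l1, l2, phi, likert = NULL) {
  set.seed(seed)
  p1 <- length(l1); p2 <- length(l2)
  z <- matrix(rnorm(2 * n), n, 2)
  eta1 <- z[, 1]
  eta2 <- phi * z[, 1] + sqrt(1 - phi^2) * z[, 2]
  X <- sapply(l1, function(l) l * eta1 + sqrt(1 - l^2) * rnorm(n))
  Y <- sapply(l2, function(l) l * eta2 + sqrt(1 - l^2) * rnorm(n))
  if (!is.null(likert))
    Y <- apply(Y, 2, function(y) findInterval(y, qnorm(seq_len(likert - 1) / likert)))
  d <- data.frame(X, Y)
  names(d) <- c(paste0("x", seq_len(p1)), paste0("y", seq_len(p2)))
  d
}

fit_lava <- function(d, p1, p2) {
  xs <- paste0("x", seq_len(p1)); ys <- paste0("y", seq_len(p2))
  m <- lvm()
  for (v in xs) regression(m) <- stats::as.formula(paste(v, "~ f1"))
  for (v in ys) regression(m) <- stats::as.formula(paste(v, "~ f2"))
  covariance(m) <- f1 ~ f2
  latent(m) <- ~ f1 + f2
  covariance(m, ~ f1 + f2) <- 1
  e <- estimate(m, d, control = list(trace = 0))
  g <- gof(e, chisq = TRUE)
  chisq <- unname(g$fit$statistic); df <- unname(g$fit$parameter)

  # independence baseline, also in lava: variances only
  m0 <- lvm()
  for (v in c(xs, ys)) m0 <- regression(m0, stats::as.formula(paste(v, "~ 1")))
  e0 <- estimate(m0, d, control = list(trace = 0))
  g0 <- gof(e0, chisq = TRUE)
  chisq_b <- unname(g0$fit$statistic); df_b <- unname(g0$fit$parameter)

  cfi <- 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)
  rb <- chisq_b / df_b
  tli <- (rb - chisq / df) / (rb - 1)
  rmsea <- unname(g$RMSEA["RMSEA"])

  # SRMR from lava's fitted moments vs the ML sample covariance
  p <- p1 + p2
  cf <- coef(e)
  lam <- c(cf[paste0(xs, "~f1")], cf[paste0(ys, "~f2")])
  phi_hat <- cf["f1~~f2"]
  psi <- cf[paste0(c(xs, ys), "~~", c(xs, ys))]
  L <- matrix(0, p, 2); L[cbind(1:p, rep(1:2, c(p1, p2)))] <- lam
  Sigma <- L %*% matrix(c(1, phi_hat, phi_hat, 1), 2) %*% t(L) + diag(unname(psi))
  X <- as.matrix(d[c(xs, ys)])
  S_ml <- cov(X) * (nrow(X) - 1) / nrow(X)
  dS <- sqrt(diag(S_ml))
  res <- (S_ml - Sigma) / outer(dS, dS)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))

  list(phi = unname(phi_hat), chisq = chisq, df = df, chisq_b = chisq_b,
       df_b = df_b, cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr)
}

write_fixture <- function(path, d, p1, p2, oracle) {
  S <- cov(as.matrix(d))  # unbiased sample covariance
  con <- file(path, "w")
  writeLines(c(
    "# Synthetic two-factor CFA oracle fixture.",
    "# Covariance of simulated indicator data; oracle values estimated with",
    sprintf("# the lava package (v%s), ML, unit factor variances.",
            as.character(packageVersion("lava"))),
    sprintf("n %d", nrow(d)),
    sprintf("p1 %d", p1),
    sprintf("p2 %d", p2),
    sprintf("oracle_phi %.10f", oracle$phi),
    sprintf("oracle_chisq %.8f", oracle$chisq),
    sprintf("oracle_df %d", oracle$df),
    sprintf("oracle_cfi %.8f", oracle$cfi),
    sprintf("oracle_tli %.8f", oracle$tli),
    sprintf("oracle_rmsea %.8f", oracle$rmsea),
    sprintf("oracle_srmr %.8f", oracle$srmr)), con)
  for (i in seq_len(nrow(S)))
    writeLines(paste(sprintf("%.17g", S[i, ]), collapse = " "), con)
  close(con)
}

dir.create("tests/testthat/fixtures", recursive = TRUE, showWarnings = FALSE)
specs <- list(
  list(file = "cfa_oracle_1.txt", seed = 101, n = 1000,
       l1 = c(0.6, 0.7, 0.8, 0.5), l2 = c(0.7, 0.6, 0.75, 0.65),
       phi = 0.4, likert = NULL),
  list(file = "cfa_oracle_2.txt", seed = 202, n = 1000,
       l1 = rep(0.7, 7), l2 = rep(0.7, 9), phi = 0.5, likert = 4),
  list(file = "cfa_oracle_3.txt", seed = 303, n = 1000,
       l1 = c(0.5, 0.6, 0.45), l2 = c(0.6, 0.55, 0.7, 0.5, 0.65),
       phi = -0.3, likert = 5))

for (s in specs) {
  d <- make_data(s$seed, s$n, s$l1, s$l2, s$phi, s$likert)
  oracle <- fit_lava(d, length(s$l1), length(s$l2))
  write_fixture(file.path("tests/testthat/fixtures", s$file), d,
                length(s$l1), length(s$l2), oracle)
  cat(sprintf("%s: phi=%.4f chisq=%.2f df=%d cfi=%.4f tli=%.4f rmsea=%.4f srmr=%.4f\n",
              s$file, oracle$phi, oracle$chisq, oracle$df, oracle$cfi,
              oracle$tli, oracle$rmsea, oracle$srmr))
}
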