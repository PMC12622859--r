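test_that("sample covariance matches hand computation under both strategies", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  sc <- compute_sample_cov(X)
  expect_equal(unname(sc$S), matrix(c(1, 2, 2, 4), 2))
  expect_equal(sc$n_used, 3L)
  # identical columns: equal diagonal, covariance = variance
  Y <- cbind(a = c(1, 3, 2, 5), b = c(1, 3, 2, 5))
  scy <- compute_sample_cov(Y)
  expect_equal(scy$S[1, 1], scy$S[2, 2])
  expect_equal(scy$S[1, 2], scy$S[1, 1])
  # listwise: one missing cell drops exactly one row
  Z <- cbind(rnorm(10), rnorm(10), rnorm(10))
  Z[4, 2] <- NA
  expect_equal(compute_sample_cov(Z)$n_used, 9L)
  expect_error(compute_sample_cov(Z[1:3, ]), "complete rows")
})

test_that("model specification enforces three indicators per factor", {
  expect_error(cfa_model_spec(c("d1", "d2"), paste0("i", 1:4)), "at least 3")
  expect_error(cfa_model_spec(c("a", "b", "c"), c("c", "d", "e")), "both factors")
  expect_s3_class(cfa_model_spec(paste0("d", 1:3), paste0("i", 1:3)),
                  "avtk_cfa_spec")
})

test_that("a model-implied covariance is recovered exactly", {
  spec <- cfa_model_spec(paste0("x", 1:4), paste0("y", 1:4))
  for (phi in c(0, 0.5)) {
    S <- analytic_sigma(0.7, phi, 4, 4)
    fit <- fit_two_factor_cfa(S, 300, spec)
    expect_true(fit$converged)
    expect_equal(fit$phi, phi, tolerance = 1e-6)
    expect_equal(fit$chisq, 0, tolerance = 1e-6)
    expect_equal(unname(fit$loadings), rep(0.7, 8), tolerance = 1e-4)
    fit <- compute_fit_indices(fit)
    expect_equal(fit$cfi, 1)
    expect_equal(fit$rmsea, 0)
    expect_lt(fit$srmr, 1e-6)
  }
})

test_that("the standardized solution is invariant to indicator rescaling", {
  set.seed(8)
  sim <- generate_study(sim_config(n_participants = 300, seed = 8))
  al <- build_aligned_dataset(sim$study, "dm", "SIM-RM")
  ind <- avtk:::cfa_indicator_data(al)
  sc <- compute_sample_cov(ind$data)
  spec <- cfa_model_spec(ind$dm_cols, ind$item_cols)
  f1 <- compute_fit_indices(fit_two_factor_cfa(sc$S, sc$n_used, spec))
  # rescale one DM indicator and one item by positive constants
  D <- diag(ncol(sc$S)); D[1, 1] <- 250; D[10, 10] <- 0.04
  S2 <- D %*% sc$S %*% D
  dimnames(S2) <- dimnames(sc$S)
  f2 <- compute_fit_indices(fit_two_factor_cfa(S2, sc$n_used, spec))
  expect_equal(f2$phi, f1$phi, tolerance = 1e-6)
  expect_equal(f2$cfi, f1$cfi, tolerance = 1e-6)
  expect_equal(f2$tli, f1$tli, tolerance = 1e-6)
  expect_equal(f2$rmsea, f1$rmsea, tolerance = 1e-6)
})

test_that("fit indices follow their formulas on synthetic chi-squares", {
  fake <- structure(list(chisq = 50, df = 10L, baseline_chisq = 500,
                         baseline_df = 15L, n_used = 101L,
                         sample_cov = diag(3), implied_cov = diag(3)),
                    class = "avtk_cfa")
  out <- compute_fit_indices(fake)
  expect_equal(out$cfi, 1 - 40 / 485)
  expect_equal(out$cfi, 0.91753, tolerance = 1e-5)
  expect_equal(out$tli, 0.87629, tolerance = 1e-5)
  expect_equal(out$rmsea, 0.2)
  expect_equal(out$srmr, 0)  # S equals Sigma exactly
  # over-fitting branch: chisq below df pegs CFI at 1 and RMSEA at 0
  fake$chisq <- 5
  out2 <- compute_fit_indices(fake)
  expect_equal(out2$cfi, 1)
  expect_equal(out2$rmsea, 0)
  expect_gt(out2$tli, 1)
})

test_that("threshold evaluation uses >= for CFI/TLI and strict < for RMSEA/SRMR", {
  th <- fit_thresholds()
  # acceptable on the majority despite failing RMSEA
  ev <- evaluate_fit(list(cfi = 0.913, tli = 0.900, rmsea = 0.081,
                          srmr = 0.079), th)
  expect_true(ev$cfi_pass); expect_true(ev$tli_pass)
  expect_false(ev$rmsea_pass); expect_true(ev$srmr_pass)
  expect_equal(ev$verdict, "acceptable")
  # TLI above 1 is accepted
  ev2 <- evaluate_fit(list(cfi = 1.000, tli = 1.004, rmsea = 0.000,
                           srmr = 0.060), th)
  expect_true(all(unlist(ev2[1:4])))
  expect_equal(ev2$verdict, "acceptable")
  # boundary semantics
  ev3 <- evaluate_fit(list(cfi = 0.90, tli = 0.95, rmsea = 0.08,
                           srmr = 0.079), th)
  expect_true(ev3$cfi_pass)
  expect_false(ev3$rmsea_pass)
  # 2-2 split is mixed
  ev4 <- evaluate_fit(list(cfi = 0.95, tli = 0.95, rmsea = 0.2, srmr = 0.2), th)
  expect_equal(ev4$verdict, "mixed")
})

test_that("estimates match the independent SEM oracle on committed fixtures", {
  for (name in c("cfa_oracle_1.txt", "cfa_oracle_2.txt", "cfa_oracle_3.txt")) {
    fx <- read_cfa_fixture(name)
    spec <- cfa_model_spec(paste0("x", seq_len(fx$p1)),
                           paste0("y", seq_len(fx$p2)))
    fit <- compute_fit_indices(fit_two_factor_cfa(fx$S, fx$n, spec))
    expect_true(fit$converged)
    expect_equal(fit$phi, fx$oracle$oracle_phi, tolerance = 1e-3)
    expect_equal(fit$cfi, fx$oracle$oracle_cfi, tolerance = 1e-3)
    expect_equal(fit$tli, fx$oracle$oracle_tli, tolerance = 1e-3)
    expect_equal(fit$rmsea, fx$oracle$oracle_rmsea, tolerance = 1e-3)
    expect_equal(fit$srmr, fx$oracle$oracle_srmr, tolerance = 1e-3)
  }
})

test_that("Heywood cases are floored and flagged, not fatal", {
  # a tiny uniqueness in the generating model pushes estimates to the bound
  S <- analytic_sigma(0.99, 0.5, 3, 3)
  diag(S)[1] <- 0.9801 + 1e-9  # indicator 1 nearly deterministic
  spec <- cfa_model_spec(paste0("x", 1:3), paste0("y", 1:3))
  expect_warning(fit <- fit_two_factor_cfa(S, 200, spec), "Heywood")
  expect_true(fit$heywood)
  expect_true(all(fit$uniquenesses > 0))
})

test_that("non-positive-definite input is refused", {
  S <- matrix(1, 6, 6)
  colnames(S) <- rownames(S) <- c(paste0("x", 1:3), paste0("y", 1:3))
  spec <- cfa_model_spec(paste0("x", 1:3), paste0("y", 1:3))
  expect_error(fit_two_factor_cfa(S, 100, spec), "positive definite")
})
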