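test_that("implied covariance reduces to Psi and traces single paths", {
  g0 <- dag(c("a", "b"))
  psi <- diag(2)
  dimnames(psi) <- list(c("a", "b"), c("a", "b"))
  m0 <- path_model(g0, data.frame(from = character(0), to = character(0),
                                  coef = numeric(0)), psi)
  expect_equal(implied_covariance(m0), psi)
  # chain Sex -> Anx (0.179), Anx -> Dep (0.745): cov(Sex, Dep) by tracing
  g <- dag(c("Sex", "Anx", "Dep"), rbind(c("Sex", "Anx"), c("Anx", "Dep")))
  B <- matrix(0, 3, 3, dimnames = list(c("Sex", "Anx", "Dep"),
                                       c("Sex", "Anx", "Dep")))
  B["Anx", "Sex"] <- 0.179
  B["Dep", "Anx"] <- 0.745
  psi3 <- complete_standardized_residuals(B)
  m <- path_model(g, data.frame(from = c("Sex", "Anx"), to = c("Anx", "Dep"),
                                coef = c(0.179, 0.745)), psi3)
  sig <- implied_covariance(m)
  expect_equal(sig["Sex", "Dep"], 0.179 * 0.745, tolerance = 1e-12)
  expect_lt(max(abs(sig - t(sig))), 1e-12)
  expect_lt(max(abs(diag(sig) - 1)), 1e-12)
})

test_that("residual-variance completion rejects infeasible coefficients", {
  B <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  B["y", "x"] <- 1.2
  expect_error(complete_standardized_residuals(B), "infeasible")
  B["y", "x"] <- 0.745
  psi <- complete_standardized_residuals(B)
  expect_equal(psi["y", "y"], 1 - 0.745^2, tolerance = 1e-12)
})

test_that("the ML discrepancy has its closed forms and is nonnegative", {
  S <- matrix(c(2, 0.3, 0.3, 1), 2)
  expect_lt(ml_discrepancy(S, S), 1e-12)
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), 1 - log(2),
               tolerance = 1e-12)
  set.seed(50)
  for (r in 1:200) {
    A1 <- matrix(rnorm(9), 3)
    A2 <- matrix(rnorm(9), 3)
    S1 <- crossprod(A1) + diag(3) * 0.1
    S2 <- crossprod(A2) + diag(3) * 0.1
    expect_gte(ml_discrepancy(S1, S2), 0)
  }
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive definite")
})

test_that("ML under a diagonal-Psi recursive model equals per-equation OLS", {
  d <- chain3_data(500, seed = 51)
  g <- chain3_dag()
  # numerical optimization route, checked against the lm() oracle
  f <- fit_path_model(g, d, residual_pairs = "none", method = "optim")
  df <- as.data.frame(d)
  ols_xy <- unname(coef(lm(y ~ x, df))["x"])
  ols_yz <- unname(coef(lm(z ~ y, df))["y"])
  est <- f$estimates
  expect_equal(est$est[est$type == "beta" & est$lhs == "y"], ols_xy,
               tolerance = 1e-6)
  expect_equal(est$est[est$type == "beta" & est$lhs == "z"], ols_yz,
               tolerance = 1e-6)
  expect_equal(est$est[est$type == "psi" & est$lhs == "y"],
               sum(residuals(lm(y ~ x, df))^2) / (500 - 1), tolerance = 1e-6)
  # the closed-form route agrees with the optimizer
  f2 <- fit_path_model(g, d, residual_pairs = "none", method = "ols")
  expect_equal(f2$theta, f$theta, tolerance = 1e-6)
})

test_that("a saturated model fits perfectly with zero degrees of freedom", {
  d <- chain3_data(200, seed = 52)
  g <- dag(c("x", "y", "z"),
           rbind(c("x", "y"), c("x", "z"), c("y", "z")))
  f <- fit_path_model(g, d, residual_pairs = "none")
  expect_equal(f$df, 0)
  expect_lt(f$discrepancy, 1e-10)
  expect_lt(abs(f$statistic), 1e-6)
  idx <- fit_indices(f)
  expect_true(is.na(idx$rmsea))
  expect_true(is.na(idx$nnfi))
  expect_equal(idx$cfi, 1)
  expect_lt(idx$srmr, 1e-6)
})

test_that("fit indices match an independently coded formula evaluation", {
  d <- chain3_data(400, seed = 53)
  g <- chain3_dag()
  f <- fit_path_model(g, d, residual_pairs = "none")
  idx <- fit_indices(f)
  # independent evaluation from first principles
  S <- cov(as.data.frame(d))[f$nodes, f$nodes]
  n <- 400
  p <- 3
  T_ <- (n - 1) * f$discrepancy
  df <- f$df
  Fb <- log(prod(diag(S))) - log(det(S))
  Tb <- (n - 1) * Fb
  dfb <- p * (p - 1) / 2
  expect_equal(idx$rmsea, sqrt(max(T_ - df, 0) / (df * (n - 1))),
               tolerance = 1e-10)
  expect_equal(idx$cfi, 1 - max(T_ - df, 0) / max(Tb - dfb, T_ - df, 0),
               tolerance = 1e-10)
  expect_equal(idx$nnfi, (Tb / dfb - T_ / df) / (Tb / dfb - 1),
               tolerance = 1e-10)
  Rm <- (S - f$Sigma) / sqrt(tcrossprod(diag(S)))
  expect_equal(idx$srmr,
               sqrt(sum(Rm[upper.tri(Rm, diag = TRUE)]^2) / (p * (p + 1) / 2)),
               tolerance = 1e-10)
  # formula limit: T == df would give rmsea 0 / cfi 1 (checked via perfect fit)
  gsat <- dag(c("x", "y", "z"), rbind(c("x", "y"), c("x", "z"), c("y", "z")))
  expect_equal(fit_indices(fit_path_model(gsat, d, residual_pairs = "none"))$cfi, 1)
})

test_that("the full generating model is recovered with free sink covariances", {
  gm <- default_generating_model()
  co <- standardize(simulate_cohort(gm, 50000, seed = 54))$table
  f <- fit_path_model(gm$model$graph, co)
  expect_true(f$converged)
  expect_false(f$heywood)
  expect_equal(f$df, 43)
  truth <- painpath:::default_path_coefficients()
  est <- f$estimates[f$estimates$type == "beta", ]
  merged <- merge(truth, est, by.x = c("from", "to"), by.y = c("rhs", "lhs"))
  expect_equal(nrow(merged), 16)
  expect_lt(max(abs(merged$coef - merged$std)), 0.02)
  # residual covariances recovered too (standardized solution)
  rc <- painpath:::default_residual_covariances()
  for (i in seq_len(nrow(rc))) {
    row <- f$estimates$type == "psi" &
      ((f$estimates$lhs == rc$a[i] & f$estimates$rhs == rc$b[i]) |
         (f$estimates$lhs == rc$b[i] & f$estimates$rhs == rc$a[i]))
    expect_lt(abs(f$estimates$std[row] - rc$value[i]), 0.02)
  }
})

test_that("parameter recovery error shrinks across seeds", {
  gm <- default_generating_model()
  truth <- painpath:::default_path_coefficients()
  errs <- vapply(1:5, function(r) {
    co <- standardize(simulate_cohort(gm, 20000, seed = 60 + r))$table
    f <- fit_path_model(gm$model$graph, co)
    est <- f$estimates[f$estimates$type == "beta", ]
    merged <- merge(truth, est, by.x = c("from", "to"), by.y = c("rhs", "lhs"))
    mean(abs(merged$coef - merged$std))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("Heywood-prone and non-converged fits are flagged not hidden", {
  # tiny n with many parameters triggers the sample-size guard
  d <- chain3_data(5, seed = 55)
  expect_error(fit_path_model(chain3_dag(), d[1:4, ]), "more observations")
})

test_that("Bollen-Stine transform reproduces the implied covariance exactly", {
  d <- chain3_data(300, seed = 56)
  g <- chain3_dag()
  f <- fit_path_model(g, d, residual_pairs = "none")
  Xc <- scale(d, scale = FALSE)
  A <- painpath:::sym_sqrt(cov(d), inverse = TRUE) %*%
    painpath:::sym_sqrt(f$Sigma)
  expect_lt(max(abs(cov(Xc %*% A) - f$Sigma)), 1e-10)
})

test_that("Bollen-Stine bootstrap is deterministic and calibrated", {
  d <- chain3_data(300, seed = 57)
  g <- chain3_dag()
  f <- fit_path_model(g, d, residual_pairs = "none")
  b1 <- bollen_stine(d, f, B = 99, seed = 3)
  b2 <- bollen_stine(d, f, B = 99, seed = 3)
  expect_identical(b1$p_value, b2$p_value)
  expect_identical(b1$estimates$se, b2$estimates$se)
  expect_equal(b1$n_fail, 0)
  # CIs bracket the estimates
  expect_true(all(b1$estimates$ci_lower <= b1$estimates$est + 1e-12))
  expect_true(all(b1$estimates$ci_upper >= b1$estimates$est - 1e-12))
  # a strong real path is significant; the model itself is not rejected
  est <- b1$estimates
  expect_lt(est$pval[est$type == "beta" & est$lhs == "y"], 0.01)
  expect_gt(b1$p_value, 0.01)
})

test_that("the test-statistic multiplier convention is configurable", {
  d <- chain3_data(250, seed = 58)
  g <- chain3_dag()
  f1 <- fit_path_model(g, d, residual_pairs = "none")
  f2 <- fit_path_model(g, d, residual_pairs = "none", multiplier = 250)
  expect_equal(f2$statistic / f1$statistic, 250 / 249, tolerance = 1e-10)
})
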