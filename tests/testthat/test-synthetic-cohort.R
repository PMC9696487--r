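test_that("default generating model reproduces the fitted standardized solution", {
  gm <- default_generating_model()
  expect_equal(nrow(gm$model$graph$arcs), 16)
  # unit implied variance at every node, by construction
  sig <- implied_covariance(gm$model)
  expect_lt(max(abs(diag(sig) - 1)), 1e-10)
  # completed residual variances agree with the reported solution
  printed <- c(Pain = 0.942, Anx = 0.968, Dep = 0.445, Sleep = 0.845,
               PainDETECT = 0.835, "S-LANSS" = 0.764, CSI = 0.591,
               Catastrop = 0.565, Fear = 0.790, "EQ-5D" = 0.907)
  for (v in names(printed)) {
    expect_lt(abs(gm$model$Psi[v, v] - printed[v]), 1e-3)
  }
  expect_equal(gm$model$Psi["BMI", "Sex"], 0.073)
  # no arcs into the exogenous variables
  expect_false(any(gm$model$graph$arcs[, 2] %in% c("BMI", "Sex")))
  expect_error(default_generating_model(missing_rate = 0.2), "0.05")
})

test_that("simulation is deterministic, seed-sensitive, and n = 0 works", {
  gm <- default_generating_model()
  a <- simulate_cohort(gm, 50, seed = 3)
  b <- simulate_cohort(gm, 50, seed = 3)
  c <- simulate_cohort(gm, 50, seed = 4)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  empty <- simulate_cohort(gm, 0, seed = 1)
  expect_equal(nrow(empty$data), 0)
  expect_equal(names(empty$data), gm$schema$name)
  expect_error(simulate_cohort(gm, -1), ">= 0")
  expect_true(all(a$data$Sex %in% c(0, 1)))
})

test_that("raw scales match the cohort descriptives at large n", {
  gm <- default_generating_model()
  co <- simulate_cohort(gm, 100000, seed = 11)
  expect_lt(abs(mean(co$data$Pain) - 5.6), 0.05)
  expect_lt(abs(sd(co$data$Pain) - 1.7), 0.05)
  expect_lt(abs(mean(co$data$Sex == 0) - 0.545), 0.01) # female fraction
  expect_lt(abs(mean(co$data$BMI) - 29.25), 0.1)
  expect_lt(abs(sd(co$data$BMI) - 5.2), 0.1)
})

test_that("simulated covariance converges to the implied covariance", {
  gm <- default_generating_model()
  co <- simulate_cohort(gm, 200000, seed = 12, standardized = TRUE)
  Z <- as.matrix(co$data)
  p_male <- 1 - 0.545
  Z[, "Sex"] <- (Z[, "Sex"] - p_male) / sqrt(p_male * (1 - p_male))
  emp <- cov(Z)[gm$model$nodes, gm$model$nodes]
  sig <- implied_covariance(gm$model)
  expect_lt(max(abs(emp - sig)), 0.01)
  # single-path check: corr(Anx, Dep) ~ 0.745
  expect_lt(abs(cor(Z[, "Anx"], Z[, "Dep"]) - 0.745), 0.01)
})

test_that("a nulled model yields uncorrelated variables", {
  gm <- default_generating_model()
  zero <- gm
  zero$model$B[] <- 0
  off <- zero$model$Psi
  off[] <- 0
  diag(off) <- 1
  dimnames(off) <- dimnames(gm$model$Psi)
  zero$model$Psi <- off
  co <- simulate_cohort(zero, 100000, seed = 13, standardized = TRUE)
  Z <- as.matrix(co$data)
  Z[, "Sex"] <- scale(Z[, "Sex"])
  cc <- cor(Z)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
})

test_that("clipping respects instrument bounds", {
  gm <- default_generating_model()
  co <- simulate_cohort(gm, 5000, seed = 14, clip = TRUE)
  sch <- gm$schema
  for (v in sch$name[sch$kind == "continuous"]) {
    expect_true(all(co$data[[v]] >= sch$scale_min[sch$name == v]))
    expect_true(all(co$data[[v]] <= sch$scale_max[sch$name == v]))
  }
})

test_that("missingness injection is MCAR at the requested rate", {
  gm <- default_generating_model()
  co <- simulate_cohort(gm, 146, seed = 2)
  expect_identical(inject_missingness(co, 0, seed = 1)$data, co$data)
  m <- inject_missingness(co, 0.03, seed = 5)
  # Sex and BMI never masked
  expect_false(anyNA(m$data$Sex))
  expect_false(anyNA(m$data$BMI))
  n_miss <- sum(is.na(m$data))
  # Binomial(1460, 0.03) 99% bounds
  bounds <- qbinom(c(0.005, 0.995), 146 * 10, 0.03)
  expect_gte(n_miss, bounds[1])
  expect_lte(n_miss, bounds[2])
  # observed values unchanged
  keep <- !is.na(m$data$CSI)
  expect_identical(m$data$CSI[keep], co$data$CSI[keep])
  expect_error(inject_missingness(co, 1.2), "rate")
})
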