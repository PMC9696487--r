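# Independent likelihood oracle: Gaussian log-likelihood of node ~ parents
# via lm(), penalised the same way.
bic_oracle <- function(X, node, parents) {
  df <- as.data.frame(X)
  n <- nrow(df)
  fml <- if (length(parents) == 0) {
    stats::reformulate("1", response = node)
  } else {
    stats::reformulate(parents, response = node)
  }
  fit <- stats::lm(fml, data = df)
  sigma2 <- sum(stats::residuals(fit)^2) / n
  logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
  logL - ((length(parents) + 2) / 2) * log(n)
}

test_that("node score matches the closed-form Gaussian likelihood", {
  x <- matrix(c(-1, 0, 1), dimnames = list(NULL, "x"))
  got <- node_bic(x, "x")
  oracle <- -(3 / 2) * (log(2 * pi * 2 / 3) + 1) - log(3)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("node score equals the brute-force regression likelihood", {
  set.seed(21)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  X[, "d"] <- 0.5 * X[, "a"] - 0.3 * X[, "b"] + X[, "d"]
  for (pa in list(character(0), "a", c("a", "b"), c("a", "b", "c"))) {
    expect_equal(node_bic(X, "d", pa), bic_oracle(X, "d", pa),
                 tolerance = 1e-8)
  }
})

test_that("degenerate residuals and singular designs are guarded", {
  set.seed(22)
  x <- rnorm(50)
  X <- cbind(x = x, y = x, z = rnorm(50)) # y identical to x
  expect_identical(node_bic(X, "y", "x"), -Inf)
  X2 <- cbind(a = x, b = 2 * x, c = rnorm(50))
  expect_error(node_bic(X2, "c", c("a", "b")), "singular")
})

test_that("the network score is decomposable", {
  set.seed(23)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  g0 <- dag(c("a", "b", "c"))
  expect_equal(network_score(X, g0),
               sum(vapply(c("a", "b", "c"), function(v) node_bic(X, v),
                          numeric(1))), tolerance = 1e-10)
  g1 <- dag(c("a", "b", "c"), rbind(c("a", "b")))
  expect_equal(network_score(X, g1) - network_score(X, g0),
               node_bic(X, "b", "a") - node_bic(X, "b"), tolerance = 1e-10)
  # matches a brute-force sum of lm likelihoods on a non-trivial DAG
  g2 <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  oracle <- bic_oracle(X, "a", character(0)) + bic_oracle(X, "b", "a") +
    bic_oracle(X, "c", c("a", "b"))
  expect_equal(network_score(X, g2), oracle, tolerance = 1e-8)
})

test_that("hill climbing attains the exhaustive-search optimum on 3 nodes", {
  nodes <- c("A", "B", "C")
  dags <- all_dags_3(nodes)
  expect_length(dags, 25)
  for (r in 1:3) {
    set.seed(30 + r)
    n <- 5000
    A <- rnorm(n)
    B <- 0.8 * A + rnorm(n)
    C <- 0.8 * B + rnorm(n)
    X <- cbind(A = A, B = B, C = C)
    learned <- hill_climb(X)
    best <- max(vapply(dags, function(g) network_score(X, g), numeric(1)))
    expect_equal(network_score(X, learned), best, tolerance = 1e-8)
    # the learned skeleton is the chain's skeleton
    skel <- sort(apply(learned$arcs, 1,
                       function(a) paste(sort(a), collapse = "-")))
    expect_identical(skel, c("A-B", "B-C"))
  }
})

test_that("independent noise yields the empty DAG", {
  set.seed(35)
  X <- matrix(rnorm(15000), 5000, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(nrow(hill_climb(X)$arcs), 0)
})

test_that("hill climbing respects blacklists and never regresses the score", {
  set.seed(36)
  n <- 2000
  A <- rnorm(n)
  B <- 0.7 * A + rnorm(n)
  C <- 0.5 * B + rnorm(n)
  X <- cbind(A = A, B = B, C = C)
  cons <- default_constraints(c("A", "B", "C"), into = "A")
  g <- hill_climb(X, cons)
  expect_false(any(g$arcs[, 2] == "A"))
  expect_gte(network_score(X, g), network_score(X, dag(c("A", "B", "C"))))
})

test_that("whitelisted arcs are kept from the start graph onward", {
  set.seed(37)
  X <- matrix(rnorm(9000), 3000, 3, dimnames = list(NULL, c("a", "b", "c")))
  cons <- constraint_set(whitelist = rbind(c("a", "b")))
  g <- hill_climb(X, cons)
  expect_true(any(g$arcs[, 1] == "a" & g$arcs[, 2] == "b"))
})

test_that("bootstrap strengths find dominant dependence and are reproducible", {
  set.seed(40)
  x <- rnorm(1000)
  y <- x + rnorm(1000, sd = 0.01)
  X <- cbind(x = x, y = y)
  st <- bootstrap_strength(X, B = 50, seed = 2)
  expect_equal(st$presence[st$from == "x" & st$to == "y"], 1.0)
  st2 <- bootstrap_strength(X, B = 50, seed = 2)
  expect_identical(as.data.frame(st), as.data.frame(st2))
  # independent noise: all presences low
  set.seed(41)
  N <- matrix(rnorm(3000), 1000, 3, dimnames = list(NULL, c("a", "b", "c")))
  stn <- bootstrap_strength(N, B = 50, seed = 3)
  expect_true(all(stn$presence < 0.5))
})

test_that("averaged network thresholds, orients, and repairs cycles", {
  skeleton <- data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
                         presence = c(0.9, 0.9, 0.71),
                         direction = c(0.8, 0.9, 0.1),
                         stringsAsFactors = FALSE)
  st <- structure(skeleton, B = 100, nodes = c("a", "b", "c"),
                  constraints = constraint_set(),
                  class = c("painpath_arc_strength", "data.frame"))
  # below threshold: empty
  low <- st
  low$presence <- c(0.5, 0.6, 0.7) # 0.70 is NOT > 0.70
  expect_equal(nrow(averaged_network(low, 0.7)$arcs), 0)
  # direction 0.8 keeps a -> b; 0.1 flips a-c to c -> a: cycle a->b->c->a
  g <- averaged_network(st, 0.7)
  # the weakest arc of the cycle (presence 0.71) was dropped
  expect_equal(nrow(g$arcs), 2)
  expect_false(any(g$arcs[, 1] == "c" & g$arcs[, 2] == "a"))
  expect_error(averaged_network(st, 1.2), "threshold")
})

test_that("the consensus skeleton recovers the generating network", {
  gm <- default_generating_model()
  # zero the sink residual covariances: pure recursive truth
  pm <- gm$model
  sinks <- c("Pain", "S-LANSS", "Catastrop", "EQ-5D")
  keep_diag <- diag(pm$Psi)[sinks]
  pm$Psi[sinks, sinks] <- 0
  diag(pm$Psi)[sinks] <- keep_diag
  gm$model <- pm
  co <- standardize(simulate_cohort(gm, 10000, seed = 11))$table
  st <- bootstrap_strength(co, default_constraints(co$schema$name),
                           B = 200, seed = 12)
  av <- averaged_network(st, 0.7)
  expect_false(any(av$arcs[, 2] %in% c("BMI", "Sex")))
  truth <- dag(gm$schema$name,
               as.matrix(gm$model$graph$arcs))
  skel <- function(arcs) unique(apply(arcs, 1,
                                      function(r) paste(sort(r), collapse = "~")))
  ts <- skel(truth$arcs)
  ls <- skel(av$arcs)
  tp <- length(intersect(ts, ls))
  f1 <- 2 * tp / (length(ts) + length(ls))
  expect_gt(f1, 0.8)
})
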