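#' Observed-variable path-analysis structural equation models
#'
#' A path model over p observed variables is the recursive linear system
#' x = B x + e with strictly lower-triangular coefficient matrix B
#' (under a topological order of the model DAG) and residual/exogenous
#' covariance Psi, implying Sigma = (I - B)^-1 Psi (I - B)^-T. The
#' exogenous block of Psi holds the (co)variances of the parentless
#' variables; free off-diagonals of the endogenous block are declared
#' residual covariances.
#'
#' @param graph A `painpath_dag`.
#' @param coef Data frame (`from`, `to`, `coef`) giving the path
#'   coefficient of every DAG arc.
#' @param psi Full p-by-p residual/exogenous covariance matrix with
#'   dimnames matching the nodes.
#' @param resid_pairs Optional two-column matrix/data frame of node
#'   pairs whose residual covariance is a declared free parameter.
#' @return An object of class `painpath_path_model` with elements
#'   `nodes` (topological order), `graph`, `B`, `Psi`, `resid_pairs`,
#'   `exo` (parentless nodes).
#' @export
path_model <- function(graph, coef, psi, resid_pairs = NULL) {
  stopifnot(inherits(graph, "painpath_dag"))
  nodes <- topological_order(graph)
  p <- length(nodes)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  coef <- as.data.frame(coef, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(coef))) {
    if (!has_arc(graph, coef$from[i], coef$to[i])) {
      stop("coefficient given for absent arc ", coef$from[i], " -> ", coef$to[i])
    }
    B[coef$to[i], coef$from[i]] <- coef$coef[i]
  }
  if (nrow(coef) != nrow(graph$arcs)) {
    stop("every DAG arc needs exactly one coefficient")
  }
  psi <- psi[nodes, nodes]
  if (max(abs(psi - t(psi))) > 1e-10) stop("Psi must be symmetric")
  if (any(diag(psi) <= 0)) stop("Psi diagonal must be strictly positive")
  parents <- dag_parents(graph)
  exo <- nodes[vapply(parents[nodes], length, integer(1)) == 0]
  m <- structure(list(nodes = nodes, graph = graph, B = B, Psi = psi,
                      resid_pairs = as_arc_matrix(resid_pairs), exo = exo),
                 class = "painpath_path_model")
  sig <- implied_covariance(m)
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("implied covariance is not positive definite")
  m
}

#' @export
print.painpath_path_model <- function(x, ...) {
  cat("path model:", length(x$nodes), "variables,",
      nrow(x$graph$arcs), "paths,", nrow(x$resid_pairs),
      "free residual covariances\n")
  invisible(x)
}

#' Model-implied covariance matrix
#'
#' @param model A `painpath_path_model`.
#' @return The p-by-p matrix (I - B)^-1 Psi (I - B)^-T, symmetrized.
#' @export
implied_covariance <- function(model) {
  stopifnot(inherits(model, "painpath_path_model"))
  sigma_from_B_psi(model$B, model$Psi)
}

sigma_from_B_psi <- function(B, Psi) {
  p <- nrow(B)
  IB <- diag(p) - B
  # recursive models: I - B unit lower triangular in topological order,
  # always invertible
  inv <- backsolve(IB, diag(p), upper.tri = FALSE)
  sig <- inv %*% Psi %*% t(inv)
  sig <- (sig + t(sig)) / 2
  dimnames(sig) <- dimnames(B)
  sig
}

#' Complete residual variances for a standardized solution
#'
#' Given path coefficients on standardized variables, exogenous moments,
#' and any declared residual covariances, fills in each endogenous
#' residual variance (in topological order) so that every variable's
#' implied total variance is exactly 1. This reconstructs the residual
#' variances of a fully standardized fitted solution from its
#' coefficients alone.
#'
#' @param B Coefficient matrix (`B[child, parent]`) with dimnames; rows
#'   ordered topologically (parentless variables first).
#' @param exo_cov Covariance matrix of the parentless variables
#'   (defaults to the identity, i.e. uncorrelated unit-variance
#'   exogenous variables).
#' @param resid_cov Optional data frame (`a`, `b`, `value`) of declared
#'   residual covariances between endogenous variables.
#' @return The completed Psi matrix.
#' @export
complete_standardized_residuals <- function(B, exo_cov = NULL, resid_cov = NULL) {
  nodes <- rownames(B)
  p <- length(nodes)
  has_parent <- rowSums(B != 0) > 0
  exo <- nodes[!has_parent]
  Psi <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (is.null(exo_cov)) exo_cov <- diag(length(exo))
  dimnames(exo_cov) <- list(exo, exo)
  Psi[exo, exo] <- exo_cov
  if (!is.null(resid_cov)) {
    for (i in seq_len(nrow(resid_cov))) {
      Psi[resid_cov$a[i], resid_cov$b[i]] <- resid_cov$value[i]
      Psi[resid_cov$b[i], resid_cov$a[i]] <- resid_cov$value[i]
    }
  }
  for (v in nodes[has_parent]) {
    sig <- sigma_from_B_psi(B, Psi)
    resid <- 1 - sig[v, v]
    if (resid <= 0) {
      stop("infeasible standardized model: structural variance of '", v,
           "' is >= 1")
    }
    Psi[v, v] <- resid
  }
  Psi
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' @param S Sample covariance matrix (symmetric positive definite).
#' @param Sigma Implied covariance matrix (same dimension).
#' @return `log|Sigma| + tr(S Sigma^-1) - log|S| - p`; zero iff
#'   `Sigma == S`.
#' @export
ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  stopifnot(nrow(Sigma) == p)
  cS <- tryCatch(chol(S), error = function(e) stop("S is not positive definite"))
  cSig <- tryCatch(chol(Sigma),
                   error = function(e) stop("Sigma is not positive definite"))
  ldS <- 2 * sum(log(diag(cS)))
  ldSig <- 2 * sum(log(diag(cSig)))
  tr <- sum(diag(chol2inv(cSig) %*% S))
  ldSig + tr - ldS - p
}

# ---------------------------------------------------------------------------
# ML fitting

# Free-parameter template for a DAG + declared residual-covariance pairs.
par_template <- function(graph, resid_pairs) {
  nodes <- topological_order(graph)
  parents <- dag_parents(graph)
  exo <- nodes[vapply(parents[nodes], length, integer(1)) == 0]
  endo <- setdiff(nodes, exo)
  rows <- list()
  for (v in nodes) {
    for (pa in parents[[v]]) {
      rows[[length(rows) + 1]] <- data.frame(type = "beta", lhs = v, rhs = pa,
                                             stringsAsFactors = FALSE)
    }
  }
  for (v in endo) {
    rows[[length(rows) + 1]] <- data.frame(type = "psi", lhs = v, rhs = v,
                                           stringsAsFactors = FALSE)
  }
  rp <- as_arc_matrix(resid_pairs)
  for (i in seq_len(nrow(rp))) {
    a <- rp[i, 1]; b <- rp[i, 2]
    if (!all(c(a, b) %in% endo)) {
      stop("residual covariance declared for non-endogenous pair ", a, "--", b)
    }
    rows[[length(rows) + 1]] <- data.frame(type = "psi", lhs = a, rhs = b,
                                           stringsAsFactors = FALSE)
  }
  list(template = do.call(rbind, rows), nodes = nodes, exo = exo, endo = endo,
       parents = parents, resid_pairs = rp)
}

theta_to_matrices <- function(theta, tm, Psi_exo) {
  nodes <- tm$nodes
  p <- length(nodes)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Psi <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Psi[tm$exo, tm$exo] <- Psi_exo
  tt <- tm$template
  for (k in seq_len(nrow(tt))) {
    if (tt$type[k] == "beta") {
      B[tt$lhs[k], tt$rhs[k]] <- theta[k]
    } else {
      Psi[tt$lhs[k], tt$rhs[k]] <- theta[k]
      Psi[tt$rhs[k], tt$lhs[k]] <- theta[k]
    }
  }
  list(B = B, Psi = Psi)
}

# Equation-by-equation least squares on the sample covariance; the ML
# solution for recursive models with uncorrelated residuals, and the
# warm start otherwise.
ols_start <- function(S, X, tm) {
  tt <- tm$template
  theta <- numeric(nrow(tt))
  n <- nrow(X)
  Xc <- X - matrix(colMeans(X), n, ncol(X), byrow = TRUE,
                   dimnames = dimnames(X))
  res <- Xc
  for (v in tm$endo) {
    pa <- tm$parents[[v]]
    if (length(pa) > 0) {
      b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
      res[, v] <- Xc[, v] - Xc[, pa, drop = FALSE] %*% b
      for (j in seq_along(pa)) {
        theta[tt$type == "beta" & tt$lhs == v & tt$rhs == pa[j]] <- b[j]
      }
    }
  }
  rc <- crossprod(res) / (n - 1)
  for (k in which(tt$type == "psi")) {
    theta[k] <- rc[tt$lhs[k], tt$rhs[k]]
  }
  theta
}

num_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Fit a path model to data by maximum likelihood
#'
#' Free parameters are one coefficient per DAG arc, one residual
#' variance per endogenous variable, and one residual covariance per
#' declared pair; the moments of the parentless (exogenous) variables
#' are fixed at their sample values and excluded from the free-parameter
#' count. The ML discrepancy between the sample covariance S (n - 1
#' denominator) and the implied covariance is minimised by BFGS from an
#' equation-wise least-squares warm start; for models with no residual
#' covariances that warm start is already the ML solution and can be
#' returned directly (`method = "ols"`).
#'
#' @param graph A `painpath_dag` giving the structural model.
#' @param data A standardized `cohort_table`, data frame, or numeric
#'   matrix containing all graph nodes as columns.
#' @param residual_pairs `"sinks"` (default) frees the residual
#'   covariances of every pair of endogenous sink variables (out-degree
#'   0); `"none"` frees none; or a two-column matrix/data frame of
#'   pairs.
#' @param method `"auto"` (OLS when no residual covariances are free,
#'   BFGS otherwise), `"ols"`, or `"optim"`.
#' @param multiplier Test-statistic multiplier: `T = multiplier * F`.
#'   Default `n - 1` (Wishart likelihood convention); set to `n` to
#'   cross-check against tools using that convention.
#' @param start Optional numeric start vector (e.g. from a previous fit)
#'   for bootstrap refits.
#' @return An object of class `painpath_sem_fit`: estimates table (with
#'   a fully standardized solution column `std`), sample and implied
#'   covariances, discrepancy `F`, statistic `T`, degrees of freedom,
#'   convergence diagnostics and a Heywood-case flag. Standard errors,
#'   CIs and p-values are added by [bollen_stine()].
#' @export
fit_path_model <- function(graph, data, residual_pairs = "sinks",
                           method = c("auto", "ols", "optim"),
                           multiplier = NULL, start = NULL) {
  method <- match.arg(method)
  X <- data_matrix(data, graph$nodes)
  n <- nrow(X)
  tm <- par_template(graph, resolve_resid_pairs(graph, residual_pairs))
  if (n <= nrow(tm$template)) {
    stop("need more observations than free parameters")
  }
  S <- stats::cov(X)
  if (is.null(multiplier)) multiplier <- n - 1
  p <- length(tm$nodes)
  S <- S[tm$nodes, tm$nodes]
  Psi_exo <- S[tm$exo, tm$exo, drop = FALSE]
  has_cov <- any(tm$template$type == "psi" & tm$template$lhs != tm$template$rhs)
  theta0 <- if (is.null(start)) ols_start(S, X, tm) else start

  objective <- function(theta) {
    mats <- theta_to_matrices(theta, tm, Psi_exo)
    sig <- sigma_from_B_psi(mats$B, mats$Psi)
    cSig <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(cSig)) return(1e10)
    2 * sum(log(diag(cSig))) + sum(chol2inv(cSig) * S)
  }
  # analytic gradient: dF/dSigma = Sigma^-1 (Sigma - S) Sigma^-1, chained
  # through Sigma = (I - B)^-1 Psi (I - B)^-T
  gradient <- function(theta) {
    mats <- theta_to_matrices(theta, tm, Psi_exo)
    pmat <- nrow(mats$B)
    G <- backsolve(diag(pmat) - mats$B, diag(pmat), upper.tri = FALSE)
    dimnames(G) <- dimnames(mats$B)
    sig <- G %*% mats$Psi %*% t(G)
    cSig <- tryCatch(chol((sig + t(sig)) / 2), error = function(e) NULL)
    if (is.null(cSig)) return(numeric(length(theta)))
    Siginv <- chol2inv(cSig)
    W <- Siginv %*% (sig - S[tm$nodes, tm$nodes]) %*% Siginv
    A1 <- sig %*% W %*% G
    A2 <- t(G) %*% W %*% G
    tt <- tm$template
    vapply(seq_len(nrow(tt)), function(k) {
      i <- match(tt$lhs[k], tm$nodes)
      j <- match(tt$rhs[k], tm$nodes)
      if (tt$type[k] == "beta") {
        2 * A1[j, i]
      } else if (i == j) {
        A2[i, i]
      } else {
        2 * A2[i, j]
      }
    }, numeric(1))
  }
  const <- -as.numeric(determinant(S, logarithm = TRUE)$modulus) - p

  use_ols <- method == "ols" || (method == "auto" && !has_cov)
  if (use_ols) {
    theta_hat <- ols_start(S, X, tm)
    converged <- TRUE
    grad_norm <- NA_real_
  } else {
    opt <- stats::optim(theta0, objective, gradient, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    theta_hat <- opt$par
    grad_norm <- sqrt(sum(gradient(theta_hat)^2))
    converged <- opt$convergence == 0 || grad_norm < 1e-6
    if (!converged) {
      warning("ML fit did not converge (gradient norm ", signif(grad_norm, 3),
              ")")
    }
  }
  mats <- theta_to_matrices(theta_hat, tm, Psi_exo)
  sigma_hat <- sigma_from_B_psi(mats$B, mats$Psi)
  Fhat <- max(objective(theta_hat) + const, 0)
  nfree <- nrow(tm$template)
  nexo <- length(tm$exo) * (length(tm$exo) + 1) / 2
  df <- p * (p + 1) / 2 - nfree - nexo
  heywood <- any(diag(mats$Psi)[tm$endo] < 0)
  if (heywood) warning("Heywood case: negative residual variance estimate")

  est <- tm$template
  est$est <- theta_hat
  sdv <- sqrt(diag(sigma_hat))
  est$std <- ifelse(est$type == "beta",
                    est$est * sdv[est$rhs] / sdv[est$lhs],
                    est$est / (sdv[est$lhs] * sdv[est$rhs]))
  structure(list(nodes = tm$nodes, graph = graph, estimates = est,
                 B = mats$B, Psi = mats$Psi, S = S, Sigma = sigma_hat,
                 discrepancy = Fhat, statistic = multiplier * Fhat, df = df,
                 n = n, multiplier = multiplier, exo = tm$exo,
                 resid_pairs = tm$resid_pairs, converged = converged,
                 grad_norm = grad_norm, heywood = heywood,
                 theta = theta_hat),
            class = "painpath_sem_fit")
}

resolve_resid_pairs <- function(graph, residual_pairs) {
  if (is.character(residual_pairs) && length(residual_pairs) == 1) {
    if (residual_pairs == "none") return(NULL)
    if (residual_pairs == "sinks") {
      parents <- dag_parents(graph)
      endo <- graph$nodes[vapply(parents[graph$nodes], length, integer(1)) > 0]
      sinks <- endo[!(endo %in% graph$arcs[, 1])]
      sinks <- sinks[order(match(sinks, graph$nodes))]
      if (length(sinks) < 2) return(NULL)
      idx <- utils::combn(length(sinks), 2)
      return(cbind(sinks[idx[1, ]], sinks[idx[2, ]]))
    }
    stop("unknown residual_pairs policy '", residual_pairs, "'")
  }
  residual_pairs
}

data_matrix <- function(data, nodes) {
  if (inherits(data, "cohort_table")) data <- data$data
  if (is.data.frame(data)) data <- as.matrix(data[, , drop = FALSE])
  missing_vars <- setdiff(nodes, colnames(data))
  if (length(missing_vars) > 0) {
    stop("data lacks variable(s): ", paste(missing_vars, collapse = ", "))
  }
  X <- data[, nodes, drop = FALSE]
  if (anyNA(X)) stop("data contains missing values; impute first")
  storage.mode(X) <- "double"
  X
}

#' @export
print.painpath_sem_fit <- function(x, ...) {
  cat(sprintf("path-model fit: %d variables, %d free parameters, df = %d\n",
              length(x$nodes), length(x$theta), x$df))
  cat(sprintf("  F = %.6g, T = %.4g (n = %d)\n", x$discrepancy, x$statistic,
              x$n))
  invisible(x)
}

#' Fit indices for a fitted path model
#'
#' Computes RMSEA, CFI, NNFI (TLI) and SRMR against the independence
#' baseline (diagonal implied covariance at the sample variances). NNFI
#' is deliberately not capped at 1. With `df = 0`, RMSEA and NNFI are
#' undefined and reported as `NA`.
#'
#' @param fit A `painpath_sem_fit`.
#' @return A list with `rmsea`, `cfi`, `nnfi`, `srmr`, `baseline_stat`,
#'   `baseline_df`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "painpath_sem_fit"))
  S <- fit$S
  p <- nrow(S)
  T_ <- fit$statistic
  df <- fit$df
  mult <- fit$multiplier
  F_b <- sum(log(diag(S))) -
    as.numeric(determinant(S, logarithm = TRUE)$modulus)
  T_b <- mult * F_b
  df_b <- p * (p - 1) / 2
  rmsea <- if (df > 0) sqrt(max(T_ - df, 0) / (df * (fit$n - 1))) else NA_real_
  denom <- max(T_b - df_b, T_ - df, 0)
  cfi <- if (denom <= 0) 1 else 1 - max(T_ - df, 0) / denom
  nnfi <- if (df > 0 && df_b > 0) {
    (T_b / df_b - T_ / df) / (T_b / df_b - 1)
  } else NA_real_
  d <- sqrt(diag(S))
  R <- (S - fit$Sigma) / tcrossprod(d)
  srmr <- sqrt(sum(R[upper.tri(R, diag = TRUE)]^2) / (p * (p + 1) / 2))
  list(rmsea = rmsea, cfi = cfi, nnfi = nnfi, srmr = srmr,
       baseline_stat = T_b, baseline_df = df_b)
}

# Symmetric matrix square root (and inverse root) via eigendecomposition.
sym_sqrt <- function(M, inverse = FALSE) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  pw <- if (inverse) -0.5 else 0.5
  e$vectors %*% (vals^pw * t(e$vectors))
}

#' Bollen-Stine bootstrap for a fitted path model
#'
#' Transforms the centred data X to X S^-1/2 Sigma-hat^1/2 so that the
#' fitted model holds exactly in the resampling population, then draws B
#' nonparametric row resamples, refits each, and reports (i) a bootstrap
#' p-value for the model test statistic, `p = (#\{T* >= T\} + 1)/(B + 1)`,
#' and (ii) bootstrap standard errors, percentile 95% CIs and normal
#' (Wald) p-values for every free parameter, on both the raw and the
#' fully standardized solution.
#'
#' @param data The data the model was fitted to.
#' @param fit A `painpath_sem_fit`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return A `painpath_sem_boot` list: `estimates` (the fit's table
#'   augmented with `se`, `ci_lower`, `ci_upper`, `pval` and
#'   standardized counterparts), `p_value` for the test statistic,
#'   `boot_T`, `B`, `n_fail`, and the original `fit`.
#' @export
bollen_stine <- function(data, fit, B = 1000, seed = 1) {
  stopifnot(inherits(fit, "painpath_sem_fit"), B >= 1)
  X <- data_matrix(data, fit$nodes)
  n <- nrow(X)
  Xc <- X - matrix(colMeans(X), n, ncol(X), byrow = TRUE)
  A <- sym_sqrt(stats::cov(X)[fit$nodes, fit$nodes], inverse = TRUE) %*%
    sym_sqrt(fit$Sigma)
  Y <- Xc %*% A
  colnames(Y) <- fit$nodes
  set.seed(seed)
  npar <- length(fit$theta)
  Tstar <- rep(NA_real_, B)
  est_raw <- matrix(NA_real_, B, npar)
  est_std <- matrix(NA_real_, B, npar)
  n_fail <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rf <- tryCatch(
      suppressWarnings(
        fit_path_model(fit$graph, Y[idx, , drop = FALSE],
                       residual_pairs = fit$resid_pairs,
                       multiplier = fit$multiplier, start = fit$theta)),
      error = function(e) NULL)
    if (is.null(rf)) { n_fail <- n_fail + 1; next }
    Tstar[b] <- rf$statistic
    est_raw[b, ] <- rf$estimates$est
    est_std[b, ] <- rf$estimates$std
  }
  if (n_fail > 0.1 * B) {
    stop("more than 10% of bootstrap refits failed (", n_fail, " of ", B, ")")
  }
  ok <- !is.na(Tstar)
  est <- fit$estimates
  est$se <- apply(est_raw[ok, , drop = FALSE], 2, stats::sd)
  ci <- apply(est_raw[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  est$ci_lower <- ci[1, ]
  est$ci_upper <- ci[2, ]
  est$pval <- 2 * stats::pnorm(-abs(est$est / est$se))
  est$std_se <- apply(est_std[ok, , drop = FALSE], 2, stats::sd)
  ci_s <- apply(est_std[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975))
  est$std_ci_lower <- ci_s[1, ]
  est$std_ci_upper <- ci_s[2, ]
  est$std_pval <- 2 * stats::pnorm(-abs(est$std / est$std_se))
  structure(list(estimates = est,
                 p_value = (sum(Tstar[ok] >= fit$statistic) + 1) /
                   (sum(ok) + 1),
                 boot_T = Tstar, B = B, n_fail = n_fail, seed = seed,
                 fit = fit),
            class = "painpath_sem_boot")
}

#' @export
print.painpath_sem_boot <- function(x, ...) {
  cat(sprintf("Bollen-Stine bootstrap: B = %d (%d failed), model p = %.4f\n",
              x$B, x$n_fail, x$p_value))
  invisible(x)
}
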