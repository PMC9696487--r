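#' Multiple imputation by chained equations
#'
#' Variable-by-variable cyclic imputation: missing cells are first
#' filled by random draws from each variable's observed values, then
#' each variable with missing data is re-imputed in schema order from a
#' model on all other variables, for `max_iter` sweeps. The whole chain
#' is repeated independently `m` times from distinct sub-seeds derived
#' from `seed`. Continuous variables are imputed by the chosen method;
#' binary variables by a logistic-regression draw.
#'
#' Methods: `"normal"` draws from the Bayesian linear-regression
#' posterior predictive; `"pmm"` is predictive mean matching on the 5
#' nearest donors; `"random_forest"` (default) grows a 10-tree forest
#' and draws from the observed values sharing the missing case's
#' terminal node in a randomly chosen tree.
#'
#' @param table A `cohort_table` possibly containing `NA`s.
#' @param m Number of completed datasets (default 20).
#' @param max_iter Sweeps per chain (default 30).
#' @param method One of `"random_forest"`, `"normal"`, `"pmm"`.
#' @param seed Integer RNG seed; results are deterministic given `seed`.
#' @return An object of class `painpath_imputation`: `completed` (list
#'   of `m` complete `cohort_table`s), `chain_means` / `chain_sds`
#'   (m x max_iter x variable arrays of imputed-cell summaries for
#'   convergence inspection), and the call settings.
#' @export
impute_chained <- function(table, m = 20, max_iter = 30,
                           method = c("random_forest", "normal", "pmm"),
                           seed = 1) {
  stopifnot(inherits(table, "cohort_table"))
  method <- match.arg(method)
  if (m < 1) stop("m must be >= 1")
  if (max_iter < 1) stop("max_iter must be >= 1")
  sch <- table$schema
  vars <- sch$name
  dat <- table$data[, vars, drop = FALSE]
  miss <- is.na(dat)
  n_obs_per_var <- colSums(!miss)
  if (any(n_obs_per_var == 0)) {
    stop("variable(s) entirely missing: ",
         paste(vars[n_obs_per_var == 0], collapse = ", "))
  }
  has_miss <- vars[colSums(miss) > 0]
  if (length(has_miss) > 0) {
    if (!any(colSums(miss) == 0)) {
      stop("at least one fully observed variable is required")
    }
    few <- has_miss[n_obs_per_var[has_miss] < 2]
    if (length(few) > 0) {
      stop("variable(s) with fewer than 2 observed values: ",
           paste(few, collapse = ", "))
    }
  }

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, m)
  chain_means <- array(NA_real_, dim = c(m, max_iter, length(has_miss)),
                       dimnames = list(NULL, NULL, has_miss))
  chain_sds <- chain_means
  completed <- vector("list", m)

  for (k in seq_len(m)) {
    if (length(has_miss) == 0) {
      completed[[k]] <- table
      next
    }
    set.seed(sub_seeds[k])
    filled <- dat
    for (v in has_miss) {
      obs <- dat[[v]][!miss[, v]]
      filled[[v]][miss[, v]] <- obs[sample.int(length(obs),
                                               sum(miss[, v]),
                                               replace = TRUE)]
    }
    for (it in seq_len(max_iter)) {
      for (v in has_miss) {
        preds <- setdiff(vars, v)
        X <- as.matrix(filled[, preds, drop = FALSE])
        ymis_idx <- which(miss[, v])
        yobs_idx <- which(!miss[, v])
        y_obs <- dat[[v]][yobs_idx]
        X_obs <- X[yobs_idx, , drop = FALSE]
        X_mis <- X[ymis_idx, , drop = FALSE]
        kind <- sch$kind[sch$name == v]
        drawn <- if (kind == "binary") {
          imp_logistic(y_obs, X_obs, X_mis)
        } else {
          switch(method,
                 normal = imp_norm(y_obs, X_obs, X_mis),
                 pmm = imp_pmm(y_obs, X_obs, X_mis),
                 random_forest = imp_rf(y_obs, X_obs, X_mis))
        }
        filled[[v]][ymis_idx] <- drawn
        chain_means[k, it, v] <- mean(drawn)
        chain_sds[k, it, v] <- stats::sd(drawn)
      }
    }
    out <- table$data
    out[, vars] <- filled
    completed[[k]] <- cohort_table(out, sch)
  }
  structure(list(completed = completed, chain_means = chain_means,
                 chain_sds = chain_sds, m = m, max_iter = max_iter,
                 method = method, seed = seed),
            class = "painpath_imputation")
}

#' @export
print.painpath_imputation <- function(x, ...) {
  cat(sprintf("chained-equations imputation: m = %d, max_iter = %d, method = %s\n",
              x$m, x$max_iter, x$method))
  invisible(x)
}

#' Select a single completed dataset
#'
#' The downstream analysis operates on one completed dataset (index 1
#' by default) rather than pooling across imputations.
#'
#' @param result A `painpath_imputation`.
#' @param index Which completed table to return, `1 <= index <= m`.
#' @return A complete `cohort_table`.
#' @export
select_imputed <- function(result, index = 1) {
  stopifnot(inherits(result, "painpath_imputation"))
  if (index < 1 || index > result$m) {
    stop("index must be between 1 and m = ", result$m)
  }
  result$completed[[index]]
}

# --- imputation engines -----------------------------------------------------

# Ridge-stabilised least squares pieces shared by norm and pmm.
ls_parts <- function(y_obs, X_obs) {
  X <- cbind(1, X_obs)
  XtX <- crossprod(X)
  XtX <- XtX + diag(1e-6 * pmax(diag(XtX), 1), nrow(XtX))
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% crossprod(X, y_obs)
  rss <- sum((y_obs - X %*% beta)^2)
  list(X = X, beta = beta, XtXinv = XtXinv, rss = rss,
       df = max(length(y_obs) - ncol(X), 1))
}

# Posterior-predictive draw from a Bayesian linear regression.
imp_norm <- function(y_obs, X_obs, X_mis) {
  f <- ls_parts(y_obs, X_obs)
  sigma2 <- f$rss / stats::rchisq(1, f$df)
  beta_draw <- f$beta + t(chol(sigma2 * (f$XtXinv + t(f$XtXinv)) / 2)) %*%
    stats::rnorm(length(f$beta))
  drop(cbind(1, X_mis) %*% beta_draw) +
    stats::rnorm(nrow(X_mis), sd = sqrt(sigma2))
}

# Predictive mean matching with 5 donors.
imp_pmm <- function(y_obs, X_obs, X_mis, donors = 5L) {
  f <- ls_parts(y_obs, X_obs)
  sigma2 <- f$rss / stats::rchisq(1, f$df)
  beta_draw <- f$beta + t(chol(sigma2 * (f$XtXinv + t(f$XtXinv)) / 2)) %*%
    stats::rnorm(length(f$beta))
  yhat_obs <- drop(f$X %*% f$beta)
  yhat_mis <- drop(cbind(1, X_mis) %*% beta_draw)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y_obs[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

# Random-forest imputation: draw from the observed values in the missing
# case's terminal node of a randomly selected tree (10-tree forest).
imp_rf <- function(y_obs, X_obs, X_mis, ntree = 10L) {
  colnames(X_obs) <- colnames(X_mis) <- paste0("x", seq_len(ncol(X_obs)))
  rf <- randomForest::randomForest(x = X_obs, y = y_obs, ntree = ntree)
  nodes_obs <- attr(stats::predict(rf, X_obs, nodes = TRUE), "nodes")
  nodes_mis <- attr(stats::predict(rf, X_mis, nodes = TRUE), "nodes")
  vapply(seq_len(nrow(X_mis)), function(i) {
    tr <- sample.int(ntree, 1)
    donors <- y_obs[nodes_obs[, tr] == nodes_mis[i, tr]]
    if (length(donors) == 0) donors <- y_obs
    donors[sample.int(length(donors), 1)]
  }, numeric(1))
}

# Logistic draw for binary variables.
imp_logistic <- function(y_obs, X_obs, X_mis) {
  if (length(unique(y_obs)) < 2) {
    return(rep(y_obs[1], nrow(X_mis)))
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X_obs), y_obs, family = stats::binomial()))
  pr <- stats::plogis(drop(cbind(1, X_mis) %*% fit$coefficients))
  as.numeric(stats::rbinom(nrow(X_mis), 1, pr))
}
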