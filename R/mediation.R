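#' Default serial mediation chains
#'
#' The four hypothesized indirect pathways examined on the fitted
#' network: anxiety acting on central-sensitization symptoms through
#' depression; depression acting on sleep quality and on catastrophizing
#' through central-sensitization symptoms and kinesiophobia; and sex
#' acting on neuropathic pain features through central-sensitization
#' symptoms and PainDETECT.
#'
#' @return A named list of character vectors (node chains).
#' @export
default_mediation_chains <- function() {
  list(
    anx_dep_csi = c("Anx", "Dep", "CSI"),
    dep_csi_fear_sleep = c("Dep", "CSI", "Fear", "Sleep"),
    sex_csi_pd_slanss = c("Sex", "CSI", "PainDETECT", "S-LANSS"),
    dep_csi_fear_cat = c("Dep", "CSI", "Fear", "Catastrop")
  )
}

# Coefficient lookup for one arc, from a fitted model (standardized or
# raw solution) or a generating/path model.
chain_coefficients <- function(object, chain, standardized = TRUE) {
  if (length(chain) < 3) stop("a mediation chain needs at least 3 nodes")
  if (inherits(object, "painpath_generating_model")) object <- object$model
  if (inherits(object, "painpath_sem_boot")) object <- object$fit
  get_coef <- if (inherits(object, "painpath_sem_fit")) {
    est <- object$estimates
    col <- if (standardized) "std" else "est"
    function(from, to) {
      row <- est$type == "beta" & est$lhs == to & est$rhs == from
      if (!any(row)) return(NULL)
      est[[col]][row]
    }
  } else if (inherits(object, "painpath_path_model")) {
    function(from, to) {
      if (!has_arc(object$graph, from, to)) return(NULL)
      object$B[to, from]
    }
  } else {
    stop("cannot extract path coefficients from class ",
         paste(class(object), collapse = "/"))
  }
  vapply(seq_len(length(chain) - 1), function(i) {
    b <- get_coef(chain[i], chain[i + 1])
    if (is.null(b)) {
      stop("chain arc ", chain[i], " -> ", chain[i + 1],
           " is not in the fitted model")
    }
    b
  }, numeric(1))
}

#' Serial indirect effect by the product of coefficients
#'
#' The indirect effect of the chain's first node on its last node
#' through the listed mediators is the product of the path coefficients
#' of each consecutive arc.
#'
#' @param object A `painpath_sem_fit`, `painpath_sem_boot`,
#'   `painpath_path_model`, or `painpath_generating_model`.
#' @param chain Character vector of node names (start, mediators,
#'   outcome); every consecutive pair must be an arc of the model.
#' @param standardized Use the fully standardized solution (default)
#'   when `object` is a fitted model.
#' @return The scalar indirect effect.
#' @examples
#' gm <- default_generating_model()
#' indirect_effect(gm, c("Anx", "Dep", "CSI")) # 0.745 * 0.119
#' @export
indirect_effect <- function(object, chain, standardized = TRUE) {
  prod(chain_coefficients(object, chain, standardized))
}

#' Bootstrap and delta-method inference for a serial indirect effect
#'
#' Refits the full path model on `B` nonparametric row resamples of the
#' data and recomputes the chain product on each, giving a bootstrap
#' SE, a percentile 95% CI, and a two-sided sign-based p-value
#' `2 (min(#\{<= 0\}, #\{>= 0\}) + 1)/(B + 1)` (capped at 1). A
#' first-order delta-method SE computed from the bootstrap covariance
#' of the chain coefficients is reported alongside.
#'
#' @param data Complete (standardized) data.
#' @param graph The model DAG (`painpath_dag`).
#' @param chain Node chain as in [indirect_effect()].
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @param residual_pairs Passed to [fit_path_model()].
#' @param standardized Use the standardized solution (default).
#' @return A list of class `painpath_mediation`: `chain`, `estimate`,
#'   `se`, `ci_lower`, `ci_upper`, `p_value`, `delta_se`, `B`,
#'   `n_fail`.
#' @export
indirect_effect_inference <- function(data, graph, chain, B = 1000, seed = 1,
                                      residual_pairs = "sinks",
                                      standardized = TRUE) {
  fit <- fit_path_model(graph, data, residual_pairs = residual_pairs)
  est <- indirect_effect(fit, chain, standardized)
  X <- data_matrix(data, graph$nodes)
  n <- nrow(X)
  set.seed(seed)
  ncoef <- length(chain) - 1
  boot_eff <- rep(NA_real_, B)
  boot_coef <- matrix(NA_real_, B, ncoef)
  n_fail <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rf <- tryCatch(
      suppressWarnings(fit_path_model(graph, X[idx, , drop = FALSE],
                                      residual_pairs = fit$resid_pairs,
                                      start = fit$theta)),
      error = function(e) NULL)
    if (is.null(rf)) { n_fail <- n_fail + 1; next }
    cf <- chain_coefficients(rf, chain, standardized)
    boot_coef[b, ] <- cf
    boot_eff[b] <- prod(cf)
  }
  if (n_fail > 0.1 * B) {
    stop("more than 10% of bootstrap refits failed (", n_fail, " of ", B, ")")
  }
  ok <- !is.na(boot_eff)
  eff <- boot_eff[ok]
  ci <- stats::quantile(eff, c(0.025, 0.975))
  pv <- min(1, 2 * (min(sum(eff <= 0), sum(eff >= 0)) + 1) / (sum(ok) + 1))
  # first-order product-variance formula on the chain coefficients
  cf_hat <- chain_coefficients(fit, chain, standardized)
  V <- stats::cov(boot_coef[ok, , drop = FALSE])
  grad <- vapply(seq_len(ncoef), function(k) prod(cf_hat[-k]), numeric(1))
  delta_se <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(chain = chain, estimate = est, se = stats::sd(eff),
                 ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
                 p_value = pv, delta_se = delta_se, B = B, n_fail = n_fail,
                 seed = seed),
            class = "painpath_mediation")
}

#' @export
print.painpath_mediation <- function(x, ...) {
  cat(sprintf("indirect effect %s: %.4f (SE %.4f, 95%% CI [%.4f, %.4f], p = %.4f)\n",
              paste(x$chain, collapse = " -> "), x$estimate, x$se,
              x$ci_lower, x$ci_upper, x$p_value))
  invisible(x)
}
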