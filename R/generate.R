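# Calibration constants for the default generating model: the 16 directed
# paths of the fitted post-COVID pain network with their standardized
# coefficients, the six residual covariances among the sink variables, and
# the BMI-Sex exogenous covariance.
default_path_coefficients <- function() {
  data.frame(
    from = c("BMI", "Dep", "Sex", "Anx", "Dep", "Fear", "CSI", "Sex",
             "PainDETECT", "Sex", "Anx", "Dep", "Dep", "Fear", "CSI", "Sleep"),
    to   = c("Pain", "Pain", "Anx", "Dep", "Sleep", "Sleep", "PainDETECT",
             "S-LANSS", "S-LANSS", "CSI", "CSI", "CSI", "Catastrop",
             "Catastrop", "Fear", "EQ-5D"),
    coef = c(0.015, 0.241, 0.179, 0.745, 0.298, 0.201, 0.406, -0.150,
             0.488, 0.319, 0.406, 0.119, 0.345, 0.494, 0.458, -0.305),
    stringsAsFactors = FALSE
  )
}

default_residual_covariances <- function() {
  data.frame(
    a = c("Pain", "Pain", "Pain", "S-LANSS", "S-LANSS", "Catastrop"),
    b = c("S-LANSS", "Catastrop", "EQ-5D", "Catastrop", "EQ-5D", "EQ-5D"),
    value = c(-0.051, -0.145, 0.047, -0.001, 0.064, -0.085),
    stringsAsFactors = FALSE
  )
}

default_exo_covariance <- function() 0.073

#' Default generating model for synthetic post-COVID pain cohorts
#'
#' Builds the linear-Gaussian recursive path model the synthetic cohort
#' generator draws from: the 16-arc DAG over the 12 cohort variables
#' with its standardized path coefficients, an exogenous covariance of
#' 0.073 between BMI and Sex, free residual covariances among the four
#' sink variables (Pain, S-LANSS, Catastrop, EQ-5D) at their fitted
#' values, and endogenous residual variances completed so that every
#' variable has implied variance exactly 1 (see
#' [complete_standardized_residuals()]).
#'
#' @param schema Variable schema carrying the raw-scale means/SDs and
#'   the cohort female fraction; defaults to [default_schema()].
#' @param missing_rate Default per-cell missingness probability used by
#'   the pipeline when injecting missingness; must lie in `[0, 0.05]`
#'   unless `allow_high_missingness = TRUE`.
#' @param allow_high_missingness Lift the 5% bound check.
#' @return An object of class `painpath_generating_model`: a list with
#'   the `painpath_path_model` (`model`), the `schema`, and
#'   `missing_rate`.
#' @examples
#' gm <- default_generating_model()
#' nrow(gm$model$graph$arcs) # 16 paths
#' @export
default_generating_model <- function(schema = default_schema(),
                                     missing_rate = 0.03,
                                     allow_high_missingness = FALSE) {
  if (missing_rate < 0 || (!allow_high_missingness && missing_rate > 0.05)) {
    stop("missing_rate must be in [0, 0.05] by default")
  }
  coefs <- default_path_coefficients()
  g <- dag(schema$name, coefs[, c("from", "to")])
  nodes <- topological_order(g)
  B <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(coefs))) B[coefs$to[i], coefs$from[i]] <- coefs$coef[i]
  exo <- c("BMI", "Sex")
  exo_cov <- matrix(c(1, default_exo_covariance(),
                      default_exo_covariance(), 1), 2, 2,
                    dimnames = list(exo, exo))
  Psi <- complete_standardized_residuals(B, exo_cov = exo_cov,
                                         resid_cov = default_residual_covariances())
  rc <- default_residual_covariances()
  model <- path_model(g, coefs, Psi, resid_pairs = rc[, c("a", "b")])
  structure(list(model = model, schema = schema, missing_rate = missing_rate),
            class = "painpath_generating_model")
}

#' @export
print.painpath_generating_model <- function(x, ...) {
  cat("generating model:", nrow(x$model$graph$arcs), "paths over",
      length(x$model$nodes), "variables; default missingness",
      sprintf("%.1f%%\n", 100 * x$missing_rate))
  invisible(x)
}

#' Simulate a synthetic cohort
#'
#' Draws n subjects from a generating model. Sex is Bernoulli with
#' P(male = 1) = 1 - female_fraction and enters the standardized
#' recursion scaled to zero mean and unit variance (so standardized path
#' coefficients apply exactly); the emitted Sex column is 0/1. All other
#' variables are generated by the topological-order linear-Gaussian
#' recursion, with the sink residuals drawn jointly from their
#' multivariate-normal residual covariance block, and are then mapped
#' affinely to raw instrument scales via the schema's generating
#' mean/SD. No clipping is applied by default because truncation at
#' instrument bounds distorts the covariance structure; `clip = TRUE`
#' applies the bounds for cosmetic realism.
#'
#' @param model A `painpath_generating_model`.
#' @param n Number of subjects (>= 0).
#' @param seed Integer RNG seed; the draw is deterministic given `seed`.
#' @param clip Clamp continuous variables to their instrument bounds.
#' @param standardized Return the latent standardized values instead of
#'   raw scales (Sex still emitted 0/1).
#' @return A `cohort_table` with no missing cells.
#' @export
simulate_cohort <- function(model, n, seed = 1, clip = FALSE,
                            standardized = FALSE) {
  stopifnot(inherits(model, "painpath_generating_model"))
  if (n < 0) stop("n must be >= 0")
  sch <- model$schema
  pm <- model$model
  nodes <- pm$nodes
  set.seed(seed)

  p_male <- 1 - sch$female_fraction[sch$name == "Sex"]
  Z <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  sex <- stats::rbinom(n, 1, p_male)
  sex_sd <- sqrt(p_male * (1 - p_male))
  Z[, "Sex"] <- (sex - p_male) / sex_sd

  r <- pm$Psi["BMI", "Sex"]
  Z[, "BMI"] <- r * Z[, "Sex"] + sqrt(1 - r^2) * stats::rnorm(n)

  parents <- dag_parents(pm$graph)
  endo <- setdiff(nodes, c("BMI", "Sex"))
  sinks <- endo[!(endo %in% pm$graph$arcs[, 1])]
  nonsink <- setdiff(endo, sinks)
  eps <- matrix(0, n, length(endo), dimnames = list(NULL, endo))
  for (v in nonsink) {
    eps[, v] <- stats::rnorm(n, sd = sqrt(pm$Psi[v, v]))
  }
  if (length(sinks) > 0 && n > 0) {
    block <- pm$Psi[sinks, sinks, drop = FALSE]
    eps[, sinks] <- matrix(stats::rnorm(n * length(sinks)), n) %*% chol(block)
  }
  for (v in endo) {
    pa <- parents[[v]]
    Z[, v] <- if (length(pa) > 0) {
      Z[, pa, drop = FALSE] %*% pm$B[v, pa] + eps[, v]
    } else {
      eps[, v]
    }
  }

  out <- as.data.frame(Z, check.names = FALSE)
  out[["Sex"]] <- as.numeric(sex)
  if (!standardized) {
    for (v in sch$name[sch$kind == "continuous"]) {
      row <- sch[sch$name == v, ]
      out[[v]] <- row$gen_mean + row$gen_sd * out[[v]]
      if (clip) out[[v]] <- pmin(pmax(out[[v]], row$scale_min), row$scale_max)
    }
  }
  cohort_table(out[, sch$name, drop = FALSE], sch)
}

#' Inject missing-completely-at-random cells into a cohort
#'
#' Each eligible cell is masked independently with probability `rate`.
#' The exogenous variables are excluded from masking by default.
#'
#' @param table A `cohort_table`.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param exclude Variables never masked (default `BMI`, `Sex`).
#' @return The `cohort_table` with `NA`s inserted; observed values are
#'   unchanged.
#' @export
inject_missingness <- function(table, rate, seed = 1,
                               exclude = c("BMI", "Sex")) {
  stopifnot(inherits(table, "cohort_table"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must be in [0, 1)")
  }
  set.seed(seed)
  dat <- table$data
  eligible <- setdiff(table$schema$name, exclude)
  for (v in eligible) {
    mask <- stats::runif(nrow(dat)) < rate
    dat[[v]][mask] <- NA_real_
  }
  cohort_table(dat, table$schema)
}
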