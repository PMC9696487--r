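#' Pipeline configuration
#'
#' Bundles every stage setting of the simulate -> impute -> standardize
#' -> learn -> fit -> mediate pipeline. One master seed deterministically
#' derives a sub-seed per stage by hashing (seed, stage name), so each
#' stage is reproducible in isolation.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate one.
#' @param n Cohort size when simulating (default 146).
#' @param seed Master seed.
#' @param missing_rate Injected MCAR rate when simulating (default from
#'   the generating model).
#' @param m,max_iter,imputation_method Chained-equations settings.
#' @param B_structure Bootstrap replicates for arc strengths.
#' @param threshold Consensus presence threshold (strict `>`).
#' @param B_sem Bollen-Stine / mediation bootstrap replicates.
#' @param residual_pairs Residual-covariance policy for the SEM fit.
#' @param chains Named list of mediation chains (default
#'   [default_mediation_chains()]).
#' @param schema Variable schema.
#' @return A validated list of class `painpath_config`.
#' @export
pipeline_config <- function(input = NULL, n = 146, seed = 1,
                            missing_rate = NULL, m = 20, max_iter = 30,
                            imputation_method = "random_forest",
                            B_structure = 1000, threshold = 0.70,
                            B_sem = 1000, residual_pairs = "sinks",
                            chains = default_mediation_chains(),
                            schema = default_schema()) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (n < 1) stop("n must be >= 1")
  if (B_structure < 1 || B_sem < 1) stop("bootstrap counts must be >= 1")
  structure(list(input = input, n = n, seed = seed,
                 missing_rate = missing_rate, m = m, max_iter = max_iter,
                 imputation_method = imputation_method,
                 B_structure = B_structure, threshold = threshold,
                 B_sem = B_sem, residual_pairs = residual_pairs,
                 chains = chains, schema = schema),
            class = "painpath_config")
}

#' Derive a stage sub-seed from the master seed
#'
#' Deterministic integer hash of (seed, stage name), kept within the
#' 31-bit positive range.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name.
#' @return An integer sub-seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Run the full data-driven path-analysis pipeline
#'
#' Simulates (or loads) a cohort, injects and reports missingness,
#' imputes by chained equations and selects the first completed
#' dataset, standardizes, learns the consensus network by bootstrap
#' model averaging over BIC hill climbs (no arcs into BMI or Sex),
#' fits the path model by ML with Bollen-Stine bootstrap inference,
#' computes fit indices, and evaluates the configured serial indirect
#' effects. Re-running the same configuration reproduces the report
#' exactly.
#'
#' @param config A `painpath_config`.
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `coefficients.csv`, `strengths.csv`, and `dag.dot`.
#' @return A list of class `painpath_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "painpath_config"))
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    timings[stage] <<- proc.time()[["elapsed"]] - t0
    res
  }

  if (is.null(config$input)) {
    gm <- default_generating_model(schema = config$schema)
    rate <- if (is.null(config$missing_rate)) gm$missing_rate else config$missing_rate
    cohort <- tick("simulate", {
      raw <- simulate_cohort(gm, config$n, seed = stage_seed(config$seed, "simulate"))
      inject_missingness(raw, rate, seed = stage_seed(config$seed, "missingness"))
    })
  } else {
    cohort <- tick("load", load_cohort(config$input, config$schema))
  }
  miss <- missingness_report(cohort)

  completed <- tick("impute", {
    imp <- impute_chained(cohort, m = config$m, max_iter = config$max_iter,
                          method = config$imputation_method,
                          seed = stage_seed(config$seed, "impute"))
    select_imputed(imp, 1)
  })
  std <- standardize(completed)

  constraints <- default_constraints(config$schema$name)
  strengths <- tick("learn", {
    bootstrap_strength(std$table, constraints, B = config$B_structure,
                       seed = stage_seed(config$seed, "learn"))
  })
  consensus <- averaged_network(strengths, config$threshold)

  fit <- tick("fit", fit_path_model(consensus, std$table,
                                    residual_pairs = config$residual_pairs))
  boot <- tick("boot", bollen_stine(std$table, fit, B = config$B_sem,
                                    seed = stage_seed(config$seed, "sem")))
  indices <- fit_indices(fit)

  mediations <- tick("mediate", {
    lapply(config$chains, function(chain) {
      valid <- all(vapply(seq_len(length(chain) - 1), function(i) {
        has_arc(consensus, chain[i], chain[i + 1])
      }, logical(1)))
      if (!valid) {
        return(list(chain = chain, estimate = NA_real_,
                    note = "chain arc absent from learned network"))
      }
      indirect_effect_inference(std$table, consensus, chain,
                                B = config$B_sem,
                                seed = stage_seed(config$seed, "mediate"),
                                residual_pairs = config$residual_pairs)
    })
  })

  report <- structure(list(
    config = config[setdiff(names(config), "schema")],
    missingness = miss,
    strengths = strengths,
    dag = consensus,
    coefficients = coefficient_table(boot),
    fit_indices = indices,
    model_p_value = boot$p_value,
    mediation = mediations,
    scaling = std$scaling,
    timings = timings,
    versions = list(painpath = as.character(utils::packageVersion("painpath")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  ), class = "painpath_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Standardized coefficient table of a bootstrapped fit
#'
#' Formats a [bollen_stine()] result as a table with columns `DV`,
#' `IV`, `Coef`, `SE`, `Pval`, `2.5%`, `97.5%`, `Type` (`Reg` for
#' regression paths, `vCov` for residual variances/covariances), using
#' the fully standardized solution.
#'
#' @param boot A `painpath_sem_boot`.
#' @return A data frame.
#' @export
coefficient_table <- function(boot) {
  stopifnot(inherits(boot, "painpath_sem_boot"))
  est <- boot$estimates
  data.frame(
    DV = est$lhs, IV = est$rhs,
    Coef = est$std, SE = est$std_se, Pval = est$std_pval,
    `2.5%` = est$std_ci_lower, `97.5%` = est$std_ci_upper,
    Type = ifelse(est$type == "beta", "Reg", "vCov"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$coefficients,
                   file.path(out_dir, "coefficients.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$strengths),
                   file.path(out_dir, "strengths.csv"), row.names = FALSE)
  writeLines(export_dag_dot(report$dag, report$strengths),
             file.path(out_dir, "dag.dot"))
  json <- list(
    config = report$config[c("n", "seed", "m", "max_iter",
                             "imputation_method", "B_structure", "threshold",
                             "B_sem")],
    missingness = report$missingness,
    arcs = as.data.frame(report$dag$arcs),
    coefficients = report$coefficients,
    fit_indices = report$fit_indices,
    model_p_value = report$model_p_value,
    mediation = lapply(report$mediation, function(m) {
      m[intersect(names(m), c("chain", "estimate", "se", "ci_lower",
                              "ci_upper", "p_value", "delta_se", "note"))]
    }),
    timings = as.list(report$timings),
    versions = report$versions
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.painpath_report <- function(x, ...) {
  cat("painpath pipeline report\n")
  cat("  consensus network:", nrow(x$dag$arcs), "arcs\n")
  fi <- x$fit_indices
  cat(sprintf("  fit: RMSEA = %.3f, CFI = %.3f, NNFI = %.3f, SRMR = %.3f\n",
              fi$rmsea, fi$cfi, fi$nnfi, fi$srmr))
  cat(sprintf("  Bollen-Stine model p = %.3f\n", x$model_p_value))
  invisible(x)
}

#' Export a DAG as Graphviz DOT text
#'
#' @param graph A `painpath_dag`.
#' @param strengths Optional `painpath_arc_strength` table; when given,
#'   arcs are labelled with their bootstrap presence frequency.
#' @return A character scalar of DOT source.
#' @export
export_dag_dot <- function(graph, strengths = NULL) {
  stopifnot(inherits(graph, "painpath_dag"))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph pathmodel {", "  rankdir=LR;",
             paste0("  ", q(graph$nodes), ";"))
  for (i in seq_len(nrow(graph$arcs))) {
    from <- graph$arcs[i, 1]; to <- graph$arcs[i, 2]
    label <- ""
    if (!is.null(strengths)) {
      a <- pmin(from, to); b <- pmax(from, to)
      row <- strengths$from == a & strengths$to == b
      if (any(row)) {
        label <- sprintf(" [label=\"%.2f\"]", strengths$presence[row][1])
      }
    }
    lines <- c(lines, paste0("  ", q(from), " -> ", q(to), label, ";"))
  }
  paste(c(lines, "}"), collapse = "\n")
}
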