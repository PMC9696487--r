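# Shared fixtures: small chain datasets and CSV round-trip helpers.

# x -> y -> z linear-Gaussian chain.
chain3_data <- function(n, bxy = 0.6, byz = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- bxy * x + rnorm(n, sd = 0.8)
  z <- byz * y + rnorm(n)
  cbind(x = x, y = y, z = z)
}

chain3_dag <- function() {
  dag(c("x", "y", "z"), rbind(c("x", "y"), c("y", "z")))
}

# A complete 3-row cohort on the full 12-variable schema.
tiny_cohort <- function() {
  sch <- default_schema()
  vals <- as.data.frame(matrix(seq_len(3 * 12), nrow = 3),
                        check.names = FALSE)
  names(vals) <- sch$name
  vals$Sex <- c(0, 1, 0)
  vals[["EQ-5D"]] <- c(0.5, 0.7, 0.9)
  cohort_table(vals, sch)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# All 25 DAGs on 3 labelled nodes, as arc matrices.
all_dags_3 <- function(nodes) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    states <- c(s1, s2, s3) # 0 absent, 1 forward, 2 backward
    arcs <- do.call(rbind, lapply(1:3, function(k) {
      if (states[k] == 0) return(NULL)
      ij <- pairs[[k]]
      if (states[k] == 1) c(nodes[ij[1]], nodes[ij[2]]) else
        c(nodes[ij[2]], nodes[ij[1]])
    }))
    g <- tryCatch(dag(nodes, arcs), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1]] <- g
  }
  out
}
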