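# Moment summary used by all node scores: MLE (1/n) covariance of the
# columns. Scores depend on the data only through this and n, which
# makes bootstrap hill climbs cheap.
moment_summary <- function(X) {
  n <- nrow(X)
  Xc <- X - matrix(colMeans(X), n, ncol(X), byrow = TRUE)
  list(M = crossprod(Xc) / n, n = n, vars = colnames(X))
}

node_bic_from_moments <- function(ms, node, parents) {
  n <- ms$n
  M <- ms$M
  syy <- M[node, node]
  if (length(parents) > 0) {
    Spp <- M[parents, parents, drop = FALSE]
    spy <- M[parents, node]
    b <- tryCatch(solve(Spp, spy), error = function(e) {
      stop("singular design for node '", node, "' with parents {",
           paste(parents, collapse = ", "), "}")
    })
    sigma2 <- syy - sum(b * spy)
  } else {
    sigma2 <- syy
  }
  if (!is.finite(sigma2) || sigma2 < 1e-12) return(-Inf)
  logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- length(parents) + 2
  logL - (k / 2) * log(n)
}

#' Gaussian BIC score of one node given a parent set
#'
#' The node is regressed (with intercept) on its parents; the score is
#' the maximized Gaussian log-likelihood penalised by `(k/2) log n`
#' with `k = |parents| + 2` (intercept and residual variance). Higher
#' is better. A zero residual variance (node is an exact linear
#' function of its parents) is guarded as `-Inf`.
#'
#' @param data A `cohort_table`, data frame, or numeric matrix with no
#'   missing values.
#' @param node Node name.
#' @param parents Character vector of parent names (may be empty).
#' @return The BIC score (scalar; `-Inf` for degenerate residuals).
#' @export
node_bic <- function(data, node, parents = character(0)) {
  X <- data_matrix(data, unique(c(node, parents)))
  if (nrow(X) <= length(parents) + 2) {
    stop("need n > |parents| + 2 observations")
  }
  node_bic_from_moments(moment_summary(X), node, parents)
}

#' Network BIC score of a DAG
#'
#' Decomposable: the sum over nodes of [node_bic()] given each node's
#' parents in the DAG.
#'
#' @param data As in [node_bic()].
#' @param graph A `painpath_dag`.
#' @return The summed score.
#' @export
network_score <- function(data, graph) {
  stopifnot(inherits(graph, "painpath_dag"))
  X <- data_matrix(data, graph$nodes)
  ms <- moment_summary(X)
  parents <- dag_parents(graph)
  sum(vapply(graph$nodes,
             function(v) node_bic_from_moments(ms, v, parents[[v]]),
             numeric(1)))
}

#' Greedy hill-climbing DAG search under a Gaussian BIC score
#'
#' Starts from the whitelist-only graph (empty when no whitelist) and
#' repeatedly applies the best strictly score-improving single-arc
#' addition, deletion, or reversal that keeps the graph acyclic and
#' respects the constraints, stopping at a local optimum. The search is
#' deterministic: candidate moves are enumerated in a fixed order and
#' ties keep the first-found best move.
#'
#' @param data Complete (typically standardized) data as in
#'   [node_bic()].
#' @param constraints A `painpath_constraints` (default: none).
#' @param nodes Node names to learn over; defaults to all columns of
#'   `data` (schema variables for a `cohort_table`).
#' @return The learned `painpath_dag`.
#' @export
hill_climb <- function(data, constraints = constraint_set(), nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- if (inherits(data, "cohort_table")) data$schema$name else colnames(data)
  }
  X <- data_matrix(data, nodes)
  ms <- moment_summary(X)
  hill_climb_ms(ms, nodes, constraints)
}

hill_climb_ms <- function(ms, nodes, constraints) {
  p <- length(nodes)
  use_vec_cache <- p <= 16
  bit <- bitwShiftL(1L, seq_len(p) - 1L)
  blmat <- matrix(FALSE, p, p)
  for (i in seq_len(nrow(constraints$blacklist))) {
    blmat[match(constraints$blacklist[i, 1], nodes),
          match(constraints$blacklist[i, 2], nodes)] <- TRUE
  }
  wlmat <- matrix(FALSE, p, p)
  A <- matrix(FALSE, p, p) # A[u, v]: arc u -> v
  pa_mask <- integer(p)
  for (i in seq_len(nrow(constraints$whitelist))) {
    u <- match(constraints$whitelist[i, 1], nodes)
    v <- match(constraints$whitelist[i, 2], nodes)
    wlmat[u, v] <- TRUE
    A[u, v] <- TRUE
    pa_mask[v] <- bitwOr(pa_mask[v], bit[u])
  }
  cache <- if (use_vec_cache) rep(NA_real_, p * bitwShiftL(1L, p)) else
    new.env(parent = emptyenv())
  score_of <- function(v, mask) {
    if (use_vec_cache) {
      idx <- (v - 1L) * bitwShiftL(1L, p) + mask + 1L
      got <- cache[idx]
      if (!is.na(got)) return(got)
    } else {
      key <- paste0(v, "_", mask)
      got <- cache[[key]]
      if (!is.null(got)) return(got)
    }
    pa <- nodes[bitwAnd(mask, bit) > 0L]
    val <- node_bic_from_moments(ms, nodes[v], pa)
    if (use_vec_cache) cache[idx] <<- val else cache[[key]] <- val
    val
  }
  node_scores <- vapply(seq_len(p), function(v) score_of(v, pa_mask[v]),
                        numeric(1))
  eps <- 1e-10
  # path u -> ... -> v in adjacency matrix (frontier expansion)
  has_path <- function(adj, u, v) {
    frontier <- adj[u, ]
    if (frontier[v]) return(TRUE)
    seen <- frontier
    while (any(frontier)) {
      frontier <- (colSums(adj[frontier, , drop = FALSE]) > 0) & !seen
      if (frontier[v]) return(TRUE)
      seen <- seen | frontier
    }
    FALSE
  }
  repeat {
    # transitive closure (Floyd-Warshall) for addition cycle checks
    closure <- A
    for (k in seq_len(p)) {
      closure <- closure | outer(closure[, k], closure[k, ], "&")
    }
    best <- NULL
    best_delta <- eps
    for (u in seq_len(p)) for (v in seq_len(p)) {
      if (u == v || A[u, v] || blmat[u, v]) next
      if (closure[v, u]) next # adding u -> v would close a cycle
      delta <- score_of(v, bitwOr(pa_mask[v], bit[u])) - node_scores[v]
      if (is.finite(delta) && delta > best_delta) {
        best_delta <- delta
        best <- c("add", u, v)
      }
    }
    for (v in seq_len(p)) for (u in which(A[, v])) {
      if (wlmat[u, v]) next
      delta <- score_of(v, bitwAnd(pa_mask[v], bitwNot(bit[u]))) -
        node_scores[v]
      if (is.finite(delta) && delta > best_delta) {
        best_delta <- delta
        best <- c("del", u, v)
      }
    }
    for (v in seq_len(p)) for (u in which(A[, v])) {
      if (wlmat[u, v] || blmat[v, u]) next
      A[u, v] <- FALSE
      cyc <- has_path(A, u, v)
      A[u, v] <- TRUE
      if (cyc) next # reversal would close a cycle
      delta <- (score_of(v, bitwAnd(pa_mask[v], bitwNot(bit[u]))) -
                  node_scores[v]) +
        (score_of(u, bitwOr(pa_mask[u], bit[v])) - node_scores[u])
      if (is.finite(delta) && delta > best_delta) {
        best_delta <- delta
        best <- c("rev", u, v)
      }
    }
    if (is.null(best)) break
    u <- as.integer(best[2]); v <- as.integer(best[3])
    if (best[1] == "add") {
      A[u, v] <- TRUE
      pa_mask[v] <- bitwOr(pa_mask[v], bit[u])
    } else if (best[1] == "del") {
      A[u, v] <- FALSE
      pa_mask[v] <- bitwAnd(pa_mask[v], bitwNot(bit[u]))
    } else {
      A[u, v] <- FALSE
      A[v, u] <- TRUE
      pa_mask[v] <- bitwAnd(pa_mask[v], bitwNot(bit[u]))
      pa_mask[u] <- bitwOr(pa_mask[u], bit[v])
    }
    node_scores[v] <- score_of(v, pa_mask[v])
    node_scores[u] <- score_of(u, pa_mask[u])
  }
  idx <- which(A, arr.ind = TRUE)
  dag(nodes, cbind(nodes[idx[, 1]], nodes[idx[, 2]]))
}

#' Bootstrap arc-strength estimation
#'
#' Draws `B` nonparametric row resamples of the data, learns a DAG on
#' each with [hill_climb()], and tallies for every unordered node pair
#' the presence frequency (edge present in either direction) and the
#' direction frequency (fraction of presences oriented from the
#' lexicographically first node), following the model-averaging
#' convention used with score-based structure learning.
#'
#' @param data Complete data as in [hill_climb()].
#' @param constraints A `painpath_constraints`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @param nodes Node names; defaults as in [hill_climb()].
#' @return A data frame of class `painpath_arc_strength` with columns
#'   `from`, `to` (`from` < `to` lexicographically), `presence`,
#'   `direction`; attributes `B`, `nodes`, `constraints`.
#' @export
bootstrap_strength <- function(data, constraints = constraint_set(),
                               B = 1000, seed = 1, nodes = NULL) {
  if (B < 1) stop("B must be >= 1")
  if (is.null(nodes)) {
    nodes <- if (inherits(data, "cohort_table")) data$schema$name else colnames(data)
  }
  X <- data_matrix(data, nodes)
  n <- nrow(X)
  pairs <- utils::combn(sort(nodes), 2)
  key <- paste(pairs[1, ], pairs[2, ], sep = "\r")
  present <- stats::setNames(numeric(length(key)), key)
  fwd <- present
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    g <- hill_climb_ms(moment_summary(X[idx, , drop = FALSE]), nodes,
                       constraints)
    for (i in seq_len(nrow(g$arcs))) {
      a <- g$arcs[i, 1]; b2 <- g$arcs[i, 2]
      lex <- a < b2
      k <- if (lex) paste(a, b2, sep = "\r") else paste(b2, a, sep = "\r")
      present[k] <- present[k] + 1
      if (lex) fwd[k] <- fwd[k] + 1
    }
  }
  out <- data.frame(from = pairs[1, ], to = pairs[2, ],
                    presence = unname(present) / B,
                    direction = unname(ifelse(present > 0,
                                              fwd / pmax(present, 1), 0.5)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, B = B, nodes = nodes, constraints = constraints,
            class = c("painpath_arc_strength", "data.frame"))
}

#' Averaged (consensus) network from bootstrap arc strengths
#'
#' Keeps every edge whose presence frequency is strictly greater than
#' the threshold, orients it by majority direction (lexicographic
#' tie-break), drops any arc in the blacklist, and, should the result
#' contain directed cycles, removes the lowest-presence arc of each
#' cycle until acyclic.
#'
#' @param strengths A `painpath_arc_strength` table.
#' @param threshold Presence-frequency cut (default 0.70, strict `>`).
#' @return The consensus `painpath_dag`.
#' @export
averaged_network <- function(strengths, threshold = 0.70) {
  stopifnot(inherits(strengths, "painpath_arc_strength"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  nodes <- attr(strengths, "nodes")
  constraints <- attr(strengths, "constraints")
  if (is.null(constraints)) constraints <- constraint_set()
  keep <- strengths[strengths$presence > threshold, , drop = FALSE]
  if (nrow(keep) > 0) {
    flip <- keep$direction < 0.5
    arcs <- cbind(from = ifelse(flip, keep$to, keep$from),
                  to = ifelse(flip, keep$from, keep$to))
    pres <- keep$presence
    ok <- !vapply(seq_len(nrow(arcs)),
                  function(i) in_blacklist(constraints, arcs[i, 1], arcs[i, 2]),
                  logical(1))
    arcs <- arcs[ok, , drop = FALSE]
    pres <- pres[ok]
  } else {
    arcs <- matrix(character(0), ncol = 2)
    pres <- numeric(0)
  }
  # cycle repair: drop the weakest arc on some cycle until acyclic
  repeat {
    cyc <- find_cycle_arcs(nodes, arcs)
    if (is.null(cyc)) break
    weakest <- cyc[order(pres[cyc], arcs[cyc, 1], arcs[cyc, 2])][1]
    arcs <- arcs[-weakest, , drop = FALSE]
    pres <- pres[-weakest]
  }
  dag(nodes, arcs)
}

# Returns row indices (into arcs) of one directed cycle, or NULL.
find_cycle_arcs <- function(nodes, arcs) {
  if (nrow(arcs) == 0) return(NULL)
  color <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new 1 active 2 done
  stack_path <- character(0)
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return()
    color[v] <<- 1L
    stack_path <<- c(stack_path, v)
    for (w in arcs[arcs[, 1] == v, 2]) {
      if (!is.null(cycle)) break
      if (color[w] == 1L) {
        ring <- c(stack_path[which(stack_path == w):length(stack_path)], w)
        cycle <<- vapply(seq_len(length(ring) - 1), function(i) {
          which(arcs[, 1] == ring[i] & arcs[, 2] == ring[i + 1])[1]
        }, integer(1))
      } else if (color[w] == 0L) {
        visit(w)
      }
    }
    color[v] <<- 2L
    stack_path <<- stack_path[-length(stack_path)]
  }
  for (v in nodes) {
    if (color[v] == 0L) visit(v)
    if (!is.null(cycle)) break
  }
  cycle
}
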