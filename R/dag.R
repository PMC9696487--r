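#' Construct a directed acyclic graph over named variables
#'
#' @param nodes Character vector of node names.
#' @param arcs Two-column character matrix or data frame (`from`, `to`);
#'   may have zero rows.
#' @return An object of class `painpath_dag`: a list with `nodes` and an
#'   `arcs` character matrix. Construction fails on unknown nodes,
#'   self-loops, duplicate arcs, or directed cycles.
#' @export
dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  arcs <- as_arc_matrix(arcs)
  if (nrow(arcs) > 0) {
    bad <- !(arcs[, 1] %in% nodes) | !(arcs[, 2] %in% nodes)
    if (any(bad)) {
      stop("arc references unknown node: ",
           paste(unique(c(arcs[bad, 1], arcs[bad, 2])), collapse = ", "))
    }
    if (any(arcs[, 1] == arcs[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(arcs[, 1], arcs[, 2], sep = "\r"))) {
      stop("duplicate arcs")
    }
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "painpath_dag")
  if (!is_acyclic(g)) stop("arc set contains a directed cycle")
  g
}

as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || (is.data.frame(arcs) && nrow(arcs) == 0) ||
      (is.matrix(arcs) && nrow(arcs) == 0)) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs[, 1:2])
  arcs <- matrix(as.character(arcs), ncol = 2)
  colnames(arcs) <- c("from", "to")
  arcs
}

#' @export
print.painpath_dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs) > 0) {
    cat(paste0("  ", x$arcs[, 1], " -> ", x$arcs[, 2], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Parents of each node in a DAG
#' @param g A `painpath_dag`.
#' @return Named list mapping each node to its parent name vector.
#' @export
dag_parents <- function(g) {
  stopifnot(inherits(g, "painpath_dag"))
  out <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (v in g$nodes) out[[v]] <- character(0)
  for (i in seq_len(nrow(g$arcs))) {
    out[[g$arcs[i, 2]]] <- c(out[[g$arcs[i, 2]]], g$arcs[i, 1])
  }
  out
}

# Acyclicity by repeated removal of in-degree-0 nodes (Kahn).
is_acyclic <- function(g) {
  nodes <- g$nodes
  arcs <- g$arcs
  while (length(nodes) > 0) {
    indeg0 <- nodes[!(nodes %in% arcs[, 2])]
    if (length(indeg0) == 0) return(FALSE)
    nodes <- setdiff(nodes, indeg0)
    arcs <- arcs[!(arcs[, 1] %in% indeg0), , drop = FALSE]
  }
  TRUE
}

#' Topological order of a DAG
#'
#' Deterministic: among in-degree-0 candidates the one listed first in
#' `g$nodes` is emitted first.
#'
#' @param g A `painpath_dag`.
#' @return Character vector of node names in topological order.
#' @export
topological_order <- function(g) {
  stopifnot(inherits(g, "painpath_dag"))
  nodes <- g$nodes
  arcs <- g$arcs
  out <- character(0)
  while (length(nodes) > 0) {
    indeg0 <- nodes[!(nodes %in% arcs[, 2])]
    if (length(indeg0) == 0) stop("graph is cyclic")
    v <- indeg0[1]
    out <- c(out, v)
    nodes <- setdiff(nodes, v)
    arcs <- arcs[arcs[, 1] != v, , drop = FALSE]
  }
  out
}

has_arc <- function(g, from, to) {
  any(g$arcs[, 1] == from & g$arcs[, 2] == to)
}

# TRUE if a directed path to -> ... -> from exists (so adding from -> to
# would close a cycle).
reaches <- function(arcs, src, dst) {
  if (src == dst) return(TRUE)
  frontier <- src
  seen <- character(0)
  while (length(frontier) > 0) {
    v <- frontier[1]
    frontier <- frontier[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    nxt <- arcs[arcs[, 1] == v, 2]
    if (dst %in% nxt) return(TRUE)
    frontier <- c(frontier, setdiff(nxt, seen))
  }
  FALSE
}

#' Blacklist/whitelist arc constraints for structure learning
#'
#' @param blacklist,whitelist Two-column (`from`, `to`) matrices or data
#'   frames of forbidden / required directed arcs; `NULL` for none.
#' @return An object of class `painpath_constraints`.
#' @export
constraint_set <- function(blacklist = NULL, whitelist = NULL) {
  blacklist <- as_arc_matrix(blacklist)
  whitelist <- as_arc_matrix(whitelist)
  key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
  if (length(intersect(key(blacklist), key(whitelist))) > 0) {
    stop("whitelist and blacklist overlap")
  }
  if (nrow(whitelist) > 0) {
    nodes <- unique(c(whitelist[, 1], whitelist[, 2]))
    dag(nodes, whitelist) # errors if the whitelist alone is cyclic
  }
  structure(list(blacklist = blacklist, whitelist = whitelist),
            class = "painpath_constraints")
}

#' Default blacklist: no arcs into the exogenous variables
#'
#' Body-mass index and sex cannot be caused by symptom variables, so
#' every arc pointing into them is forbidden.
#'
#' @param nodes All node names.
#' @param into Nodes that may not receive arcs (default `BMI`, `Sex`).
#' @return A `painpath_constraints` object.
#' @export
default_constraints <- function(nodes, into = c("BMI", "Sex")) {
  into <- intersect(into, nodes)
  from <- setdiff(nodes, character(0))
  bl <- do.call(rbind, lapply(into, function(v) {
    cbind(from = setdiff(from, v), to = v)
  }))
  constraint_set(blacklist = bl)
}

in_blacklist <- function(constraints, from, to) {
  bl <- constraints$blacklist
  nrow(bl) > 0 && any(bl[, 1] == from & bl[, 2] == to)
}

in_whitelist <- function(constraints, from, to) {
  wl <- constraints$whitelist
  nrow(wl) > 0 && any(wl[, 1] == from & wl[, 2] == to)
}
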