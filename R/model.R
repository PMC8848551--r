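# Bayesian network models: DAG structure + per-node arities + per-node CPTs.
#
# The joint distribution factorizes over the structure as
#   P(X1, ..., Xn) = prod_i P(Xi | parents(Xi)),
# each factor stored as a simplex-column table.  Parent sets are ordered
# canonically by topological position, with the first parent the most
# significant digit of the mixed-radix ancestor-event encoding.

#' Assemble and validate a Bayesian network model
#'
#' @param dag a `bn_dag` structure.
#' @param arities named integer vector of per-node state counts (>= 2), names
#'   covering every node of `dag`.
#' @param tables named list of `bn_cpt`, one per node; each table's
#'   `ancestor_arities` must match the arities of the node's structural
#'   parents in canonical (topological) order.  Root nodes carry single-column
#'   tables holding their unconditional distribution.
#' @return A `bn_model`: list with `dag`, `arities`, `parents` (named list of
#'   canonical parent label vectors) and `tables`.
#' @export
bn_model <- function(dag, arities, tables) {
  if (!inherits(dag, "bn_dag"))
    bn_stop("invalid_argument", "`dag` must be a bn_dag")
  nodes <- dag$order
  if (!all(nodes %in% names(arities)))
    bn_stop("invalid_argument", "arities missing for node(s): %s",
            paste(setdiff(nodes, names(arities)), collapse = ", "))
  arities <- vapply(arities[nodes], check_count, integer(1),
                    name = "arity", min = 2L)
  parents <- lapply(stats::setNames(nodes, nodes),
                    function(v) dag_parents(dag, v))
  for (v in nodes) {
    tab <- tables[[v]]
    if (is.null(tab) || !inherits(tab, "bn_cpt"))
      bn_stop("invalid_argument", "node %s has no valid table", v)
    want <- unname(arities[parents[[v]]])
    if (!identical(as.integer(tab$ancestor_arities), as.integer(want)))
      bn_stop("invalid_argument",
              "table of %s conditions on arities (%s), structure implies (%s)",
              v, paste(tab$ancestor_arities, collapse = ","),
              paste(want, collapse = ","))
    if (nrow(tab$columns) != arities[v])
      bn_stop("invalid_argument", "table of %s has %d rows, arity is %d",
              v, nrow(tab$columns), arities[v])
    if (ncol(tab$columns) != prod(want))
      bn_stop("invalid_argument",
              "table of %s has %d columns, expected %d ancestor events",
              v, ncol(tab$columns), prod(want))
    validate_stochastic(tab$columns, v)
  }
  structure(list(dag = dag, arities = arities, parents = parents,
                 tables = tables[nodes]),
            class = "bn_model")
}

validate_stochastic <- function(M, node, tol = 1e-8) {
  if (any(M < -tol))
    bn_stop("format_error", "table of %s has negative entries", node)
  bad <- which(abs(colSums(M) - 1) > tol)
  if (length(bad))
    bn_stop("format_error",
            "table of %s: column %d sums to %.6f, expected 1",
            node, bad[1L], colSums(M)[bad[1L]])
  invisible(TRUE)
}

#' Generate a fully random Bayesian network model
#'
#' Draws a random DAG structure (see [sample_dag()]) and equips every node
#' with a Dirichlet(alpha)-sampled conditional table over its structural
#' parents.  This is the generator behind all simulation experiments: with
#' `alpha = 1` every table column is uniform on its simplex.
#'
#' @param n number of nodes.
#' @param arities per-node state counts: a single integer (recycled) or a
#'   vector of length n. Default 3 (tertiary variables).
#' @param mode,d,p density regime, passed to [sample_dag()]. Default: per-edge
#'   probability 0.8, the reference configuration of the simulation study.
#' @param alpha Dirichlet concentration for every table column.
#' @param permute_labels randomly permute node labels (default FALSE).
#' @param seed optional integer seed.
#' @return A `bn_model`.
#' @examples
#' m <- random_bn(8, arities = 3, seed = 42)
#' @export
random_bn <- function(n, arities = 3L, mode = c("prob", "uniform", "fixed"),
                      d = NULL, p = 0.8, alpha = 1, permute_labels = FALSE,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  dag <- sample_dag(n, mode = mode, d = d, p = p,
                    permute_labels = permute_labels)
  ar <- rep_len(as.integer(arities), n)
  names(ar) <- dag$order
  tables <- lapply(stats::setNames(dag$order, dag$order), function(v) {
    pa <- dag_parents(dag, v)
    build_cpt(ar[v], unname(ar[pa]), alpha = alpha)
  })
  bn_model(dag, ar, tables)
}

#' @export
print.bn_model <- function(x, ...) {
  cat(sprintf("bn_model: %d nodes (arities %s), %d edges\n",
              x$dag$n_nodes, paste(range(x$arities), collapse = "-"),
              nrow(x$dag$edges)))
  invisible(x)
}

# column index of node v's table for given parent states (0-based vector or
# matrix with one column per parent)
cpt_column_index <- function(model, v, parent_states) {
  event_encode(parent_states, unname(model$arities[model$parents[[v]]]))
}

# root nodes = empty parent set
model_roots <- function(model) {
  names(Filter(function(p) length(p) == 0L, model$parents))
}

# terminal nodes = no outgoing edges
model_terminals <- function(model) {
  setdiff(model$dag$order, unique(model$dag$edges[, "from"]))
}
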