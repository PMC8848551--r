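# Random DAG structure generation and model-space density combinatorics.
#
# Acyclicity is structural: edges are drawn in the upper triangle of an
# adjacency matrix under a fixed topological ordering (the triangular
# extraction of a symmetric adjacency matrix), so no cycle check is ever
# needed.  For n nodes the maximum number of edges is D = n(n-1)/2 and the
# number of structures with exactly d edges is C(D, d); structure counts are
# reported in exact integer arithmetic because mid-density counts overflow
# doubles even at n = 16.

#' Maximum edge count (density) of a DAG on n ordered nodes
#'
#' @param n number of nodes.
#' @return The integer n(n-1)/2, the number of node pairs compatible with a
#'   topological ordering.
#' @examples
#' max_density(16)  # 120
#' @export
max_density <- function(n) {
  n <- check_count(n, "n", min = 1L)
  as.integer(n * (n - 1L) / 2L)
}

#' Exact count of DAG structures with a prescribed density
#'
#' Number of distinct edge sets with exactly `d` edges over a fixed topological
#' ordering of `n` nodes: the binomial coefficient C(D, d) with D = n(n-1)/2,
#' computed in exact arbitrary-precision integer arithmetic (mid-density counts
#' such as C(120, 60) exceed the double-precision integer range).
#'
#' @param n number of nodes.
#' @param d number of edges, 0 <= d <= max_density(n).
#' @return An exact integer of class `bnsynth_bigint`; convert with
#'   `as.character()` or (when small enough) `as.numeric()`.
#' @examples
#' as.numeric(config_count(16, 8))  # 840261910995
#' @export
config_count <- function(n, d) {
  n <- check_count(n, "n", min = 1L)
  d <- check_count(d, "d", min = 0L)
  D <- max_density(n)
  if (d > D)
    bn_stop("invalid_argument", "d = %d exceeds max density %d for n = %d", d, D, n)
  d <- min(d, D - d)                    # symmetry keeps factors small
  out <- big_from_num(1)
  for (i in seq_len(d)) {               # C(D,d) = prod (D-d+i)/i, exact at each step
    out <- big_mul_small(out, D - d + i)
    out <- big_div_small(out, i)
  }
  out
}

#' Probability that a uniformly random structure has density d
#'
#' Under the uniform distribution over all 2^D edge subsets of a fixed
#' topological ordering, the density follows Binomial(D, 1/2):
#' P(delta(G) = d) = C(D, d) / 2^D.  Mid-density structures dominate the model
#' space, a systematic bias any naive structure sampler inherits.
#'
#' @inheritParams config_count
#' @return The probability as a double (computed on the log scale).
#' @export
density_pmf <- function(n, d) {
  n <- check_count(n, "n", min = 1L)
  D <- max_density(n)
  d <- vapply(d, check_count, integer(1), name = "d", min = 0L)
  if (any(d > D))
    bn_stop("invalid_argument", "d exceeds max density %d", D)
  exp(lchoose(D, d) - D * log(2))
}

#' Sample a random DAG structure
#'
#' Draws edge sets in the upper triangle over a topological ordering, under one
#' of three densities regimes:
#' \describe{
#'   \item{uniform}{every one of the 2^D edge subsets is equiprobable (each
#'     potential edge included independently with probability 1/2), so density
#'     follows Binomial(D, 1/2);}
#'   \item{fixed}{uniform over the C(D, d) structures with exactly `d` edges;}
#'   \item{prob}{each potential edge included independently with probability
#'     `p` (expected density p*D).}
#' }
#' By default nodes are labeled X1..Xn in topological order; with
#' `permute_labels = TRUE` a random label permutation is applied (the
#' topological ordering is reported either way).
#'
#' @param n number of nodes.
#' @param mode one of "uniform", "fixed", "prob".
#' @param d edge count for `mode = "fixed"`.
#' @param p per-edge inclusion probability for `mode = "prob"`.
#' @param permute_labels randomly permute node labels (default FALSE).
#' @param seed optional integer seed for reproducibility.
#' @return A `bn_dag`: list with `n_nodes`, `order` (labels in topological
#'   order) and `edges` (two-column character matrix, ancestor -> descendant).
#' @examples
#' g <- sample_dag(8, mode = "fixed", d = 5, seed = 1)
#' nrow(g$edges)  # 5
#' @export
sample_dag <- function(n, mode = c("uniform", "fixed", "prob"), d = NULL,
                       p = NULL, permute_labels = FALSE, seed = NULL) {
  n <- check_count(n, "n", min = 1L)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  D <- max_density(n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # i < j positions
  keep <- switch(mode,
    uniform = stats::runif(D) < 0.5,
    fixed = {
      d <- check_count(d, "d", min = 0L)
      if (d > D)
        bn_stop("invalid_argument", "fixed density d = %d exceeds D = %d", d, D)
      seq_len(D) %in% sample.int(D, d)
    },
    prob = {
      if (is.null(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
        bn_stop("invalid_argument", "`p` must be a probability in [0, 1]")
      stats::runif(D) < p
    })
  labels <- paste0("X", seq_len(n))
  if (permute_labels) labels <- sample(labels)
  edges <- cbind(from = labels[pairs[keep, 1L]], to = labels[pairs[keep, 2L]])
  if (!length(edges)) edges <- matrix(character(0), 0L, 2L,
                                      dimnames = list(NULL, c("from", "to")))
  structure(list(n_nodes = n, order = labels, edges = edges),
            class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("bn_dag: %d nodes, %d edges (max %d)\n",
              x$n_nodes, nrow(x$edges), max_density(x$n_nodes)))
  invisible(x)
}

# topological position lookup: named integer vector label -> position
dag_positions <- function(dag) stats::setNames(seq_len(dag$n_nodes), dag$order)

# immediate ancestors of `node`, ordered by topological position
dag_parents <- function(dag, node) {
  pa <- unname(dag$edges[dag$edges[, "to"] == node, "from"])
  pos <- dag_positions(dag)
  pa[order(pos[pa])]
}

# immediate descendants of `node`, ordered by topological position
dag_children <- function(dag, node) {
  ch <- unname(dag$edges[dag$edges[, "from"] == node, "to"])
  pos <- dag_positions(dag)
  ch[order(pos[ch])]
}

#' Export a DAG structure to DOT or GraphML
#'
#' @param dag a `bn_dag`.
#' @param path output file path.
#' @param format "dot" or "graphml".
#' @return `path`, invisibly.
#' @export
export_dag <- function(dag, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  g <- igraph::graph_from_data_frame(
    as.data.frame(dag$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = dag$order, stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
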