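# Conditional probability tables as simplex-column matrices.
#
# A CPT for a child with n states and ancestors of arities (a1, ..., ak) is an
# n x m column-stochastic matrix D with m = prod(a_i) (m = 1 for a root):
# column i is the child's distribution given joint ancestor event i.  Viewed as
# a linear operator, D carries any ancestor distribution q to the child
# marginal p = D q, so the dependence structure the table encodes is a
# property of D alone:
#   - the child is conditionally dependent on its ancestors iff rank(D) >= 2;
#   - the child marginal always lies in the convex hull of the columns;
#   - the hull's vertex columns are the structurally dependent ancestor
#     events (those whose conditional differs from the marginal under every
#     full-support ancestor distribution); rank r, vertex count d and column
#     count m satisfy r <= d <= m.

#' Sample a point uniformly (or Dirichlet-weighted) from the probability simplex
#'
#' Draws from Dirichlet(alpha) via normalized Gamma variates. With `alpha` all
#' ones the draw is uniform on the (k-1)-simplex.
#'
#' @param k dimension (number of states).
#' @param alpha concentration: a single positive value (recycled) or a vector
#'   of k positive values.
#' @param seed optional integer seed.
#' @return Numeric vector of k non-negative entries summing to 1.
#' @export
sample_simplex <- function(k, alpha = 1, seed = NULL) {
  k <- check_count(k, "k", min = 1L)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    bn_stop("invalid_argument", "Dirichlet concentration must be positive")
  if (length(alpha) == 1L) alpha <- rep(alpha, k)
  if (length(alpha) != k)
    bn_stop("invalid_argument", "alpha must have length 1 or k = %d", k)
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) return(1)
  repeat {
    g <- stats::rgamma(k, shape = alpha)
    s <- sum(g)
    if (s > 0) return(g / s)            # guards underflow at tiny alpha
  }
}

# Dirichlet sample matrix: k x m, each column an independent Dirichlet(alpha)
rdirichlet_cols <- function(k, m, alpha) {
  if (length(alpha) == 1L) alpha <- rep(alpha, k)
  g <- matrix(stats::rgamma(k * m, shape = alpha), nrow = k)
  sweep(g, 2L, colSums(g), "/")
}

new_cpt <- function(columns, ancestor_arities) {
  structure(list(child_arity = nrow(columns),
                 ancestor_arities = as.integer(ancestor_arities),
                 columns = columns),
            class = "bn_cpt")
}

#' Build a random conditional probability table
#'
#' Each of the m = prod(ancestor_arities) columns is an independent
#' Dirichlet(alpha) draw on the (child_arity - 1)-simplex.  When
#' `n_vertex_columns = k` is given, only k columns are free Dirichlet draws and
#' the remaining m - k columns are random convex combinations of them (flat
#' Dirichlet weights), so the convex hull of the columns has at most k vertices
#' — i.e. at most k structurally dependent ancestor events.  Tables built with
#' k >= 2 are verified conditionally dependent (rank >= 2) and redrawn (up to
#' `max_retries`) on the measure-zero event of a degenerate draw.
#'
#' @param child_arity number of child states (>= 2).
#' @param ancestor_arities integer vector of ancestor arities (possibly empty
#'   for a root node).
#' @param alpha Dirichlet concentration (scalar or child_arity vector).
#' @param n_vertex_columns optional cap (>= 2) on the number of hull vertices.
#' @param max_retries resampling budget for degenerate draws.
#' @param seed optional integer seed.
#' @return A `bn_cpt`: `child_arity`, `ancestor_arities`, and `columns`
#'   (child_arity x m column-stochastic matrix).
#' @export
build_cpt <- function(child_arity, ancestor_arities = integer(0), alpha = 1,
                      n_vertex_columns = NULL, max_retries = 100L,
                      seed = NULL) {
  child_arity <- check_count(child_arity, "child_arity", min = 2L)
  m <- ancestor_event_space(ancestor_arities)$count
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_vertex_columns)) {
    cols <- rdirichlet_cols(child_arity, m, alpha)
    return(new_cpt(cols, ancestor_arities))
  }
  k <- check_count(n_vertex_columns, "n_vertex_columns", min = 2L)
  if (k > m)
    bn_stop("invalid_argument",
            "n_vertex_columns = %d exceeds the %d ancestor events", k, m)
  for (try in seq_len(max_retries)) {
    verts <- rdirichlet_cols(child_arity, k, alpha)
    cols <- matrix(0, child_arity, m)
    vpos <- sort(sample.int(m, k))
    cols[, vpos] <- verts
    rest <- setdiff(seq_len(m), vpos)
    if (length(rest)) {
      w <- rdirichlet_cols(k, length(rest), 1)   # flat combination weights
      cols[, rest] <- verts %*% w
    }
    tab <- new_cpt(cols, ancestor_arities)
    if (is_dependent(tab)) return(tab)
  }
  bn_stop("degenerate_draw",
          "failed to draw a rank >= 2 table in %d attempts", max_retries)
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat(sprintf("bn_cpt: child arity %d, %d ancestor event column(s)\n",
              x$child_arity, ncol(x$columns)))
  invisible(x)
}

#' Rank-based conditional dependence test
#'
#' A child is conditionally dependent on its ancestors if and only if the
#' numerical rank of its table is at least two (a rank-1 table maps every
#' ancestor distribution to the same child marginal).
#'
#' @param table a `bn_cpt` or a plain column-stochastic matrix.
#' @param tol singular-value cutoff; default `max(dim) * eps * sigma_max`.
#' @return TRUE iff rank >= 2.
#' @export
is_dependent <- function(table, tol = NULL) {
  M <- cpt_matrix(table)
  sv <- svd(M, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * max(sv)
  sum(sv > tol) >= 2L
}

cpt_matrix <- function(table) {
  if (inherits(table, "bn_cpt")) table$columns else as.matrix(table)
}

#' Brute-force conditional dependence criterion
#'
#' The literal definition: given a strictly positive ancestor distribution
#' `pY`, the child is dependent iff at least one column of the table differs
#' from the induced marginal D pY.  Serves as the independent oracle for
#' [is_dependent()].
#'
#' @param table a `bn_cpt` or column-stochastic matrix.
#' @param pY strictly positive ancestor distribution (full support).
#' @param tol max-norm difference below which a column is considered equal to
#'   the marginal.
#' @return TRUE iff some ancestor event is dependent under `pY`.
#' @export
dependence_oracle <- function(table, pY, tol = 1e-9) {
  M <- cpt_matrix(table)
  if (length(pY) != ncol(M))
    bn_stop("invalid_argument", "pY has length %d, table has %d columns",
            length(pY), ncol(M))
  if (any(pY <= 0))
    bn_stop("invalid_argument",
            "the dependence criterion requires a full-support ancestor distribution")
  px <- drop(M %*% pY)
  any(apply(abs(M - px), 2L, max) > tol)
}

#' Induced child marginal D pY
#'
#' Marginalization as a matrix-vector product: the child marginal given an
#' ancestor distribution. The result always lies in the convex hull of the
#' table's columns.
#'
#' @param table a `bn_cpt` or column-stochastic matrix.
#' @param pY ancestor distribution on the (m-1)-simplex.
#' @return Child distribution (length child_arity).
#' @export
induced_marginal <- function(table, pY) {
  M <- cpt_matrix(table)
  if (length(pY) != ncol(M))
    bn_stop("invalid_argument", "pY has length %d, table has %d columns",
            length(pY), ncol(M))
  drop(M %*% pY)
}

# Is `target` a convex combination of the columns of `basis`?  Solved as
# non-negative least squares on the system augmented with the sum-to-one row;
# the NNLS optimum of this convex problem has residual ~ 0 iff feasible.
in_hull <- function(basis, target, tol = 1e-7) {
  if (!ncol(basis)) return(FALSE)
  A <- rbind(basis, rep(1, ncol(basis)))
  b <- c(target, 1)
  fit <- pracma::lsqnonneg(A, b)
  sqrt(sum((A %*% fit$x - b)^2)) <= tol
}

#' Vertex columns of a table's convex hull
#'
#' Returns the indices of columns that are not expressible as a convex
#' combination of the other columns — the structurally dependent ancestor
#' events.  Duplicate columns (max-norm difference below `dup_tol`) are
#' collapsed to one representative before testing, and every duplicate of a
#' vertex representative is reported as a vertex.
#'
#' @param table a `bn_cpt` or column-stochastic matrix.
#' @param tol feasibility tolerance of the convex-combination test.
#' @param dup_tol max-norm threshold for collapsing duplicate columns.
#' @return Sorted integer vector of vertex column indices.
#' @export
hull_vertices <- function(table, tol = 1e-7, dup_tol = 1e-9) {
  M <- cpt_matrix(table)
  m <- ncol(M)
  if (m == 1L) return(1L)
  # group duplicate columns
  group <- integer(m)
  reps <- integer(0)
  for (i in seq_len(m)) {
    hit <- 0L
    for (r in reps) {
      if (max(abs(M[, i] - M[, r])) <= dup_tol) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- i }
    group[i] <- hit
  }
  if (length(reps) == 1L) return(reps)  # single-point hull
  vert_reps <- reps[vapply(seq_along(reps), function(j) {
    !in_hull(M[, reps[-j], drop = FALSE], M[, reps[j]], tol = tol)
  }, logical(1))]
  sort(which(group %in% vert_reps))
}
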