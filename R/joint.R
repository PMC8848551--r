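# Exact joint and marginal computation from the model factorization.
#
# The full joint table is the product, over nodes, of the table entry selected
# by each joint assignment — exact by construction, feasible whenever the
# joint event space (product of arities) fits below a configurable cap.  Joint
# events are indexed in canonical mixed-radix order over nodes in model
# (topological) order, first node most significant, matching the ancestor
# event encoding.

new_joint <- function(nodes, arities, probs) {
  structure(list(nodes = nodes, arities = as.integer(arities), probs = probs),
            class = "bn_joint")
}

#' @export
print.bn_joint <- function(x, ...) {
  cat(sprintf("bn_joint: %d events over %d node(s)\n",
              length(x$probs), length(x$nodes)))
  invisible(x)
}

# per-node 0-based state vectors over all K joint events (depends on arities
# only, so it can be precomputed and reused across models of one shape)
joint_state_plan <- function(arities) {
  K <- prod(arities)
  rad <- rev(cumprod(rev(c(arities[-1L], 1L))))
  idx <- seq_len(K) - 1L
  lapply(seq_along(arities), function(j) (idx %/% rad[j]) %% arities[j])
}

joint_probs_from_plan <- function(model, plan) {
  nodes <- model$dag$order
  K <- length(plan[[1L]])
  probs <- rep(1, K)
  pos <- stats::setNames(seq_along(nodes), nodes)
  for (j in seq_along(nodes)) {
    v <- nodes[j]
    pa <- model$parents[[v]]
    M <- model$tables[[v]]$columns
    if (length(pa)) {
      par <- unname(model$arities[pa])
      rad <- rev(cumprod(rev(c(par[-1L], 1L))))
      colidx <- rep(1L, K)
      for (i in seq_along(pa))
        colidx <- colidx + plan[[pos[pa[i]]]] * rad[i]
    } else {
      colidx <- rep(1L, K)
    }
    probs <- probs * M[cbind(plan[[j]] + 1L, colidx)]
  }
  probs
}

#' Enumerate the exact joint distribution of a model
#'
#' Computes the probability of every joint assignment as the product of the
#' per-node table entries it selects.  Errors (rather than approximating) when
#' the joint event space exceeds `cap`: exactness is the design point.
#'
#' @param model a `bn_model`.
#' @param cap maximum admissible number of joint events (default 1e7).
#' @return A `bn_joint`: `nodes`, `arities`, and `probs`, a vector with one
#'   entry per joint event in canonical mixed-radix order (first node in model
#'   order most significant).
#' @examples
#' m <- random_bn(8, arities = 3, seed = 1)
#' length(enumerate_joint(m)$probs)  # 6561
#' @export
enumerate_joint <- function(model, cap = 1e7) {
  ar <- unname(model$arities)
  if (prod(ar) > cap)
    bn_stop("too_large",
            "joint event space (%.3g events) exceeds the cap of %.3g",
            prod(ar), cap)
  plan <- joint_state_plan(ar)
  new_joint(model$dag$order, ar, joint_probs_from_plan(model, plan))
}

#' Exact per-node marginal distributions
#'
#' Two independent routes to the same quantity: `method = "joint"`
#' marginalizes the fully enumerated joint to each node; `method =
#' "propagate"` sweeps nodes in topological order, expanding a prefix joint
#' one node at a time via the matrix-vector marginalization P(X) = D P(Y) over
#' the joint parent distribution, and reads each node's marginal as it is
#' absorbed.
#'
#' @param model a `bn_model`.
#' @param method "joint" or "propagate".
#' @param cap event-space cap, as in [enumerate_joint()].
#' @return Named list of per-node probability vectors.
#' @export
node_marginals <- function(model, method = c("joint", "propagate"),
                           cap = 1e7) {
  method <- match.arg(method)
  nodes <- model$dag$order
  if (method == "joint") {
    jt <- enumerate_joint(model, cap = cap)
    plan <- joint_state_plan(jt$arities)
    return(stats::setNames(lapply(seq_along(nodes), function(j) {
      as.vector(rowsum(jt$probs, plan[[j]]))
    }), nodes))
  }
  # propagate: prefix joint over nodes seen so far (prefix order, first node
  # most significant); each new node multiplies in its conditional columns
  if (prod(model$arities) > cap)
    bn_stop("too_large", "joint event space exceeds the cap of %.3g", cap)
  marg <- vector("list", length(nodes))
  names(marg) <- nodes
  q <- 1          # joint over empty prefix
  seen <- character(0)
  seen_ar <- integer(0)
  for (v in nodes) {
    pa <- model$parents[[v]]
    M <- model$tables[[v]]$columns
    E <- length(q)
    if (length(pa)) {
      states <- event_decode(seq_len(E), seen_ar)
      colidx <- event_encode(states[, match(pa, seen), drop = FALSE],
                             unname(model$arities[pa]))
    } else {
      colidx <- rep(1L, E)
    }
    block <- M[, colidx, drop = FALSE] * rep(q, each = nrow(M))
    marg[[v]] <- rowSums(block)                  # = D . P(parents) exactly
    # column-major vectorization leaves the prefix most significant and the
    # new node least significant, matching the mixed-radix convention
    q <- as.vector(block)
    seen <- c(seen, v)
    seen_ar <- c(seen_ar, model$arities[[v]])
  }
  marg
}

# exact joint marginal over a subset of nodes, computed by sum-product over
# the subset's ancestral closure only; event order = mixed-radix over `nodes`
# as given (first most significant)
joint_marginal <- function(model, nodes, cap = 1e7) {
  if (!all(nodes %in% model$dag$order))
    bn_stop("invalid_argument", "unknown node(s): %s",
            paste(setdiff(nodes, model$dag$order), collapse = ", "))
  if (!length(nodes)) return(1)
  closure <- nodes
  repeat {
    more <- unique(unlist(model$parents[closure], use.names = FALSE))
    more <- setdiff(more, closure)
    if (!length(more)) break
    closure <- c(closure, more)
  }
  closure <- model$dag$order[model$dag$order %in% closure]  # topological order
  sub_ar <- unname(model$arities[closure])
  if (prod(sub_ar) > cap)
    bn_stop("too_large", "ancestral closure event space exceeds cap")
  plan <- joint_state_plan(sub_ar)
  K <- prod(sub_ar)
  probs <- rep(1, K)
  pos <- stats::setNames(seq_along(closure), closure)
  for (v in closure) {
    pa <- model$parents[[v]]
    M <- model$tables[[v]]$columns
    if (length(pa)) {
      par <- unname(model$arities[pa])
      rad <- rev(cumprod(rev(c(par[-1L], 1L))))
      colidx <- rep(1L, K)
      for (i in seq_along(pa))
        colidx <- colidx + plan[[pos[pa[i]]]] * rad[i]
    } else colidx <- rep(1L, K)
    probs <- probs * M[cbind(plan[[pos[v]]] + 1L, colidx)]
  }
  # marginalize onto `nodes` in requested order
  tar <- unname(model$arities[nodes])
  rad <- rev(cumprod(rev(c(tar[-1L], 1L))))
  key <- rep(0L, K)
  for (i in seq_along(nodes))
    key <- key + plan[[pos[nodes[i]]]] * rad[i]
  out <- numeric(prod(tar))
  agg <- rowsum(probs, key)
  out[as.integer(rownames(agg)) + 1L] <- agg
  out
}

#' Empirical joint distribution of a dataset under a model's event encoding
#'
#' Normalized event counts over the model's canonical joint enumeration;
#' events never observed get probability 0.
#'
#' @param dataset data.frame of 0-based integer states with one column per
#'   model node (as produced by [sample_dataset()]).
#' @param model the `bn_model` defining node order and arities.
#' @param cap event-space cap.
#' @return A `bn_joint` of relative frequencies.
#' @export
empirical_joint <- function(dataset, model, cap = 1e7) {
  nodes <- model$dag$order
  if (!all(nodes %in% names(dataset)))
    bn_stop("data_integrity", "dataset is missing column(s): %s",
            paste(setdiff(nodes, names(dataset)), collapse = ", "))
  if (nrow(dataset) < 1L) bn_stop("data_integrity", "empty dataset")
  ar <- unname(model$arities)
  if (prod(ar) > cap) bn_stop("too_large", "joint event space exceeds cap")
  S <- as.matrix(dataset[, nodes, drop = FALSE])
  for (j in seq_along(nodes)) {
    bad <- which(S[, j] < 0L | S[, j] >= ar[j] | S[, j] != floor(S[, j]))
    if (length(bad))
      bn_stop("data_integrity", "row %d: state %s out of range for node %s",
              bad[1L], S[bad[1L], j], nodes[j])
  }
  idx <- event_encode(S, ar)
  counts <- tabulate(idx, nbins = prod(ar))
  new_joint(nodes, ar, counts / sum(counts))
}

#' Jensen-Shannon divergence
#'
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2, using
#' logarithm base `base` (default 2, which bounds the divergence by 1).
#' Zero-probability terms contribute 0.
#'
#' @param p,q probability vectors of equal length (or `bn_joint` objects).
#' @param base logarithm base; 2 for bits (default), `exp(1)` for nats.
#' @return The divergence, in [0, 1] for base 2.
#' @export
jsd <- function(p, q, base = 2) {
  if (inherits(p, "bn_joint")) p <- p$probs
  if (inherits(q, "bn_joint")) q <- q$probs
  if (length(p) != length(q))
    bn_stop("invalid_argument", "distributions differ in length (%d vs %d)",
            length(p), length(q))
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * (log(a[i], base = base) - log(m[i], base = base)))
  }
  (kl(p) + kl(q)) / 2
}
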