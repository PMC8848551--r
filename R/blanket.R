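# Markov-blanket extraction and factored conditional inference.
#
# The blanket M of a center node X is X, its immediate ancestors a(X), its
# immediate descendants d(X), and the co-ancestors ad(X) = a(d(X)) - X - a(X)
# - d(X).  Conditioning on the periphery M - X renders X independent of the
# rest of the network.  Because every descendant's parent set lies inside M
# (a parent of a child of X is, by definition, X itself or a co-ancestor or
# another descendant), the joint over the blanket decomposes exactly as
#   P(M) = P(X | a(X)) * prod_{Y in d(X)} P(Y | a(Y)) * Phi(M - X),
# where Phi collects the factors of the ancestor/co-ancestor members and of
# any out-of-blanket nodes they depend on, summed over the out-of-blanket
# states.  No factor in Phi can have X as a parent (a child of X would be a
# descendant, hence a member), so Phi is a pure periphery term and cancels in
# every conditional on X — the center conditional keeps the clean
# table-factor form even when co-ancestors have ancestors outside the
# blanket or are linked to other members through out-of-blanket paths.

#' Markov blanket of a node
#'
#' @param model a `bn_model`.
#' @param center node label.
#' @return A `bn_blanket`: `center`, `ancestors` (immediate), `descendants`
#'   (immediate), `co_ancestors`, and `members` (all of the above plus the
#'   center, in model topological order).
#' @examples
#' # chain A -> X -> D: blanket of X is {A, X, D}
#' @export
blanket <- function(model, center) {
  if (!center %in% model$dag$order)
    bn_stop("invalid_argument", "unknown node: %s", center)
  a <- dag_parents(model$dag, center)
  d <- dag_children(model$dag, center)
  ad <- unique(unlist(lapply(d, dag_parents, dag = model$dag),
                      use.names = FALSE))
  ad <- setdiff(ad, c(center, a, d))
  members <- model$dag$order[model$dag$order %in% c(center, a, d, ad)]
  structure(list(center = center, ancestors = a, descendants = d,
                 co_ancestors = model$dag$order[model$dag$order %in% ad],
                 members = members),
            class = "bn_blanket")
}

#' @export
print.bn_blanket <- function(x, ...) {
  cat(sprintf("bn_blanket of %s: a = {%s}, d = {%s}, ad = {%s}\n",
              x$center, paste(x$ancestors, collapse = ","),
              paste(x$descendants, collapse = ","),
              paste(x$co_ancestors, collapse = ",")))
  invisible(x)
}

#' Exact joint table over the members of a Markov blanket
#'
#' Evaluates the factored blanket joint for every member assignment at once:
#' direct table lookups for the center and descendant factors (their parent
#' sets lie inside the blanket by construction), and exact summation over the
#' out-of-blanket ancestral closure for the periphery term.
#'
#' @param model a `bn_model`.
#' @param b a `bn_blanket` (from [blanket()]).
#' @param cap cap on the out-of-blanket summation space.
#' @return Vector of probabilities over member assignments in canonical
#'   mixed-radix order (members in model order, first most significant), with
#'   attributes `members` and `arities`.
#' @export
blanket_joint_table <- function(model, b, cap = 1e7) {
  members <- b$members
  ar <- unname(model$arities[members])
  plan <- joint_state_plan(ar)
  pos <- stats::setNames(seq_along(members), members)
  K <- prod(ar)
  U <- members[members %in% c(b$ancestors, b$co_ancestors)]
  # out-of-blanket nodes the periphery term must sum over: ancestral closure
  # of U through non-members
  S <- character(0)
  frontier <- U
  repeat {
    more <- setdiff(unique(unlist(model$parents[frontier], use.names = FALSE)),
                    c(members, S))
    if (!length(more)) break
    S <- c(S, more)
    frontier <- more
  }
  S <- model$dag$order[model$dag$order %in% S]
  if (prod(model$arities[S]) > cap)
    bn_stop("too_large", "out-of-blanket summation space exceeds cap")
  # gather the table entry of node v as a K-vector, parents resolved from the
  # member plan or from a fixed out-of-blanket assignment `sstate`
  gather <- function(v, sstate) {
    M <- model$tables[[v]]$columns
    pa <- model$parents[[v]]
    if (length(pa)) {
      par <- unname(model$arities[pa])
      rad <- rev(cumprod(rev(c(par[-1L], 1L))))
      colidx <- rep(1L, K)
      for (i in seq_along(pa)) {
        digit <- if (pa[i] %in% members) plan[[pos[pa[i]]]]
                 else sstate[[pa[i]]]
        colidx <- colidx + digit * rad[i]
      }
    } else colidx <- rep(1L, K)
    child <- if (v %in% members) plan[[pos[v]]] + 1L
             else rep(sstate[[v]] + 1L, K)
    M[cbind(child, colidx)]
  }
  if (length(S)) {
    sar <- unname(model$arities[S])
    sevents <- event_decode(seq_len(prod(sar)), sar)
    phi <- numeric(K)
    for (e in seq_len(nrow(sevents))) {
      sstate <- as.list(stats::setNames(sevents[e, ], S))
      term <- rep(1, K)
      for (v in c(U, S)) term <- term * gather(v, sstate)
      phi <- phi + term
    }
  } else {
    phi <- rep(1, K)
    for (v in U) phi <- phi * gather(v, NULL)
  }
  probs <- phi
  for (v in c(b$center, b$descendants)) probs <- probs * gather(v, NULL)
  attr(probs, "members") <- members
  attr(probs, "arities") <- ar
  probs
}

# resolve a named assignment over `members` into the canonical event index
member_event_index <- function(assignment, members, arities) {
  if (!setequal(names(assignment), members))
    bn_stop("invalid_argument",
            "assignment must cover exactly the members {%s}",
            paste(members, collapse = ","))
  event_encode(as.integer(assignment[members]), arities)
}

#' Blanket joint probability of one member assignment
#'
#' @param model a `bn_model`.
#' @param b a `bn_blanket`.
#' @param assignment named vector of 0-based states covering exactly the
#'   blanket members.
#' @param table optional precomputed [blanket_joint_table()] (avoids
#'   recomputation across repeated queries).
#' @return The probability P(M = assignment).
#' @export
blanket_joint <- function(model, b, assignment, table = NULL) {
  if (is.null(table)) table <- blanket_joint_table(model, b)
  members <- attr(table, "members")
  idx <- member_event_index(assignment, members, attr(table, "arities"))
  if (any(assignment < 0L) ||
      any(assignment[members] >= model$arities[members]))
    bn_stop("invalid_argument", "state out of range in blanket assignment")
  as.numeric(table[idx])
}

#' Conditional distribution of the center node given its blanket periphery
#'
#' P(X = x | M - X) by normalizing the blanket joint over the center's states
#' (the upstream factor cancels, leaving exactly the center and descendant
#' table factors).
#'
#' @param model a `bn_model`.
#' @param center node label.
#' @param periphery named 0-based assignment covering the blanket periphery
#'   (members minus the center).
#' @param table optional precomputed [blanket_joint_table()].
#' @return Probability vector over the center's states (sums to 1).
#' @export
center_conditional <- function(model, center, periphery, table = NULL) {
  b <- blanket(model, center)
  if (is.null(table)) table <- blanket_joint_table(model, b)
  members <- attr(table, "members")
  ar <- attr(table, "arities")
  num <- vapply(seq_len(model$arities[[center]]) - 1L, function(s) {
    as.numeric(table[member_event_index(
      c(stats::setNames(s, center), periphery[setdiff(members, center)]),
      members, ar)])
  }, numeric(1))
  tot <- sum(num)
  if (tot <= 0)
    bn_stop("undefined_conditional",
            "periphery assignment of %s has probability zero", center)
  num / tot
}

#' Conditional distribution of a periphery node given the center and the rest
#'
#' P(Z = z | X = x, M - X - Z), by normalizing the blanket joint over Z's
#' states.
#'
#' @param model a `bn_model`.
#' @param center node label X.
#' @param x_state observed 0-based state of the center.
#' @param target periphery node Z whose distribution is sought.
#' @param rest named 0-based assignment over the remaining members
#'   (M - X - Z).
#' @param table optional precomputed [blanket_joint_table()].
#' @return Probability vector over the target's states (sums to 1).
#' @export
periphery_inference <- function(model, center, x_state, target, rest,
                                table = NULL) {
  b <- blanket(model, center)
  if (!target %in% setdiff(b$members, center))
    bn_stop("invalid_argument", "%s is not in the blanket periphery of %s",
            target, center)
  if (is.null(table)) table <- blanket_joint_table(model, b)
  members <- attr(table, "members")
  ar <- attr(table, "arities")
  num <- vapply(seq_len(model$arities[[target]]) - 1L, function(z) {
    asn <- c(stats::setNames(x_state, center), stats::setNames(z, target),
             rest[setdiff(members, c(center, target))])
    as.numeric(table[member_event_index(asn, members, ar)])
  }, numeric(1))
  tot <- sum(num)
  if (tot <= 0)
    bn_stop("undefined_conditional",
            "conditioning assignment has probability zero")
  num / tot
}

#' Center conditionals for every periphery assignment at once
#'
#' Vectorized companion to [center_conditional()]: reshapes the blanket joint
#' table into (center state) x (periphery assignment) and normalizes columns.
#' Periphery assignments with probability zero yield NA columns.
#'
#' @param model a `bn_model`.
#' @param center node label.
#' @return List with `periphery` (node labels in model order), `assignments`
#'   (0-based assignment matrix, one row per periphery event) and `cond`
#'   (matrix, center arity x periphery events).
#' @export
blanket_conditionals <- function(model, center) {
  b <- blanket(model, center)
  tab <- blanket_joint_table(model, b)
  members <- attr(tab, "members")
  ar <- attr(tab, "arities")
  plan <- joint_state_plan(ar)
  ci <- match(center, members)
  periph <- members[-ci]
  par <- ar[-ci]
  prad <- rev(cumprod(rev(c(par[-1L], 1L))))
  pkey <- rep(0L, length(tab))
  ppos <- which(members %in% periph)
  for (i in seq_along(ppos))
    pkey <- pkey + plan[[ppos[i]]] * prad[i]
  nP <- max(1L, prod(par))
  cond <- matrix(0, nrow = ar[ci], ncol = nP)
  cond[cbind(plan[[ci]] + 1L, pkey + 1L)] <- as.numeric(tab)
  tot <- colSums(cond)
  cond <- sweep(cond, 2L, tot, "/")
  cond[, tot <= 0] <- NA_real_
  list(periphery = periph,
       assignments = event_decode(seq_len(nP), par),
       cond = cond)
}
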