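# Fixture builders shared across tests: hand-specified small networks and
# brute-force oracles computed from the fully enumerated joint.

rdirichlet_cols_test <- function(k, m, alpha = 1) {
  bnsynth:::rdirichlet_cols(k, m, alpha)
}

identity_cpt <- function(k, ancestor_arities = k) {
  # deterministic table: child copies its (single) ancestor
  new_cpt_cols(diag(k), ancestor_arities)
}

new_cpt_cols <- function(columns, ancestor_arities = integer(0)) {
  structure(list(child_arity = nrow(columns),
                 ancestor_arities = as.integer(ancestor_arities),
                 columns = columns),
            class = "bn_cpt")
}

# chain A -> X -> D with arbitrary tables (prior: column vector for A)
chain_model <- function(prior, tab_X, tab_D,
                        labels = c("A", "X", "D")) {
  k <- c(length(prior), nrow(tab_X), nrow(tab_D))
  dag <- structure(list(n_nodes = 3L, order = labels,
                        edges = cbind(from = labels[1:2], to = labels[2:3])),
                   class = "bn_dag")
  tables <- list(new_cpt_cols(matrix(prior, ncol = 1)),
                 new_cpt_cols(tab_X, k[1L]),
                 new_cpt_cols(tab_D, k[2L]))
  names(tables) <- labels
  bn_model(dag, stats::setNames(k, labels), tables)
}

# model of independent roots with given priors (no edges)
roots_model <- function(priors) {
  n <- length(priors)
  labels <- paste0("X", seq_len(n))
  dag <- structure(list(n_nodes = n, order = labels,
                        edges = matrix(character(0), 0, 2,
                                       dimnames = list(NULL, c("from", "to")))),
                   class = "bn_dag")
  tables <- lapply(priors, function(p) new_cpt_cols(matrix(p, ncol = 1)))
  names(tables) <- labels
  bn_model(dag, stats::setNames(vapply(priors, length, 1L), labels), tables)
}

# brute-force joint marginal over `members` from the enumerated joint
oracle_blanket_joint <- function(model, members) {
  jt <- enumerate_joint(model)
  plan <- bnsynth:::joint_state_plan(jt$arities)
  mi <- match(members, model$dag$order)
  mar <- unname(model$arities[members])
  rad <- rev(cumprod(rev(c(mar[-1], 1))))
  key <- rep(0L, length(jt$probs))
  for (i in seq_along(mi)) key <- key + plan[[mi[i]]] * rad[i]
  out <- numeric(prod(mar))
  agg <- rowsum(jt$probs, key)
  out[as.integer(rownames(agg)) + 1L] <- agg
  out
}

# brute-force conditional P(X | all other nodes) for every assignment of the
# others; returns list(cond = arity x n_other_events matrix, den = marginal
# probability of each conditioning assignment)
oracle_full_conditional <- function(model, X) {
  jt <- enumerate_joint(model)
  nodes <- model$dag$order
  ar <- unname(model$arities)
  plan <- bnsynth:::joint_state_plan(ar)
  ci <- match(X, nodes)
  others <- setdiff(seq_along(nodes), ci)
  oar <- ar[others]
  orad <- rev(cumprod(rev(c(oar[-1], 1))))
  okey <- rep(0L, length(jt$probs))
  for (i in seq_along(others)) okey <- okey + plan[[others[i]]] * orad[i]
  den <- numeric(prod(oar))
  agg <- rowsum(jt$probs, okey)
  den[as.integer(rownames(agg)) + 1L] <- agg
  cond <- matrix(NA_real_, ar[ci], prod(oar))
  for (s in seq_len(ar[ci]) - 1L) {
    sel <- plan[[ci]] == s
    num <- numeric(prod(oar))
    agg <- rowsum(jt$probs[sel], okey[sel])
    num[as.integer(rownames(agg)) + 1L] <- agg
    cond[s + 1L, ] <- num / den
  }
  list(cond = cond, den = den, other_nodes = nodes[others], other_arities = oar)
}
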