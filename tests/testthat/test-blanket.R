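# Markov-blanket extraction and factored inference against brute-force
# full-joint oracles.

test_that("blanket membership follows the ancestor/descendant definition", {
  m <- chain_model(c(0.3, 0.7), diag(2), diag(2))
  b <- blanket(m, "X")
  expect_identical(b$ancestors, "A")
  expect_identical(b$descendants, "D")
  expect_identical(b$co_ancestors, character(0))
  expect_identical(b$members, c("A", "X", "D"))
  expect_error(blanket(m, "nope"), class = "bnsynth_invalid_argument")
})

test_that("colliders pull co-ancestors into the blanket", {
  # X -> C <- Z
  labels <- c("X", "Z", "C")
  dag <- structure(list(n_nodes = 3L, order = labels,
                        edges = cbind(from = c("X", "Z"), to = c("C", "C"))),
                   class = "bn_dag")
  tables <- list(X = new_cpt_cols(matrix(c(0.4, 0.6), ncol = 1)),
                 Z = new_cpt_cols(matrix(c(0.7, 0.3), ncol = 1)),
                 C = new_cpt_cols(rdirichlet_cols_test(2, 4), c(2, 2)))
  m <- bn_model(dag, c(X = 2L, Z = 2L, C = 2L), tables)
  b <- blanket(m, "X")
  expect_identical(b$co_ancestors, "Z")
  expect_identical(b$members, c("X", "Z", "C"))
  # isolated node: empty sets
  iso <- roots_model(list(c(0.5, 0.5), c(0.5, 0.5)))
  bi <- blanket(iso, "X1")
  expect_identical(bi$members, "X1")
  expect_length(bi$ancestors, 0)
})

test_that("deterministic chain blanket joints reduce to the root prior", {
  m <- chain_model(c(0.3, 0.7), diag(2), diag(2))
  b <- blanket(m, "X")
  expect_equal(blanket_joint(m, b, c(A = 0, X = 0, D = 0)), 0.3)
  expect_equal(blanket_joint(m, b, c(A = 1, X = 1, D = 1)), 0.7)
  expect_equal(blanket_joint(m, b, c(A = 0, X = 1, D = 1)), 0)
  expect_error(blanket_joint(m, b, c(A = 0, X = 0)),
               class = "bnsynth_invalid_argument")
})

test_that("blanket joints agree with marginalizing the full joint", {
  set.seed(1)
  for (i in 1:20) {
    mod <- random_bn(5, arities = sample(2:3, 5, replace = TRUE),
                     mode = "prob", p = runif(1, 0.3, 0.9))
    for (X in mod$dag$order) {
      b <- blanket(mod, X)
      tab <- blanket_joint_table(mod, b)
      expect_lt(max(abs(as.numeric(tab) - oracle_blanket_joint(mod, b$members))),
                1e-10)
      expect_lt(abs(sum(tab) - 1), 1e-10)
    }
  }
})

test_that("center conditionals match the full conditional on all other nodes", {
  m <- chain_model(c(0.3, 0.7), diag(2), diag(2))
  expect_equal(center_conditional(m, "X", c(A = 1, D = 1)), c(0, 1))
  set.seed(2)
  for (i in 1:20) {
    mod <- random_bn(sample(4:6, 1), arities = sample(2:3, 1),
                     mode = "prob", p = runif(1, 0.3, 0.9))
    for (X in mod$dag$order) {
      bc <- blanket_conditionals(mod, X)
      or <- oracle_full_conditional(mod, X)
      # map every positive-probability full assignment of the others onto its
      # blanket periphery assignment
      pk <- match(bc$periphery, or$other_nodes)
      full <- bnsynth:::event_decode(seq_len(prod(or$other_arities)),
                                     or$other_arities)
      pidx <- bnsynth:::event_encode(full[, pk, drop = FALSE],
                                     unname(mod$arities[bc$periphery]))
      ok <- or$den > 1e-12
      expect_lt(max(abs(or$cond[, ok, drop = FALSE] -
                          bc$cond[, pidx[ok], drop = FALSE])), 1e-10)
      # normalization of each defined conditional
      keep <- !is.na(bc$cond[1, ])
      expect_true(all(abs(colSums(bc$cond[, keep, drop = FALSE]) - 1) < 1e-12))
    }
  }
})

test_that("impossible periphery assignments raise a typed error", {
  m <- chain_model(c(0.3, 0.7), diag(2), diag(2))
  expect_error(center_conditional(m, "X", c(A = 0, D = 1)),
               class = "bnsynth_undefined_conditional")
})

test_that("periphery inference inverts the chain by Bayes rule", {
  tabX <- cbind(c(0.9, 0.1), c(0.2, 0.8))
  m <- chain_model(c(0.3, 0.7), tabX, cbind(c(0.6, 0.4), c(0.1, 0.9)))
  # infer A given X observed (D fixed): P(A | X = x, D = d) = P(A|X = x)
  post <- periphery_inference(m, "X", 0L, "A", c(D = 0))
  bayes <- tabX[1, ] * c(0.3, 0.7) / sum(tabX[1, ] * c(0.3, 0.7))
  expect_equal(post, unname(bayes), tolerance = 1e-12)
  expect_lt(abs(sum(post) - 1), 1e-12)
  # deterministic invertible chain: point mass on the preimage
  det <- chain_model(c(0.3, 0.7), diag(2)[, 2:1], diag(2))
  expect_equal(periphery_inference(det, "X", 0L, "A", c(D = 0)), c(0, 1))
})

test_that("inference is invariant to the periphery listing order", {
  set.seed(3)
  mod <- random_bn(5, arities = 2, mode = "prob", p = 0.7)
  for (X in mod$dag$order) {
    b <- blanket(mod, X)
    periph <- setdiff(b$members, X)
    if (length(periph) < 2) next
    asn <- stats::setNames(rep(0L, length(periph)), periph)
    c1 <- tryCatch(center_conditional(mod, X, asn),
                   bnsynth_undefined_conditional = function(e) NULL)
    c2 <- tryCatch(center_conditional(mod, X, rev(asn)),
                   bnsynth_undefined_conditional = function(e) NULL)
    expect_identical(c1, c2)
  }
})

test_that("the blanket never contains its own center in the periphery sets", {
  set.seed(4)
  mod <- random_bn(8, arities = 2, mode = "prob", p = 0.8)
  for (X in mod$dag$order) {
    b <- blanket(mod, X)
    expect_false(X %in% c(b$ancestors, b$descendants, b$co_ancestors))
  }
})
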