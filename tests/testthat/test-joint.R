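# Analytic joint computation, empirical joints, divergence, sample size.

test_that("the joint enumerates the full event space and normalizes", {
  m <- random_bn(8, arities = 3, seed = 1)
  jt <- enumerate_joint(m)
  expect_identical(length(jt$probs), 6561L)
  expect_lt(abs(sum(jt$probs) - 1), 1e-10)
  expect_true(all(jt$probs >= 0))
  expect_error(enumerate_joint(random_bn(10, arities = 3, seed = 2),
                               cap = 1e3),
               class = "bnsynth_too_large")
})

test_that("independent roots give the outer-product joint", {
  m <- roots_model(list(c(0.3, 0.7), c(0.4, 0.6)))
  expect_equal(enumerate_joint(m)$probs, c(0.12, 0.18, 0.28, 0.42))
})

test_that("marginals agree between joint summation and propagation", {
  m <- chain_model(c(0.3, 0.7), cbind(c(0.9, 0.1), c(0.2, 0.8)), diag(2))
  mg <- node_marginals(m)
  expect_equal(mg$A, c(0.3, 0.7))
  expect_equal(mg$X, as.vector(cbind(c(0.9, 0.1), c(0.2, 0.8)) %*% c(0.3, 0.7)))
  set.seed(3)
  for (i in 1:20) {
    mod <- random_bn(6, arities = sample(2:3, 6, replace = TRUE),
                     mode = "prob", p = runif(1, 0.3, 0.9))
    m1 <- node_marginals(mod, "joint")
    m2 <- node_marginals(mod, "propagate")
    expect_lt(max(abs(unlist(m1) - unlist(m2))), 1e-10)
    expect_true(all(abs(vapply(m1, sum, 1) - 1) < 1e-10))
  }
})

test_that("empirical joints are normalized counts on the canonical encoding", {
  m <- roots_model(list(c(0.5, 0.5), c(0.5, 0.5)))
  one <- data.frame(X1 = 1L, X2 = 0L)
  ej <- empirical_joint(one, m)
  expect_equal(ej$probs, c(0, 0, 1, 0))  # event (1,0), first node most significant
  ds <- sample_dataset(m, 1000, seed = 4)
  ej <- empirical_joint(ds, m)
  expect_equal(sum(ej$probs), 1)
  bad <- data.frame(X1 = 2L, X2 = 0L)
  expect_error(empirical_joint(bad, m), class = "bnsynth_data_integrity")
})

test_that("Jensen-Shannon divergence is a bounded symmetric divergence", {
  p <- c(0.2, 0.3, 0.5)
  q <- c(0.5, 0.25, 0.25)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(p, q), jsd(q, p))
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)        # disjoint supports, base 2
  expect_error(jsd(p, c(0.5, 0.5)), class = "bnsynth_invalid_argument")
  set.seed(5)
  for (i in 1:50) {
    a <- sample_simplex(6); b <- sample_simplex(6)
    v <- jsd(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    # natural-log variant is bounded by log(2) instead
    expect_lte(jsd(a, b, base = exp(1)), log(2) + 1e-12)
  }
})

test_that("summing the joint over all but one node reproduces the marginals", {
  set.seed(6)
  for (i in 1:50) {
    mod <- random_bn(sample(3:6, 1), arities = sample(2:3, 1),
                     mode = "prob", p = runif(1, 0.2, 0.9))
    jt <- enumerate_joint(mod)
    plan <- bnsynth:::joint_state_plan(jt$arities)
    mg <- node_marginals(mod)
    for (j in seq_along(mod$dag$order)) {
      marg <- as.vector(rowsum(jt$probs, plan[[j]]))
      expect_lt(max(abs(marg - mg[[j]])), 1e-10)
    }
  }
})

test_that("sample-size search meets the maximum-deviation criterion", {
  p <- c(0.5, 0.5)
  # vacuous constraint: minimal grid N
  expect_identical(required_sample_size(p, delta = 1, eps = 0.999,
                                        method = "union-bound"), 1L)
  # monotonicity in delta (union bound is deterministic)
  n_tight <- required_sample_size(p, delta = 5, eps = 0.05,
                                  method = "union-bound")
  n_loose <- required_sample_size(p, delta = 10, eps = 0.05,
                                  method = "union-bound")
  expect_gte(n_tight, n_loose)
  # the union bound is conservative relative to Monte-Carlo: for a uniform p
  # over two events both deviations coincide, so the bound double-counts
  for (i in 1:10) {
    eps_i <- 0.05 + 0.01 * i
    n_ub <- required_sample_size(c(0.5, 0.5), delta = 0.1, eps = eps_i,
                                 method = "union-bound", relative = TRUE)
    n_mc <- required_sample_size(c(0.5, 0.5), delta = 0.1, eps = eps_i,
                                 method = "monte-carlo", reps = 400,
                                 relative = TRUE, seed = i)
    expect_gte(n_ub, n_mc)
  }
  # a deviation bound below the sampling granularity is never attained
  expect_error(required_sample_size(c(0.5, 0.5), delta = 0.4, eps = 1e-6,
                                    method = "union-bound", n_max = 64),
               class = "bnsynth_bound_not_attained")
})
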