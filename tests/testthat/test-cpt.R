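# Conditional probability tables: simplex sampling, dependence rank theory,
# convex-hull vertex structure.

test_that("simplex draws are normalized points of the right dimension", {
  expect_identical(sample_simplex(1, 5), 1)
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    s <- sample_simplex(k, runif(1, 0.2, 3))
    expect_length(s, k)
    expect_true(all(s >= 0))
    expect_lt(abs(sum(s) - 1), 1e-12)
  }
  expect_error(sample_simplex(3, c(1, -1, 1)),
               class = "bnsynth_invalid_argument")
})

test_that("flat draws on the 1-simplex have a uniform first component", {
  set.seed(2)
  x <- replicate(2e4, sample_simplex(2, 1)[1])
  expect_gt(suppressWarnings(stats::ks.test(x, "punif"))$p.value, 0.01)
})

test_that("ancestor event spaces enumerate joint assignments mixed-radix", {
  expect_identical(ancestor_event_space(c(2, 2))$count, 4L)
  expect_identical(ancestor_event_space(c(2, 3))$count, 6L)
  expect_identical(ancestor_event_space(integer(0))$count, 1L)
  es <- ancestor_event_space(c(2, 3))
  # first ancestor most significant: assignment 4 (index 3+1) is (1, 0)
  expect_identical(es$assignments[4, ], c(1L, 0L))
  expect_identical(es$assignments[1, ], c(0L, 0L))
  expect_identical(es$assignments[6, ], c(1L, 2L))
  expect_error(ancestor_event_space(c(2, 1)),
               class = "bnsynth_invalid_argument")
})

test_that("built tables have simplex columns of the prescribed shape", {
  tab <- build_cpt(3, c(3, 3), alpha = 1, seed = 4)
  expect_identical(dim(tab$columns), c(3L, 9L))
  expect_true(all(abs(colSums(tab$columns) - 1) < 1e-12))
  expect_true(all(tab$columns >= 0))
  root <- build_cpt(2, integer(0), seed = 5)
  expect_identical(ncol(root$columns), 1L)
})

test_that("vertex-constrained construction caps the hull vertex count", {
  set.seed(6)
  for (i in 1:200) {
    tab <- build_cpt(3, c(2, 2), n_vertex_columns = 2)
    expect_lte(length(hull_vertices(tab)), 2L)
    expect_true(is_dependent(tab))
  }
  expect_identical(length(hull_vertices(build_cpt(3, c(2, 2),
                                                  n_vertex_columns = 2,
                                                  seed = 7))), 2L)
  expect_error(build_cpt(3, c(2, 2), n_vertex_columns = 1),
               class = "bnsynth_invalid_argument")
})

test_that("rank criterion classifies dependence", {
  rank1 <- cbind(c(0.3, 0.7), c(0.3, 0.7), c(0.3, 0.7))
  expect_false(is_dependent(rank1))
  expect_true(is_dependent(diag(2)))
  v1 <- c(0.8, 0.1, 0.1); v2 <- c(0.1, 0.8, 0.1)
  expect_true(is_dependent(cbind(v1, v2, (v1 + v2) / 2)))
})

test_that("the brute-force event criterion agrees with the rank test", {
  expect_true(dependence_oracle(diag(2), c(0.5, 0.5)))
  rank1 <- cbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_false(dependence_oracle(rank1, c(0.2, 0.8)))
  expect_error(dependence_oracle(diag(2), c(1, 0)),
               class = "bnsynth_invalid_argument")
  # sweep: random tables (mixed constructions), several full-support priors
  set.seed(8)
  for (i in 1:200) {
    n <- sample(2:4, 1)
    anc <- sample(2:3, sample(1:2, 1), replace = TRUE)
    m <- prod(anc)
    tab <- switch(sample(3, 1),
      build_cpt(n, anc, alpha = runif(1, 0.3, 3)),
      {
        ks <- seq(2, max(2, min(m, n)))
        build_cpt(n, anc, n_vertex_columns = ks[sample.int(length(ks), 1)])
      },
      new_cpt_cols(matrix(sample_simplex(n), n, m), anc))  # rank 1
    dep <- is_dependent(tab)
    for (j in 1:5) {
      pY <- sample_simplex(m, 2)
      expect_identical(dependence_oracle(tab, pY), dep)
    }
    r <- sum(svd(tab$columns)$d > max(dim(tab$columns)) *
               .Machine$double.eps * max(svd(tab$columns)$d))
    d <- length(hull_vertices(tab))
    expect_lte(r, d)
    expect_lte(d, m)
  }
})

test_that("hull vertices are the non-representable columns", {
  expect_identical(hull_vertices(diag(3)), c(1L, 2L, 3L))
  v1 <- c(0.8, 0.1, 0.1); v2 <- c(0.1, 0.8, 0.1)
  expect_identical(hull_vertices(cbind(v1, v2, (v1 + v2) / 2)), c(1L, 2L))
  # all-identical columns collapse to one representative
  expect_identical(hull_vertices(cbind(v1, v1, v1)), 1L)
  # duplicates of a vertex representative are all reported
  expect_identical(hull_vertices(cbind(v1, v2, v2)), c(1L, 2L, 3L))
})

test_that("dependent tables have at least two hull vertices", {
  set.seed(9)
  for (i in 1:100) {
    tab <- build_cpt(sample(2:4, 1), sample(2:3, 2, replace = TRUE))
    if (is_dependent(tab)) expect_gte(length(hull_vertices(tab)), 2L)
  }
})

test_that("the induced marginal is the matrix-vector product in the hull", {
  expect_equal(induced_marginal(diag(3), c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  rank1 <- cbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(induced_marginal(rank1, c(0.9, 0.1)), c(0.3, 0.7))
  expect_error(induced_marginal(diag(3), c(0.5, 0.5)),
               class = "bnsynth_invalid_argument")
  set.seed(10)
  for (i in 1:100) {
    tab <- build_cpt(3, c(2, 2))
    p <- induced_marginal(tab, sample_simplex(4))
    expect_true(bnsynth:::in_hull(tab$columns, p))
  }
})
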