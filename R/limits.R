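# Distributional diagnostics: the entropy-density law for naive CPT mixing,
# beta column moments, central-limit drift of descendant marginals, and the
# root-vs-terminal entropy-bias experiment.
#
# When table columns are drawn flat on the simplex and mixed by a flat weight
# vector (exactly what marginalization does to a descendant node), the induced
# marginal is not flat: for two binary columns the density of the mixed first
# component z is 2H(z), twice the binary entropy, and as the number of mixed
# columns grows the component distribution tends to a normal concentrated at
# the simplex center.  Descendant nodes therefore drift toward maximum-entropy
# configurations — a systematic bias of naive Dirichlet model construction.

entropy_nat <- function(p) {
  i <- p > 0
  -sum(p[i] * log(p[i]))
}

#' Density of the mixed component z = t p + (1 - t) q
#'
#' With t, p, q independent and flat on the 1-simplex, the first component of
#' the induced marginal has density f(z) = 2 (-z log z - (1 - z) log(1 - z))
#' = 2 H(z) (natural logarithm): twice the binary entropy, maximal at
#' z = 1/2 and vanishing at the simplex vertices.
#'
#' @param z values in (0, 1); the density extends by continuity to 0 at the
#'   endpoints.
#' @return Density values.
#' @export
entropy_density <- function(z) {
  if (any(!is.finite(z)) || any(z <= 0) || any(z >= 1))
    bn_stop("invalid_argument", "`z` must lie strictly inside (0, 1)")
  2 * (-z * log(z) - (1 - z) * log(1 - z))
}

#' Cumulative distribution of the entropy-density law
#'
#' Closed-form antiderivative of [entropy_density()], used as the reference
#' CDF in goodness-of-fit tests.
#'
#' @param z values in [0, 1].
#' @return CDF values in [0, 1].
#' @export
entropy_cdf <- function(z) {
  out <- numeric(length(z))
  mid <- z > 0 & z < 1
  zm <- z[mid]
  out[mid] <- zm^2 / 2 - zm^2 * log(zm) + 0.5 +
    (1 - zm)^2 * log(1 - zm) - (1 - zm)^2 / 2
  out[z >= 1] <- 1
  out
}

#' Simulation check of the mixed-component law
#'
#' Draws t, p, q independently flat on the 1-simplex, forms
#' z = t p + (1 - t) q, and compares the empirical distribution of z against
#' the entropy-density law via the Kolmogorov-Smirnov statistic.
#'
#' @param n_draws number of draws (>= 1e4).
#' @param seed optional integer seed.
#' @return List: `ks_statistic`, `ks_p_value`, `mean_z`, `n_draws`, and the
#'   draws `z`.
#' @export
prop1_simulation <- function(n_draws = 1e5, seed = NULL) {
  n_draws <- check_count(n_draws, "n_draws", min = 1e4)
  if (!is.null(seed)) set.seed(seed)
  t <- stats::runif(n_draws)
  p <- stats::runif(n_draws)
  q <- stats::runif(n_draws)
  z <- t * p + (1 - t) * q
  ks <- suppressWarnings(stats::ks.test(z, entropy_cdf))
  list(ks_statistic = unname(ks$statistic), ks_p_value = ks$p.value,
       mean_z = mean(z), n_draws = n_draws, z = z)
}

#' Moments of the components of a flat-Dirichlet simplex column
#'
#' Each component of a flat Dirichlet draw on the (m-1)-simplex is
#' Beta(1, m - 1), with mean 1/m and variance (m - 1) / (m^2 (m + 1)).
#'
#' @param m column dimension (>= 2).
#' @return Named list `mean`, `variance`.
#' @export
beta_column_moments <- function(m) {
  m <- check_count(m, "m", min = 2L)
  list(mean = 1 / m, variance = (m - 1) / (m^2 * (m + 1)))
}

#' Central-limit drift experiment for mixed simplex columns
#'
#' Repeatedly draws a flat-Dirichlet m x n column matrix D and a flat weight
#' vector t on the (n-1)-simplex, and records the first component of z = D t.
#' As n (the ancestor event count) grows, the component distribution
#' concentrates around 1/m and approaches normality — the mechanism that
#' pushes descendant-node marginals toward the simplex center.
#'
#' @param m child arity (>= 2).
#' @param n number of mixed columns, i.e. ancestor events (>= 2).
#' @param n_reps number of replicates.
#' @param seed optional integer seed.
#' @return List: `mean`, `variance`, `shapiro_w`, `shapiro_p` (computed on at
#'   most 5000 centered-scaled values), and the recorded components `z1`.
#' @export
clt_experiment <- function(m, n, n_reps = 1e4, seed = NULL) {
  m <- check_count(m, "m", min = 2L)
  n <- check_count(n, "n", min = 2L)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  z1 <- vapply(seq_len(n_reps), function(r) {
    D <- rdirichlet_cols(m, n, 1)
    t <- sample_simplex(n, 1)
    sum(D[1L, ] * t)
  }, numeric(1))
  zs <- (z1 - mean(z1)) / stats::sd(z1)
  sub <- if (length(zs) > 5000L) zs[seq_len(5000L)] else zs
  sh <- stats::shapiro.test(sub)
  list(mean = mean(z1), variance = stats::var(z1),
       shapiro_w = unname(sh$statistic), shapiro_p = sh$p.value, z1 = z1)
}

#' Root-versus-terminal entropy bias experiment
#'
#' For each replicate, draws a random tertiary network (default 8 nodes,
#' per-edge probability 0.8, all table columns flat Dirichlet), computes
#' exact node marginals by propagating the factorized joint, and records the
#' marginal of a root node (the first node in topological order) and of a
#' terminal node (the last).  Root marginals are flat-Dirichlet draws by
#' construction; terminal marginals drift toward the maximum-entropy center,
#' so their mean entropy is systematically higher.
#'
#' @param n_reps number of replicate networks (>= 10).
#' @param n_nodes nodes per network (default 8).
#' @param arity state count per node (default 3).
#' @param p_edge per-edge inclusion probability (default 0.8).
#' @param alpha Dirichlet concentration for all columns (default 1).
#' @param seed optional integer seed.
#' @return A `bn_entropy_report`: `root_samples` and `terminal_samples`
#'   (n_reps x arity matrices of marginals), `mean_entropy_root`,
#'   `mean_entropy_terminal` (natural log), `n_reps`, `seed`.
#' @export
fig1_replication <- function(n_reps = 1e4, n_nodes = 8L, arity = 3L,
                             p_edge = 0.8, alpha = 1, seed = NULL) {
  n_reps <- check_count(n_reps, "n_reps", min = 10L)
  if (!is.null(seed)) set.seed(seed)
  ar <- rep(check_count(arity, "arity", min = 2L), n_nodes)
  plan <- joint_state_plan(ar)          # one shape for every replicate
  root_s <- matrix(0, n_reps, arity)
  term_s <- matrix(0, n_reps, arity)
  labels <- paste0("X", seq_len(n_nodes))
  for (r in seq_len(n_reps)) {
    dag <- sample_dag(n_nodes, mode = "prob", p = p_edge)
    parents <- lapply(stats::setNames(labels, labels), dag_parents, dag = dag)
    tables <- lapply(labels, function(v) {
      m <- prod(ar[match(parents[[v]], labels)])
      list(columns = rdirichlet_cols(arity, max(1L, m), alpha))
    })
    names(tables) <- labels
    mod <- list(dag = dag, arities = stats::setNames(ar, labels),
                parents = parents, tables = tables)
    probs <- joint_probs_from_plan(mod, plan)
    root_s[r, ] <- tables[[1L]]$columns[, 1L]      # first node is always a root
    term_s[r, ] <- as.vector(rowsum(probs, plan[[n_nodes]]))
  }
  structure(list(root_samples = root_s, terminal_samples = term_s,
                 mean_entropy_root = mean(apply(root_s, 1L, entropy_nat)),
                 mean_entropy_terminal = mean(apply(term_s, 1L, entropy_nat)),
                 n_reps = n_reps, seed = seed),
            class = "bn_entropy_report")
}

#' @export
print.bn_entropy_report <- function(x, ...) {
  cat(sprintf(paste0("bn_entropy_report: %d replicates\n",
                     "  mean entropy (nats): root %.4f, terminal %.4f\n"),
              x$n_reps, x$mean_entropy_root, x$mean_entropy_terminal))
  invisible(x)
}
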