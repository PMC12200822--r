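test_that("exact enumeration: symmetry, constraint, and normalization", {
  set.seed(21)
  x <- rnorm(300)
  y <- 0.9 * x + rnorm(300, sd = 0.4)
  X <- cbind(a = x, b = y)

  en <- enumerate_posterior(X)
  expect_equal(en$n_dags, 3L)
  # strong dependence: an edge in either direction with the two
  # Markov-equivalent orientations splitting the mass evenly
  expect_gt(en$p_edge[1, 2] + en$p_edge[2, 1], 0.99)
  expect_equal(en$p_edge[1, 2], en$p_edge[2, 1], tolerance = 1e-9)

  # temporal constraint: backward edge has probability exactly 0
  en2 <- enumerate_posterior(X, slices = c(0L, 1L))
  expect_equal(en2$p_edge[2, 1], 0)
  expect_gt(en2$p_edge[1, 2], 0.99)

  # 3 unconstrained nodes enumerate to the known 25 DAGs
  en3 <- enumerate_posterior(chain_data(50, seed = 3))
  expect_equal(en3$n_dags, 25L)
  expect_true(all(en3$p_edge >= 0 & en3$p_edge <= 1))
  expect_error(enumerate_posterior(matrix(rnorm(60), 10, 6)), "refuses")
})

test_that("partition MCMC reproduces the exact posterior on 3 nodes", {
  X <- chain_data(500, seed = 11)
  en <- enumerate_posterior(X)
  s <- run_partition_mcmc(X, slices = NA, config = mcmc_config(
    chains = 2, iterations = 6000, burn_in = 1500, thin = 5, seed = 5,
    max_parents = 2))
  p <- edge_probabilities(s)
  # each edge probability within 3 Monte-Carlo standard errors (with a small
  # floor guarding the zero-variance indicator case)
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) next
      ind <- (bitwAnd(s$draws[, j], bitwShiftL(1L, i - 1L)) > 0L) * 1
      mcse <- stats::sd(ind) / sqrt(causalrank:::effective_size(ind))
      expect_lt(abs(p[i, j] - en$p_edge[i, j]), max(3 * mcse, 0.01))
    }
  }
})

test_that("same master seed gives bit-identical samples", {
  X <- chain_data(120, seed = 4)
  cfg <- mcmc_config(chains = 2, iterations = 800, burn_in = 200, thin = 4,
                     seed = 42, max_parents = 2)
  s1 <- run_partition_mcmc(X, slices = NA, config = cfg)
  s2 <- run_partition_mcmc(X, slices = NA, config = cfg)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$seeds, s2$seeds)
  s3 <- run_partition_mcmc(X, slices = NA, config = mcmc_config(
    chains = 2, iterations = 800, burn_in = 200, thin = 4, seed = 43,
    max_parents = 2))
  expect_false(identical(s1$draws, s3$draws))
})

test_that("every sampled DAG is acyclic and never points back in time", {
  cfg <- generator_config(domains = TRI, n_lagged = 1, n_within = 1)
  truth <- sample_scm(cfg, seed = 3)
  panel <- simulate_panel(truth, 300, seed = 4)
  s <- run_partition_mcmc(ordinal_encode(panel), config = mcmc_config(
    chains = 2, iterations = 1500, burn_in = 500, thin = 10, seed = 9))
  n <- length(s$nodes)
  expect_identical(s$slices, c(0L, 0L, 0L, 1L, 1L, 1L))
  for (r in seq_len(nrow(s$draws))) {
    adj <- causalrank:::masks_to_adj(s$draws[r, ], n)
    expect_true(causalrank:::is_acyclic(adj))
    expect_equal(sum(adj[s$slices == 1L, s$slices == 0L]), 0)
  }
})

test_that("with near-uninformative data the sampler visits all partition sizes", {
  set.seed(77)
  X <- matrix(rnorm(4 * 3), 4, 3) # prior-predictive-sized draw
  s <- run_partition_mcmc(X, slices = NA, config = mcmc_config(
    chains = 1, iterations = 3000, burn_in = 500, thin = 2, seed = 1,
    max_parents = 2))
  sizes <- vapply(seq_len(nrow(s$draws)), function(r) {
    adj <- causalrank:::masks_to_adj(s$draws[r, ], 3)
    length(causalrank:::dag_to_partition(adj))
  }, 0L)
  expect_setequal(unique(sizes), 1:3)
})

test_that("edge probabilities are draw frequencies with exclusive directions", {
  nodes <- c("a_t0", "b_t0", "a_t1", "b_t1")
  adj1 <- matrix(0L, 4, 4); adj1[1, 3] <- 1L; adj1[2, 4] <- 1L
  s_same <- manual_samples(list(adj1, adj1, adj1), nodes)
  p <- edge_probabilities(s_same)
  expect_true(all(p %in% c(0, 1)))
  expect_equal(p[1, 3], 1)

  X <- chain_data(200, seed = 8)
  s <- run_partition_mcmc(X, slices = NA, config = mcmc_config(
    chains = 2, iterations = 1000, burn_in = 200, thin = 5, seed = 3,
    max_parents = 2))
  p2 <- edge_probabilities(s)
  expect_true(all(p2 + t(p2) <= 1 + 1e-12))
})

test_that("path probability dominates edge probability and matches reachability", {
  # chain-only sample set: a path a -> c with no direct edge
  nodes <- c("a", "b", "c")
  chain <- matrix(0L, 3, 3); chain[1, 2] <- 1L; chain[2, 3] <- 1L
  s <- manual_samples(list(chain, chain), nodes)
  expect_equal(path_probability(s, "a", "c"), 1)
  expect_equal(edge_probabilities(s)[1, 3], 0)
  expect_error(path_probability(s, "a", "a"), "differ")

  # reachability oracle on random 5-node DAGs
  set.seed(99)
  dfs_reaches <- function(adj, i, j) {
    seen <- rep(FALSE, nrow(adj))
    stack <- which(adj[i, ] > 0)
    while (length(stack) > 0L) {
      v <- stack[1L]; stack <- stack[-1L]
      if (v == j) return(TRUE)
      if (!seen[v]) {
        seen[v] <- TRUE
        stack <- c(stack, which(adj[v, ] > 0))
      }
    }
    FALSE
  }
  for (rep_i in 1:100) {
    perm <- sample(5)
    adj <- matrix(0L, 5, 5)
    for (a in 1:4) for (b in (a + 1):5) {
      if (runif(1) < 0.4) adj[perm[a], perm[b]] <- 1L
    }
    s1 <- manual_samples(list(adj), paste0("v", 1:5))
    pm <- causalrank:::path_probability_matrix(s1)
    ij <- sample(5, 2)
    expect_equal(pm[ij[1], ij[2]],
                 as.numeric(dfs_reaches(adj, ij[1], ij[2])))
  }

  # p_path >= p_parent over a sampled run
  X <- chain_data(300, seed = 12)
  srun <- run_partition_mcmc(X, slices = NA, config = mcmc_config(
    chains = 2, iterations = 1500, burn_in = 300, thin = 5, seed = 2,
    max_parents = 2))
  expect_true(all(causalrank:::path_probability_matrix(srun) -
                    edge_probabilities(srun) >= -1e-12))
})

test_that("consensus graph filters edges at the display threshold", {
  nodes <- c("a_t0", "b_t0", "a_t1", "b_t1")
  adj1 <- matrix(0L, 4, 4); adj1[1, 3] <- 1L; adj1[2, 4] <- 1L # always
  adj2 <- adj1; adj2[1, 4] <- 1L                               # half
  s <- manual_samples(list(adj1, adj2), nodes, slices = c(0L, 0L, 1L, 1L))
  all_edges <- consensus_graph(s, threshold = 0)
  expect_equal(nrow(all_edges$edges), 3L)
  expect_setequal(all_edges$edges$type, c("autoregressive", "lagged"))
  high <- consensus_graph(s, threshold = 0.9)
  expect_equal(nrow(high$edges), 2L)
  expect_true(all(high$edges$p_parent == 1))
  expect_true(all(all_edges$p_path >= all_edges$p_parent - 1e-12))
  # default threshold is the 10% display rule
  expect_equal(consensus_graph(s)$threshold, 0.1)
})

test_that("convergence report measures cross-chain edge-probability spread", {
  nodes <- c("a", "b")
  e <- matrix(0L, 2, 2)
  full <- e; full[1, 2] <- 1L
  identical_chains <- manual_samples(list(full, full, full, full), nodes,
                                     chain = c(1L, 1L, 2L, 2L))
  rep1 <- convergence_report(identical_chains)
  expect_equal(rep1$max_spread, 0)
  expect_true(rep1$pass)

  opposite <- manual_samples(list(e, e, full, full), nodes,
                             chain = c(1L, 1L, 2L, 2L))
  rep2 <- convergence_report(opposite)
  expect_equal(rep2$max_spread, 1)
  expect_false(rep2$pass)

  single <- manual_samples(list(full), nodes)
  expect_error(convergence_report(single), "two chains")
})

test_that("a well-mixed 3-node run keeps chains within tight agreement", {
  X <- chain_data(400, seed = 17)
  s <- run_partition_mcmc(X, slices = NA, config = mcmc_config(
    chains = 3, iterations = 6000, burn_in = 1500, thin = 5, seed = 6,
    max_parents = 2))
  expect_lt(convergence_report(s)$max_spread, 0.05)
})
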