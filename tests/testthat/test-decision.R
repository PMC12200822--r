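test_that("utility presets evaluate the documented values", {
  expect_equal(utility(uniform_state("healthy"), utility_spec()), 7)
  expect_equal(utility(uniform_state("poor"), utility_spec()), 0)
  expect_equal(utility(uniform_state("fair"), utility_spec()), 7 * 0.75)
  expect_equal(utility(uniform_state("fair"), utility_spec("risk_neutral")), 3.5)
  expect_equal(utility(uniform_state("fair"), utility_spec("risk_averse")), 7)

  # custom weights enter linearly
  spec <- utility_spec(weights = c(sleep = 2))
  st <- profile_state(sleep = "healthy", distress = "poor", social = "fair",
                      domains = TRI)
  expect_equal(utility(st, spec), 2 * 1 + 0 + 0.75)

  expect_error(utility_spec("bogus"), "preset")
  expect_error(utility_spec(c(poor = 1, fair = 0.5, healthy = 0)),
               "non-decreasing")
  expect_error(utility_spec(weights = c(-1)), "named")
})

test_that("expected utility is exact and obeys the childless-do identity", {
  det <- point_mass_bn(TRI)
  st <- uniform_state("poor", TRI)
  for (a in c("nothing", TRI)) {
    expect_equal(expected_utility(det, st, a), 3, tolerance = 1e-12)
  }

  # childless target: EU(do(d)) = EU(nothing) + w_d * (1 - E[u_d])
  cfg <- generator_config(domains = TRI, n_lagged = 0, n_within = 0)
  truth <- sample_scm(cfg, seed = 51)
  st2 <- profile_state(sleep = "poor", distress = "fair", social = "healthy",
                       domains = TRI)
  spec <- utility_spec()
  eu0 <- expected_utility(truth$bn, st2, "nothing", spec)
  marg <- followup_marginals(followup_distribution(truth$bn, st2))
  for (d in TRI) {
    eu_d <- sum(spec$u * marg[d, ])
    expect_equal(expected_utility(truth$bn, st2, d, spec),
                 eu0 + 1 * (1 - eu_d), tolerance = 1e-10)
  }
  expect_error(expected_utility(truth$bn, st2, "karma"), "action")
})

test_that("exact EU matches a forward-sampling Monte Carlo estimate", {
  cfg <- generator_config(domains = TRI, n_lagged = 1, n_within = 2,
                          effect_size = 0.3)
  truth <- sample_scm(cfg, seed = 53)
  st <- profile_state(sleep = "fair", distress = "poor", social = "healthy",
                      domains = TRI)
  spec <- utility_spec()
  for (a in c("nothing", "distress")) {
    bn <- if (a == "nothing") truth$bn else mutilate(truth$bn, a)
    set.seed(54)
    draws <- sample_followups(bn, st, 1e5)
    u_draws <- rowSums(matrix(spec$u[draws + 1L], nrow = nrow(draws)))
    mc <- mean(u_draws)
    se <- stats::sd(u_draws) / sqrt(length(u_draws))
    expect_lt(abs(expected_utility(truth$bn, st, a, spec) - mc), 3.5 * se)
  }
})

test_that("posterior EU averages per-sample exact EU with an MCSE", {
  cfg <- generator_config(domains = TRI, n_lagged = 1, n_within = 1)
  truth <- sample_scm(cfg, seed = 55)
  panel <- simulate_panel(truth, 400, seed = 56)
  dag0 <- matrix(0L, 6, 6)
  bn_a <- fit_cpts(dag0, panel, 1)
  dag1 <- dag0; dag1[1, 4] <- 1L; dag1[2, 5] <- 1L; dag1[3, 6] <- 1L
  bn_b <- fit_cpts(dag1, panel, 1)
  st <- uniform_state("fair", TRI)

  same <- posterior_eu(list(bn_a, bn_a, bn_a), st)
  expect_equal(same$se, 0)
  expect_equal(same$sd, 0)

  mixed <- posterior_eu(list(bn_a, bn_b, bn_a, bn_b), st)
  flipped <- posterior_eu(list(bn_b, bn_a, bn_b, bn_a), st)
  expect_equal(mixed$mean, flipped$mean, tolerance = 1e-12)
  expect_gt(mixed$se, 0)

  expect_error(posterior_eu(list(bn_a), st), "at least two")
})

test_that("ATE is the paired EU difference and vanishes for a saturated target", {
  cfg <- generator_config(domains = TRI, n_lagged = 1, n_within = 1)
  truth <- sample_scm(cfg, seed = 57)
  panel <- simulate_panel(truth, 500, seed = 58)
  dag0 <- matrix(0L, 6, 6); dag0[1, 4] <- 1L
  dag1 <- dag0; dag1[2, 5] <- 1L
  bns <- list(fit_cpts(dag0, panel, 1), fit_cpts(dag1, panel, 1))
  st <- uniform_state("poor", TRI)

  a <- ate(bns, st, "sleep")
  # paired average equals difference of averages, by linearity, exactly
  expect_equal(a$mean,
               posterior_eu(bns, st, "sleep")$mean -
                 posterior_eu(bns, st, "nothing")$mean,
               tolerance = 1e-12)
  # childless target: ATE >= 0 whenever u(healthy) is maximal
  expect_gte(a$mean, 0)

  # a deterministic-healthy childless target gains nothing
  det <- point_mass_bn(TRI)
  expect_equal(ate(list(det, det), st, "sleep")$mean, 0, tolerance = 1e-12)
  expect_error(ate(bns, st, "nothing"), "domain")
})

test_that("a multi-descendant intervention exceeds the single-domain ATE bound", {
  # distress drives three other domains; do(distress) lifts all four
  doms <- c("functioning", "distress", "sleep", "social")
  eff <- rbind(c(0.9, 0.05, 0.05),
               c(1, 1, 1) / 3,
               c(0.05, 0.05, 0.9))
  bn <- manual_bn(doms, list(
    distress_t1 = list(parents = character(0),
                       table = matrix(c(0.9, 0.05, 0.05), 1)),
    functioning_t1 = list(parents = "distress_t1", table = eff),
    sleep_t1 = list(parents = "distress_t1", table = eff),
    social_t1 = list(parents = "distress_t1", table = eff)))
  st <- uniform_state("poor", doms)
  res <- ate(list(bn, bn), st, "distress")
  expect_gt(res$mean, 1) # only possible through cross-domain effects
  for (d in setdiff(doms, "distress")) {
    expect_lt(ate(list(bn, bn), st, d)$mean, 1 + 1e-9)
  }
})

test_that("rank_targets prefers the failing domain and reports ordered actions", {
  # edge-free persistence: the single unhealthy domain is the best target
  cfg <- generator_config(domains = TRI, n_lagged = 0, n_within = 0,
                          ar_strength = 0.8)
  truth <- sample_scm(cfg, seed = 61)
  bns <- list(truth$bn, truth$bn)
  st <- profile_state(sleep = "healthy", distress = "poor", social = "healthy",
                      domains = TRI)
  res <- rank_targets(bns, st)
  expect_s3_class(res, "decision_result")
  expect_equal(res$ranking[1], "distress")
  expect_equal(res$table$ate[res$table$action == "nothing"], 0)
  expect_true(all(diff(res$table$eu) <= 1e-12))
  expect_true(all(res$table$eu >= 0 & res$table$eu <= 3 + 1e-9))

  # regression to the mean: with everything healthy, the domain most likely
  # to revert to unhealthy ranks first
  revert <- rbind(c(0.05, 0.05, 0.9),
                  c(0.05, 0.05, 0.9),
                  c(0.4, 0.2, 0.4))
  persist <- rbind(c(0.9, 0.05, 0.05),
                   c(0.05, 0.9, 0.05),
                   c(0.02, 0.03, 0.95))
  bn2 <- manual_bn(TRI, list(
    sleep_t1 = list(parents = "sleep_t0", table = persist),
    distress_t1 = list(parents = "distress_t0", table = persist),
    social_t1 = list(parents = "social_t0", table = revert)))
  res2 <- rank_targets(list(bn2, bn2), uniform_state("healthy", TRI))
  expect_equal(res2$ranking[1], "social")
  sub <- res2$subutility
  expect_lt(sub$eu_sub[sub$domain == "social"],
            min(sub$eu_sub[sub$domain != "social"]))
})

test_that("preference order is invariant under positive affine utility maps", {
  cfg <- generator_config(domains = TRI, n_lagged = 1, n_within = 1)
  truth <- sample_scm(cfg, seed = 63)
  panel <- simulate_panel(truth, 400, seed = 64)
  s <- run_partition_mcmc(ordinal_encode(panel), config = mcmc_config(
    chains = 2, iterations = 1200, burn_in = 400, thin = 10, seed = 3))
  bns <- fit_posterior_bns(s, panel, max_bns = 20)
  base <- utility_spec()
  affine <- utility_spec(0.4 * base$u + 0.2, name = "affine")
  w <- baseline_state_weights(panel)
  for (st in list(uniform_state("poor", TRI), uniform_state("fair", TRI))) {
    expect_identical(rank_targets(bns, st, base)$ranking,
                     rank_targets(bns, st, affine)$ranking)
  }
  expect_equal(p_opt_summary(bns, w, base)$p_opt,
               p_opt_summary(bns, w, affine)$p_opt, tolerance = 1e-12)
})

test_that("p_opt and p_rec are proper distributions over targets", {
  doms <- c("functioning", "distress", "sleep", "social")
  cfg <- generator_config(domains = doms, n_lagged = 1, n_within = 1)
  truth <- sample_scm(cfg, seed = 65)
  panel <- simulate_panel(truth, 600, seed = 66)
  dag0 <- matrix(0L, 8, 8)
  for (d in 1:4) dag0[d, 4 + d] <- 1L
  dag1 <- dag0; dag1[6, 7] <- 1L
  bns <- list(fit_cpts(dag0, panel, 1), fit_cpts(dag1, panel, 1))
  w <- baseline_state_weights(panel)
  po <- p_opt_summary(bns, w, top_n = 3L)
  expect_equal(sum(po$p_opt), 1, tolerance = 1e-9)
  expect_equal(sum(po$p_rec), 3, tolerance = 1e-9)
  expect_true(all(po$p_opt >= 0 & po$p_opt <= 1))
  expect_true(all(po$p_rec >= po$p_opt - 1e-12))
  # p_rec(1) is p_opt
  po1 <- p_opt_summary(bns, w, top_n = 1L)
  expect_equal(po1$p_rec, po1$p_opt, tolerance = 1e-12)

  # one state, identical samples: p_opt is an indicator vector
  one <- w[1, , drop = FALSE]
  one$weight <- 1
  po_one <- p_opt_summary(list(bns[[1]], bns[[1]]), one)
  expect_setequal(unique(as.numeric(po_one$p_opt)), c(0, 1))

  expect_error(p_opt_summary(bns, transform(w, weight = weight * 2)),
               "sum to 1")
})

test_that("end-to-end: the learned system recovers the true optimal targets", {
  cfg <- generator_config(domains = TRI, n_lagged = 1, n_within = 1)
  truth <- sample_scm(cfg, seed = 41)
  panel <- simulate_panel(truth, 5000, seed = 42)
  s <- run_partition_mcmc(ordinal_encode(panel), config = mcmc_config(
    chains = 2, iterations = 4000, burn_in = 1000, thin = 10, seed = 7))
  bns <- fit_posterior_bns(s, panel, max_bns = 100)
  w <- baseline_state_weights(panel)
  po <- p_opt_summary(bns, w)
  rr <- recovery_report(truth, s, po)
  expect_gt(rr$min_autoregressive_prob, 0.8)

  heavy <- po$per_state[po$per_state$weight > 0.05, ]
  expect_gt(nrow(heavy), 0)
  tt <- true_optimal_targets(truth, heavy[, TRI])
  expect_identical(heavy$modal_target, tt$optimal_target)
  # the posterior concentrates on the true optimum for the common states
  p_true <- vapply(seq_len(nrow(heavy)), function(i) {
    heavy[i, paste0("p_opt_", tt$optimal_target[i])]
  }, 0)
  expect_true(all(p_true > 0.9))
})

test_that("sensitivity analysis reacts to risk attitude and weights", {
  cfg <- generator_config(domains = TRI, n_lagged = 1, n_within = 1)
  truth <- sample_scm(cfg, seed = 67)
  panel <- simulate_panel(truth, 400, seed = 68)
  dag0 <- matrix(0L, 6, 6)
  for (d in 1:3) dag0[d, 3 + d] <- 1L
  bns <- list(fit_cpts(dag0, panel, 1), fit_cpts(dag0, panel, 1))
  w <- baseline_state_weights(panel)

  tab <- sensitivity_table(bns, w, specs = list(a = utility_spec(),
                                                b = utility_spec()))
  expect_equal(unlist(tab[1, -1]), unlist(tab[2, -1]), tolerance = 1e-12)

  # risk-averse preset: a domain stuck at fair with no descendants gains
  # nothing from self-intervention
  stuck <- manual_bn(TRI, list(
    sleep_t1 = list(parents = character(0), table = matrix(c(0, 1, 0), 1)),
    distress_t1 = list(parents = character(0),
                       table = matrix(c(0.3, 0.3, 0.4), 1)),
    social_t1 = list(parents = character(0),
                     table = matrix(c(0.3, 0.3, 0.4), 1))))
  st <- uniform_state("fair", TRI)
  ra <- utility_spec("risk_averse")
  expect_equal(expected_utility(stuck, st, "sleep", ra),
               expected_utility(stuck, st, "nothing", ra), tolerance = 1e-12)
  expect_gt(expected_utility(stuck, st, "sleep", utility_spec()),
            expected_utility(stuck, st, "nothing", utility_spec()))

  # weights reorder targets once the weight ratio crosses the EU-difference
  # ratio: gains are w_a * 0.5 vs w_b * 0.2, crossing at w_b / w_a = 2.5
  two <- manual_bn(c("a", "b"), list(
    a_t1 = list(parents = character(0), table = matrix(c(0.5, 0, 0.5), 1)),
    b_t1 = list(parents = character(0), table = matrix(c(0.2, 0, 0.8), 1))))
  st2 <- uniform_state("poor", c("a", "b"))
  equal_w <- rank_targets(list(two, two), st2, utility_spec())
  expect_equal(equal_w$ranking[1], "a")
  up_b <- rank_targets(list(two, two), st2,
                       utility_spec(weights = c(b = 3)))
  expect_equal(up_b$ranking[1], "b")
})
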