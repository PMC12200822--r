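# Bayesian decision layer: utilities, expected utility under the posterior
# over causal networks, treatment effects, and intervention-target rankings.

#' Utility specification
#'
#' A utility is an equal- or custom-weighted sum of per-domain subutilities
#' of the ordinal level. Named presets:
#' \describe{
#'   \item{default}{u = (poor 0, fair 0.75, healthy 1); moderately
#'     risk-averse.}
#'   \item{risk_neutral}{u = (poor 0, fair 0.5, healthy 1).}
#'   \item{risk_averse}{u = (poor 0, fair 1, healthy 1).}
#' }
#'
#' @param subutility a preset name or a named numeric vector
#'   `c(poor=, fair=, healthy=)`, non-decreasing in the level order.
#' @param weights `NULL` for equal weight 1 per domain, or a named
#'   non-negative vector over domains (missing domains get weight 1).
#' @param name label used in reports.
#' @return list of class `"utility_spec"` with elements `u`, `weights`,
#'   `name`.
#' @export
#' @examples
#' utility_spec()                     # the default preset
#' utility_spec("risk_neutral")
#' utility_spec(weights = c(distress = 2, functioning = 2))
utility_spec <- function(subutility = "default", weights = NULL,
                         name = NULL) {
  presets <- list(default = c(poor = 0, fair = 0.75, healthy = 1),
                  risk_neutral = c(poor = 0, fair = 0.5, healthy = 1),
                  risk_averse = c(poor = 0, fair = 1, healthy = 1))
  if (is.character(subutility) && length(subutility) == 1L) {
    if (!subutility %in% names(presets)) {
      stop("unknown subutility preset: ", subutility, call. = FALSE)
    }
    if (is.null(name)) name <- subutility
    u <- presets[[subutility]]
  } else {
    u <- subutility[LEVELS]
    if (anyNA(u)) stop("subutility must name poor, fair and healthy", call. = FALSE)
    if (is.unsorted(u)) {
      stop("subutility must be non-decreasing in poor < fair < healthy",
           call. = FALSE)
    }
    if (is.null(name)) name <- "custom"
  }
  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(!is.finite(weights)) || any(weights < 0)) {
      stop("weights must be a named, finite, non-negative vector", call. = FALSE)
    }
  }
  structure(list(u = u, weights = weights, name = name),
            class = "utility_spec")
}

resolve_weights <- function(spec, domains) {
  w <- stats::setNames(rep(1, length(domains)), domains)
  if (!is.null(spec$weights)) {
    known <- intersect(names(spec$weights), domains)
    w[known] <- spec$weights[known]
  }
  w
}

#' Utility of a profile state
#'
#' `sum_d w_d * u(level_d)`. With the default spec and seven equal-weighted
#' domains the utility ranges from 0 (all poor) to 7 (all healthy).
#'
#' @param state a [profile_state()].
#' @param spec a [utility_spec()].
#' @return scalar utility.
#' @export
#' @examples
#' utility(uniform_state("healthy"), utility_spec())  # 7
#' utility(uniform_state("poor"), utility_spec())     # 0
utility <- function(state, spec = utility_spec()) {
  domains <- names(state)
  w <- resolve_weights(spec, domains)
  sum(w * spec$u[unclass(state)[domains]])
}

# Validate/normalize an action: "nothing" or a registered domain name,
# meaning do(domain = healthy) at follow-up.
check_action <- function(action, domains) {
  if (identical(action, "nothing")) return("nothing")
  if (is.character(action) && length(action) == 1L && action %in% domains) {
    return(action)
  }
  stop("action must be \"nothing\" or a registered domain name", call. = FALSE)
}

#' Exact expected utility of an action
#'
#' For `action = "nothing"`, the expectation of [utility()] over the exact
#' [followup_distribution()]; for a domain name, the same on the
#' [mutilate()]d network (the do-operation). Computed by exhaustive
#' enumeration of all follow-up states - no sampling error.
#'
#' @param bn a `cat_bn`.
#' @param baseline a [profile_state()].
#' @param action `"nothing"` or a domain name to intervene on.
#' @param spec a [utility_spec()].
#' @return scalar expected utility.
#' @export
expected_utility <- function(bn, baseline, action = "nothing",
                             spec = utility_spec()) {
  action <- check_action(action, bn$domains)
  net <- if (action == "nothing") bn else mutilate(bn, action)
  dist <- followup_distribution(net, baseline)
  configs <- attr(dist, "configs")
  w <- resolve_weights(spec, bn$domains)
  uu <- config_utilities(configs, spec$u, w)
  sum(dist * uu)
}

config_utilities <- function(configs, u, w) {
  uu <- numeric(nrow(configs))
  for (d in seq_len(ncol(configs))) {
    uu <- uu + w[d] * u[configs[, d] + 1L]
  }
  uu
}

# --- fast exact evaluator -------------------------------------------------
#
# For ranking and p_opt summaries the same BN is queried for 1 + K actions
# and many baseline states. The joint factorizes over follow-up nodes, so we
# precompute, per BN and follow-up node, the configuration-indexed CPT
# lookups that do not depend on the baseline, and obtain all interventional
# joints from leave-one-out prefix/suffix products (robust to zero entries,
# equivalent to enumeration on the mutilated network because intervened
# factors are replaced by the indicator of "healthy").

prep_bn_eval <- function(bn, configs) {
  k <- length(bn$domains)
  pernode <- vector("list", k)
  for (d in seq_len(k)) {
    cpt <- bn$cpts[[k + d]]
    parents <- cpt$parents
    idx <- rep(1L, nrow(configs))
    bp <- integer(0)
    bp_mult <- numeric(0)
    if (length(parents) > 0L) {
      for (i in seq_along(parents)) {
        pa <- parents[i]
        if (pa <= k) {
          bp <- c(bp, pa)
          bp_mult <- c(bp_mult, 3L^(i - 1L))
        } else {
          idx <- idx + configs[, pa - k] * 3L^(i - 1L)
        }
      }
    }
    pernode[[d]] <- list(lin0 = idx + (configs[, d]) * nrow(cpt$table),
                         bp = bp, bp_mult = bp_mult,
                         table = as.numeric(cpt$table))
  }
  pernode
}

# Expected utilities of all actions (nothing + do(d) for every domain) for
# one BN and one baseline, plus the per-domain expected subutility under
# nothing. uu: utility of each config; uu_do[[d]]: uu restricted to configs
# with domain d healthy.
eu_all_actions <- function(prep, baseline_codes, configs, uu, uu_do, u) {
  k <- ncol(configs)
  nc <- nrow(configs)
  probs <- vector("list", k)
  for (d in seq_len(k)) {
    pn <- prep[[d]]
    off <- if (length(pn$bp)) sum(baseline_codes[pn$bp] * pn$bp_mult) else 0
    probs[[d]] <- pn$table[pn$lin0 + off]
  }
  pref <- vector("list", k + 1L)
  suf <- vector("list", k + 1L)
  pref[[1L]] <- rep(1, nc)
  suf[[k + 1L]] <- rep(1, nc)
  for (d in seq_len(k)) pref[[d + 1L]] <- pref[[d]] * probs[[d]]
  for (d in rev(seq_len(k))) suf[[d]] <- suf[[d + 1L]] * probs[[d]]
  joint <- pref[[k + 1L]]
  eu <- numeric(k + 1L)
  eu[1L] <- sum(joint * uu)
  eu_sub <- numeric(k)
  for (d in seq_len(k)) {
    eu[d + 1L] <- sum(pref[[d]] * suf[[d + 1L]] * uu_do[[d]])
    eu_sub[d] <- sum(joint * u[configs[, d] + 1L])
  }
  list(eu = eu, eu_sub = eu_sub)
}

# Shared precomputation across BNs for a fixed registry and utility spec.
decision_prep <- function(bns, spec) {
  stopifnot(length(bns) >= 1L)
  domains <- bns[[1L]]$domains
  configs <- enumerate_configs(length(domains))
  w <- resolve_weights(spec, domains)
  uu <- config_utilities(configs, spec$u, w)
  uu_do <- lapply(seq_along(domains), function(d) uu * (configs[, d] == 2L))
  preps <- lapply(bns, prep_bn_eval, configs = configs)
  list(domains = domains, configs = configs, uu = uu, uu_do = uu_do,
       u = spec$u, preps = preps)
}

# EU matrix (n_bns x (K+1)) and subutility matrix (n_bns x K) for one state.
eu_matrix_for_state <- function(dp, baseline_codes) {
  nb <- length(dp$preps)
  k <- length(dp$domains)
  eu <- matrix(0, nb, k + 1L)
  eu_sub <- matrix(0, nb, k)
  for (b in seq_len(nb)) {
    res <- eu_all_actions(dp$preps[[b]], baseline_codes, dp$configs,
                          dp$uu, dp$uu_do, dp$u)
    eu[b, ] <- res$eu
    eu_sub[b, ] <- res$eu_sub
  }
  colnames(eu) <- c("nothing", dp$domains)
  colnames(eu_sub) <- dp$domains
  list(eu = eu, eu_sub = eu_sub)
}

#' Posterior expected utility of an action
#'
#' Averages the exact per-network expected utility over a collection of
#' networks sampled from the structure posterior. The standard error is the
#' Monte Carlo standard error `sd / sqrt(ESS)` with the effective sample
#' size estimated from the autocorrelation of the per-sample EU series; the
#' plain posterior standard deviation is also returned.
#'
#' @param bns list of `cat_bn` networks (posterior samples); at least 2.
#' @param baseline a [profile_state()].
#' @param action `"nothing"` or a domain name.
#' @param spec a [utility_spec()].
#' @return list with `mean`, `se`, `sd`, `ess` and the per-sample `draws`.
#' @export
posterior_eu <- function(bns, baseline, action = "nothing",
                         spec = utility_spec()) {
  if (length(bns) < 2L) {
    stop("posterior_eu needs at least two posterior samples", call. = FALSE)
  }
  action <- check_action(action, bns[[1L]]$domains)
  draws <- vapply(bns, expected_utility, 0, baseline = baseline,
                  action = action, spec = spec)
  summarize_draws(draws)
}

summarize_draws <- function(draws) {
  ess <- effective_size(draws)
  sdv <- stats::sd(draws)
  list(mean = mean(draws), se = sdv / sqrt(ess), sd = sdv, ess = ess,
       draws = draws)
}

#' Average treatment effect of an intervention
#'
#' Difference in expected utility between the idealized intervention
#' `do(target = healthy)` and doing nothing, conditional on the baseline
#' state, paired per posterior sample before averaging.
#'
#' @param bns list of `cat_bn` posterior samples (at least 2).
#' @param baseline a [profile_state()].
#' @param target a registered domain name.
#' @param spec a [utility_spec()].
#' @return list with `mean`, `se`, `sd`, `ess` and per-sample `draws` of the
#'   paired difference.
#' @export
ate <- function(bns, baseline, target, spec = utility_spec()) {
  if (length(bns) < 2L) {
    stop("ate needs at least two posterior samples", call. = FALSE)
  }
  target <- check_action(target, bns[[1L]]$domains)
  if (target == "nothing") stop("target must be a domain", call. = FALSE)
  diffs <- vapply(bns, function(bn) {
    expected_utility(bn, baseline, target, spec) -
      expected_utility(bn, baseline, "nothing", spec)
  }, 0)
  summarize_draws(diffs)
}

#' Rank intervention targets for a baseline state
#'
#' Evaluates the exact expected utility of doing nothing and of intervening
#' on each domain, per posterior network sample, and ranks actions by
#' posterior-mean EU (descending). Ties are broken by registry order, with
#' "nothing" last; a triggered tie-break is reported via `message()`.
#'
#' @param bns list of `cat_bn` posterior samples (at least 2).
#' @param baseline a [profile_state()].
#' @param spec a [utility_spec()].
#' @return object of class `"decision_result"`: a `table` data.frame with
#'   per-action EU, Monte Carlo SE, posterior SD and paired ATE, a
#'   `subutility` data.frame with per-domain expected subutility under
#'   nothing, the `ranking` (action labels, best first), and the inputs.
#' @export
rank_targets <- function(bns, baseline, spec = utility_spec()) {
  if (length(bns) < 2L) {
    stop("rank_targets needs at least two posterior samples", call. = FALSE)
  }
  dp <- decision_prep(bns, spec)
  codes <- level_code(unclass(baseline)[dp$domains])
  em <- eu_matrix_for_state(dp, codes)
  actions <- colnames(em$eu)
  stats_list <- lapply(seq_along(actions), function(a) summarize_draws(em$eu[, a]))
  eu_mean <- vapply(stats_list, `[[`, 0, "mean")
  ates <- vapply(seq_along(actions), function(a) {
    if (a == 1L) 0 else mean(em$eu[, a] - em$eu[, 1L])
  }, 0)
  ate_se <- vapply(seq_along(actions), function(a) {
    if (a == 1L) 0 else summarize_draws(em$eu[, a] - em$eu[, 1L])$se
  }, 0)
  # tie-break: registry order (columns already in registry order, nothing
  # first -> move it last among equals by ordering key)
  tie_key <- c(length(actions), seq_len(length(actions) - 1L))
  ord <- order(-eu_mean, tie_key)
  if (anyDuplicated(round(eu_mean, 12L))) {
    message("rank_targets: tie in posterior-mean EU broken by registry order")
  }
  tab <- data.frame(
    action = actions,
    eu = eu_mean,
    se = vapply(stats_list, `[[`, 0, "se"),
    sd = vapply(stats_list, `[[`, 0, "sd"),
    ate = ates,
    ate_se = ate_se,
    stringsAsFactors = FALSE)
  tab$rank <- match(seq_along(actions), ord)
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  sub <- data.frame(
    domain = dp$domains,
    eu_sub = colMeans(em$eu_sub),
    se = apply(em$eu_sub, 2L, function(x) summarize_draws(x)$se),
    stringsAsFactors = FALSE)
  structure(list(table = tab, subutility = sub, ranking = tab$action,
                 baseline = baseline, spec = spec),
            class = "decision_result")
}

#' @export
print.decision_result <- function(x, ...) {
  cat("<decision_result> spec=", x$spec$name, "\n", sep = "")
  print(x$table, digits = 4L)
  invisible(x)
}

#' Probability of being the optimal (or top-N) intervention target
#'
#' For every baseline state with positive weight and every posterior network
#' sample, ranks the domain interventions by exact EU (doing nothing is
#' excluded from this tabulation) and tabulates, per domain, the probability
#' of ranking first (`p_opt`) and of appearing in the top N (`p_rec`),
#' weighted by the baseline-state weights.
#'
#' @param bns list of `cat_bn` posterior samples (at least 2).
#' @param baseline_weights data.frame with one column per domain (baseline
#'   levels) and a `weight` column summing to 1, e.g. from
#'   [baseline_state_weights()].
#' @param spec a [utility_spec()].
#' @param top_n size of the recommendation short-list (default 3).
#' @return object of class `"recommendation_summary"`: named vectors
#'   `p_opt` (sums to 1) and `p_rec` (sums to `top_n`), the per-state table
#'   with each state's weight, modal target and per-domain `p_opt`, and the
#'   spec name.
#' @export
p_opt_summary <- function(bns, baseline_weights, spec = utility_spec(),
                          top_n = 3L) {
  if (length(bns) < 2L) {
    stop("p_opt_summary needs at least two posterior samples", call. = FALSE)
  }
  dp <- decision_prep(bns, spec)
  domains <- dp$domains
  k <- length(domains)
  top_n <- as.integer(top_n)
  stopifnot(top_n >= 1L, top_n <= k)
  wts <- baseline_weights$weight
  if (abs(sum(wts) - 1) > 1e-9) {
    stop("baseline weights must sum to 1", call. = FALSE)
  }
  p_opt <- stats::setNames(numeric(k), domains)
  p_rec <- stats::setNames(numeric(k), domains)
  per_state <- matrix(0, nrow(baseline_weights), k,
                      dimnames = list(NULL, domains))
  nb <- length(bns)
  for (s in seq_len(nrow(baseline_weights))) {
    codes <- level_code(unlist(baseline_weights[s, domains]))
    eu <- eu_matrix_for_state(dp, codes)$eu[, -1L, drop = FALSE]
    # per-sample rank-1 (ties resolved to the earliest registry index) and
    # top-N membership
    first <- apply(eu, 1L, which.max)
    popt_s <- tabulate(first, nbins = k) / nb
    rec_s <- numeric(k)
    for (b in seq_len(nb)) {
      topb <- order(-eu[b, ], seq_len(k))[seq_len(top_n)]
      rec_s[topb] <- rec_s[topb] + 1
    }
    rec_s <- rec_s / nb
    per_state[s, ] <- popt_s
    p_opt <- p_opt + wts[s] * popt_s
    p_rec <- p_rec + wts[s] * rec_s
  }
  colnames(per_state) <- paste0("p_opt_", domains)
  per_state_df <- cbind(baseline_weights[, domains, drop = FALSE],
                        weight = wts,
                        modal_target = domains[apply(per_state, 1L, which.max)],
                        as.data.frame(per_state))
  rownames(per_state_df) <- NULL
  structure(list(p_opt = p_opt, p_rec = p_rec, top_n = top_n,
                 per_state = per_state_df, spec_name = spec$name),
            class = "recommendation_summary")
}

#' @export
print.recommendation_summary <- function(x, ...) {
  cat("<recommendation_summary> spec=", x$spec_name, ", top_n=", x$top_n,
      "\n p_opt:\n", sep = "")
  print(round(sort(x$p_opt, decreasing = TRUE), 4L))
  cat(" p_rec(", x$top_n, "):\n", sep = "")
  print(round(sort(x$p_rec, decreasing = TRUE), 4L))
  invisible(x)
}

#' Sensitivity of recommendations to the utility specification
#'
#' Recomputes [p_opt_summary()] under each utility specification and lays
#' the per-domain `p_opt` values side by side.
#'
#' @param bns list of `cat_bn` posterior samples.
#' @param baseline_weights as in [p_opt_summary()].
#' @param specs named list of [utility_spec()]s; defaults to the three
#'   presets plus an illustrative variant up-weighting psychological
#'   distress and personal functioning (weight 2 each) when those domains
#'   are registered.
#' @param top_n short-list size.
#' @return data.frame: one row per spec, one `p_opt` column per domain, and
#'   the full summaries as attribute `"summaries"`.
#' @export
sensitivity_table <- function(bns, baseline_weights, specs = NULL, top_n = 3L) {
  if (is.null(specs)) {
    specs <- list(default = utility_spec("default"),
                  risk_neutral = utility_spec("risk_neutral"),
                  risk_averse = utility_spec("risk_averse"))
    domains <- bns[[1L]]$domains
    if (all(c("distress", "functioning") %in% domains)) {
      specs$upweight_distress_functioning <-
        utility_spec("default", weights = c(distress = 2, functioning = 2),
                     name = "upweight_distress_functioning")
    }
  }
  stopifnot(length(specs) >= 1L)
  summaries <- lapply(specs, function(sp) {
    p_opt_summary(bns, baseline_weights, sp, top_n)
  })
  rows <- lapply(summaries, function(s) as.data.frame(as.list(s$p_opt)))
  out <- cbind(data.frame(spec = names(specs), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "summaries") <- summaries
  out
}
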