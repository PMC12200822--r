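# Ground-truth two-slice structural causal models and synthetic panels.
#
# The generator emulates the statistical structure the analysis assumes:
# every domain persists strongly between time points (autoregressive edge
# with probability mass `ar_strength` on staying at the same level), a
# sparse set of lagged (baseline -> other domain's follow-up) and
# contemporaneous (within follow-up) edges, ordinal effects realized as
# monotone probability-mass shifts along the level order, and baseline
# category marginals matching a large two-wave well-being cohort.

# Baseline category proportions (poor, fair, healthy) per canonical domain,
# from the analyzed cohort's baseline table (n = 619).
COHORT_MARGINALS <- local({
  m <- rbind(
    functioning = c(224, 186, 209),
    distress    = c(122, 171, 326),
    nutrition   = c(138, 213, 268),
    activity    = c(131,  22, 466),
    sleep       = c(103, 343, 173),
    social      = c(267, 169, 180),
    substance   = c( 78, 158, 383))
  m <- m / rowSums(m)
  colnames(m) <- LEVELS
  m
})

#' Synthetic-panel generator configuration
#'
#' @param domains domain registry (default the canonical seven).
#' @param ar_strength probability that a domain persists at its baseline
#'   level at follow-up, before cross-domain effects; must be at least 1/3
#'   so that persistence dominates and effects stay ordinally monotone.
#' @param n_lagged number of lagged cross-domain edges
#'   (`A_baseline -> B_followup`, A != B).
#' @param n_within number of contemporaneous edges within the follow-up
#'   slice.
#' @param effect_size fraction of probability mass shifted one level toward
#'   the parent's side per non-autoregressive parent at "poor" or "healthy"
#'   (no shift for "fair"); in `[0, 1)`.
#' @param baseline_marginals matrix (domains x 3, columns poor/fair/healthy)
#'   of baseline category probabilities. Defaults to the cohort table for
#'   canonical domains and uniform otherwise.
#' @param within_baseline logical; also draw `n_within` dependence edges
#'   within the baseline slice (off by default).
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(domains = default_domains(), ar_strength = 0.6,
                             n_lagged = 2L, n_within = 4L, effect_size = 0.25,
                             baseline_marginals = NULL,
                             within_baseline = FALSE) {
  domains <- check_registry(domains)
  k <- length(domains)
  stopifnot(ar_strength >= 1 / 3, ar_strength < 1,
            effect_size >= 0, effect_size < 1,
            n_lagged >= 0, n_within >= 0)
  if (n_lagged > k * (k - 1L)) stop("n_lagged exceeds the number of ordered pairs",
                                    call. = FALSE)
  if (n_within > k * (k - 1L) / 2) stop("n_within exceeds the number of pairs",
                                        call. = FALSE)
  if (is.null(baseline_marginals)) {
    baseline_marginals <- matrix(1 / 3, k, 3L, dimnames = list(domains, LEVELS))
    known <- intersect(domains, rownames(COHORT_MARGINALS))
    baseline_marginals[known, ] <- COHORT_MARGINALS[known, ]
  }
  baseline_marginals <- as.matrix(baseline_marginals)
  if (!all(dim(baseline_marginals) == c(k, 3L)) ||
      any(baseline_marginals < 0) ||
      any(abs(rowSums(baseline_marginals) - 1) > 1e-9)) {
    stop("baseline_marginals must be a domains x 3 stochastic matrix",
         call. = FALSE)
  }
  rownames(baseline_marginals) <- domains
  structure(list(domains = domains, ar_strength = ar_strength,
                 n_lagged = as.integer(n_lagged), n_within = as.integer(n_within),
                 effect_size = effect_size,
                 baseline_marginals = baseline_marginals,
                 within_baseline = isTRUE(within_baseline)),
            class = "generator_config")
}

# Shift a fraction s of probability mass one level up (s > 0) or down
# (s < 0); monotone in s and mass-conserving.
shift_mass <- function(p, s) {
  if (s > 0) {
    c(p[1L] * (1 - s), p[2L] * (1 - s) + s * p[1L], p[3L] + s * p[2L])
  } else if (s < 0) {
    s <- -s
    c(p[1L] + s * p[2L], p[2L] * (1 - s) + s * p[3L], p[3L] * (1 - s))
  } else p
}

# Persistence row for a node whose own baseline level is `own` (0/1/2):
# `ar` mass on staying, the remainder mostly on the adjacent level.
persistence_row <- function(own, ar) {
  rest <- 1 - ar
  switch(own + 1L,
         c(ar, rest * 2 / 3, rest / 3),
         c(rest / 2, ar, rest / 2),
         c(rest / 3, rest * 2 / 3, ar))
}

# CPT of a follow-up node: parents are the global indices (must include the
# node's own baseline); every other parent shifts mass by
# effect_size * (code - 1) in its own direction.
build_effect_cpt <- function(parents, own_parent, ar, effect_size) {
  p <- length(parents)
  rows <- 3L^p
  tbl <- matrix(0, rows, 3L)
  own_pos <- match(own_parent, parents)
  for (r in seq_len(rows)) {
    codes <- (r - 1L) %/% 3L^(seq_len(p) - 1L) %% 3L
    row <- persistence_row(codes[own_pos], ar)
    for (i in seq_len(p)) {
      if (i == own_pos) next
      row <- shift_mass(row, effect_size * (codes[i] - 1L))
    }
    tbl[r, ] <- row
  }
  list(parents = parents, table = tbl)
}

#' Draw a ground-truth structural causal model
#'
#' Builds a two-slice DAG with all autoregressive edges, the requested
#' number of lagged and within-follow-up cross-domain edges (acyclic by
#' construction, never backwards in time), and monotone ordinal-effect
#' conditional probability tables, then packages it as a `cat_bn`.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the same seed yields the identical model.
#' @return object of class `"ground_truth"`: `dag` (adjacency matrix over
#'   [node_names()]), `bn` (a `cat_bn`), and the `config`.
#' @export
sample_scm <- function(config = generator_config(), seed = 1L) {
  domains <- config$domains
  k <- length(domains)
  n <- 2L * k
  nodes <- node_names(domains)
  with_local_seed(seed, {
    adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    for (d in seq_len(k)) adj[d, k + d] <- 1L # autoregressive
    # lagged cross-domain edges
    pairs <- which(outer(seq_len(k), seq_len(k), `!=`), arr.ind = TRUE)
    if (config$n_lagged > 0L) {
      pick <- pairs[sample.int(nrow(pairs), config$n_lagged), , drop = FALSE]
      adj[cbind(pick[, 1L], k + pick[, 2L])] <- 1L
    }
    # contemporaneous edges within follow-up, oriented along a random order
    if (config$n_within > 0L) {
      ord <- sample.int(k)
      ut <- utils::combn(k, 2L)
      pick <- ut[, sample.int(ncol(ut), config$n_within), drop = FALSE]
      for (c_i in seq_len(ncol(pick))) {
        a <- pick[1L, c_i]; b <- pick[2L, c_i]
        if (which(ord == a) > which(ord == b)) { tmp <- a; a <- b; b <- tmp }
        adj[k + a, k + b] <- 1L
      }
    }
    # optional dependence within baseline
    if (config$within_baseline && config$n_within > 0L) {
      ordb <- sample.int(k)
      ut <- utils::combn(k, 2L)
      pick <- ut[, sample.int(ncol(ut), config$n_within), drop = FALSE]
      for (c_i in seq_len(ncol(pick))) {
        a <- pick[1L, c_i]; b <- pick[2L, c_i]
        if (which(ordb == a) > which(ordb == b)) { tmp <- a; a <- b; b <- tmp }
        adj[a, b] <- 1L
      }
    }
    cpts <- vector("list", n)
    for (d in seq_len(k)) {
      parents <- which(adj[, d] > 0)
      if (length(parents) == 0L) {
        cpts[[d]] <- list(parents = integer(0),
                          table = matrix(config$baseline_marginals[d, ], 1L, 3L))
      } else {
        # baseline dependence: shift the marginal row per parent level
        p <- length(parents)
        tbl <- matrix(0, 3L^p, 3L)
        for (r in seq_len(3L^p)) {
          codes <- (r - 1L) %/% 3L^(seq_len(p) - 1L) %% 3L
          row <- config$baseline_marginals[d, ]
          for (i in seq_len(p)) {
            row <- shift_mass(row, config$effect_size * (codes[i] - 1L))
          }
          tbl[r, ] <- row
        }
        cpts[[d]] <- list(parents = sort(parents), table = tbl)
      }
    }
    for (d in seq_len(k)) {
      j <- k + d
      parents <- sort(which(adj[, j] > 0))
      cpts[[j]] <- build_effect_cpt(parents, d, config$ar_strength,
                                    config$effect_size)
    }
    bn <- structure(list(dag = adj, nodes = nodes, domains = domains,
                         cpts = cpts, n = NA_integer_, pseudocount = NA_real_),
                    class = "cat_bn")
    structure(list(dag = adj, bn = bn, config = config, seed = as.integer(seed)),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$config$domains), " domains, ",
      sum(x$dag), " edges (", length(x$config$domains), " autoregressive)\n",
      sep = "")
  invisible(x)
}

#' Simulate a two-wave panel from a ground-truth model
#'
#' Baselines are drawn from the model's baseline tables (ancestrally, if
#' within-baseline edges exist), follow-ups by ancestral sampling through
#' the network. Days between observations are drawn from a log-normal
#' matched to a median of 55 and interquartile range of roughly 35-96 days,
#' truncated to the 7-183 day selection window.
#'
#' @param truth a [sample_scm()] result.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return a [panel_dataset()].
#' @export
simulate_panel <- function(truth, n, seed = 1L) {
  stopifnot(n >= 1L)
  bn <- truth$bn
  k <- length(bn$domains)
  with_local_seed(seed, {
    codes <- matrix(0L, n, 2L * k)
    ord <- topological_order(bn$dag)
    for (j in ord) {
      cpt <- bn$cpts[[j]]
      parents <- cpt$parents
      if (length(parents) == 0L) {
        idx <- rep(1L, n)
      } else {
        idx <- 1L + as.integer(codes[, parents, drop = FALSE] %*%
                                 3L^(seq_along(parents) - 1L))
      }
      u <- stats::runif(n)
      c1 <- cpt$table[idx, 1L]
      c2 <- c1 + cpt$table[idx, 2L]
      codes[, j] <- ifelse(u < c1, 0L, ifelse(u < c2, 1L, 2L))
    }
    days <- as.integer(pmin(pmax(round(stats::rlnorm(n, log(55), 0.826)), 7L), 183L))
    b <- as.data.frame(matrix(LEVELS[codes[, seq_len(k)] + 1L], n, k),
                       stringsAsFactors = FALSE)
    f <- as.data.frame(matrix(LEVELS[codes[, k + seq_len(k)] + 1L], n, k),
                       stringsAsFactors = FALSE)
    names(b) <- bn$domains
    names(f) <- bn$domains
    panel_dataset(b, f, days_between = days, domains = bn$domains)
  })
}

#' Exact optimal intervention target per baseline state
#'
#' Evaluates, on the true network by exact enumeration, the expected utility
#' of intervening on each domain for each requested baseline state and
#' returns the best target (ties broken by registry order).
#'
#' @param truth a [sample_scm()] result.
#' @param states data.frame with one column per domain (baseline levels);
#'   `NULL` enumerates all `3^K` states.
#' @param spec a [utility_spec()].
#' @return `states` with an `optimal_target` column appended.
#' @export
true_optimal_targets <- function(truth, states = NULL, spec = utility_spec()) {
  domains <- truth$bn$domains
  if (is.null(states)) {
    cfg <- enumerate_configs(length(domains))
    states <- as.data.frame(matrix(LEVELS[cfg + 1L], nrow(cfg), ncol(cfg)),
                            stringsAsFactors = FALSE)
    names(states) <- domains
  }
  dp <- decision_prep(list(truth$bn), spec)
  states$optimal_target <- vapply(seq_len(nrow(states)), function(s) {
    codes <- level_code(unlist(states[s, domains]))
    eu <- eu_matrix_for_state(dp, codes)$eu[1L, -1L]
    domains[which.max(eu)]
  }, character(1))
  states
}

#' Structure and decision recovery metrics
#'
#' Compares a posterior DAG sample against the generating ground truth:
#' posterior probability of every true edge, total posterior mass on false
#' edges, and (when a [p_opt_summary()] is supplied) the weighted agreement
#' between each state's modal recommended target and the true optimal
#' target.
#'
#' @param truth a [sample_scm()] result.
#' @param samples a `dag_samples` over the same node registry.
#' @param summary optional `recommendation_summary` whose per-state modal
#'   targets are checked against the truth.
#' @param spec utility used for the true optimal targets.
#' @return list with `true_edge_probs` (named), `mean_true_edge_prob`,
#'   `min_autoregressive_prob`, `false_edge_mass`, and (with `summary`)
#'   `target_agreement` (weighted) and the per-state comparison table.
#' @export
recovery_report <- function(truth, samples, summary = NULL,
                            spec = utility_spec()) {
  if (!identical(samples$nodes, truth$bn$nodes)) {
    stop("node registries of truth and samples differ", call. = FALSE)
  }
  k <- length(truth$bn$domains)
  p <- edge_probabilities(samples)
  true_idx <- which(truth$dag > 0)
  labels <- outer(rownames(p), colnames(p), paste, sep = "->")
  out <- list(
    true_edge_probs = stats::setNames(p[true_idx], labels[true_idx]),
    mean_true_edge_prob = mean(p[true_idx]),
    min_autoregressive_prob = min(p[cbind(seq_len(k), k + seq_len(k))]),
    false_edge_mass = sum(p[-true_idx]))
  if (!is.null(summary)) {
    ps <- summary$per_state
    truth_tab <- true_optimal_targets(truth, ps[, truth$bn$domains, drop = FALSE],
                                      spec)
    agree <- ps$modal_target == truth_tab$optimal_target
    out$target_agreement <- sum(ps$weight * agree) / sum(ps$weight)
    out$per_state <- cbind(ps[, c(truth$bn$domains, "weight", "modal_target")],
                           true_target = truth_tab$optimal_target,
                           agree = agree)
  }
  out
}
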