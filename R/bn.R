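# Categorical Bayesian networks over the temporal variables: Dirichlet-MAP
# conditional probability tables, exact follow-up inference given a clamped
# baseline state, and the do-operation by graph mutilation.
#
# CPT row order is lexicographic in the parent ordinal codes with the FIRST
# listed parent varying fastest: row = 1 + sum_i code_i * 3^(i-1). Parents
# are listed in ascending node-index order.

#' Fit conditional probability tables for a DAG
#'
#' Each table cell is the smoothed estimate
#' `(count + pseudocount) / (row_total + 3 * pseudocount)`, i.e. the mode of
#' a symmetric Dirichlet(`pseudocount + 1`) posterior. Parent configurations
#' never observed yield the uniform row (1/3, 1/3, 1/3).
#'
#' @param dag adjacency matrix over the `2 * n_domains` temporal variables
#'   in [node_names()] order (`dag[i, j] = 1` for edge `i -> j`).
#' @param panel a `panel_df`.
#' @param pseudocount positive smoothing constant (default 1).
#' @return object of class `"cat_bn"`: the DAG, one CPT per node, the
#'   domain registry and fitting metadata.
#' @export
fit_cpts <- function(dag, panel, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  domains <- panel_domains(panel)
  nodes <- node_names(domains)
  n <- length(nodes)
  dag <- as.matrix(dag)
  if (!all(dim(dag) == n)) {
    stop("dag must be a ", n, " x ", n, " adjacency matrix", call. = FALSE)
  }
  if (!is_acyclic(dag)) stop("graph has a cycle", call. = FALSE)
  codes <- matrix(0L, nrow(panel), n)
  for (k in seq_len(n)) {
    col <- c(paste0(domains, "_t0"), paste0(domains, "_t1"))[k]
    codes[, k] <- level_code(panel[[col]])
  }
  cpts <- vector("list", n)
  for (j in seq_len(n)) {
    parents <- which(dag[, j] > 0)
    cpts[[j]] <- fit_one_cpt(codes, j, parents, pseudocount)
  }
  structure(list(dag = dag, nodes = nodes, domains = domains, cpts = cpts,
                 n = nrow(panel), pseudocount = pseudocount),
            class = "cat_bn")
}

fit_one_cpt <- function(codes, j, parents, pseudocount) {
  parents <- sort(as.integer(parents))
  p <- length(parents)
  n_rows <- 3L^p
  if (p == 0L) {
    cfg <- rep(1L, nrow(codes))
  } else {
    cfg <- 1L + as.integer(codes[, parents, drop = FALSE] %*% 3L^(seq_len(p) - 1L))
  }
  counts <- matrix(0, n_rows, 3L)
  tabbed <- tabulate((codes[, j] * n_rows) + cfg, nbins = 3L * n_rows)
  counts[] <- tabbed
  smoothed <- counts + pseudocount
  tbl <- smoothed / rowSums(smoothed)
  list(parents = parents, table = tbl)
}

#' @export
print.cat_bn <- function(x, ...) {
  cat("<cat_bn> ", length(x$domains), " domains (", sum(x$dag), " edges), fitted on n=",
      x$n, ", pseudocount=", x$pseudocount, "\n", sep = "")
  invisible(x)
}

# All 3^k follow-up configurations as a matrix of ordinal codes; the first
# column varies fastest (consistent with the CPT row order).
enumerate_configs <- function(k) {
  as.matrix(expand.grid(rep(list(0:2), k), KEEP.OUT.ATTRS = FALSE))
}

# Per-follow-up-node probability vectors over all 3^K configurations, with
# baseline nodes clamped to `baseline_codes`. Row j of the result list is
# P(followup_j = config_j | parents as in config/baseline).
followup_node_probs <- function(bn, baseline_codes, configs) {
  k <- length(bn$domains)
  out <- vector("list", k)
  for (d in seq_len(k)) {
    j <- k + d
    cpt <- bn$cpts[[j]]
    parents <- cpt$parents
    idx <- rep(1L, nrow(configs))
    if (length(parents) > 0L) {
      for (i in seq_along(parents)) {
        pa <- parents[i]
        contrib <- if (pa <= k) baseline_codes[pa] else configs[, pa - k]
        idx <- idx + contrib * 3L^(i - 1L)
      }
    }
    out[[d]] <- cpt$table[cbind(idx, configs[, d] + 1L)]
  }
  out
}

#' Exact follow-up distribution given a baseline state
#'
#' Enumerates all `3^K` follow-up configurations (K = number of domains) and
#' evaluates the joint probability of each as the product of the follow-up
#' nodes' CPT entries with every baseline node clamped to the given state.
#' This is the "doing nothing" forward simulation; intervened distributions
#' are obtained by first applying [mutilate()].
#'
#' @param bn a `cat_bn`.
#' @param baseline a [profile_state()] over the BN's domains.
#' @return object of class `"followup_dist"`: numeric vector of length
#'   `3^K` summing to 1, with the configuration matrix (ordinal codes, one
#'   column per domain) as attribute `"configs"`.
#' @export
followup_distribution <- function(bn, baseline) {
  domains <- bn$domains
  baseline_codes <- level_code(unclass(baseline)[domains])
  k <- length(domains)
  configs <- enumerate_configs(k)
  probs <- followup_node_probs(bn, baseline_codes, configs)
  joint <- Reduce(`*`, probs)
  structure(as.numeric(joint), configs = configs, domains = domains,
            class = "followup_dist")
}

#' @export
print.followup_dist <- function(x, ...) {
  cat("<followup_dist> over ", length(x), " follow-up states; total mass ",
      format(sum(x)), "\n", sep = "")
  invisible(x)
}

#' Per-domain follow-up marginals
#'
#' @param dist a [followup_distribution()].
#' @return matrix (domains x 3 levels) of marginal probabilities.
#' @export
followup_marginals <- function(dist) {
  configs <- attr(dist, "configs")
  domains <- attr(dist, "domains")
  out <- matrix(0, length(domains), 3L, dimnames = list(domains, LEVELS))
  for (d in seq_along(domains)) {
    for (lv in 0:2) out[d, lv + 1L] <- sum(dist[configs[, d] == lv])
  }
  out
}

#' Apply the do-operation to an intervention target
#'
#' Mutilates the network: removes every edge into the target domain's
#' follow-up node and replaces its CPT by a point mass on "healthy". All
#' other tables are untouched and the input network is not modified.
#' Idempotent.
#'
#' @param bn a `cat_bn`.
#' @param target a registered domain name.
#' @return a new `cat_bn` encoding `do(target = healthy)` at follow-up.
#' @export
mutilate <- function(bn, target) {
  d <- match(target, bn$domains)
  if (is.na(d)) stop("unknown domain: ", target, call. = FALSE)
  j <- length(bn$domains) + d
  bn$dag[, j] <- 0L
  bn$cpts[[j]] <- list(parents = integer(0),
                       table = matrix(c(0, 0, 1), 1L, 3L))
  bn
}

#' Fit one categorical network per sampled DAG
#'
#' @param samples a `dag_samples` from [run_partition_mcmc()].
#' @param panel the `panel_df` the structures were learned from.
#' @param pseudocount smoothing constant passed to [fit_cpts()].
#' @param max_bns optionally subsample (evenly across the retained draws) to
#'   at most this many networks.
#' @return list of `cat_bn` objects.
#' @export
fit_posterior_bns <- function(samples, panel, pseudocount = 1, max_bns = NULL) {
  n <- length(samples$nodes)
  if (!identical(samples$nodes, node_names(panel_domains(panel)))) {
    stop("samples and panel node registries differ", call. = FALSE)
  }
  rows <- seq_len(nrow(samples$draws))
  if (!is.null(max_bns) && max_bns < length(rows)) {
    rows <- rows[unique(round(seq(1L, length(rows), length.out = max_bns)))]
  }
  lapply(rows, function(r) {
    fit_cpts(masks_to_adj(samples$draws[r, ], n), panel, pseudocount)
  })
}

# Plain-list form for JSON serialization (documented row order).
bn_to_list <- function(bn) {
  list(nodes = bn$nodes, domains = bn$domains, n = bn$n,
       pseudocount = bn$pseudocount,
       edges = apply(which(bn$dag > 0, arr.ind = TRUE), 1L, function(e) {
         list(from = bn$nodes[e[1L]], to = bn$nodes[e[2L]])
       }),
       cpts = lapply(seq_along(bn$cpts), function(j) {
         list(node = bn$nodes[j], parents = bn$nodes[bn$cpts[[j]]$parents],
              row_order = "first parent fastest; poor<fair<healthy",
              table = unname(bn$cpts[[j]]$table))
       }))
}
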