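# Shared fixtures: tiny panels, hand-built networks, and hand-rolled
# sample-set objects used across the test files.

TRI <- c("sleep", "distress", "social")

tiny_panel <- function() {
  b <- data.frame(sleep = c("poor", "fair", "healthy", "poor"),
                  distress = c("fair", "fair", "healthy", "poor"),
                  social = c("healthy", "poor", "healthy", "fair"))
  f <- data.frame(sleep = c("fair", "fair", "healthy", "poor"),
                  distress = c("healthy", "fair", "healthy", "poor"),
                  social = c("healthy", "poor", "healthy", "healthy"))
  panel_dataset(b, f, days_between = c(10L, 55L, 30L, 90L), domains = TRI)
}

# A cat_bn built from explicit tables. `cpts` is a named list keyed by node
# name with elements list(parents = <node names>, table = <3^p x 3 matrix>);
# unnamed nodes get a uniform parentless table.
manual_bn <- function(domains, cpts) {
  nodes <- node_names(domains)
  n <- length(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  out <- vector("list", n)
  for (j in seq_len(n)) {
    nm <- nodes[j]
    if (!is.null(cpts[[nm]])) {
      pa <- match(cpts[[nm]]$parents, nodes)
      stopifnot(!anyNA(pa))
      ord <- order(pa)
      pa_sorted <- pa[ord]
      tbl <- cpts[[nm]]$table
      # reorder table rows if parents were not given in ascending node order
      if (!identical(pa_sorted, pa)) {
        p <- length(pa)
        old_codes <- as.matrix(expand.grid(rep(list(0:2), p)))
        new_idx <- 1L + as.integer(old_codes[, ord, drop = FALSE] %*%
                                     3L^(seq_len(p) - 1L))
        tbl2 <- tbl
        tbl2[new_idx, ] <- tbl
        tbl <- tbl2
      }
      adj[pa_sorted, j] <- 1L
      out[[j]] <- list(parents = pa_sorted, table = tbl)
    } else {
      out[[j]] <- list(parents = integer(0), table = matrix(1 / 3, 1L, 3L))
    }
  }
  structure(list(dag = adj, nodes = nodes, domains = domains, cpts = out,
                 n = NA_integer_, pseudocount = NA_real_),
            class = "cat_bn")
}

# A deterministic network: every follow-up node goes to `level` regardless
# of baseline.
point_mass_bn <- function(domains, level = "healthy") {
  row <- matrix(0, 1L, 3L)
  row[1L, level_code(level) + 1L] <- 1
  cpts <- stats::setNames(
    lapply(domains, function(d) list(parents = character(0), table = row)),
    paste0(domains, "_t1"))
  manual_bn(domains, cpts)
}

# Wrap a list of adjacency matrices as a dag_samples object.
manual_samples <- function(adjs, nodes, chain = NULL, slices = NULL) {
  n <- length(nodes)
  draws <- t(vapply(adjs, function(a) {
    vapply(seq_len(n), function(j) causalrank:::mask_of(which(a[, j] > 0)), 0L)
  }, integer(n)))
  if (is.null(chain)) chain <- rep(1L, length(adjs))
  structure(list(draws = draws, chain = chain, nodes = nodes, slices = slices,
                 seeds = 0L, acceptance = NA_real_, config = NULL),
            class = "dag_samples")
}

# Ancestral forward sampler for follow-up states given a clamped baseline:
# an independent Monte-Carlo oracle for followup_distribution / EU.
sample_followups <- function(bn, baseline, n_draws) {
  k <- length(bn$domains)
  codes <- matrix(0L, n_draws, 2L * k)
  codes[, seq_len(k)] <- matrix(rep(level_code(unclass(baseline)[bn$domains]),
                                    each = n_draws), n_draws, k)
  ord <- causalrank:::topological_order(bn$dag)
  for (j in ord[ord > k]) {
    cpt <- bn$cpts[[j]]
    if (length(cpt$parents) == 0L) {
      idx <- rep(1L, n_draws)
    } else {
      idx <- 1L + as.integer(codes[, cpt$parents, drop = FALSE] %*%
                               3L^(seq_along(cpt$parents) - 1L))
    }
    u <- stats::runif(n_draws)
    c1 <- cpt$table[idx, 1L]
    c2 <- c1 + cpt$table[idx, 2L]
    codes[, j] <- ifelse(u < c1, 0L, ifelse(u < c2, 1L, 2L))
  }
  codes[, k + seq_len(k), drop = FALSE]
}

# Independent brute-force partition-compatibility rule (the oracle used
# against compatible_dags): parents strictly earlier, at least one in the
# immediately preceding block.
compatible_by_definition <- function(adj, blocks) {
  n <- nrow(adj)
  block_of <- integer(n)
  for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
  for (j in seq_len(n)) {
    pa <- which(adj[, j] > 0)
    if (block_of[j] == 1L) {
      if (length(pa) > 0L) return(FALSE)
    } else {
      if (any(block_of[pa] >= block_of[j])) return(FALSE)
      if (!any(block_of[pa] == block_of[j] - 1L)) return(FALSE)
    }
  }
  TRUE
}

# Every DAG on 4 labelled nodes, enumerated from scratch (543 of them).
all_dags_4 <- function() {
  masks <- expand.grid(rep(list(0:15), 4))
  keep <- list()
  for (r in seq_len(nrow(masks))) {
    adj <- matrix(0L, 4, 4)
    ok <- TRUE
    for (j in 1:4) {
      pa <- which(bitwAnd(masks[r, j], bitwShiftL(1L, 0:3)) > 0)
      if (j %in% pa) { ok <- FALSE; break }
      adj[pa, j] <- 1L
    }
    if (ok && causalrank:::is_acyclic(adj)) keep[[length(keep) + 1L]] <- adj
  }
  keep
}

# Random small continuous dataset with a linear chain structure.
chain_data <- function(n, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- 0.7 * x + stats::rnorm(n, sd = 0.8)
  z <- 0.6 * y + stats::rnorm(n, sd = 0.9)
  cbind(x = x, y = y, z = z)
}
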