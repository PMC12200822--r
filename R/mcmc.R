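# Partition MCMC over temporally constrained DAGs, exact small-graph
# enumeration, and posterior summaries.

#' MCMC settings for structure learning
#'
#' @param chains number of independent chains (default 8).
#' @param iterations iterations per chain.
#' @param burn_in iterations discarded per chain (must be < `iterations`).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param max_parents cap on parent-set size (keeps the per-node parent-set
#'   sums exact and cheap; default 4).
#' @param seed master seed; per-chain seeds are derived deterministically
#'   from it.
#' @param move_probs mixture weights of the three partition moves: relocate
#'   one node, swap two cross-block nodes, swap two adjacent blocks.
#' @return list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 8L, iterations = 60000L, burn_in = 20000L,
                        thin = 40L, max_parents = 4L, seed = 1L,
                        move_probs = c(relocate = 0.6, swap_nodes = 0.25,
                                       swap_blocks = 0.15)) {
  stopifnot(chains >= 1L, iterations > burn_in, burn_in >= 0L, thin >= 1L,
            max_parents >= 1L, length(move_probs) == 3L, all(move_probs >= 0),
            sum(move_probs) > 0)
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 max_parents = as.integer(max_parents), seed = as.integer(seed),
                 move_probs = move_probs / sum(move_probs)),
            class = "mcmc_config")
}

# All distinct non-identity partitions reachable by relocating node x.
relocation_candidates <- function(blocks, x) {
  b_idx <- which(vapply(blocks, function(b) x %in% b, TRUE))
  base <- lapply(blocks, function(b) setdiff(b, x))
  base <- base[vapply(base, length, 1L) > 0L]
  key <- function(bl) paste(vapply(bl, function(b) paste(sort(b), collapse = ","),
                                   character(1)), collapse = "|")
  orig_key <- key(blocks)
  cands <- list()
  keys <- character(0)
  # into an existing block
  for (t in seq_along(base)) {
    cand <- base
    cand[[t]] <- sort(c(cand[[t]], x))
    k <- key(cand)
    if (k != orig_key && !(k %in% keys)) {
      cands[[length(cands) + 1L]] <- cand
      keys <- c(keys, k)
    }
  }
  # as a new singleton block in any gap
  for (g in 0:length(base)) {
    cand <- append(base, list(x), after = g)
    k <- key(cand)
    if (k != orig_key && !(k %in% keys)) {
      cands[[length(cands) + 1L]] <- cand
      keys <- c(keys, k)
    }
  }
  cands
}

# One chain of partition MCMC. Returns retained draws as parent-mask rows.
run_one_chain <- function(tab, cfg, chain_seed) {
  n <- tab$n
  blocks <- list(seq_len(n)) # single block = empty DAG, always finite score
  sc <- partition_logscore_tab(tab, blocks)
  n_keep <- (cfg$iterations - cfg$burn_in) %/% cfg$thin
  draws <- matrix(0L, n_keep, n)
  kept <- 0L
  accepted <- 0L
  proposed <- 0L
  rescore <- function(blocks_new, sc_old) {
    pm <- partition_masks(blocks_new, n)
    per_node <- sc_old$per_node
    for (j in seq_len(n)) {
      if (pm$pool[j] != sc_old$pool[j] || pm$prev[j] != sc_old$prev[j]) {
        per_node[j] <- score_node_in_partition(tab, j, pm$pool[j], pm$prev[j])
      }
    }
    list(per_node = per_node, total = sum(per_node), pool = pm$pool, prev = pm$prev)
  }
  with_local_seed(chain_seed, {
    if (!is.finite(sc$total)) {
      stop("non-finite partition score at initialization", call. = FALSE)
    }
    for (it in seq_len(cfg$iterations)) {
      mv <- sample.int(3L, 1L, prob = cfg$move_probs)
      prop <- NULL
      log_hastings <- 0
      if (mv == 1L) { # relocate one node
        x <- sample.int(n, 1L)
        fwd <- relocation_candidates(blocks, x)
        if (length(fwd) > 0L) {
          prop <- fwd[[sample.int(length(fwd), 1L)]]
          k_rev <- length(relocation_candidates(prop, x))
          log_hastings <- log(length(fwd)) - log(k_rev)
        }
      } else if (mv == 2L) { # swap two nodes across blocks (symmetric)
        if (length(blocks) >= 2L) {
          memb <- integer(n)
          for (bi in seq_along(blocks)) memb[blocks[[bi]]] <- bi
          pair <- sample.int(n, 2L)
          while (memb[pair[1L]] == memb[pair[2L]]) pair <- sample.int(n, 2L)
          prop <- blocks
          b1 <- memb[pair[1L]]; b2 <- memb[pair[2L]]
          prop[[b1]] <- sort(c(setdiff(prop[[b1]], pair[1L]), pair[2L]))
          prop[[b2]] <- sort(c(setdiff(prop[[b2]], pair[2L]), pair[1L]))
        }
      } else { # swap two adjacent blocks (symmetric)
        m <- length(blocks)
        if (m >= 2L) {
          i <- if (m == 2L) 1L else sample.int(m - 1L, 1L)
          prop <- blocks
          prop[c(i, i + 1L)] <- prop[c(i + 1L, i)]
        }
      }
      if (!is.null(prop)) {
        proposed <- proposed + 1L
        sc_prop <- rescore(prop, sc)
        log_alpha <- sc_prop$total - sc$total + log_hastings
        if (is.finite(sc_prop$total) && log(stats::runif(1L)) < log_alpha) {
          blocks <- prop
          sc <- sc_prop
          accepted <- accepted + 1L
        }
      }
      if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- sample_dag_from_partition(tab, sc)
      }
    }
  })
  list(draws = draws[seq_len(kept), , drop = FALSE],
       acceptance = accepted / max(proposed, 1L))
}

# Draw one DAG from a partition proportionally to its score: per node, an
# admissible parent set is drawn with probability exp(logscore) (normalized
# within the node's family). Returns the parent-mask vector.
sample_dag_from_partition <- function(tab, sc) {
  n <- tab$n
  masks <- integer(n)
  for (j in seq_len(n)) {
    if (sc$prev[j] < 0L) next # first block: empty parent set
    mj <- tab$masks[[j]]
    sel <- which(bitwAnd(mj, sc$pool[j]) == mj & bitwAnd(mj, sc$prev[j]) != 0L)
    w <- tab$logsc[[j]][sel]
    w <- exp(w - max(w))
    masks[j] <- mj[sel[sample.int(length(sel), 1L, prob = w)]]
  }
  masks
}

#' Sample DAGs from the posterior by partition MCMC
#'
#' Runs the requested number of independent chains of Metropolis-Hastings
#' over labelled node partitions scored by the summed BGe score of their
#' compatible DAGs, then draws one DAG per retained partition state
#' proportionally to its score. The prior over DAGs is uniform apart from
#' the temporal constraint (no arrow from a follow-up node into a baseline
#' node) and the parent-count cap.
#'
#' @param data numeric matrix, e.g. from [ordinal_encode()]. Columns are
#'   standardized internally; constant columns are an error.
#' @param hyper a [bge_hyper()]; default `bge_hyper(ncol(data))`.
#' @param slices integer vector (0 = baseline, 1 = follow-up) per column. By
#'   default inferred from `"_t0"`/`"_t1"` column-name suffixes; `NA` to
#'   force an unconstrained run.
#' @param config an [mcmc_config()].
#' @return object of class `"dag_samples"`: retained DAG draws (as
#'   parent-mask matrix), per-draw chain ids, per-chain seeds and acceptance
#'   rates, node names and the configuration used.
#' @export
run_partition_mcmc <- function(data, hyper = NULL, slices = NULL,
                               config = mcmc_config()) {
  data <- as.matrix(data)
  n <- ncol(data)
  if (is.null(slices) && !is.null(colnames(data))) {
    if (all(grepl("_t[01]$", colnames(data)))) {
      slices <- ifelse(grepl("_t1$", colnames(data)), 1L, 0L)
    }
  }
  if (length(slices) == 1L && is.na(slices)) slices <- NULL
  tab <- build_score_table(data, hyper, slices, config$max_parents)
  seeds <- vapply(seq_len(config$chains), function(c) derive_seed(config$seed, c), 0L)
  per_chain <- lapply(seq_len(config$chains), function(c) {
    run_one_chain(tab, config, seeds[c])
  })
  draws <- do.call(rbind, lapply(per_chain, `[[`, "draws"))
  chain <- rep(seq_len(config$chains),
               vapply(per_chain, function(x) nrow(x$draws), 0L))
  nodes <- colnames(data)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(n))
  structure(list(draws = draws, chain = chain, nodes = nodes, slices = slices,
                 seeds = seeds,
                 acceptance = vapply(per_chain, `[[`, 0, "acceptance"),
                 config = config),
            class = "dag_samples")
}

#' @export
print.dag_samples <- function(x, ...) {
  cat("<dag_samples> ", nrow(x$draws), " DAG draws over ", length(x$nodes),
      " nodes from ", length(unique(x$chain)), " chain(s); mean acceptance ",
      sprintf("%.2f", mean(x$acceptance)), "\n", sep = "")
  invisible(x)
}

# Adjacency matrix of one draw (row of parent masks).
masks_to_adj <- function(masks, n) {
  adj <- matrix(0L, n, n)
  for (j in seq_len(n)) {
    if (masks[j] > 0L) adj[nodes_of_mask(masks[j], n), j] <- 1L
  }
  adj
}

#' Posterior probability of each directed edge
#'
#' @param samples a `dag_samples` object.
#' @return numeric matrix `p` with `p[i, j]` the fraction of draws that
#'   contain the edge `i -> j`.
#' @export
edge_probabilities <- function(samples) {
  draws <- samples$draws
  if (nrow(draws) < 1L) stop("need at least one sampled DAG", call. = FALSE)
  n <- length(samples$nodes)
  p <- matrix(0, n, n, dimnames = list(samples$nodes, samples$nodes))
  for (i in seq_len(n)) {
    hit <- bitwAnd(as.vector(draws), bitwShiftL(1L, i - 1L)) > 0L
    dim(hit) <- dim(draws)
    p[i, ] <- colMeans(hit)
  }
  p
}

# ndraws x n x n logical array of per-draw reachability, folded to the
# posterior path-probability matrix.
path_probability_matrix <- function(samples) {
  n <- length(samples$nodes)
  acc <- matrix(0, n, n, dimnames = list(samples$nodes, samples$nodes))
  for (r in seq_len(nrow(samples$draws))) {
    acc <- acc + reachability(masks_to_adj(samples$draws[r, ], n))
  }
  acc / nrow(samples$draws)
}

#' Posterior probability of a directed path
#'
#' Fraction of sampled DAGs containing a directed path (of length >= 1)
#' from `src` to `dst`. Always at least the corresponding edge probability.
#'
#' @param samples a `dag_samples` object.
#' @param src,dst node names or indices; must differ.
#' @return scalar probability.
#' @export
path_probability <- function(samples, src, dst) {
  n <- length(samples$nodes)
  if (is.character(src)) src <- match(src, samples$nodes)
  if (is.character(dst)) dst <- match(dst, samples$nodes)
  if (is.na(src) || is.na(dst)) stop("unknown node name", call. = FALSE)
  if (src == dst) stop("src and dst must differ", call. = FALSE)
  path_probability_matrix(samples)[src, dst]
}

#' Consensus graph of the DAG posterior
#'
#' Summarizes edge and path posterior probabilities and retains the edges
#' whose probability exceeds the display threshold (default 10%).
#'
#' @param samples a `dag_samples` object.
#' @param threshold retain edges with `p_parent > threshold`; in `[0, 1]`.
#' @return object of class `"consensus_graph"`: matrices `p_parent` and
#'   `p_path`, the threshold, and an edge data.frame with columns `from`,
#'   `to`, `p_parent` and `type` (`"autoregressive"`, `"lagged"`,
#'   `"within_baseline"`, `"within_followup"`, or `"edge"` when slices are
#'   unknown).
#' @export
consensus_graph <- function(samples, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold <= 1)
  p <- edge_probabilities(samples)
  pp <- path_probability_matrix(samples)
  keep <- which(p > threshold, arr.ind = TRUE)
  n <- length(samples$nodes)
  edge_type <- function(i, j) {
    sl <- samples$slices
    if (is.null(sl)) return("edge")
    k <- n / 2L
    di <- (i - 1L) %% k; dj <- (j - 1L) %% k
    if (sl[i] == 0L && sl[j] == 1L) {
      if (di == dj) "autoregressive" else "lagged"
    } else if (sl[i] == 0L) "within_baseline" else "within_followup"
  }
  edges <- data.frame(
    from = samples$nodes[keep[, 1L]],
    to = samples$nodes[keep[, 2L]],
    p_parent = p[keep],
    type = if (nrow(keep)) mapply(edge_type, keep[, 1L], keep[, 2L]) else character(0),
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$p_parent), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(p_parent = p, p_path = pp, threshold = threshold,
                 edges = edges),
            class = "consensus_graph")
}

#' @export
print.consensus_graph <- function(x, ...) {
  cat("<consensus_graph> ", nrow(x$edges), " edges with p_parent > ",
      x$threshold, "\n", sep = "")
  print(utils::head(x$edges, 15L))
  invisible(x)
}

#' Cross-chain convergence check on edge probabilities
#'
#' Computes, for every ordered node pair, the spread (max minus min) of the
#' per-chain posterior edge probabilities, and passes when the largest
#' spread is below the tolerance.
#'
#' @param samples a `dag_samples` object with at least two chains.
#' @param tolerance maximum allowed spread (default 0.05).
#' @return list with `max_spread`, `pass`, the per-pair `spread` matrix and
#'   `tolerance`.
#' @export
convergence_report <- function(samples, tolerance = 0.05) {
  chains <- unique(samples$chain)
  if (length(chains) < 2L) {
    stop("convergence_report needs at least two chains", call. = FALSE)
  }
  n <- length(samples$nodes)
  per_chain <- lapply(chains, function(cc) {
    sub <- samples
    sub$draws <- samples$draws[samples$chain == cc, , drop = FALSE]
    edge_probabilities(sub)
  })
  arr <- simplify2array(per_chain)
  spread <- apply(arr, c(1L, 2L), max) - apply(arr, c(1L, 2L), min)
  dimnames(spread) <- list(samples$nodes, samples$nodes)
  list(max_spread = max(spread), pass = max(spread) < tolerance,
       spread = spread, tolerance = tolerance)
}

#' Exact posterior edge probabilities by DAG enumeration
#'
#' Exhaustively enumerates every DAG satisfying the temporal constraint and
#' parent cap (uniform prior), scores each with the BGe score, and returns
#' normalized posterior edge probabilities. A test oracle: refuses more than
#' 5 nodes.
#'
#' @param data numeric matrix.
#' @param hyper a [bge_hyper()]; default `bge_hyper(ncol(data))`.
#' @param slices optional temporal constraint (as in [run_partition_mcmc()]).
#' @param max_parents cap on parent-set size; default unrestricted.
#' @return list with `p_edge` (matrix), `log_evidence`, and `n_dags`.
#' @export
enumerate_posterior <- function(data, hyper = NULL, slices = NULL,
                                max_parents = ncol(data) - 1L) {
  data <- as.matrix(data)
  n <- ncol(data)
  if (n > 5L) stop("enumerate_posterior refuses more than 5 nodes", call. = FALSE)
  tab <- build_score_table(data, hyper, slices, max_parents)
  grid <- expand.grid(tab$masks, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- NULL
  gm <- as.matrix(grid)
  # acyclicity by iterated elimination on parent masks
  acyclic <- vapply(seq_len(nrow(gm)), function(r) {
    masks <- gm[r, ]
    removed <- 0L
    repeat {
      free <- which(bitwAnd(masks, bitwNot(removed)) == 0L &
                      bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), removed) == 0L)
      if (length(free) == 0L) return(FALSE)
      removed <- bitwOr(removed, mask_of(free))
      if (removed == mask_of(seq_len(n))) return(TRUE)
    }
  }, TRUE)
  gm <- gm[acyclic, , drop = FALSE]
  logw <- numeric(nrow(gm))
  for (j in seq_len(n)) {
    logw <- logw + tab$logsc[[j]][match(gm[, j], tab$masks[[j]])]
  }
  lz <- logsumexp(logw)
  w <- exp(logw - lz)
  p <- matrix(0, n, n, dimnames = list(colnames(data), colnames(data)))
  for (i in seq_len(n)) {
    hit <- bitwAnd(as.vector(gm), bitwShiftL(1L, i - 1L)) > 0L
    dim(hit) <- dim(gm)
    p[i, ] <- colSums(w * hit)
  }
  list(p_edge = p, log_evidence = lz, n_dags = nrow(gm))
}
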