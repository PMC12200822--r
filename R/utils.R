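# Internal numerical and bookkeeping helpers.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log values (may contain -Inf).
#' @return log(sum(exp(x))) as a scalar; -Inf for an empty vector or a
#'   vector of -Inf.
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All exported stochastic entry points funnel
# through this so that a master seed fully determines results.
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic derivation of per-chain seeds from a master seed.
# Kept below 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 7919) %% 2147483629)
}

# Effective sample size of a (possibly autocorrelated) scalar series using
# the initial positive sequence of sample autocorrelations.
effective_size <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  if (stats::var(x) == 0) return(n)
  max_lag <- min(n - 1L, floor(10 * log10(n)) + 20L)
  rho <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1L]
  s <- 0
  for (r in rho) {
    if (r <= 0.05) break
    s <- s + r
  }
  ess <- n / (1 + 2 * s)
  min(max(ess, 1), n)
}

# Parent-set bitmask helpers: node i (1-based) <-> bit 2^(i-1).
mask_of <- function(idx) {
  if (length(idx) == 0L) return(0L)
  as.integer(sum(bitwShiftL(1L, idx - 1L)))
}

nodes_of_mask <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
}

# Topological order of an adjacency matrix (adj[i, j] = 1 for edge i -> j).
# Returns NULL when the graph has a cycle.
topological_order <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  active <- rep(TRUE, n)
  for (step in seq_len(n)) {
    ready <- which(active & indeg == 0)
    if (length(ready) == 0L) return(NULL)
    v <- ready[1L]
    order <- c(order, v)
    active[v] <- FALSE
    indeg <- indeg - adj[v, ]
    indeg[!active] <- 1L # never re-selected
    indeg[ready[1L]] <- 1L
  }
  order
}

is_acyclic <- function(adj) !is.null(topological_order(adj))

# Reachability (transitive closure) of a small adjacency matrix by repeated
# boolean squaring; closure[i, j] is TRUE iff a directed path i -> ... -> j
# with at least one edge exists.
reachability <- function(adj) {
  n <- nrow(adj)
  reach <- adj > 0
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}
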