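# Bayesian Gaussian equivalent (BGe) marginal-likelihood score.
#
# The score of a node given a parent set is the ratio of two set-marginals
# p(d_A) of the normal-Wishart model,
#   log p(d_A) = -(l N / 2) log(pi) + (l / 2) log(am / (am + N))
#                + log Gamma_l((N + aw - n + l) / 2)
#                - log Gamma_l((aw - n + l) / 2)
#                + ((aw - n + l) / 2) log|T0_A|
#                - ((N + aw - n + l) / 2) log|R_A|,
# with l = |A|, Gamma_l the multivariate gamma function and
#   R = T0 + S_N + (N am / (N + am)) (xbar - mu0)(xbar - mu0)',
# so that score(j | P) = log p(d_{P+j}) - log p(d_P). Being a ratio of set
# functions, the total DAG score is constant on Markov-equivalence classes.

#' BGe hyperparameters
#'
#' Literature-default normal-Wishart hyperparameters: `alpha_mu = 1`,
#' `alpha_w = n_vars + 2`, prior mean zero, and prior scale matrix
#' `t * I` with `t = alpha_mu * (alpha_w - n_vars - 1) / (alpha_mu + 1)`,
#' which makes the prior covariance of each variable equal 1 (matching
#' per-column standardized data).
#'
#' @param n_vars number of variables (columns) the score will see.
#' @param alpha_mu positive real; precision of the prior mean.
#' @param alpha_w degrees of freedom; must exceed `n_vars - 1`.
#' @param t0 prior scale matrix; defaults to `t * I` as above. May be any
#'   symmetric positive definite matrix.
#' @param mu0 prior mean vector (recycled); default 0.
#' @return list of class `"bge_hyper"`.
#' @export
#' @examples
#' bge_hyper(14)
bge_hyper <- function(n_vars, alpha_mu = 1, alpha_w = n_vars + 2,
                      t0 = NULL, mu0 = 0) {
  stopifnot(n_vars >= 1, alpha_mu > 0)
  if (!(alpha_w > n_vars - 1)) {
    stop("alpha_w must exceed n_vars - 1", call. = FALSE)
  }
  if (is.null(t0)) {
    t_scalar <- alpha_mu * (alpha_w - n_vars - 1) / (alpha_mu + 1)
    t0 <- diag(t_scalar, n_vars)
  } else {
    t0 <- as.matrix(t0)
    if (!isTRUE(all.equal(t0, t(t0))) || any(eigen(t0, symmetric = TRUE,
                                                   only.values = TRUE)$values <= 0)) {
      stop("t0 must be symmetric positive definite", call. = FALSE)
    }
  }
  structure(list(n_vars = as.integer(n_vars), alpha_mu = alpha_mu,
                 alpha_w = alpha_w, t0 = t0,
                 mu0 = rep_len(mu0, n_vars)),
            class = "bge_hyper")
}

# Center and scale columns to unit variance; constant columns are rejected
# because they carry no ordering information and make the score direction
# ill-posed.
standardize_columns <- function(data) {
  data <- as.matrix(data)
  sds <- apply(data, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(data)[sds == 0 | is.na(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | is.na(sds))
    stop("constant data column(s) cannot be scored: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  scale(data)
}

# log of the multivariate gamma function Gamma_l(x)
lmvgamma <- function(l, x) {
  l * (l - 1) / 4 * log(pi) + sum(lgamma(x - (seq_len(l) - 1) / 2))
}

# Closure that scores (node, parent set) pairs against fixed data, with
# memoized log-determinants of the submatrices of T0 and R.
make_bge_scorer <- function(data, hyper, standardize = TRUE) {
  data <- as.matrix(data)
  n <- ncol(data)
  N <- nrow(data)
  if (hyper$n_vars != n) stop("hyper was built for ", hyper$n_vars,
                              " variables but data has ", n, call. = FALSE)
  if (standardize) data <- standardize_columns(data)
  am <- hyper$alpha_mu
  aw <- hyper$alpha_w
  xbar <- colMeans(data)
  centered <- sweep(data, 2L, xbar)
  S <- crossprod(centered)
  dev <- xbar - hyper$mu0
  R <- hyper$t0 + S + (N * am / (N + am)) * tcrossprod(dev)
  logdet_cache_R <- new.env(parent = emptyenv())
  logdet_cache_T <- new.env(parent = emptyenv())
  logdet_sub <- function(M, idx, cache) {
    key <- paste(idx, collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- 2 * sum(log(diag(chol(M[idx, idx, drop = FALSE]))))
    cache[[key]] <- val
    val
  }
  logp_subset <- function(idx) {
    l <- length(idx)
    if (l == 0L) return(0)
    idx <- sort(idx)
    -(l * N / 2) * log(pi) + (l / 2) * log(am / (am + N)) +
      lmvgamma(l, (N + aw - n + l) / 2) - lmvgamma(l, (aw - n + l) / 2) +
      ((aw - n + l) / 2) * logdet_sub(hyper$t0, idx, logdet_cache_T) -
      ((N + aw - n + l) / 2) * logdet_sub(R, idx, logdet_cache_R)
  }
  function(node, parents) {
    parents <- as.integer(parents)
    if (node %in% parents) stop("a node cannot be its own parent", call. = FALSE)
    if (N <= length(parents) + 1L) {
      stop("need more observations than parents + 1", call. = FALSE)
    }
    logp_subset(c(parents, node)) - logp_subset(parents)
  }
}

#' BGe score of one node given a parent set
#'
#' Log marginal-likelihood contribution of a single node with the given
#' parents under the BGe score. Columns are standardized (centered, unit
#' variance) before scoring; constant columns are rejected.
#'
#' @param node column index of the child.
#' @param parents integer vector of parent column indices (may be empty).
#' @param data numeric matrix (rows = observations).
#' @param hyper a [bge_hyper()]; defaults to `bge_hyper(ncol(data))`.
#' @param standardize standardize columns first (default `TRUE`).
#' @return scalar log score.
#' @export
bge_node_score <- function(node, parents, data, hyper = NULL, standardize = TRUE) {
  data <- as.matrix(data)
  if (is.null(hyper)) hyper <- bge_hyper(ncol(data))
  scorer <- make_bge_scorer(data, hyper, standardize = standardize)
  scorer(as.integer(node), as.integer(parents))
}

#' BGe score of a DAG
#'
#' Decomposable total score: the sum of [bge_node_score()] over all nodes
#' with their parent sets in `dag`. Identical (up to numerical error) across
#' members of a Markov-equivalence class.
#'
#' @param dag adjacency matrix (`dag[i, j] = 1` for an edge `i -> j`) over
#'   the columns of `data`.
#' @param data numeric matrix.
#' @param hyper a [bge_hyper()]; defaults to `bge_hyper(ncol(data))`.
#' @param standardize standardize columns first (default `TRUE`).
#' @return scalar log score.
#' @export
dag_score <- function(dag, data, hyper = NULL, standardize = TRUE) {
  dag <- as.matrix(dag)
  data <- as.matrix(data)
  if (ncol(dag) != ncol(data)) stop("dag and data dimension mismatch", call. = FALSE)
  if (!is_acyclic(dag)) stop("graph has a cycle", call. = FALSE)
  if (is.null(hyper)) hyper <- bge_hyper(ncol(data))
  scorer <- make_bge_scorer(data, hyper, standardize = standardize)
  total <- 0
  for (j in seq_len(ncol(dag))) {
    total <- total + scorer(j, which(dag[, j] > 0))
  }
  total
}
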