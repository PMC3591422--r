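#' @importFrom stats optim
NULL

# Binary traits are named vectors (species -> 0/1), matching the named-vector
# convention used for continuous traits.

#' Transition probabilities of the symmetric two-state Mk chain
#'
#' For equal transition rates q in both directions over a branch of length t:
#' P(stay) = (1 + exp(-2qt)) / 2, P(switch) = (1 - exp(-2qt)) / 2.
#'
#' @param q transition rate (> 0) per unit branch length.
#' @param t branch length (>= 0).
#' @return a symmetric 2 x 2 stochastic matrix (rows = from-state 0/1).
#' @export
mk_transition_prob <- function(q, t) {
  if (q <= 0) stopf("q must be positive")
  if (t < 0) stopf("t must be non-negative")
  stay <- 0.5 * (1 + exp(-2 * q * t))
  switch_ <- 1 - stay
  matrix(c(stay, switch_, switch_, stay), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Equal-rates Mk log-likelihood of a binary trait on a tree
#'
#' Felsenstein pruning: post-order traversal combining per-child partial
#' likelihood vectors through the branch transition probabilities, with a
#' uniform (1/2, 1/2) root prior (the stationary distribution of the
#' symmetric chain).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param states named vector of 0/1 tip states covering every tip.
#' @param q transition rate (> 0).
#' @return the log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, q) {
  validate_tree(tree)
  if (q <= 0) stopf("q must be positive")
  ntip <- ape::Ntip(tree)
  if (is.null(names(states))) stopf("states must be named by species")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stopf("missing tip states: %s", paste(missing, collapse = ", "))
  st <- states[tree$tip.label]
  if (!all(st %in% c(0, 1))) stopf("states must be 0 or 1")
  nnode <- ntip + tree$Nnode
  # partial likelihoods L[node, state+1]; internal nodes start at (1,1)
  L <- matrix(1, nnode, 2L)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), st + 1L)] <- 1
  logscale <- 0
  # postorder edge ordering guarantees each child's subtree is complete
  # before its edge is folded into the parent
  po <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]
    child <- po$edge[r, 2L]
    P <- mk_transition_prob(q, po$edge.length[r])
    L[p, ] <- L[p, ] * as.numeric(P %*% L[child, ])
    m <- max(L[p, ])
    if (m <= 0) return(-Inf)
    L[p, ] <- L[p, ] / m
    logscale <- logscale + log(m)
  }
  root <- ntip + 1L
  logscale + log(sum(0.5 * L[root, ]))
}

mk_optimize_q <- function(tree, states, height) {
  # q searched on the log scale per unit tree height for conditioning;
  # reported on the original branch-length scale
  obj <- function(logq) -mk_loglik(tree, states, exp(logq) / height)
  opt <- optimize(function(lq) -obj(lq), interval = log(c(1e-4, 1e3)),
                  maximum = TRUE, tol = 1e-7)
  list(q = exp(opt$maximum) / height, loglik = opt$objective)
}

#' Maximum-likelihood Pagel's lambda for a binary trait
#'
#' Jointly maximizes the equal-rates Mk likelihood over lambda in \[0, 1\]
#' (applied through [lambda_transform_tree()]) and the transition rate q
#' (log-scale search per unit tree height), then tests lambda-hat against the
#' star tree (lambda = 0, q re-optimized) with a one-degree-of-freedom
#' likelihood-ratio test. A 9 x 9 (lambda x log-q) grid pre-scan seeds the
#' joint optimizer. Monomorphic traits are returned flagged degenerate with
#' lambda-hat 0 and p 1 rather than as errors so that runs over a full trait
#' panel complete.
#'
#' @param tree a rooted ultrametric `phylo`.
#' @param states named vector of 0/1 tip states.
#' @return a list of class `mk_lambda_result`: `lambda_hat`, `q_hat`,
#'   `loglik_at_hat`, `loglik_at_zero`, `LRT_stat`, `p`, `degenerate`.
#' @export
fit_lambda_discrete <- function(tree, states) {
  validate_tree(tree)
  st <- states[tree$tip.label]
  if (any(is.na(st))) stopf("missing tip states")
  height <- max(node_depths(tree))
  if (length(unique(st)) < 2L) {
    ll <- log(0.5) # q -> 0 limit: only the root prior contributes
    return(structure(list(lambda_hat = 0, q_hat = NA_real_,
                          loglik_at_hat = ll, loglik_at_zero = ll,
                          LRT_stat = 0, p = 1, degenerate = TRUE),
                     class = "mk_lambda_result"))
  }
  lam_grid <- seq(0, 1, length.out = 9)
  logq_grid <- seq(log(1e-3), log(1e2), length.out = 9)
  trees <- lapply(lam_grid, function(l) lambda_transform_tree(tree, l))
  ll_fun <- function(lambda_idx, logq)
    mk_loglik(trees[[lambda_idx]], st, exp(logq) / height)
  scan <- outer(seq_along(lam_grid), logq_grid, Vectorize(ll_fun))
  best <- which(scan == max(scan), arr.ind = TRUE)[1L, ]
  start <- c(lam_grid[best[1L]], logq_grid[best[2L]])
  nll <- function(par) {
    lam <- min(max(par[1L], 0), 1)
    tr <- lambda_transform_tree(tree, lam)
    -mk_loglik(tr, st, exp(par[2L]) / height)
  }
  opt <- optim(start, nll, method = "L-BFGS-B",
               lower = c(0, log(1e-4)), upper = c(1, log(1e3)),
               control = list(factr = 1e5))
  lambda_hat <- opt$par[1L]
  q_hat <- exp(opt$par[2L]) / height
  ll_hat <- -opt$value
  if (ll_hat < max(scan)) { # never fall below the grid pre-scan
    lambda_hat <- start[1L]
    q_hat <- exp(start[2L]) / height
    ll_hat <- max(scan)
  }
  star <- lambda_transform_tree(tree, 0)
  fit0 <- mk_optimize_q(star, st, height)
  ll0 <- fit0$loglik
  if (ll0 > ll_hat) { # lambda = 0 lies in the domain: take it as the optimum
    lambda_hat <- 0
    q_hat <- fit0$q
    ll_hat <- ll0
  }
  lrt <- max(0, 2 * (ll_hat - ll0))
  structure(list(lambda_hat = lambda_hat, q_hat = q_hat,
                 loglik_at_hat = ll_hat, loglik_at_zero = ll0,
                 LRT_stat = lrt, p = lrt_pvalue(lrt / 2),
                 degenerate = FALSE),
            class = "mk_lambda_result")
}
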