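# Independent oracles used across test files. These deliberately avoid the
# package's own computation paths: covariances by explicit all-pairs MRCA
# walks, Mk likelihoods by full enumeration over interior-state assignments,
# log-rank statistics by direct hypergeometric tabulation.

# all-pairs MRCA-depth covariance by walking root paths
oracle_covariance <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  root <- ntip + 1L
  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- tree$edge[tree$edge[, 2] == node, 1]
      path <- c(path, node)
    }
    path
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  C <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- max(depth[shared])
    }
  }
  C
}

# Mk likelihood by summation over all 2^n_internal interior assignments
oracle_mk_loglik <- function(tree, states, q) {
  ntip <- ape::Ntip(tree)
  st <- states[tree$tip.label]
  combs <- expand.grid(rep(list(0:1), tree$Nnode))
  total <- 0
  for (i in seq_len(nrow(combs))) {
    full <- c(st, as.integer(combs[i, ]))
    pr <- 0.5 # uniform root prior
    for (r in seq_len(nrow(tree$edge))) {
      P <- mk_transition_prob(q, tree$edge.length[r])
      pr <- pr * P[full[tree$edge[r, 1]] + 1, full[tree$edge[r, 2]] + 1]
    }
    total <- total + pr
  }
  log(total)
}

# log-rank O-E/V by direct hypergeometric tabulation over event times
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  O <- E <- V <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d <- sum(event & time == t)
    d_a <- sum(event & time == t & grp_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chi_square = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# direct closed-form evaluation of the K ratio with explicit inverses
oracle_blomberg_K <- function(C, x) {
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  ahat <- as.numeric(t(one) %*% Ci %*% x) / as.numeric(t(one) %*% Ci %*% one)
  d <- x - ahat
  obs <- sum(d^2) / as.numeric(t(d) %*% Ci %*% d)
  expct <- (sum(diag(C)) - n / as.numeric(t(one) %*% Ci %*% one)) / (n - 1)
  obs / expct
}

# a small fixed non-ultrametric-free toolkit for tests
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

random_yule <- function(n, seed) simulate_yule_tree(n, seed = seed)
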