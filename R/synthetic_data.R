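#' @importFrom stats rexp rnorm runif rbinom
NULL

# Simulators for every input the analysis consumes: pure-birth trees,
# Brownian-motion and Mk traits with known signal, perturbed tree samples
# standing in for posterior uncertainty, and raw survival / feeding tables.
# All are deterministic given their seed.

#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Forward simulation: starting from two lineages, each of the k current
#' lineages splits at total rate k * birth_rate; growth stops at `n_tips`
#' lineages, a final exponential waiting time is appended, and the tree is
#' rescaled to height 1 (branch lengths in relative time units).
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @param birth_rate speciation rate (cancels after rescaling; default 1).
#' @return an ultrametric `phylo` of height 1.
#' @export
simulate_yule_tree <- function(n_tips, seed, birth_rate = 1) {
  if (n_tips < 3L) stopf("n_tips must be >= 3")
  with_seed(seed, {
    # active lineages carry their parent (temporary id) and start time
    root <- 1L
    next_id <- 2L
    par <- c(root, root)
    start <- c(0, 0)
    edge_par <- integer(0); edge_child <- integer(0); edge_len <- numeric(0)
    t <- 0
    while (length(par) < n_tips) {
      k <- length(par)
      t <- t + rexp(1L, k * birth_rate)
      i <- sample.int(k, 1L)
      nid <- next_id; next_id <- next_id + 1L
      edge_par <- c(edge_par, par[i])
      edge_child <- c(edge_child, nid)
      edge_len <- c(edge_len, t - start[i])
      par <- c(par[-i], nid, nid)
      start <- c(start[-i], t, t)
    }
    height <- t + rexp(1L, n_tips * birth_rate)
    n_int <- next_id - 1L
    # final numbering: tips 1..n, internal nodes n+1.. in creation order
    tip_ids <- seq.int(n_int + 1L, n_int + n_tips)
    edge_par <- c(edge_par, par)
    edge_child <- c(edge_child, tip_ids)
    edge_len <- c(edge_len, height - start)
    renum <- function(id) ifelse(id > n_int, id - n_int, id + n_tips)
    tree <- list(edge = cbind(renum(edge_par), renum(edge_child)),
                 edge.length = edge_len / height,
                 tip.label = sprintf("t%02d", seq_len(n_tips)),
                 Nnode = n_int)
    class(tree) <- "phylo"
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Simulate a continuous trait under (lambda-scaled) Brownian motion
#'
#' Draws one multivariate-normal tip vector with mean `root_value` and
#' covariance `sigma2` times the lambda-transformed phylogenetic covariance:
#' lambda = 1 gives plain Brownian motion, lambda = 0 i.i.d. tips.
#'
#' @param tree a rooted ultrametric `phylo`.
#' @param sigma2 Brownian rate (>= 0) per unit branch length.
#' @param root_value ancestral trait value (default 0).
#' @param lambda signal level in `[0, 1]` (default 1).
#' @param seed integer seed.
#' @return named numeric trait vector (species -> value).
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root_value = 0, lambda = 1,
                              seed = 1) {
  validate_tree(tree)
  check_lambda(lambda)
  if (sigma2 < 0) stopf("sigma2 must be >= 0")
  n <- ape::Ntip(tree)
  if (sigma2 == 0)
    return(setNames(rep(root_value, n), tree$tip.label))
  C <- lambda_transform_cov(tree_to_covariance(tree), lambda)
  z <- with_seed(seed, rnorm(n))
  x <- root_value + sqrt(sigma2) * as.numeric(crossprod(chol(C), z))
  setNames(x, rownames(C))
}

#' Simulate a binary trait under the equal-rates Mk process
#'
#' Root state drawn from the stationary (1/2, 1/2) prior; states evolve down
#' each branch with the symmetric transition probabilities of
#' [mk_transition_prob()].
#'
#' @param tree a rooted `phylo`.
#' @param q transition rate (> 0) per unit branch length.
#' @param seed integer seed.
#' @return named 0/1 vector (species -> state).
#' @export
simulate_mk_trait <- function(tree, q, seed = 1) {
  validate_tree(tree)
  if (q <= 0) stopf("q must be positive")
  ntip <- ape::Ntip(tree)
  tree <- ape::reorder.phylo(tree, "cladewise") # parents before children
  with_seed(seed, {
    state <- integer(ntip + tree$Nnode)
    state[ntip + 1L] <- rbinom(1L, 1L, 0.5)
    for (r in seq_len(nrow(tree$edge))) {
      p_switch <- 0.5 * (1 - exp(-2 * q * tree$edge.length[r]))
      flip <- rbinom(1L, 1L, p_switch)
      state[tree$edge[r, 2L]] <- (state[tree$edge[r, 1L]] + flip) %% 2L
    }
    setNames(state[seq_len(ntip)], tree$tip.label)
  })
}

# rebuild branch lengths from target internal-node ages (time before
# present; tips at age 0), clamping parents above their children and
# renormalizing the root age to 1, so the result is ultrametric of height 1
set_node_ages <- function(tree, age_target) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  age <- age_target
  age[seq_len(ntip)] <- 0
  for (r in seq_len(nrow(po$edge))) { # children final before their parent
    p <- po$edge[r, 1L]; child <- po$edge[r, 2L]
    age[p] <- max(age[p], age[child] * (1 + 1e-9) + 1e-12)
  }
  age <- age / age[ntip + 1L]
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  tree
}

# nearest-neighbour interchange around the shallowest (most tipward)
# non-root internal node: one of its children is exchanged with its sibling
nni_at_shallowest <- function(tree, depth) {
  ntip <- ape::Ntip(tree)
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), ntip + 1L)
  if (!length(internal)) return(tree)
  v <- internal[which.max(depth[internal])]
  row_v <- which(tree$edge[, 2L] == v)
  u <- tree$edge[row_v, 1L]
  sib_rows <- setdiff(which(tree$edge[, 1L] == u), row_v)
  child_rows <- which(tree$edge[, 1L] == v)
  if (!length(sib_rows) || !length(child_rows)) return(tree)
  s_row <- sib_rows[1L]; c_row <- child_rows[1L]
  tree$edge[s_row, 1L] <- v # sibling moves under v
  tree$edge[c_row, 1L] <- u # v's first child moves up beside v
  tree
}

#' Perturbed tree sample mimicking posterior uncertainty
#'
#' Generates `n` trees from one base tree by multiplying internal node ages
#' (time before present) by independent lognormal factors, then restoring
#' ultrametricity at height 1. Because the jitter is multiplicative on ages,
#' node times move in proportion to their distance from the tips and
#' terminal branches never collapse. A nearest-neighbour interchange at the
#' shallowest internal node is applied with probability `nni_prob` to
#' emulate topological uncertainty.
#'
#' @param base a rooted ultrametric `phylo`.
#' @param n number of trees.
#' @param jitter_sd standard deviation of the log node-age factors
#'   (0 = exact copies).
#' @param seed integer seed.
#' @param nni_prob probability of one topology move per tree (default 0).
#' @return a `multiPhylo` tree sample.
#' @export
perturb_tree_sample <- function(base, n, jitter_sd, seed, nni_prob = 0) {
  validate_tree(base)
  if (jitter_sd < 0) stopf("jitter_sd must be >= 0")
  if (nni_prob < 0 || nni_prob > 1) stopf("nni_prob must be in [0, 1]")
  ntip <- ape::Ntip(base)
  depth <- node_depths(base)
  h <- max(depth[seq_len(ntip)])
  age <- 1 - depth / h
  internal <- seq.int(ntip + 1L, ntip + base$Nnode)
  trees <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- age
      if (jitter_sd > 0)
        a[internal] <- a[internal] * exp(rnorm(length(internal), 0, jitter_sd))
      tr <- base
      if (nni_prob > 0 && runif(1L) < nni_prob)
        tr <- nni_at_shallowest(tr, depth)
      set_node_ages(tr, a)
    })
  })
  tree_sample(trees, data.frame(run = "perturbed", n = n))
}

#' Simulate an interval-recorded survival experiment
#'
#' Exponential death times per species x treatment arm, rounded up to the
#' next recording interval and censored at the observation bound: the design
#' of a heat-tolerance assay read every 12 h up to 96 h.
#'
#' @param hazards data frame with a `species` column and one column of
#'   per-hour hazard rates per treatment arm (e.g. `control`, `elevated`,
#'   `variable`); a zero hazard means no deaths (all censored).
#' @param n_replicates replicates per species per treatment (default 15).
#' @param max_time censoring bound in hours (default 96).
#' @param interval recording interval in hours (default 12).
#' @param seed integer seed.
#' @return data frame `species`, `treatment`, `time`, `event`.
#' @export
simulate_survival_experiment <- function(hazards, n_replicates = 15,
                                         max_time = 96, interval = 12,
                                         seed = 1) {
  arms <- setdiff(names(hazards), "species")
  if (!length(arms)) stopf("hazards must have at least one treatment column")
  if (any(as.matrix(hazards[arms]) < 0)) stopf("hazards must be >= 0")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(hazards)), function(i) {
      do.call(rbind, lapply(arms, function(a) {
        rate <- hazards[[a]][i]
        raw <- if (rate > 0) rexp(n_replicates, rate) else rep(Inf, n_replicates)
        rec <- ceiling(raw / interval) * interval
        event <- rec <= max_time
        data.frame(species = hazards$species[i], treatment = a,
                   time = ifelse(event, rec, max_time), event = event)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate no-choice feeding trials with no-grazer controls
#'
#' Each grazer cup starts with a fixed amount of one food; the end amount
#' reflects a shared food x trial drift (growth or decay), the species'
#' consumption rate plus a trial-level random effect and residual noise, and
#' the per-cup grazer count. Ten no-grazer control cups per food per trial
#' carry the drift (and measurement noise) only, so the control adjustment
#' of [adjust_feeding_records()] is exactly invertible when all noise is 0.
#'
#' @param rates species x food matrix of true consumption rates per
#'   individual per 24 h (dimnames required).
#' @param n_trials number of trials (default 5); each species' cups are
#'   spread across at least two trials.
#' @param reps_per_species replicate cups per species per food (default 8).
#' @param n_controls no-grazer control cups per food per trial (default 10).
#' @param n_individuals grazers per cup (default 3).
#' @param start_amount starting amount per cup (default 100).
#' @param duration_h trial duration in hours (default 48).
#' @param drift_sd sd of the food x trial proportional drift (default 0.05).
#' @param trial_sd sd of the additive trial effect on the consumption-rate
#'   scale (default 0).
#' @param residual_sd sd of residual noise on the consumption-rate scale;
#'   also used (amount scale) for control measurement noise (default 0).
#' @param seed integer seed.
#' @return data frame `species`, `trial`, `food`, `start_amount`,
#'   `end_amount`, `n_individuals`, `duration_h` (controls have
#'   `species == "CONTROL"`).
#' @export
simulate_feeding_trials <- function(rates, n_trials = 5, reps_per_species = 8,
                                    n_controls = 10, n_individuals = 3,
                                    start_amount = 100, duration_h = 48,
                                    drift_sd = 0.05, trial_sd = 0,
                                    residual_sd = 0, seed = 1) {
  if (is.null(dimnames(rates))) stopf("rates must have species x food dimnames")
  species <- rownames(rates); foods <- colnames(rates)
  if (n_trials < 2L) stopf("at least 2 trials are required by the design")
  scale24 <- duration_h / 24
  with_seed(seed, {
    drift <- matrix(rnorm(length(foods) * n_trials, 0, drift_sd),
                    length(foods), n_trials,
                    dimnames = list(foods, NULL))
    trial_eff <- rnorm(n_trials, 0, trial_sd)
    out <- list()
    for (f in foods) {
      for (tr in seq_len(n_trials)) {
        out[[length(out) + 1L]] <- data.frame(
          species = "CONTROL", trial = paste0("trial", tr), food = f,
          start_amount = start_amount,
          end_amount = start_amount * (1 + drift[f, tr]) +
            rnorm(n_controls, 0, residual_sd),
          n_individuals = 0L, duration_h = duration_h)
      }
      for (s in species) {
        # replicates split round-robin over trials (>= 2 trials per species)
        trials <- rep(seq_len(n_trials), length.out = reps_per_species)
        y <- rates[s, f] + trial_eff[trials] +
          rnorm(reps_per_species, 0, residual_sd)
        consumed <- n_individuals * y * scale24
        out[[length(out) + 1L]] <- data.frame(
          species = s, trial = paste0("trial", trials), food = f,
          start_amount = start_amount,
          end_amount = start_amount * (1 + drift[f, trials]) - consumed,
          n_individuals = n_individuals, duration_h = duration_h)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
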