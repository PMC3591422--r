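test_that("Yule simulator yields seed-reproducible height-1 ultrametric trees", {
  tr <- simulate_yule_tree(3, seed = 1)
  expect_equal(ape::Ntip(tr), 3L)
  expect_true(check_ultrametric(tr)$ultrametric)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)
  expect_identical(write_trees(simulate_yule_tree(12, seed = 9)),
                   write_trees(simulate_yule_tree(12, seed = 9)))
  expect_false(identical(write_trees(simulate_yule_tree(12, seed = 9)),
                         write_trees(simulate_yule_tree(12, seed = 10))))
  expect_error(simulate_yule_tree(2, seed = 1), "n_tips")
})

test_that("root split sizes follow the Yule split law", {
  # for a pure-birth tree on n tips, a designated root child subtends k tips
  # with probability 1/(n-1); the unordered minimum has mass 2/(n-1) below
  # n/2 and 1/(n-1) at exactly n/2
  n <- 16; reps <- 500
  mins <- vapply(seq_len(reps), function(i) {
    tr <- simulate_yule_tree(n, seed = 20000 + i)
    root <- ape::Ntip(tr) + 1L
    kids <- tr$edge[tr$edge[, 1] == root, 2]
    k <- vapply(kids, function(ch)
      if (ch <= n) 1L else ape::Ntip(ape::extract.clade(tr, ch)), 1L)
    min(k)
  }, 1L)
  expected <- c(rep(2 / (n - 1), n / 2 - 1), 1 / (n - 1))
  emp <- tabulate(mins, nbins = n / 2) / reps
  expect_lt(max(abs(emp - expected)), 0.06)
})

test_that("BM trait simulator matches its analytic covariance and limits", {
  tr <- balanced4()
  C <- tree_to_covariance(tr)
  X <- t(vapply(1:2000, function(i)
    simulate_bm_trait(tr, sigma2 = 1, seed = 30000 + i)[rownames(C)],
    numeric(4)))
  expect_lt(max(abs(cov(X) - C)), 0.15) # Monte-Carlo error at 2000 draws
  # sigma2 = 0 -> all tips at the root value
  expect_equal(unname(simulate_bm_trait(tr, sigma2 = 0, root_value = 3.3,
                                        seed = 1)),
               rep(3.3, 4))
  # lambda = 0 -> i.i.d. tips: empirical cross-covariance near zero
  X0 <- t(vapply(1:2000, function(i)
    simulate_bm_trait(tr, sigma2 = 1, lambda = 0, seed = 40000 + i)[rownames(C)],
    numeric(4)))
  off <- cov(X0); diag(off) <- 0
  expect_lt(max(abs(off)), 0.15)
})

test_that("Mk trait simulator respects rate limits and sister-tip concordance", {
  tr <- random_yule(10, seed = 55)
  st_slow <- simulate_mk_trait(tr, q = 1e-9, seed = 1)
  expect_length(unique(st_slow), 1L) # no change possible
  # q -> infinity: tips approach i.i.d. fair coins
  means <- vapply(1:300, function(i)
    mean(simulate_mk_trait(tr, q = 500, seed = 50000 + i)), numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.03)
  # concordance of a cherry matches (1 + exp(-2q * 2t)) / 2
  tr4 <- balanced4() # A,B are sisters with terminal branches t = 1
  q <- 0.4
  conc <- mean(vapply(1:800, function(i) {
    st <- simulate_mk_trait(tr4, q = q, seed = 60000 + i)
    st["A"] == st["B"]
  }, logical(1)))
  expect_lt(abs(conc - 0.5 * (1 + exp(-2 * q * 2))), 0.05)
})

test_that("perturbed tree samples stay ultrametric and center on the base tree", {
  base <- random_yule(12, seed = 77)
  copies <- perturb_tree_sample(base, 5, jitter_sd = 0, seed = 1)
  Cb <- tree_to_covariance(base)
  for (i in 1:5)
    expect_lt(max(abs(tree_to_covariance(copies[[i]], rownames(Cb)) -
                        Cb / max(Cb))), 1e-9) # base renormalized to height 1
  jit <- perturb_tree_sample(base, 60, jitter_sd = 0.1, seed = 2,
                             nni_prob = 0.3)
  devs <- vapply(seq_along(jit), function(i) {
    chk <- check_ultrametric(jit[[i]])
    expect_true(chk$ultrametric)
    max(abs(tree_to_covariance(jit[[i]], rownames(Cb)) - Cb / max(Cb)))
  }, numeric(1))
  Cmean <- Reduce(`+`, lapply(seq_along(jit), function(i)
    tree_to_covariance(jit[[i]], rownames(Cb)))) / length(jit)
  expect_lt(max(abs(Cmean - Cb / max(Cb))), 0.12)
  # more jitter -> more spread
  jit2 <- perturb_tree_sample(base, 60, jitter_sd = 0.3, seed = 2)
  devs2 <- vapply(seq_along(jit2), function(i)
    max(abs(tree_to_covariance(jit2[[i]], rownames(Cb)) - Cb / max(Cb))),
    numeric(1))
  expect_gt(mean(devs2), mean(devs))
})

test_that("survival simulator reproduces the experimental design", {
  hz <- data.frame(species = sprintf("sp%02d", 1:16),
                   control = 0.001, elevated = 0.03, variable = 0.03)
  rec <- simulate_survival_experiment(hz, n_replicates = 15, seed = 3)
  expect_equal(nrow(rec), 15 * 3 * 16)
  expect_true(all(rec$time %% 12 == 0 & rec$time >= 12 & rec$time <= 96))
  expect_true(all(rec$time[!rec$event] == 96))
  # zero hazard -> everything censored at the bound
  rec0 <- simulate_survival_experiment(
    data.frame(species = "a", control = 0), n_replicates = 10, seed = 1)
  expect_true(all(!rec0$event) && all(rec0$time == 96))
})

test_that("log-rank rejection rate is near nominal when arms share a hazard", {
  hz <- data.frame(species = "a", control = 0.02, elevated = 0.02)
  reps <- 120
  rej <- vapply(seq_len(reps), function(i) {
    rec <- simulate_survival_experiment(hz, n_replicates = 15,
                                        seed = 80000 + i)
    ctl <- rec[rec$treatment == "control", ]
    elv <- rec[rec$treatment == "elevated", ]
    logrank_test(ctl, elv)$p <= 0.05
  }, logical(1))
  band <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(sum(rej), band[1])
  expect_lte(sum(rej), band[2])
})

test_that("feeding simulator is invertible without noise and control-corrected under drift", {
  rates <- matrix(c(1.5, 4, 7), 3, 1,
                  dimnames = list(c("a", "b", "c"), "eelgrass"))
  rec <- simulate_feeding_trials(rates, n_trials = 2, reps_per_species = 4,
                                 drift_sd = 0, trial_sd = 0, residual_sd = 0,
                                 seed = 1)
  adj <- adjust_feeding_records(rec)
  expect_equal(unname(c(tapply(adj$consumed_per_ind_24h, adj$species, mean))),
               c(1.5, 4, 7), tolerance = 1e-10)
  # 10 controls per food per trial by design
  ctl <- rec[rec$species == "CONTROL", ]
  expect_true(all(table(ctl$food, ctl$trial) == 10))
  # systematic decay: unadjusted consumption is biased, adjusted is not
  rec2 <- simulate_feeding_trials(rates, n_trials = 2, reps_per_species = 4,
                                  drift_sd = 0, trial_sd = 0,
                                  residual_sd = 0, seed = 2)
  grz <- rec2[rec2$species != "CONTROL", ]
  decay <- -0.1
  grz$end_amount <- grz$end_amount + grz$start_amount * decay
  ctl2 <- rec2[rec2$species == "CONTROL", ]
  ctl2$end_amount <- ctl2$end_amount + ctl2$start_amount * decay
  both <- rbind(grz, ctl2)
  adj2 <- adjust_feeding_records(both)
  expect_equal(unname(c(tapply(adj2$consumed_per_ind_24h, adj2$species, mean))),
               c(1.5, 4, 7), tolerance = 1e-10)
  naive <- (grz$start_amount - grz$end_amount) / grz$n_individuals /
    (grz$duration_h / 24)
  expect_gt(mean(naive) - mean(adj2$consumed_per_ind_24h), 0.1)
})

test_that("fixture bundles regenerate byte-identically from the same config", {
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  cfg <- default_sim_config(seed = 11)
  cfg$n_trees <- 10
  write_fixture_bundle(d1, cfg)
  write_fixture_bundle(d2, cfg)
  files <- list.files(d1)
  expect_setequal(files, c("trees.nwk", "traits_continuous.tsv",
                           "traits_discrete.tsv", "survival.tsv",
                           "feeding.tsv", "config.tsv"))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # the written traits read back as usable named vectors
  traits <- read_trait_table(file.path(d1, "traits_continuous.tsv"))
  expect_setequal(names(traits), c("bm_trait", "iid_trait", "biomass_mg"))
  expect_length(traits$bm_trait, 16)
  expect_length(attr(traits$bm_trait, "se"), 16)
})
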