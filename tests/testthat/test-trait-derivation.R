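surv_df <- function(time, event) data.frame(time = time, event = event)

test_that("log-rank test matches hand-tabulated hypergeometric sums and is symmetric", {
  a <- surv_df(c(12, 24), c(TRUE, TRUE))
  b <- surv_df(c(84, 96), c(TRUE, TRUE))
  ours <- logrank_test(a, b)
  byhand <- oracle_logrank(a$time, a$event, b$time, b$event)
  expect_equal(ours$chi_square, byhand$chi_square, tolerance = 1e-10)
  expect_equal(ours$p, byhand$p, tolerance = 1e-10)
  # two more fixed toy tables with censoring
  a2 <- surv_df(c(12, 36, 96, 96), c(TRUE, TRUE, FALSE, FALSE))
  b2 <- surv_df(c(48, 60, 72, 96), c(TRUE, TRUE, TRUE, FALSE))
  o2 <- oracle_logrank(a2$time, a2$event, b2$time, b2$event)
  expect_equal(logrank_test(a2, b2)$chi_square, o2$chi_square,
               tolerance = 1e-10)
  a3 <- surv_df(c(12, 12, 24), c(TRUE, TRUE, TRUE))
  b3 <- surv_df(c(12, 96, 96), c(TRUE, FALSE, FALSE))
  o3 <- oracle_logrank(a3$time, a3$event, b3$time, b3$event)
  expect_equal(logrank_test(a3, b3)$chi_square, o3$chi_square,
               tolerance = 1e-10)
  # symmetry in group order
  expect_equal(logrank_test(a2, b2)$chi_square,
               logrank_test(b2, a2)$chi_square)
  # identical groups -> statistic 0, p 1
  same <- logrank_test(a, a)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-6)
  # all censored -> no events -> p 1
  cens <- surv_df(c(96, 96), c(FALSE, FALSE))
  expect_equal(logrank_test(cens, cens), list(chi_square = 0, p = 1))
})

test_that("temperature tolerance is the survival-time reduction with the zeroing rule", {
  rec <- rbind(
    data.frame(species = "sp1", treatment = "control", time = 96,
               event = FALSE)[rep(1, 6), ],
    data.frame(species = "sp1", treatment = "elevated", time = 36,
               event = TRUE)[rep(1, 6), ])
  tt <- temperature_tolerance_trait(rec)
  expect_equal(tt$value, 60)
  expect_false(tt$zeroed)
  # identical arms: statistic 0, value 0
  rec2 <- rbind(
    data.frame(species = "sp2", treatment = "control",
               time = c(24, 48, 96, 96), event = c(TRUE, TRUE, FALSE, FALSE)),
    data.frame(species = "sp2", treatment = "elevated",
               time = c(24, 48, 96, 96), event = c(TRUE, TRUE, FALSE, FALSE)))
  tt2 <- temperature_tolerance_trait(rec2)
  expect_equal(tt2$value, 0)
  expect_true(tt2$zeroed)
  expect_equal(tt2$p, 1, tolerance = 1e-6)
  # non-significant difference -> zeroed even though means differ
  rec3 <- rbind(
    data.frame(species = "sp3", treatment = "control",
               time = c(48, 96, 96), event = c(TRUE, FALSE, FALSE)),
    data.frame(species = "sp3", treatment = "elevated",
               time = c(36, 84, 96), event = c(TRUE, TRUE, FALSE)))
  tt3 <- temperature_tolerance_trait(rec3)
  expect_gt(tt3$p, 0.05)
  expect_equal(tt3$value, 0)
  expect_true(tt3$zeroed)
  # the same data keep their value at a permissive alpha
  tt3b <- temperature_tolerance_trait(rec3, alpha = 0.99)
  expect_equal(tt3b$value, mean(c(48, 96, 96)) - mean(c(36, 84, 96)))
  # missing arm errors
  expect_error(temperature_tolerance_trait(
    data.frame(species = "sp4", treatment = "control", time = 96,
               event = FALSE)), "missing a treatment arm")
})

test_that("control adjustment of consumption follows the percent-change rule", {
  # start 100, end 80, controls -10%, 1 individual, 48 h -> (90-80)/1/2 = 5
  expect_equal(adjust_consumption_for_controls(100, 80, -0.1, 1, 48), 5)
  expect_equal(adjust_consumption_for_controls(50, 50, 0, 2, 24), 0)
  # control growth +20%: equal start/end still means consumption happened
  expect_equal(adjust_consumption_for_controls(100, 100, 0.2, 1, 24), 20)
  expect_error(adjust_consumption_for_controls(1, 1, 0, 0, 24), "n_individuals")
})

test_that("control means use per-cup percent changes by food and trial", {
  rec <- data.frame(
    species = c("CONTROL", "CONTROL", "CONTROL", "spA"),
    trial = c("t1", "t1", "t2", "t1"),
    food = "eelgrass",
    start_amount = c(100, 100, 100, 100),
    end_amount = c(90, 110, 120, 70),
    n_individuals = c(0, 0, 0, 2),
    duration_h = 48)
  ctl <- control_pct_change(rec)
  expect_equal(ctl$control_pct_change[ctl$trial == "t1"], 0)
  expect_equal(ctl$control_pct_change[ctl$trial == "t2"], 0.2)
  adj <- adjust_feeding_records(rec)
  expect_equal(adj$consumed_per_ind_24h, (100 - 70) / 2 / 2)
})

test_that("mixed feeding model reduces to raw species means without trial variance", {
  rates <- matrix(c(2, 5, 9), 3, 1,
                  dimnames = list(c("a", "b", "c"), "eelgrass"))
  rec <- simulate_feeding_trials(rates, n_trials = 2, reps_per_species = 6,
                                 trial_sd = 0, residual_sd = 0, seed = 4)
  adj <- adjust_feeding_records(rec)
  # noise-free data are degenerate for REML; convergence chatter is expected
  fit <- suppressWarnings(fit_feeding_model(adj))
  expect_equal(setNames(fit$estimate, fit$species)[c("a", "b", "c")],
               c(a = 2, b = 5, c = 9), tolerance = 1e-8)
})

test_that("mixed feeding model recovers known species effects up to the trial mean", {
  rates <- matrix(seq(1, 8, length.out = 8), 8, 1,
                  dimnames = list(paste0("s", 1:8), "eelgrass"))
  rmse <- vapply(1:10, function(i) {
    rec <- simulate_feeding_trials(rates, trial_sd = 1, residual_sd = 0.1,
                                   seed = 900 + i)
    fit <- fit_feeding_model(adjust_feeding_records(rec))
    err <- setNames(fit$estimate, fit$species)[rownames(rates)] - rates[, 1]
    err <- err - mean(err) # species effects identified up to the trial mean
    sqrt(mean(err^2))
  }, numeric(1))
  expect_lt(mean(rmse), 0.1)
})

test_that("null species keep large p-values in the feeding model", {
  rates <- matrix(c(0, 0, 4, 6), 4, 1,
                  dimnames = list(paste0("s", 1:4), "eelgrass"))
  ps <- t(vapply(1:30, function(i) {
    rec <- simulate_feeding_trials(rates, trial_sd = 0.05, residual_sd = 0.8,
                                   seed = 2000 + i)
    fit <- fit_feeding_model(adjust_feeding_records(rec))
    setNames(fit$p, fit$species)[rownames(rates)]
  }, numeric(4)))
  # true-zero species rarely significant; strong feeders almost always are
  expect_lt(mean(ps[, 1] < 0.05), 0.3)
  expect_gt(mean(ps[, 4] < 0.05), 0.9)
})

test_that("single-trial feeding data fall back to fixed-effects means with a warning", {
  adj <- data.frame(species = rep(c("a", "b"), each = 4),
                    trial = "t1", food = "eelgrass",
                    consumed_per_ind_24h = c(1, 2, 3, 2, 7, 8, 9, 8))
  expect_warning(fit <- fit_feeding_model(adj), "single trial")
  expect_true(attr(fit, "single_trial_fallback"))
  expect_equal(setNames(fit$estimate, fit$species),
               c(a = 2, b = 8))
})

test_that("feeding-rate zeroing rule keeps significant estimates only, flags negatives", {
  mo <- data.frame(species = c("a", "b", "c"),
                   estimate = c(3.2, 3.2, -0.5),
                   se = c(0.5, 1.8, 0.1),
                   p = c(0.01, 0.20, 0.01))
  expect_warning(tr <- feeding_rate_trait(mo), "negative")
  expect_equal(tr$value, c(3.2, 0, -0.5))
  expect_equal(tr$zeroed, c(FALSE, TRUE, FALSE))
  # idempotence: re-applying the rule to its own output changes nothing
  mo2 <- data.frame(species = tr$species, estimate = tr$value,
                    se = mo$se, p = mo$p)
  expect_equal(suppressWarnings(feeding_rate_trait(mo2))$value, tr$value)
})

test_that("per-mg normalization divides by biomass and can reverse rankings", {
  tr <- suppressWarnings(feeding_rate_trait(
    data.frame(species = c("small", "mid", "big"),
               estimate = c(2, 6, 10), se = 1, p = c(0.01, 0.01, 0.2))))
  biomass <- c(small = 1, mid = 10, big = 100)
  pm <- per_mg_rates(tr, biomass)
  expect_equal(pm$value, c(2, 0.6, 0)) # zeroed stays zero
  # per-individual ranking big > mid > small flips per mg
  expect_gt(pm$value[1], pm$value[2])
  expect_error(per_mg_rates(tr, c(small = 1, mid = 0, big = 2)), "positive")
  expect_error(per_mg_rates(tr, biomass[1:2]), "missing")
})

test_that("pearson correlation handles perfect fits and matches the direct formula", {
  x <- setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5))
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  y <- setNames(c(2.3, 1.1, 4.2, 3.3, 5.0), paste0("s", 1:5))
  res <- pearson_correlation(x, y)
  r_direct <- cov(x, y) / (sd(x) * sd(y))
  t_stat <- r_direct * sqrt(3 / (1 - r_direct^2))
  expect_equal(res$r, r_direct)
  expect_equal(res$p, 2 * pt(-abs(t_stat), df = 3))
  # pairwise species matching drops non-shared names
  y2 <- setNames(c(y, 99), c(names(y), "s9"))
  expect_equal(pearson_correlation(x, y2)$n, 5)
  expect_error(pearson_correlation(x[1:2], y[1:2]), "3 complete pairs")
  expect_error(pearson_correlation(x, setNames(rep(1, 5), names(x))),
               "zero variance")
})
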