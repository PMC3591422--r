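#' @importFrom stats median quantile
NULL

#' Is a trait vector binary?
#' @keywords internal
is_discrete_trait <- function(x) all(x %in% c(0, 1))

summarize_per_tree <- function(per_tree) {
  ok <- per_tree[is.na(per_tree$error), ]
  qs <- function(v) {
    c(mean = mean(v), median = median(v),
      q2.5 = unname(quantile(v, 0.025)), q97.5 = unname(quantile(v, 0.975)))
  }
  list(statistic = qs(ok$statistic), p = qs(ok$p),
       n_ok = nrow(ok), n_failed = sum(!is.na(per_tree$error)))
}

#' Run one signal test for one trait across a tree sample
#'
#' Applies the chosen test (`"K"` = randomization test for Blomberg's K,
#' `"lambda_continuous"` = ML Pagel's lambda with LRT,
#' `"lambda_discrete"` = equal-rates Mk lambda with LRT) to every tree in
#' the sample, pruning each tree to the trait's species first. Each tree
#' gets its own randomization seed derived from the master seed and the tree
#' index, so results do not depend on execution order. Per-tree failures are
#' recorded with the tree index, never silently dropped.
#'
#' @param sample a `multiPhylo` tree sample.
#' @param trait named trait vector; continuous numeric, or 0/1 for the
#'   discrete test. An optional `se` attribute (named vector) switches the K
#'   test to the measurement-error model.
#' @param test one of `"K"`, `"lambda_continuous"`, `"lambda_discrete"`.
#' @param n_perm randomizations for the K test (default 1000).
#' @param seed master integer seed.
#' @param trait_name label stored in the result (default from the call).
#' @param pool species-pool label (default `"all"`).
#' @return a `signal_distribution`: list with `trait`, `test`, `pool`,
#'   `n_trees`, `seed`, `per_tree` (data frame: tree, statistic, p, error)
#'   and `summary` (mean/median/2.5%/97.5% of statistic and p, failure
#'   counts).
#' @export
signal_over_sample <- function(sample, trait,
                               test = c("K", "lambda_continuous",
                                        "lambda_discrete"),
                               n_perm = 1000, seed = 1,
                               trait_name = deparse(substitute(trait)),
                               pool = "all") {
  test <- match.arg(test)
  trees <- unclass(sample)
  species <- names(trait)
  if (is.null(species)) stopf("trait must be named by species")
  se <- attr(trait, "se")
  missing <- setdiff(species, trees[[1L]]$tip.label)
  if (length(missing))
    stopf("trait species absent from trees: %s", paste(missing, collapse = ", "))
  rows <- lapply(seq_along(trees), function(i) {
    res <- tryCatch({
      tr <- trees[[i]]
      if (length(species) < ape::Ntip(tr)) tr <- prune_tips(tr, species)
      tree_seed <- derive_seed(seed, i)
      fit <- switch(test,
        K = {
          C <- tree_to_covariance(tr, species)
          if (!is.null(se))
            blomberg_K_with_SE(C, trait, se, n_perm = n_perm, seed = tree_seed)
          else
            K_randomization_test(C, trait, n_perm = n_perm, seed = tree_seed)
        },
        lambda_continuous = {
          C <- tree_to_covariance(tr, species)
          fit_lambda_continuous(C, setNames(as.numeric(trait), names(trait)))
        },
        lambda_discrete = fit_lambda_discrete(tr, trait))
      stat <- if (test == "K") fit$K else fit$lambda_hat
      data.frame(tree = i, statistic = stat, p = fit$p, error = NA_character_)
    }, error = function(e) {
      data.frame(tree = i, statistic = NA_real_, p = NA_real_,
                 error = conditionMessage(e))
    })
    res
  })
  per_tree <- do.call(rbind, rows)
  structure(list(trait = trait_name, test = test, pool = pool,
                 n_trees = length(trees), seed = seed,
                 per_tree = per_tree,
                 summary = summarize_per_tree(per_tree)),
            class = "signal_distribution")
}

#' Print a signal distribution
#' @param x a `signal_distribution`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @method print signal_distribution
#' @export
print.signal_distribution <- function(x, ...) {
  cat(sprintf("Signal distribution: trait '%s', test %s, pool '%s'\n",
              x$trait, x$test, x$pool))
  cat(sprintf("  %d trees (%d failed)\n", x$n_trees, x$summary$n_failed))
  cat(sprintf("  statistic: mean %.3f, median %.3f [%.3f, %.3f]\n",
              x$summary$statistic["mean"], x$summary$statistic["median"],
              x$summary$statistic["q2.5"], x$summary$statistic["q97.5"]))
  cat(sprintf("  p:         mean %.3f, median %.3f [%.3f, %.3f]\n",
              x$summary$p["mean"], x$summary$p["median"],
              x$summary$p["q2.5"], x$summary$p["q97.5"]))
  invisible(x)
}

#' Rank traits from most to least evidence for phylogenetic signal
#'
#' Orders signal distributions by ascending mean p-value, breaking ties by
#' descending mean statistic and then by trait name (deterministic).
#'
#' @param distributions list of `signal_distribution` objects from the same
#'   pool and tree sample.
#' @return data frame `trait`, `test`, `mean_statistic`, `mean_p`,
#'   `median_p`, `n_failed`, ordered by evidence for signal.
#' @export
rank_traits_by_signal <- function(distributions) {
  if (!length(distributions)) stopf("no distributions supplied")
  pools <- unique(vapply(distributions, `[[`, "", "pool"))
  if (length(pools) > 1L)
    stopf("distributions come from different pools: %s",
          paste(pools, collapse = ", "))
  df <- do.call(rbind, lapply(distributions, function(d) {
    data.frame(trait = d$trait, test = d$test,
               mean_statistic = unname(d$summary$statistic["mean"]),
               mean_p = unname(d$summary$p["mean"]),
               median_p = unname(d$summary$p["median"]),
               n_failed = d$summary$n_failed)
  }))
  df <- df[order(df$mean_p, -df$mean_statistic, df$trait), ]
  rownames(df) <- NULL
  df
}

#' Repeat the signal analysis on a species-pool subset
#'
#' Prunes every tree to `keep`, then runs each trait through the appropriate
#' test(s): continuous traits get both the K randomization test and the
#' continuous lambda fit, binary traits the discrete lambda fit. Traits are
#' restricted to species present in `keep`. Power to detect signal drops
#' with pool size; a warning is issued for pools under 10 species.
#'
#' @param sample a `multiPhylo` tree sample.
#' @param traits named list of trait vectors.
#' @param keep character vector of species to retain (>= 3).
#' @param label pool label recorded in each distribution.
#' @param n_perm randomizations for K tests.
#' @param seed master seed.
#' @return list of `signal_distribution` objects.
#' @export
subset_analysis <- function(sample, traits, keep, label, n_perm = 1000,
                            seed = 1) {
  trees <- unclass(sample)
  if (length(keep) < 3L) stopf("a pool needs at least 3 species")
  if (length(keep) < 10L)
    warning(sprintf("pool '%s' has only %d species: power to detect signal decreases with the number of species",
                    label, length(keep)), call. = FALSE)
  pruned <- if (setequal(keep, trees[[1L]]$tip.label)) sample else
    tree_sample(lapply(trees, prune_tips, keep = keep),
                attr(sample, "provenance"))
  out <- list()
  for (nm in names(traits)) {
    trait <- traits[[nm]]
    trait_keep <- trait[names(trait) %in% keep]
    if (length(trait_keep) < 3L) next
    se <- attr(trait, "se")
    if (!is.null(se)) attr(trait_keep, "se") <- se[names(trait_keep)]
    tests <- if (is_discrete_trait(trait_keep)) "lambda_discrete" else
      c("K", "lambda_continuous")
    for (tst in tests) {
      out[[paste(nm, tst, sep = ".")]] <-
        signal_over_sample(pruned, trait_keep, tst, n_perm = n_perm,
                           seed = seed, trait_name = nm, pool = label)
    }
  }
  out
}

#' Flatten signal distributions to long per-tree and summary tables
#'
#' @param distributions list of `signal_distribution` objects.
#' @return list of two data frames: `per_tree` (pool, trait, test, tree,
#'   statistic, p, error) and `summary` (one row per distribution).
#' @export
signal_tables <- function(distributions) {
  per_tree <- do.call(rbind, lapply(distributions, function(d)
    cbind(pool = d$pool, trait = d$trait, test = d$test, d$per_tree)))
  summary <- do.call(rbind, lapply(distributions, function(d)
    data.frame(pool = d$pool, trait = d$trait, test = d$test,
               n_trees = d$n_trees, n_failed = d$summary$n_failed,
               mean_statistic = unname(d$summary$statistic["mean"]),
               median_statistic = unname(d$summary$statistic["median"]),
               stat_q2.5 = unname(d$summary$statistic["q2.5"]),
               stat_q97.5 = unname(d$summary$statistic["q97.5"]),
               mean_p = unname(d$summary$p["mean"]),
               median_p = unname(d$summary$p["median"]),
               p_q2.5 = unname(d$summary$p["q2.5"]),
               p_q97.5 = unname(d$summary$p["q97.5"]),
               seed = d$seed)))
  rownames(per_tree) <- rownames(summary) <- NULL
  list(per_tree = per_tree, summary = summary)
}
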