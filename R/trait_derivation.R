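#' @importFrom survival survdiff Surv
#' @importFrom lme4 lmer
#' @importFrom stats cor.test coef lm setNames aggregate pchisq
NULL

# Raw experiment records are plain data frames:
#   survival: species, treatment ("control"/"elevated"/...), time (h), event
#   feeding:  species ("CONTROL" for no-grazer cups), trial, food,
#             start_amount, end_amount, n_individuals, duration_h

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the pooled ordered event times (censored
#' records enter the risk sets only), with p from a one-degree-of-freedom
#' chi-square. Wraps [survival::survdiff()]. If neither group has any event
#' the statistic is 0 and p = 1.
#'
#' @param group_a,group_b data frames with columns `time` (positive) and
#'   `event` (logical/0-1; `FALSE` = censored).
#' @return list with `chi_square` and `p`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (!nrow(group_a) || !nrow(group_b)) stopf("both groups must be non-empty")
  time <- c(group_a$time, group_b$time)
  event <- as.integer(c(group_a$event, group_b$event))
  grp <- rep(c("a", "b"), c(nrow(group_a), nrow(group_b)))
  if (sum(event) == 0L) return(list(chi_square = 0, p = 1))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- as.numeric(fit$chisq)
  list(chi_square = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

new_derived_trait <- function(df, rule) {
  stopifnot(all(c("species", "value", "p", "zeroed") %in% names(df)))
  structure(df, class = c("derived_trait", "data.frame"), rule = rule)
}

#' Extract a named trait vector from a derived trait table
#'
#' @param trait a `derived_trait` data frame.
#' @return named numeric vector (species -> value) ready for the signal tests.
#' @export
trait_vector <- function(trait) {
  setNames(trait$value, trait$species)
}

#' Temperature tolerance from survival records
#'
#' The trait is the average reduction in survival time under the elevated
#' temperature arm: mean(control time) - mean(elevated time), censored
#' replicates entering the mean at the 96 h observation bound. Species whose
#' log-rank treatment p-value exceeds `alpha` are assigned 0 (no detectable
#' treatment effect); larger values mean lower tolerance. Treatment arms
#' other than "control"/"elevated" are ignored.
#'
#' @param records data frame with columns `species`, `treatment`, `time`,
#'   `event`.
#' @param alpha significance threshold for the log-rank screen (default
#'   0.05; values with p > alpha are zeroed).
#' @return a `derived_trait` data frame: `species`, `value`, `p`, `zeroed`.
#' @export
temperature_tolerance_trait <- function(records, alpha = 0.05) {
  records <- records[records$treatment %in% c("control", "elevated"), ]
  out <- lapply(split(records, records$species), function(d) {
    ctl <- d[d$treatment == "control", ]
    elv <- d[d$treatment == "elevated", ]
    if (!nrow(ctl) || !nrow(elv))
      stopf("species %s is missing a treatment arm", d$species[1L])
    lr <- logrank_test(ctl, elv)
    value <- mean(ctl$time) - mean(elv$time)
    zeroed <- lr$p > alpha
    data.frame(species = d$species[1L],
               value = if (zeroed) 0 else value,
               p = lr$p, zeroed = zeroed)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  new_derived_trait(df, "survival_reduction_logrank")
}

#' Mean percent change in no-grazer control cups
#'
#' The per-cup percent change (end - start) / start is averaged over the
#' control cups of each food x trial combination.
#'
#' @param records feeding records (see [adjust_feeding_records()]); control
#'   cups have `species == "CONTROL"`.
#' @return data frame `food`, `trial`, `control_pct_change`.
#' @export
control_pct_change <- function(records) {
  ctl <- records[records$species == "CONTROL", ]
  if (!nrow(ctl)) stopf("no control records found")
  agg <- aggregate(cbind(pct = (end_amount - start_amount) / start_amount) ~
                     food + trial, data = ctl, FUN = mean)
  names(agg)[names(agg) == "pct"] <- "control_pct_change"
  agg
}

#' Control-adjusted consumption per individual per 24 h
#'
#' Adjusts the starting amount by the mean percent change of the matching
#' no-grazer controls, then scales to a per-individual, per-24 h rate:
#' (start * (1 + control change) - end) / n_individuals / (duration / 24).
#' Negative values (apparent growth beyond controls) are passed through to
#' the model stage.
#'
#' @param start_amount,end_amount amounts (same units).
#' @param control_mean_pct_change mean proportional change in the matching
#'   control cups (e.g. -0.1 for a 10 % loss).
#' @param n_individuals grazers per cup (>= 1).
#' @param duration_h trial duration in hours (> 0).
#' @return consumption per individual per 24 h (same units as the amounts).
#' @export
adjust_consumption_for_controls <- function(start_amount, end_amount,
                                            control_mean_pct_change,
                                            n_individuals, duration_h) {
  if (any(duration_h <= 0)) stopf("duration must be positive")
  if (any(n_individuals < 1)) stopf("n_individuals must be >= 1")
  (start_amount * (1 + control_mean_pct_change) - end_amount) /
    n_individuals / (duration_h / 24)
}

#' Control-adjust a full table of feeding records
#'
#' Joins each grazer cup with the mean control change for its food x trial
#' and applies [adjust_consumption_for_controls()]. Control cups are dropped
#' from the output.
#'
#' @param records data frame with columns `species`, `trial`, `food`,
#'   `start_amount`, `end_amount`, `n_individuals`, `duration_h`.
#' @return the grazer records with an added `consumed_per_ind_24h` column.
#' @export
adjust_feeding_records <- function(records) {
  need <- c("species", "trial", "food", "start_amount", "end_amount",
            "n_individuals", "duration_h")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stopf("feeding records are missing columns: %s",
          paste(missing, collapse = ", "))
  ctl <- control_pct_change(records)
  grz <- records[records$species != "CONTROL", ]
  grz <- merge(grz, ctl, by = c("food", "trial"), all.x = TRUE)
  if (any(is.na(grz$control_pct_change)))
    stopf("no controls for some food x trial combinations")
  grz$consumed_per_ind_24h <- adjust_consumption_for_controls(
    grz$start_amount, grz$end_amount, grz$control_pct_change,
    grz$n_individuals, grz$duration_h)
  grz
}

#' Per-species feeding-rate estimates from a mixed model
#'
#' For one food, fits consumption per individual per 24 h with grazer species
#' as fixed effect and trial as random intercept by REML
#' ([lmerTest::lmer()], cell-means coding), returning each species' estimate,
#' standard error and Satterthwaite p-value for the test estimate != 0. With
#' a single trial the random effect is inestimable and the fit falls back to
#' ordinary fixed-effects species means, flagged in the result.
#'
#' @param adjusted output of [adjust_feeding_records()] restricted to one
#'   food.
#' @return data frame `species`, `estimate`, `se`, `p` with attribute
#'   `single_trial_fallback`.
#' @export
fit_feeding_model <- function(adjusted) {
  if (length(unique(adjusted$food)) > 1L)
    stopf("fit one food at a time (got: %s)",
          paste(unique(adjusted$food), collapse = ", "))
  adjusted$species <- factor(adjusted$species)
  adjusted$trial <- factor(adjusted$trial)
  single_trial <- nlevels(adjusted$trial) < 2L
  if (single_trial) {
    warning("single trial: falling back to fixed-effects species means",
            call. = FALSE)
    fit <- lm(consumed_per_ind_24h ~ 0 + species, data = adjusted)
    sm <- summary(fit)$coefficients
  } else {
    fit <- suppressMessages(
      lmerTest::lmer(consumed_per_ind_24h ~ 0 + species + (1 | trial),
                     data = adjusted, REML = TRUE))
    sm <- coef(summary(fit))
  }
  out <- data.frame(
    species = sub("^species", "", rownames(sm)),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    p = sm[, ncol(sm)])
  rownames(out) <- NULL
  attr(out, "single_trial_fallback") <- single_trial
  out
}

#' Apply the feeding-rate zeroing rule
#'
#' A species' feeding rate is kept only when its estimate differs
#' significantly from 0 (p < `alpha`); otherwise it is recorded as 0.
#' Significant negative estimates are retained (the rule concerns
#' significance, not sign) but flagged with a warning.
#'
#' @param model_out output of [fit_feeding_model()].
#' @param alpha significance threshold (default 0.05).
#' @return a `derived_trait` data frame.
#' @export
feeding_rate_trait <- function(model_out, alpha = 0.05) {
  keep <- model_out$p < alpha
  if (any(keep & model_out$estimate < 0))
    warning("significant negative feeding estimate(s) for: ",
            paste(model_out$species[keep & model_out$estimate < 0],
                  collapse = ", "), call. = FALSE)
  df <- data.frame(species = model_out$species,
                   value = ifelse(keep, model_out$estimate, 0),
                   p = model_out$p,
                   zeroed = !keep)
  new_derived_trait(df, "feeding_mixed_model")
}

#' Convert per-individual rates to per-mg-of-grazer rates
#'
#' Divides each species' rate by its mean dry biomass; zeroed rates stay 0.
#'
#' @param trait a `derived_trait` of per-individual rates.
#' @param biomass named numeric vector of mean dry biomass in mg (> 0),
#'   covering every species in `trait`.
#' @return a `derived_trait` of per-mg rates.
#' @export
per_mg_rates <- function(trait, biomass) {
  b <- biomass[trait$species]
  if (any(is.na(b))) stopf("biomass missing for some species")
  if (any(b <= 0)) stopf("biomass must be positive")
  df <- trait
  df$value <- trait$value / as.numeric(b)
  new_derived_trait(as.data.frame(df), paste0(attr(trait, "rule"), "_per_mg"))
}

#' Pearson correlation between two species-paired trait vectors
#'
#' Species present in only one vector are dropped pairwise; r and the
#' two-sided p come from the t transform on n - 2 degrees of freedom
#' ([stats::cor.test()]).
#'
#' @param x,y named numeric vectors (species -> value).
#' @return list with `r`, `p`, `n` (complete pairs used).
#' @export
pearson_correlation <- function(x, y) {
  common <- intersect(names(x), names(y))
  xv <- x[common]; yv <- y[common]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stopf("fewer than 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) stopf("zero variance in one of the vectors")
  ct <- cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xv))
}
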