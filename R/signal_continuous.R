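#' @importFrom stats optimize pchisq sd var
NULL

# Continuous traits are named numeric vectors (species -> trait mean), the
# convention used throughout R comparative methods; standard errors, when
# present, are a second named vector on the same species set.

#' Align a continuous trait with a covariance matrix
#' @keywords internal
align_trait <- function(C, x, se = NULL) {
  labs <- rownames(C)
  if (is.null(names(x))) stopf("trait vector must be named by species")
  if (!setequal(names(x), labs))
    stopf("trait species do not match covariance labels (missing: %s; extra: %s)",
          paste(setdiff(labs, names(x)), collapse = ", "),
          paste(setdiff(names(x), labs), collapse = ", "))
  x <- x[labs]
  if (any(!is.finite(x))) stopf("trait contains non-finite values")
  if (length(x) < 3L) stopf("at least 3 species are required")
  if (!is.null(se)) {
    if (!setequal(names(se), labs))
      stopf("SE species do not match covariance labels")
    se <- se[labs]
    if (any(!is.finite(se)) || any(se < 0)) stopf("SEs must be finite and >= 0")
  }
  list(x = x, se = se)
}

#' Multivariate-normal log-likelihood with a common mean
#'
#' Log density of `x` under N(mu * 1, V), evaluated via the Cholesky factor
#' of `V`.
#'
#' @param x numeric vector.
#' @param mu scalar mean.
#' @param V symmetric positive-definite covariance matrix.
#' @return the log-likelihood (scalar).
#' @export
mvn_loglik <- function(x, mu, V) {
  n <- length(x)
  if (!is.matrix(V) || nrow(V) != n || ncol(V) != n)
    stopf("V must be a %d x %d matrix", n, n)
  R <- tryCatch(chol(V), error = function(e) stopf("V is not positive definite"))
  d <- x - mu
  z <- backsolve(R, d, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
}

# add-one one-sided permutation p; floating-point ties count as >= (on a
# star covariance every permutation gives K = 1 up to rounding, so p = 1)
perm_pvalue <- function(stat_perm, stat_obs) {
  tol <- 1e-9 * max(1, abs(stat_obs))
  (1 + sum(stat_perm >= stat_obs - tol)) / (length(stat_perm) + 1)
}

# K ratio for a general working covariance V (scale-invariant in V):
#   ahat  = GLS mean under V
#   K     = [(sum (x-ahat)^2) / ((x-ahat)' V^-1 (x-ahat))] /
#           [(tr V - n / sum(V^-1)) / (n - 1)]
# On a star covariance (V = T I) both ratios equal T, giving K = 1.
k_ratio <- function(Vinv, trV, x) {
  n <- length(x)
  s <- sum(Vinv)
  ahat <- sum(Vinv %*% x) / s
  d <- x - ahat
  num <- sum(d * d)
  den <- as.numeric(d %*% Vinv %*% d)
  expected <- (trV - n / s) / (n - 1)
  (num / den) / expected
}

#' Blomberg's K for a continuous trait
#'
#' Ratio of the observed mean squared deviation from the phylogenetically
#' weighted mean to its GLS counterpart, scaled by the Brownian-motion
#' expectation: K = 1 under Brownian motion on the tree, K < 1 for less
#' resemblance among relatives, K > 1 for more. Scale-invariant in the trait.
#'
#' @param cov phylogenetic covariance matrix (see [tree_to_covariance()]).
#' @param x named numeric trait vector (species -> mean).
#' @return the K statistic (scalar).
#' @export
blomberg_K <- function(cov, x) {
  al <- align_trait(cov, x)
  x <- al$x
  if (sd(x) == 0) stopf("trait is constant; K is undefined")
  Vinv <- chol2inv(chol(cov))
  k_ratio(Vinv, sum(diag(cov)), x)
}

#' Randomization test for Blomberg's K
#'
#' Compares observed K to the K obtained when trait values are shuffled
#' across the tips; the p-value is the add-one permutation estimate
#' p = (1 + #\{K_perm >= K_obs\}) / (n_perm + 1), one-sided with large K
#' indicating signal. Ties count against the observed statistic.
#'
#' @inheritParams blomberg_K
#' @param n_perm number of randomizations (default 1000).
#' @param seed integer seed for the permutations.
#' @return a list of class `K_result`: `K`, `p`, `n_randomizations`,
#'   `used_SE`.
#' @export
K_randomization_test <- function(cov, x, n_perm = 1000, seed = 1) {
  al <- align_trait(cov, x)
  x <- al$x
  if (sd(x) == 0) stopf("trait is constant; K is undefined")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  Vinv <- chol2inv(chol(cov))
  trV <- sum(diag(cov))
  K_obs <- k_ratio(Vinv, trV, x)
  n <- length(x)
  K_perm <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) k_ratio(Vinv, trV, x[sample.int(n)]),
           numeric(1))
  })
  p <- perm_pvalue(K_perm, K_obs)
  structure(list(K = K_obs, p = p, n_randomizations = n_perm,
                 used_SE = FALSE),
            class = "K_result")
}

# ML estimate of sigma2 in V = sigma2 * C + diag(se^2), profiling the GLS
# mean; returns list(sigma2, loglik, mu)
fit_sigma2_with_se <- function(C, x, se) {
  n <- length(x)
  D <- diag(se^2, n)
  prof <- function(log_s2) {
    V <- exp(log_s2) * C + D
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(list(ll = -Inf))
    Vinv <- chol2inv(R)
    mu <- sum(Vinv %*% x) / sum(Vinv)
    d <- x - mu
    z <- backsolve(R, d, transpose = TRUE)
    ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
    list(ll = ll, mu = mu)
  }
  # bracket around the scale suggested by the raw trait variance
  centre <- log(max(var(x) / mean(diag(C)), 1e-12))
  opt <- optimize(function(ls) prof(ls)$ll, interval = centre + c(-15, 15),
                  maximum = TRUE, tol = 1e-8)
  at <- prof(opt$maximum)
  list(sigma2 = exp(opt$maximum), loglik = at$ll, mu = at$mu)
}

#' Blomberg's K incorporating standard errors of trait means
#'
#' Replaces the Brownian covariance sigma2 * C with the measurement-error
#' model V = sigma2 * C + diag(SE^2), with sigma2 estimated by maximum
#' likelihood (GLS mean profiled out), and evaluates the K ratio under V.
#' With all SEs equal to zero the result reduces exactly to the plain
#' statistic, so that case is delegated to [K_randomization_test()].
#'
#' @inheritParams K_randomization_test
#' @param se named numeric vector of standard errors (same species as `x`).
#' @return a `K_result` list with `used_SE = TRUE` (unless all SEs are 0).
#' @export
blomberg_K_with_SE <- function(cov, x, se, n_perm = 1000, seed = 1) {
  al <- align_trait(cov, x, se)
  x <- al$x; se <- al$se
  if (is.null(se)) stopf("standard errors are required")
  if (all(se == 0)) return(K_randomization_test(cov, x, n_perm, seed))
  if (sd(x) == 0) stopf("trait is constant; K is undefined")
  n <- length(x)
  k_with_se <- function(xv, sev) {
    fit <- fit_sigma2_with_se(cov, xv, sev)
    V <- fit$sigma2 * cov + diag(sev^2, n)
    k_ratio(chol2inv(chol(V)), sum(diag(V)), xv)
  }
  K_obs <- k_with_se(x, se)
  K_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      k_with_se(x[idx], se[idx])
    }, numeric(1))
  })
  p <- perm_pvalue(K_perm, K_obs)
  structure(list(K = K_obs, p = p, n_randomizations = n_perm,
                 used_SE = TRUE),
            class = "K_result")
}

# profile log-likelihood in lambda: GLS mean and ML variance concentrated out
lambda_profile <- function(C, x, lambda) {
  n <- length(x)
  Cl <- lambda_transform_cov(C, lambda)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  Vinv <- chol2inv(R)
  mu <- sum(Vinv %*% x) / sum(Vinv)
  d <- x - mu
  q <- as.numeric(d %*% Vinv %*% d)
  sigma2 <- q / n
  if (sigma2 <= 0) return(list(ll = -Inf))
  ll <- -0.5 * (n * (log(2 * pi) + 1) + n * log(sigma2) +
                  2 * sum(log(diag(R))))
  list(ll = ll, mu = mu, sigma2 = sigma2)
}

#' Maximum-likelihood Pagel's lambda for a continuous trait
#'
#' Maximizes the profile log-likelihood of the lambda-transformed Brownian
#' model over lambda in \[0, 1\] (GLS mean and ML variance concentrated out),
#' and tests lambda-hat against lambda = 0 with a likelihood-ratio test on
#' one degree of freedom. A 17-point grid pre-scan guards the bounded scalar
#' search against local maxima. On a star phylogeny the likelihood is flat in
#' lambda; the fit is then flagged degenerate with lambda-hat 0 and p 1.
#'
#' @inheritParams blomberg_K
#' @return a list of class `lambda_result`: `lambda_hat`, `loglik_at_hat`,
#'   `loglik_at_zero`, `LRT_stat`, `p`, `sigma2_hat`, `mu_hat`, `degenerate`.
#' @export
fit_lambda_continuous <- function(cov, x) {
  al <- align_trait(cov, x)
  x <- al$x
  if (sd(x) == 0) stopf("trait is constant; lambda is undefined")
  grid <- seq(0, 1, length.out = 17)
  ll_grid <- vapply(grid, function(l) lambda_profile(cov, x, l)$ll, numeric(1))
  if (all(!is.finite(ll_grid))) stopf("likelihood undefined at every lambda")
  fin <- is.finite(ll_grid)
  if (diff(range(ll_grid[fin])) < 1e-8) {
    at0 <- lambda_profile(cov, x, 0)
    return(structure(list(lambda_hat = 0, loglik_at_hat = at0$ll,
                          loglik_at_zero = at0$ll, LRT_stat = 0, p = 1,
                          sigma2_hat = at0$sigma2, mu_hat = at0$mu,
                          degenerate = TRUE),
                     class = "lambda_result"))
  }
  i <- which.max(ll_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(l) lambda_profile(cov, x, l)$ll,
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  # keep the better of interior optimum and the exact boundary evaluations
  cand <- c(opt$maximum, 0, 1, grid[i])
  cand_ll <- c(opt$objective, ll_grid[1L], ll_grid[length(grid)], ll_grid[i])
  best <- which.max(cand_ll)
  lambda_hat <- cand[best]
  at_hat <- lambda_profile(cov, x, lambda_hat)
  at0 <- lambda_profile(cov, x, 0)
  lrt <- max(0, 2 * (at_hat$ll - at0$ll))
  structure(list(lambda_hat = lambda_hat, loglik_at_hat = at_hat$ll,
                 loglik_at_zero = at0$ll, LRT_stat = lrt,
                 p = pchisq(lrt, df = 1, lower.tail = FALSE),
                 sigma2_hat = at_hat$sigma2, mu_hat = at_hat$mu,
                 degenerate = FALSE),
            class = "lambda_result")
}

#' Likelihood-ratio p-value on one degree of freedom
#'
#' Upper chi-square(1) tail of twice the log-likelihood difference.
#'
#' @param delta_loglik non-negative log-likelihood difference
#'   (`loglik_alt - loglik_null`).
#' @return the p-value.
#' @export
lrt_pvalue <- function(delta_loglik) {
  if (delta_loglik < 0) stopf("delta_loglik must be non-negative")
  pchisq(2 * delta_loglik, df = 1, lower.tail = FALSE)
}
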