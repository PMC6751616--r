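# Maximum-likelihood fitting of beta densities and finite beta mixtures.
#
# The beta log-likelihood depends on the data only through n, mean(log x)
# and mean(log(1 - x)); all fits below work on those sufficient statistics,
# which keeps the manual dichotomisation search (hundreds of candidate
# cuts) cheap.

# Weighted sufficient statistics: list(n, mlx, ml1x).
beta_suffstats <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  n <- sum(w)
  list(n = n,
       mlx = sum(w * log(x)) / n,
       ml1x = sum(w * log1p(-x)) / n,
       mean = sum(w * x) / n,
       var = sum(w * (x - sum(w * x) / n)^2) / n)
}

beta_loglik_suff <- function(a, b, ss) {
  ss$n * ((a - 1) * ss$mlx + (b - 1) * ss$ml1x - lbeta(a, b))
}

# Method-of-moments (a, b); falls back to a sharp spike (ESS `spike_ess`)
# centred at the common value when the variance is (near) zero.
beta_mom <- function(m, v, bounds, spike_ess = 1000) {
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m)) {
    a <- m * spike_ess; b <- (1 - m) * spike_ess
  } else {
    common <- m * (1 - m) / v - 1
    a <- m * common; b <- (1 - m) * common
  }
  c(clamp(a, bounds[1], bounds[2]), clamp(b, bounds[1], bounds[2]))
}

# ML fit from sufficient statistics; optimises on the log-shape scale with
# the analytic gradient (digamma terms).
beta_ml_suff <- function(ss, bounds, init = NULL) {
  if (is.null(init)) init <- beta_mom(ss$mean, ss$var, bounds)
  nll <- function(p) -beta_loglik_suff(exp(p[1]), exp(p[2]), ss)
  grad <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    dab <- digamma(a + b)
    c(-ss$n * a * (ss$mlx - digamma(a) + dab),
      -ss$n * b * (ss$ml1x - digamma(b) + dab))
  }
  fit <- stats::optim(log(init), nll, gr = grad, method = "L-BFGS-B",
                      lower = log(bounds[1]), upper = log(bounds[2]),
                      control = list(maxit = 500))
  list(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]),
       loglik = -fit$value, convergence = fit$convergence)
}

#' Maximum-likelihood fit of a single beta density
#'
#' Building block for the mixture-fitting methods. Initialised by the
#' method of moments and refined by bounded quasi-Newton optimisation of
#' the log-likelihood on the log-shape scale.
#'
#' @param values numeric vector of proportions strictly inside (0, 1).
#' @param config an [elicit_config()]; `shape_bounds` bounds the shape
#'   parameters.
#' @return a list with `shape1`, `shape2`, `loglik` and `degenerate`
#'   (`TRUE` when the spike fallback for < 2 distinct values was used).
#' @details With fewer than two distinct values the likelihood is unbounded;
#'   a sharp spike (effective sample size 1000) centred at the common value
#'   is returned with a warning.
#' @export
fit_beta_ml <- function(values, config = elicit_config()) {
  if (length(values) < 1L) stopf("no values to fit")
  if (any(values <= 0 | values >= 1))
    stopf("all values must lie strictly inside (0, 1)")
  bounds <- config$shape_bounds
  if (length(unique(values)) < 2L) {
    warnf("fewer than 2 distinct values: degenerate spike fit used")
    ab <- beta_mom(values[1], 0, bounds)
    ss <- beta_suffstats(values)
    return(list(shape1 = ab[1], shape2 = ab[2],
                loglik = beta_loglik_suff(ab[1], ab[2], ss),
                degenerate = TRUE))
  }
  fit <- beta_ml_suff(beta_suffstats(values), bounds)
  fit$degenerate <- FALSE
  fit
}

# --- EM for a K-component beta mixture --------------------------------------

# One EM run from a given initialisation. Returns NULL on failure
# (component collapse or non-finite log-likelihood).
em_run <- function(x, K, w, A, B, max_iter, tol, bounds) {
  n <- length(x)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- matrix(0, n, K)
    for (k in seq_len(K))
      logd[, k] <- log(w[k]) + stats::dbeta(x, A[k], B[k], log = TRUE)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    if (!is.finite(ll)) return(NULL)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-8))
      break
    ll_old <- ll
    r <- exp(logd - lse)                      # responsibilities, n x K
    w <- colMeans(r)
    if (any(w < 1e-8) || any(colSums(r) < 2)) return(NULL)
    for (k in seq_len(K)) {
      ss <- beta_suffstats(x, r[, k])
      fit <- beta_ml_suff(ss, bounds, init = c(A[k], B[k]))
      A[k] <- fit$shape1; B[k] <- fit$shape2
    }
  }
  ord <- order(A / (A + B))                   # report components by mean
  list(weights = w[ord], shape1 = A[ord], shape2 = B[ord],
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       iterations = length(ll_trace))
}

# Partition-based initialisation: split the sorted data at given quantile
# breakpoints and take method-of-moments fits per block.
em_init_partition <- function(xs, K, breaks, bounds) {
  n <- length(xs)
  idx <- findInterval(seq_len(n) / n, c(0, breaks, 1), left.open = TRUE)
  idx <- clamp(idx, 1, K)
  A <- B <- w <- numeric(K)
  for (k in seq_len(K)) {
    blk <- xs[idx == k]
    if (length(blk) < 2L) blk <- xs[clamp(which(idx == k)[1] + c(0, 1), 1, n)]
    if (length(blk) < 1L || anyNA(blk)) return(NULL)
    ab <- beta_mom(mean(blk), stats::var(blk) * (length(blk) - 1) / length(blk),
                   bounds)
    A[k] <- ab[1]; B[k] <- ab[2]
    w[k] <- max(length(blk), 1) / n
  }
  list(w = w / sum(w), A = A, B = B)
}

# EM with seeded restarts for one fixed K; best run by log-likelihood.
em_fixed_k <- function(x, K, config) {
  xs <- sort(x)
  runs <- list()
  with_seed(derive_seed(config$seed, K, 101), {
    for (r in seq_len(config$n_restarts)) {
      breaks <- if (r == 1L) seq_len(K - 1) / K
                else sort(stats::runif(K - 1, 0.05, 0.95))
      init <- em_init_partition(xs, K, breaks, config$shape_bounds)
      if (is.null(init)) next
      run <- em_run(x, K, init$w, init$A, init$B,
                    config$max_iter, config$tol, config$shape_bounds)
      if (!is.null(run)) runs[[length(runs) + 1L]] <- run
    }
  })
  if (length(runs) == 0L) return(NULL)
  runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
}

# --- Goodness-of-fit criteria -----------------------------------------------

# Lower is better for every criterion (the fit with the lowest criterion is
# retained). n_params counts free parameters: 2 shapes per active component
# plus (k - 1) free weights.
fit_criteria <- function(mixture, values) {
  ll <- sum(log(mixture_density(mixture, values)))
  k <- mixture$k
  n_params <- 2 * k + (k - 1)
  n <- length(values)
  xs <- sort(values)
  Fm <- mixture_cdf(mixture, xs)
  ks <- max(pmax(abs(seq_len(n) / n - Fm), abs((seq_len(n) - 1) / n - Fm)))
  c(neg_loglik = -ll,
    aic = -2 * ll + 2 * n_params,
    bic = -2 * ll + n_params * log(n),
    ks = ks)
}

criterion_names <- c("neg_loglik", "aic", "bic", "ks")
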