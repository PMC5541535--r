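# Seeded Gibbs sampler for the no-intercept Gaussian linear model
#
#   y = X b + e,  e ~ N(0, sigma^2)
#   b_k ~ N(0, prior_sd^2)   (independent, regularising)
#   sigma ~ half-Normal(0, sigma_prior_sd)
#
# b | sigma is conjugate multivariate normal; sigma | b is drawn by a
# univariate slice sampler on log(sigma). Small fixed-dimension problems
# (p <= ~15), so dense Cholesky per iteration is cheap.

slice_sample_1d <- function(logf_raw, x0, w = 0.5, max_steps = 50L) {
  logf <- function(x) {
    v <- logf_raw(x)
    if (is.nan(v) || is.na(v)) -Inf else v
  }
  y <- logf(x0) - stats::rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  k <- max_steps
  while (k > 0 && logf(L) > y) { L <- L - w; k <- k - 1L }
  k <- max_steps
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1L }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

gibbs_lm <- function(X, y, prior_sd = 0.1, sigma_prior_sd = 1,
                     draws = 1000L, warmup = 1000L, chains = 2L, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- length(y)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1]
  yty <- sum(y^2)
  prior_prec <- diag(1 / prior_sd^2, p)

  run_chain <- function(chain_seed) {
    with_seed(chain_seed, {
      B <- matrix(NA_real_, draws, p)
      S <- numeric(draws)
      sigma <- 1
      total <- warmup + draws
      for (it in seq_len(total)) {
        A <- XtX / sigma^2 + prior_prec
        R <- chol(A)
        mu <- backsolve(R, forwardsolve(t(R), Xty / sigma^2))
        beta <- mu + backsolve(R, rnorm(p))
        ssr <- max(yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta)), 1e-12)
        logf <- function(u) {
          s2 <- exp(2 * u)
          -n * u - ssr / (2 * s2) - s2 / (2 * sigma_prior_sd^2) + u
        }
        sigma <- exp(slice_sample_1d(logf, log(sigma)))
        if (it > warmup) {
          B[it - warmup, ] <- beta
          S[it - warmup] <- sigma
        }
      }
      list(beta = B, sigma = S)
    })
  }

  res <- lapply(seq_len(chains), function(ch) run_chain(child_seed(seed, ch)))
  beta <- do.call(rbind, lapply(res, `[[`, "beta"))
  colnames(beta) <- colnames(X)
  list(beta = beta, sigma = unlist(lapply(res, `[[`, "sigma")),
       n_obs = n, p = p)
}

# Pointwise Gaussian log-likelihood matrix (draws x observations).
pointwise_loglik_lm <- function(X, y, beta_draws, sigma_draws) {
  M <- X %*% t(beta_draws)          # n x D fitted values
  E <- (y - M)^2
  tE <- t(E)                        # D x n; sigma recycles over draws
  -0.5 * log(2 * pi) - log(sigma_draws) - tE / (2 * sigma_draws^2)
}
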