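#' Sampler settings
#'
#' @param draws Post-warmup draws per chain.
#' @param warmup Warmup iterations per chain (discarded).
#' @param chains Independent chains; draws are pooled.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(draws = 1000L, warmup = 1000L, chains = 2L) {
  structure(list(draws = as.integer(draws), warmup = as.integer(warmup),
                 chains = as.integer(chains)), class = "mcmc_settings")
}

build_design <- function(steps, reduced = FALSE) {
  nb <- step_neighbours(steps)
  y <- c(steps$obs_x, steps$obs_y)
  cols <- list()
  if (!reduced) {
    for (j in nb) {
      cols[[j]] <- c(steps[[paste0("to_x.", j)]], steps[[paste0("to_y.", j)]])
    }
  }
  cols[["cm"]] <- c(steps$cm_x, steps$cm_y)
  cols[["prev"]] <- c(steps$prev_x, steps$prev_y)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = y, neighbours = if (reduced) character(0) else nb)
}

fit_direction_model <- function(steps, reduced, prior_sd, sigma_prior_sd,
                                mcmc, seed, n_min, hpdi_prob) {
  n_steps <- nrow(steps)
  focal <- attr(steps, "focal") %||% unique(steps$focal)
  if (n_steps < n_min) {
    abort(sprintf("focal '%s' has %d usable steps; at least %d are required",
                  focal, n_steps, n_min))
  }
  d <- build_design(steps, reduced = reduced)
  post <- gibbs_lm(d$X, d$y, prior_sd = prior_sd,
                   sigma_prior_sd = sigma_prior_sd,
                   draws = mcmc$draws, warmup = mcmc$warmup,
                   chains = mcmc$chains, seed = seed)
  terms <- colnames(d$X)
  ints <- t(apply(post$beta, 2, hpdi, prob = hpdi_prob))
  summ <- tibble(
    term = terms,
    role = ifelse(terms %in% c("cm", "prev"), terms, "neighbour"),
    estimate = colMeans(post$beta),
    hpdi_low = ints[, 1],
    hpdi_high = ints[, 2]
  )
  sig_int <- hpdi(post$sigma, prob = hpdi_prob)
  ll <- pointwise_loglik_lm(d$X, d$y, post$beta, post$sigma)
  structure(list(
    focal = focal,
    model = if (reduced) "reduced" else "full",
    summary = summ,
    sigma = tibble(estimate = mean(post$sigma),
                   hpdi_low = sig_int[1], hpdi_high = sig_int[2]),
    beta_draws = post$beta,
    sigma_draws = post$sigma,
    pointwise_loglik = ll,
    neighbours = d$neighbours,
    n_steps = n_steps,
    n_obs = post$n_obs,
    prior_sd = prior_sd,
    hpdi_prob = hpdi_prob,
    mcmc = mcmc,
    seed = seed
  ), class = "influence_fit")
}

#' Fit the full direction-matching model for one focal
#'
#' Regresses the stacked x- and y-components of the focal's observed unit
#' direction of travel on the matching components of (i) the unit vector to
#' every other group member, (ii) the unit vector to the centroid of the
#' others, and (iii) the previous heading. There is no intercept (one would
#' encode an absolute compass bias); the x and y components are treated as
#' independent observations sharing one residual sd, so interval widths are
#' anti-conservative and the 99% HPDI screening compensates. Coefficients
#' get regularising Normal(0, `prior_sd`) priors; the residual sd a
#' half-Normal(1) prior.
#'
#' @param steps Step table from [build_steps()].
#' @param prior_sd Prior sd of every coefficient (default 0.1).
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed; fits are deterministic given it.
#' @param n_min Minimum usable steps (default 50).
#' @param sigma_prior_sd Scale of the half-Normal prior on the residual sd.
#' @param hpdi_prob Mass of the highest-posterior-density interval reported
#'   (default 0.99, the edge-screening rule).
#' @return An `influence_fit`: posterior summaries (`$summary`), draws,
#'   pointwise log-likelihoods (draws x 2*n_steps, x-components then
#'   y-components) for WAIC, and metadata. Use [tidy()] / [glance()].
#' @export
fit_full_model <- function(steps, prior_sd = 0.1, mcmc = mcmc_settings(),
                           seed = 1L, n_min = 50L, sigma_prior_sd = 1,
                           hpdi_prob = 0.99) {
  fit_direction_model(steps, reduced = FALSE, prior_sd, sigma_prior_sd,
                      mcmc, seed, n_min, hpdi_prob)
}

#' Fit the group-only reduced model for one focal
#'
#' As [fit_full_model()] but with only the previous-heading and
#' group-centroid predictors (all individual-specific influences removed).
#' Comparing it to the full model with WAIC asks whether individual
#' identities matter beyond the group as a whole.
#'
#' @inheritParams fit_full_model
#' @return An `influence_fit` with an empty neighbour coefficient set.
#' @export
fit_reduced_model <- function(steps, prior_sd = 0.1, mcmc = mcmc_settings(),
                              seed = 1L, n_min = 50L, sigma_prior_sd = 1,
                              hpdi_prob = 0.99) {
  fit_direction_model(steps, reduced = TRUE, prior_sd, sigma_prior_sd,
                      mcmc, seed, n_min, hpdi_prob)
}

#' Fit direction-matching models for every focal
#'
#' Convenience wrapper: builds steps and fits the full (and optionally the
#' reduced) model for each animal in the table, with per-focal seeds derived
#' from `seed`.
#'
#' @param obs Observation tibble.
#' @param reduced Also fit the group-only model per focal?
#' @param max_gap,min_step Passed to [build_steps()].
#' @param ... Passed to the fitting functions.
#' @param seed Master seed.
#' @param quiet Suppress per-focal progress messages.
#' @return A tibble with one row per focal and list-columns `steps`, `full`
#'   and (optionally) `reduced`; focals with too few steps are dropped with a
#'   message.
#' @export
fit_all_focals <- function(obs, reduced = TRUE, max_gap = NULL, min_step = 5,
                           seed = 1L, quiet = FALSE, ...) {
  ids <- sort(unique(obs$animal_id))
  rows <- purrr::imap(setNames(ids, ids), function(id, nm) {
    st <- build_steps(obs, id, max_gap = max_gap, min_step = min_step)
    full <- tryCatch(
      fit_full_model(st, seed = child_seed(seed, match(id, ids)), ...),
      error = function(e) {
        inform(sprintf("skipping focal '%s': %s", id, conditionMessage(e)))
        NULL
      })
    if (is.null(full)) return(NULL)
    red <- NULL
    if (reduced) {
      red <- fit_reduced_model(st, seed = child_seed(seed, 1000 + match(id, ids)),
                               ...)
    }
    if (!quiet) inform(sprintf("fitted focal '%s' (%d steps)", id, nrow(st)))
    tibble(focal = id, n_steps = nrow(st), steps = list(st),
           full = list(full), reduced = list(red))
  })
  bind_rows(purrr::compact(rows))
}

#' Widely applicable information criterion (deviance scale)
#'
#' Computes WAIC from a matrix of pointwise log-likelihoods:
#' `lppd = sum_i log(mean_d exp(ll[d, i]))`, `p_waic = sum_i var_d(ll[d, i])`,
#' `waic = -2 (lppd - p_waic)` (lower is better), with the conventional
#' standard error `sqrt(n * var_i(pointwise))`.
#'
#' @param pointwise_loglik Draws x observations matrix (>= 2 draws).
#' @return A list with `waic`, `se`, `lppd`, `p_waic` and the `pointwise`
#'   per-observation WAIC contributions.
#' @export
compute_waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 2L || ncol(ll) < 1L) {
    abort("need >= 2 draws and >= 1 observation")
  }
  if (any(!is.finite(ll))) abort("non-finite pointwise log-likelihoods")
  nd <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_i <- apply(ll, 2, var)
  pointwise <- -2 * (lppd_i - p_i)
  n <- ncol(ll)
  list(waic = sum(pointwise), se = sqrt(n * var(pointwise)),
       lppd = sum(lppd_i), p_waic = sum(p_i), pointwise = pointwise)
}

#' Compare the full and group-only models with WAIC
#'
#' `dwaic` is the group-only model's WAIC minus the full model's, on the
#' deviance scale, so a positive value favours the full model (individual
#' identities matter). `dse` is the standard error of the difference from the
#' paired pointwise contributions.
#'
#' @param full,reduced `influence_fit`s for the same focal on the identical
#'   step set.
#' @return A `model_comparison` tibble row: `focal, dwaic, dse, waic_full,
#'   waic_reduced`.
#' @export
compare_models <- function(full, reduced) {
  if (ncol(full$pointwise_loglik) != ncol(reduced$pointwise_loglik)) {
    abort("fits have different observation counts; compare fits on the same steps")
  }
  wf <- compute_waic(full$pointwise_loglik)
  wr <- compute_waic(reduced$pointwise_loglik)
  d <- wr$pointwise - wf$pointwise
  out <- tibble(focal = full$focal,
                dwaic = wr$waic - wf$waic,
                dse = sqrt(length(d) * var(d)),
                waic_full = wf$waic, waic_reduced = wr$waic)
  class(out) <- c("model_comparison", class(out))
  out
}

#' @export
print.influence_fit <- function(x, ...) {
  cat(sprintf("<influence_fit: %s model, focal %s, %d steps, %d draws>\n",
              x$model, x$focal, x$n_steps, nrow(x$beta_draws)))
  print(x$summary, ...)
  invisible(x)
}

#' @rdname fit_full_model
#' @param x An `influence_fit`.
#' @param ... Unused.
#' @export
tidy.influence_fit <- function(x, ...) {
  x$summary |>
    mutate(focal = x$focal, model = x$model, .before = 1) |>
    mutate(excludes_zero = .data$hpdi_low > 0 | .data$hpdi_high < 0)
}

#' @rdname fit_full_model
#' @export
glance.influence_fit <- function(x, ...) {
  w <- compute_waic(x$pointwise_loglik)
  tibble(focal = x$focal, model = x$model, n_steps = x$n_steps,
         n_obs = x$n_obs, waic = w$waic, se_waic = w$se, p_waic = w$p_waic,
         sigma = x$sigma$estimate)
}
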