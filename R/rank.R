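#' Build the dyadic rank dataset
#'
#' One row per ordered dyad (influenced animal `i`, influencing animal `j`)
#' with the fitted influence coefficient `beta_ij` (posterior mean from the
#' full direction-matching model of focal `i`) and the rank difference
#' `drank_ij = ordinal(i) - ordinal(j)` on a single group-wide ordinal
#' ordering (by default males first, then females; see
#' [merged_ordinal_ranks()]). With this convention a positive `drank` means
#' `j` outranks `i`, so a positive rank effect means animals are more
#' influenced by those that outrank them.
#'
#' @param fits Either the tibble from [fit_all_focals()] or a list of
#'   `influence_fit`s from [fit_full_model()].
#' @param ranks Rank tibble covering every animal in `fits`.
#' @param order Sex ordering for the merged scale, top first.
#' @return A tibble `(i, j, beta_ij, drank_ij)`.
#' @export
build_rank_dataset <- function(fits, ranks, order = c("M", "F")) {
  fits <- as_fit_list(fits)
  ord <- merged_ordinal_ranks(ranks, order = order)
  lookup <- setNames(ord$ordinal, ord$animal_id)
  rows <- purrr::map(fits, function(f) {
    nb <- f$neighbours
    if (!length(nb)) return(NULL)
    miss <- setdiff(c(f$focal, nb), names(lookup))
    if (length(miss)) {
      abort(sprintf("animal(s) missing from rank table: %s",
                    paste(miss, collapse = ", ")))
    }
    est <- f$summary |> filter(.data$role == "neighbour")
    tibble(i = f$focal, j = est$term,
           beta_ij = est$estimate,
           drank_ij = as.integer(lookup[f$focal] - lookup[est$term]))
  })
  bind_rows(purrr::compact(rows))
}

as_fit_list <- function(fits) {
  if (is.data.frame(fits) && "full" %in% names(fits)) return(fits$full)
  if (inherits(fits, "influence_fit")) return(list(fits))
  fits
}

#' Fit the rank model for dyadic influence
#'
#' Explains the dyadic influence coefficients by rank difference with a
#' Bayesian varying-intercept model
#' `beta_ij = beta_r * drank_ij + g_i + e`, where `g_i` is the varying
#' intercept of the influenced animal (hierarchical Normal(0, sigma_g)) and
#' the rank effect `beta_r` carries a regularising Normal(0, `prior_sd`)
#' prior. Point estimates of `beta_ij` enter as data; their first-stage
#' uncertainty is not propagated (two-stage procedure).
#'
#' Posterior R-squared follows the variance-partition definition, per draw:
#' `r2_fixed = V_f / (V_f + sigma_g^2 + sigma^2)` and
#' `r2_full = (V_f + sigma_g^2) / (V_f + sigma_g^2 + sigma^2)`, where `V_f`
#' is the variance over dyads of the fixed-effect fitted values; each is
#' summarised by its posterior median, so `r2_full >= r2_fixed` always.
#'
#' @param data Tibble from [build_rank_dataset()] with columns
#'   `i, j, beta_ij, drank_ij`.
#' @param prior_sd Prior sd of the rank effect (default 0.1).
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed.
#' @param hpdi_prob HPDI mass (default 0.99).
#' @return A `rank_model_fit` with the rank-effect summary (`$beta_r`),
#'   per-animal intercept summaries (`$g`), scale summaries, `r2_fixed`,
#'   `r2_full` and draws. Use [tidy()] / [glance()].
#' @export
fit_rank_model <- function(data, prior_sd = 0.1, mcmc = mcmc_settings(),
                           seed = 1L, hpdi_prob = 0.99) {
  stop_if_missing_cols(data, c("i", "j", "beta_ij", "drank_ij"), "rank dataset")
  if (length(unique(data$i)) < 2) {
    abort("need >= 2 distinct influenced animals")
  }
  if (sd(data$beta_ij) < 1e-12) {
    warn("all beta_ij identical; fit proceeds but is degenerate")
  }
  y <- data$beta_ij
  x <- as.double(data$drank_ij)
  grp <- factor(data$i)
  gi <- as.integer(grp)
  n_g <- nlevels(grp)
  n <- length(y)
  draws <- mcmc$draws; warmup <- mcmc$warmup; chains <- mcmc$chains

  run_chain <- function(chain_seed) {
    with_seed(chain_seed, {
      br <- 0; g <- numeric(n_g); sigma <- sd(y) + 1e-6; sigma_g <- sigma
      ng_count <- tabulate(gi, n_g)
      sxx <- sum(x^2)
      BR <- numeric(draws); G <- matrix(NA_real_, draws, n_g)
      SG <- numeric(draws); SR <- numeric(draws)
      total <- warmup + draws
      for (it in seq_len(total)) {
        # beta_r | rest
        r <- y - g[gi]
        prec <- sxx / sigma^2 + 1 / prior_sd^2
        mu <- sum(x * r) / sigma^2 / prec
        br <- rnorm(1, mu, sqrt(1 / prec))
        # g | rest
        r2 <- y - br * x
        sums <- tapply(r2, gi, sum)
        precg <- ng_count / sigma^2 + 1 / sigma_g^2
        mug <- (sums / sigma^2) / precg
        g <- rnorm(n_g, mug, sqrt(1 / precg))
        # sigma | rest (half-Normal(1) prior), slice on log scale
        ssr <- max(sum((y - br * x - g[gi])^2), 1e-20)
        sigma <- exp(slice_sample_1d(function(u) {
          s2 <- exp(2 * u); -n * u - ssr / (2 * s2) - s2 / 2 + u
        }, log(sigma)))
        # sigma_g | g (half-Normal(1) prior)
        ssg <- max(sum(g^2), 1e-20)
        sigma_g <- exp(slice_sample_1d(function(u) {
          s2 <- exp(2 * u); -n_g * u - ssg / (2 * s2) - s2 / 2 + u
        }, log(sigma_g)))
        if (it > warmup) {
          BR[it - warmup] <- br
          G[it - warmup, ] <- g
          SG[it - warmup] <- sigma_g
          SR[it - warmup] <- sigma
        }
      }
      list(BR = BR, G = G, SG = SG, SR = SR)
    })
  }

  res <- lapply(seq_len(chains), function(ch) run_chain(child_seed(seed, ch)))
  BR <- unlist(lapply(res, `[[`, "BR"))
  G <- do.call(rbind, lapply(res, `[[`, "G"))
  SG <- unlist(lapply(res, `[[`, "SG"))
  SR <- unlist(lapply(res, `[[`, "SR"))
  colnames(G) <- levels(grp)

  vf <- BR^2 * var(x)                    # draw-wise variance of fixed fitted
  r2_fixed_d <- vf / (vf + SG^2 + SR^2)
  r2_full_d <- (vf + SG^2) / (vf + SG^2 + SR^2)

  br_int <- hpdi(BR, prob = hpdi_prob)
  g_int <- t(apply(G, 2, hpdi, prob = hpdi_prob))
  structure(list(
    beta_r = tibble(estimate = mean(BR), hpdi_low = br_int[1],
                    hpdi_high = br_int[2]),
    g = tibble(animal_id = colnames(G), estimate = colMeans(G),
               hpdi_low = g_int[, 1], hpdi_high = g_int[, 2]),
    sigma_g = tibble(estimate = mean(SG), median = median(SG)),
    sigma_resid = tibble(estimate = mean(SR), median = median(SR)),
    r2_fixed = median(r2_fixed_d),
    r2_full = median(r2_full_d),
    draws = list(beta_r = BR, g = G, sigma_g = SG, sigma_resid = SR,
                 r2_fixed = r2_fixed_d, r2_full = r2_full_d),
    n_dyads = n, hpdi_prob = hpdi_prob, prior_sd = prior_sd,
    mcmc = mcmc, seed = seed
  ), class = "rank_model_fit")
}

#' Simulate a dyadic rank dataset from the rank model
#'
#' Generates `beta_ij` values directly under the dyadic model for a roster of
#' `n` animals: all ordered pairs, `beta_ij = beta_r * drank_ij + g_i + e`.
#' Used for parameter-recovery checks of [fit_rank_model()].
#'
#' @param n Number of animals (182 dyads for `n = 14`).
#' @param beta_r Planted rank effect per ordinal-rank unit.
#' @param g_sd SD of the per-animal intercepts.
#' @param resid_sd Residual SD.
#' @param seed Integer seed.
#' @return A tibble `(i, j, beta_ij, drank_ij)`.
#' @export
simulate_rank_dataset <- function(n = 14, beta_r = 0.007, g_sd = 0.01,
                                  resid_sd = 0.02, seed = 1L) {
  ids <- sprintf("X%02d", seq_len(n))
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, ]
  with_seed(seed, {
    g <- rnorm(n, 0, g_sd)
    dr <- pairs$i - pairs$j
    tibble(i = ids[pairs$i], j = ids[pairs$j],
           beta_ij = beta_r * dr + g[pairs$i] + rnorm(nrow(pairs), 0, resid_sd),
           drank_ij = as.integer(dr))
  })
}

#' @export
print.rank_model_fit <- function(x, ...) {
  cat(sprintf("<rank_model_fit: %d dyads, %d animals>\n",
              x$n_dyads, nrow(x$g)))
  cat(sprintf("  rank effect: %.4g  [%.4g, %.4g] (%.0f%% HPDI)\n",
              x$beta_r$estimate, x$beta_r$hpdi_low, x$beta_r$hpdi_high,
              100 * x$hpdi_prob))
  cat(sprintf("  R2 (rank only): %.3f   R2 (rank + intercepts): %.3f\n",
              x$r2_fixed, x$r2_full))
  invisible(x)
}

#' @rdname fit_rank_model
#' @param x A `rank_model_fit`.
#' @param ... Unused.
#' @export
tidy.rank_model_fit <- function(x, ...) {
  bind_rows(
    x$beta_r |> mutate(term = "beta_r", .before = 1),
    x$g |> rename(term = "animal_id")
  )
}

#' @rdname fit_rank_model
#' @export
glance.rank_model_fit <- function(x, ...) {
  tibble(n_dyads = x$n_dyads, r2_fixed = x$r2_fixed, r2_full = x$r2_full,
         sigma_g = x$sigma_g$estimate, sigma_resid = x$sigma_resid$estimate)
}
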