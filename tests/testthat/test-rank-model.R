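test_that("the dyad table has n(n-1) rows and antisymmetric rank differences", {
  mk_stub <- function(ids) {
    lapply(ids, function(f) {
      nb <- setdiff(ids, f)
      stub_fit(f, nb, estimate = rep(0.05, length(nb)),
               hpdi_low = rep(0.01, length(nb)),
               hpdi_high = rep(0.09, length(nb)))
    })
  }
  rk3 <- tibble::tibble(animal_id = c("F1", "F2", "F3"), sex = "F", rank = 1:3)
  d3 <- build_rank_dataset(mk_stub(c("F1", "F2", "F3")), rk3)
  expect_equal(nrow(d3), 6)

  rk14 <- synthetic_roster()
  d14 <- build_rank_dataset(mk_stub(rk14$animal_id), rk14)
  expect_equal(nrow(d14), 182)

  key <- paste(d14$i, d14$j)
  rev <- match(paste(d14$j, d14$i), key)
  expect_equal(d14$drank_ij, -d14$drank_ij[rev])

  expect_error(build_rank_dataset(mk_stub(c("F1", "F2", "XX")), rk3),
               "missing from rank table")
})

test_that("the rank model recovers a planted effect and a planted null", {
  d <- simulate_rank_dataset(14, beta_r = 0.007, seed = 101)
  fit <- fit_rank_model(d, mcmc = quick_mcmc, seed = 5)
  expect_gt(fit$beta_r$hpdi_high, 0.007)
  expect_lt(fit$beta_r$hpdi_low, 0.007)
  expect_gte(fit$r2_full, fit$r2_fixed)
  expect_true(fit$r2_fixed >= 0 && fit$r2_full <= 1)

  d0 <- simulate_rank_dataset(14, beta_r = 0, seed = 103)
  fit0 <- fit_rank_model(d0, mcmc = quick_mcmc, seed = 5)
  expect_true(fit0$beta_r$hpdi_low < 0 && fit0$beta_r$hpdi_high > 0)
})

test_that("explained variance rises with the planted rank effect", {
  med_r2 <- vapply(c(0, 0.004, 0.008), function(b) {
    r2 <- vapply(1:20, function(r) {
      d <- simulate_rank_dataset(14, beta_r = b, seed = 1000 * b * 1000 + r)
      fit_rank_model(d, mcmc = tiny_mcmc, seed = r)$r2_fixed
    }, numeric(1))
    median(r2)
  }, numeric(1))
  expect_true(all(diff(med_r2) > 0))
})

test_that("rank-structured group movement yields a positive recovered rank effect", {
  cfg <- rank_structured_config(6, slope = 0.08, duration = 100, seed = 41)
  sim <- simulate_group(cfg)
  obs <- degrade_observations(sim$trajectories,
                              observer_schedule(cfg$agent_ids, dwell = 80),
                              seed = 42)
  fits <- fit_all_focals(obs, reduced = FALSE, seed = 43, quiet = TRUE,
                         mcmc = tiny_mcmc)
  ranks <- tibble::tibble(animal_id = cfg$agent_ids, sex = "F", rank = 1:6)
  dyads <- build_rank_dataset(fits, ranks)
  expect_equal(nrow(dyads), 30)
  fit <- fit_rank_model(dyads, mcmc = quick_mcmc, seed = 44)
  # lower-ranked animals were built to follow higher-ranked ones
  expect_gt(fit$beta_r$estimate, 0)
  expect_gt(mean(fit$draws$beta_r > 0), 0.75)
})

test_that("degenerate dyad data warn but still fit", {
  d <- simulate_rank_dataset(5, beta_r = 0, g_sd = 0, resid_sd = 0.02, seed = 7)
  d$beta_ij <- 0.05
  expect_warning(fit <- fit_rank_model(d, mcmc = tiny_mcmc, seed = 2),
                 "identical")
  expect_s3_class(fit, "rank_model_fit")
})
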