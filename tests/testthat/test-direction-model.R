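test_that("step construction counts candidate steps and enforces filters", {
  # 3 focal fixes in a line -> 1 usable step (the first lacks a previous one)
  st <- build_steps(tiny_obs(3), "A", min_step = 5)
  expect_equal(nrow(st), 1)
  # 2 fixes -> no step at all
  expect_equal(nrow(build_steps(tiny_obs(2), "A", min_step = 5)), 0)
  # displacement below min_step -> dropped
  expect_equal(nrow(build_steps(tiny_obs(3, step = 2), "A", min_step = 5)), 0)
  expect_error(build_steps(tiny_obs(3), "Z"), "no observations")
})

test_that("every stored step vector is unit norm and v_cm matches its definition", {
  rep <- scenario_replicate("chain", 4, hours = 6, seed = 11, fit = FALSE)
  st <- build_steps(rep$obs, "A02")
  expect_gt(nrow(st), 10)
  for (pair in list(c("obs_x", "obs_y"), c("prev_x", "prev_y"),
                    c("cm_x", "cm_y"))) {
    norms <- sqrt(st[[pair[1]]]^2 + st[[pair[2]]]^2)
    expect_equal(norms, rep(1, nrow(st)), tolerance = 1e-9)
  }
  for (nb in attr(st, "neighbours")) {
    norms <- sqrt(st[[paste0("to_x.", nb)]]^2 + st[[paste0("to_y.", nb)]]^2)
    expect_equal(norms, rep(1, nrow(st)), tolerance = 1e-9)
  }
})

test_that("with noiseless following, the observed direction equals the direction to the target", {
  W <- matrix(0, 3, 3); W[2, 1] <- 1  # A02 follows A01; A03 independent
  cfg <- sim_config(3, duration = 1, tick = 30, speed = 10,
                    true_influence = W, w_cm = 0, w_persist = 0,
                    heading_noise_sd = 0, start_spread = 150, seed = 13)
  traj <- simulate_group(cfg)$trajectories
  st <- build_steps(validate_observations(traj), "A02", min_step = 1)
  expect_gt(nrow(st), 5)
  # v_obs was computed from the tick AFTER the step start; the simulator used
  # positions AT the step start, which build_steps sees as to_x/to_y.A01
  expect_equal(st$obs_x, st$to_x.A01, tolerance = 1e-6)
  expect_equal(st$obs_y, st$to_y.A01, tolerance = 1e-6)
})

test_that("the Gibbs posterior matches a grid-quadrature oracle and rjags", {
  set.seed(42)
  n <- 40
  x <- rnorm(n)
  y <- 0.15 * x + rnorm(n, 0, 0.5)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "b"))

  # independent oracle 1: dense 2-D quadrature over (b, sigma)
  bg <- seq(-0.6, 0.9, length.out = 401)
  sg <- seq(0.02, 2.5, length.out = 400)
  lp <- outer(bg, sg, Vectorize(function(b, s) {
    sum(dnorm(y, b * x, s, log = TRUE)) + dnorm(b, 0, 0.1, log = TRUE) +
      dnorm(s, 0, 1, log = TRUE)
  }))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  oracle_mean <- sum(rowSums(w) * bg)
  oracle_sd <- sqrt(sum(rowSums(w) * bg^2) - oracle_mean^2)

  post <- dirmatch:::gibbs_lm(X, y, prior_sd = 0.1, draws = 2000,
                              warmup = 500, chains = 2, seed = 7)
  expect_equal(mean(post$beta[, 1]), oracle_mean, tolerance = 0.02)
  expect_equal(sd(post$beta[, 1]), oracle_sd, tolerance = 0.02)

  # independent oracle 2: the same model in JAGS
  model <- "model {
    for (i in 1:n) { y[i] ~ dnorm(b * x[i], tau) }
    b ~ dnorm(0, 100)          # sd 0.1
    sigma ~ dnorm(0, 1) T(0,)
    tau <- 1 / (sigma * sigma)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = y, x = x, n = n),
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 11),
                          n.chains = 1, quiet = TRUE)
  stats::update(jm, 1000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("b", "sigma"), 4000,
                              progress.bar = "none")[[1]]
  expect_equal(mean(post$beta[, 1]), unname(colMeans(samp)["b"]),
               tolerance = 0.02)
  expect_equal(mean(post$sigma), unname(colMeans(samp)["sigma"]),
               tolerance = 0.03)
})

test_that("fits are deterministic given a seed and honour the n_min contract", {
  rep <- scenario_replicate("chain", 4, hours = 15, seed = 17, fit = FALSE)
  st <- build_steps(rep$obs, "A02")
  f1 <- fit_full_model(st, mcmc = tiny_mcmc, seed = 5)
  f2 <- fit_full_model(st, mcmc = tiny_mcmc, seed = 5)
  expect_identical(f1$summary, f2$summary)
  expect_error(fit_full_model(st[1:10, ], mcmc = tiny_mcmc, seed = 5),
               "at least 50")
  red <- fit_reduced_model(st, mcmc = tiny_mcmc, seed = 5)
  expect_equal(nrow(red$summary), 2)  # cm + prev only
  expect_equal(red$neighbours, character(0))
})

test_that("regularised priors shrink coefficients fitted to pure noise", {
  rep <- scenario_replicate("chain", 4, hours = 15, seed = 19, fit = FALSE)
  st <- build_steps(rep$obs, "A03")
  noise <- withr::with_seed(3, {
    ang <- runif(nrow(st), 0, 2 * pi)
    cbind(cos(ang), sin(ang))
  })
  st$obs_x <- noise[, 1]
  st$obs_y <- noise[, 2]
  fit <- fit_full_model(st, prior_sd = 0.1, mcmc = quick_mcmc, seed = 23)
  expect_true(all(abs(fit$summary$estimate) < 0.1))
})

test_that("a focal travelling on a fixed bearing loads on the persistence term", {
  cfg <- sim_config(4, duration = 10, tick = 30, speed = 10, w_cm = 0,
                    w_persist = 1, heading_noise_sd = 0.05,
                    start_spread = 80, seed = 29)
  sim <- simulate_group(cfg)
  obs <- degrade_observations(sim$trajectories,
                              observer_schedule(cfg$agent_ids, dwell = 120),
                              seed = 30)
  fit <- fit_full_model(build_steps(obs, "A01"), mcmc = quick_mcmc, seed = 31)
  prev <- fit$summary[fit$summary$term == "prev", ]
  expect_gt(prev$hpdi_low, 0)
  expect_equal(unname(which.max(abs(fit$summary$estimate))),
               which(fit$summary$term == "prev"))
})

test_that("WAIC follows its defining formulas", {
  # zero posterior variance: p_waic = 0, waic = -2 * sum(loglik)
  ll <- matrix(rep(c(-1.2, -0.7), each = 3), nrow = 3)
  w <- compute_waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * (-1.2 - 0.7))
  # duplicating every observation column doubles waic
  ll2 <- matrix(rnorm(12, -1, 0.3), nrow = 3)
  expect_equal(compute_waic(cbind(ll2, ll2))$waic, 2 * compute_waic(ll2)$waic)
  expect_error(compute_waic(matrix(c(1, NaN), 2, 1)), "non-finite")
  expect_error(compute_waic(matrix(1, 1, 3)), ">= 2 draws")
})

test_that("model self-comparison gives exactly zero and mismatches error", {
  rep <- scenario_replicate("chain", 4, hours = 15, seed = 37, fit = FALSE)
  st <- build_steps(rep$obs, "A02")
  full <- fit_full_model(st, mcmc = tiny_mcmc, seed = 5)
  cmp <- compare_models(full, full)
  expect_equal(cmp$dwaic, 0)
  expect_equal(cmp$dse, 0)
  red <- fit_reduced_model(st[1:60, ], mcmc = tiny_mcmc, seed = 5)
  expect_error(compare_models(full, red), "different observation counts")
})
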