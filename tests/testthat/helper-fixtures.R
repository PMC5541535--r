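# Shared fixtures, all generated in code.

quick_mcmc <- mcmc_settings(draws = 400L, warmup = 400L, chains = 2L)
tiny_mcmc <- mcmc_settings(draws = 300L, warmup = 300L, chains = 1L)

# A minimal observation table: focal "A" with fixes on a line, neighbour "B"
# interpolatable at every focal fix time.
tiny_obs <- function(n_focal_fixes = 3, dt = 60, step = 10) {
  t_a <- seq_len(n_focal_fixes) * dt
  t_b <- c(0, max(t_a) + dt)
  validate_observations(tibble::tibble(
    animal_id = c(rep("A", n_focal_fixes), rep("B", 2)),
    t = c(t_a, t_b),
    x = c(seq_len(n_focal_fixes) * step, 100, 100),
    y = c(rep(0, n_focal_fixes), 50, 50),
    day_id = 0
  ))
}

# Stub influence_fit with prescribed neighbour summaries (for network tests).
stub_fit <- function(focal, neighbours, estimate, hpdi_low, hpdi_high) {
  structure(list(
    focal = focal,
    model = "full",
    neighbours = neighbours,
    summary = tibble::tibble(
      term = c(neighbours, "cm", "prev"),
      role = c(rep("neighbour", length(neighbours)), "cm", "prev"),
      estimate = c(estimate, 0, 0.2),
      hpdi_low = c(hpdi_low, -0.1, 0.1),
      hpdi_high = c(hpdi_high, 0.1, 0.3)
    ),
    n_steps = 100L, n_obs = 200L, hpdi_prob = 0.99
  ), class = "influence_fit")
}

# Influence network with explicit edges.
net_from_edges <- function(nodes, source, target, weight) {
  dirmatch:::new_influence_network(nodes, tibble::tibble(
    source = source, target = target, weight = weight,
    sign = ifelse(weight > 0, 1L, -1L)))
}

# Field-like sparse core/periphery network: densely and strongly connected
# core, sparse weak periphery, a couple of isolated nodes.
field_like_cp_network <- function(n = 13, core = 6, seed = 1) {
  ids <- sprintf("N%02d", seq_len(n))
  withr::with_seed(seed, {
    ed <- list()
    for (i in seq_len(core)) for (j in seq_len(core)) {
      if (i != j && runif(1) < 0.8) {
        ed[[length(ed) + 1]] <- tibble::tibble(
          source = ids[i], target = ids[j], weight = runif(1, 0.06, 0.12))
      }
    }
    for (i in (core + 1):(n - 2)) {
      for (k in sample(core, sample(1:2, 1))) {
        ed[[length(ed) + 1]] <- tibble::tibble(
          source = ids[k], target = ids[i], weight = runif(1, 0.01, 0.03))
      }
    }
    ed <- dplyr::bind_rows(ed)
    ed$sign <- 1L
    dirmatch:::new_influence_network(ids, ed)
  })
}

# One simulated-and-degraded scenario replicate, fitted for all focals.
scenario_replicate <- function(scenario, n_agents, hours, seed,
                               reduced = FALSE, mcmc = quick_mcmc,
                               w_cm = 0.2, fit = TRUE) {
  cfg <- if (scenario == "null") {
    sim_config(n_agents, duration = hours, w_cm = 0, seed = seed)
  } else {
    make_scenario(scenario, n_agents, seed = seed, duration = hours,
                  w_cm = w_cm)
  }
  sim <- simulate_group(cfg)
  obs <- degrade_observations(
    sim$trajectories,
    observer_schedule(cfg$agent_ids, dwell = 480 / n_agents),
    seed = seed + 1)
  fits <- if (fit) {
    fit_all_focals(obs, reduced = reduced, seed = seed + 2,
                   quiet = TRUE, mcmc = mcmc)
  }
  list(cfg = cfg, truth = sim$truth, obs = obs, fits = fits)
}
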