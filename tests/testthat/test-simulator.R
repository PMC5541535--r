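test_that("a pure follower heads straight at its target every tick", {
  W <- matrix(0, 2, 2); W[2, 1] <- 1
  cfg <- sim_config(2, duration = 0.5, tick = 30, speed = 5,
                    true_influence = W, w_cm = 0, w_persist = 0,
                    heading_noise_sd = 0, start_spread = 100, seed = 7)
  traj <- simulate_group(cfg)$trajectories
  a <- traj[traj$animal_id == "A01", ]
  b <- traj[traj$animal_id == "A02", ]
  for (k in 2:nrow(b)) {
    move <- c(b$x[k] - b$x[k - 1], b$y[k] - b$y[k - 1])
    to_a <- c(a$x[k - 1] - b$x[k - 1], a$y[k - 1] - b$y[k - 1])
    expect_equal(move / sqrt(sum(move^2)), to_a / sqrt(sum(to_a^2)),
                 tolerance = 1e-9)
  }
})

test_that("simulation is deterministic given the seed and counts records", {
  cfg <- make_scenario("diffuse", 6, seed = 3, duration = 2, tick = 30)
  s1 <- simulate_group(cfg)
  s2 <- simulate_group(cfg)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_equal(nrow(s1$trajectories), 6 * 2 * 3600 / 30)
})

test_that("agents move exactly `speed` metres per tick (unit-norm headings)", {
  cfg <- sim_config(3, duration = 0.5, speed = 8, seed = 2)
  traj <- simulate_group(cfg)$trajectories
  for (id in unique(traj$animal_id)) {
    p <- traj[traj$animal_id == id, ]
    d <- sqrt(diff(p$x)^2 + diff(p$y)^2)
    expect_equal(d, rep(8, length(d)), tolerance = 1e-9)
  }
})

test_that("group attraction alone keeps the group from spreading", {
  diam <- function(tr, at) {
    p <- tr[tr$t == at, ]
    max(dist(cbind(p$x, p$y)))
  }
  shrunk <- logical(100)
  for (r in 1:100) {
    cfg <- sim_config(5, duration = 50 * 30 / 3600, tick = 30, speed = 5,
                      w_cm = 1, w_persist = 0, heading_noise_sd = 0.3,
                      start_spread = 200, seed = r)
    tr <- simulate_group(cfg)$trajectories
    shrunk[r] <- diam(tr, max(tr$t)) <= diam(tr, min(tr$t))
  }
  expect_gt(mean(shrunk), 0.9)
})

test_that("scenario constructors plant the documented structures", {
  W <- make_scenario("leader", 5, seed = 1)$true_influence
  expect_equal(sum(W != 0), 4)
  expect_true(all(which(W != 0, arr.ind = TRUE)[, 2] == 1))

  W <- make_scenario("diffuse", 4, seed = 1)$true_influence
  off <- W[row(W) != col(W)]
  expect_equal(length(off), 12)
  expect_equal(length(unique(off)), 1)

  cfg <- make_scenario("chain", 3, seed = 1)
  expect_equal(which(cfg$true_influence != 0, arr.ind = TRUE,
                     useNames = FALSE),
               cbind(c(2, 3), c(1, 2)))

  cp <- make_scenario("core_periphery", 9, seed = 1)
  expect_equal(cp$planted_core, sprintf("A%02d", 1:3))
  expect_error(make_scenario("anarchy", 5), "unknown scenario")
})

test_that("observer degradation matches the field revisit regime", {
  cfg <- sim_config(14, duration = 6, tick = 30, seed = 5)
  sim <- simulate_group(cfg)
  sched <- observer_schedule(cfg$agent_ids, dwell = 540 / 14)
  obs <- degrade_observations(sim$trajectories, sched, seed = 6)
  revisit <- obs |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(mu = mean(diff(t))) |>
    dplyr::pull(mu)
  expect_equal(mean(revisit), 540, tolerance = 0.05)
})

test_that("noiseless degradation is an exact subsample of the trajectory", {
  cfg <- sim_config(4, duration = 2, seed = 8)
  sim <- simulate_group(cfg)
  sched <- observer_schedule(cfg$agent_ids, dwell = 120, jitter_sd = 0,
                             gps_noise_sd = 0)
  obs <- degrade_observations(sim$trajectories, sched, seed = 9)
  key <- paste(sim$trajectories$animal_id, sim$trajectories$t,
               sim$trajectories$x, sim$trajectories$y)
  expect_true(all(paste(obs$animal_id, obs$t, obs$x, obs$y) %in% key))
  # ~ duration / (n_agents * dwell) fixes per animal
  expect_equal(unname(table(obs$animal_id))[1], 2 * 3600 / (4 * 120),
               tolerance = 0.1)
  expect_error(degrade_observations(sim$trajectories,
                                    observer_schedule(cfg$agent_ids, dwell = 10),
                                    seed = 1),
               "dwell shorter")
})
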