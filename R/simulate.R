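#' Simulation configuration
#'
#' Bundles the parameters of the attraction--repulsion group-movement
#' simulator. Per tick, agent `i`'s new heading is the normalisation of
#'
#' `w_persist * h_prev + sum_j W[i, j] * u(i -> j) + w_cm * u(i -> centroid_-i)`
#'
#' rotated by Gaussian angular noise; the agent then advances `speed` metres
#' along the new heading. `W[i, j]` is the signed influence of `j`'s position
#' on `i`'s heading (positive = attraction, negative = repulsion); `diag(W)`
#' must be zero. This is the generative counterpart of the direction-matching
#' regression the package fits, so planted `W` entries are recoverable as
#' fitted coefficients.
#'
#' @param n_agents Number of agents (>= 2).
#' @param duration Simulated time, hours.
#' @param tick Simulation step, seconds.
#' @param speed Distance travelled per tick, metres (scalar or per agent).
#' @param true_influence `n_agents x n_agents` signed weight matrix `W`
#'   (zero diagonal). Default all zero.
#' @param w_cm Group-attraction weight (scalar or per agent).
#' @param w_persist Directional-persistence weight (scalar or per agent).
#' @param heading_noise_sd SD of the per-tick heading rotation, radians.
#' @param arena `NULL` (unbounded) or the side length (m) of a reflecting
#'   square centred on the origin.
#' @param day_hours Length of an observation day; records are grouped into
#'   independent days of this length and no downstream step crosses one.
#' @param agent_ids Optional character ids; default `"A01", "A02", ...`.
#' @param start_spread Side (m) of the square over which initial positions are
#'   scattered.
#' @param seed Integer seed making the run deterministic.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_agents,
                       duration = 100,
                       tick = 30,
                       speed = 10,
                       true_influence = NULL,
                       w_cm = 0.2,
                       w_persist = 0.5,
                       heading_noise_sd = 0.3,
                       arena = NULL,
                       day_hours = 12,
                       agent_ids = NULL,
                       start_spread = 40,
                       seed = 1L) {
  if (n_agents < 2) abort("n_agents must be >= 2")
  if (tick <= 0 || any(speed <= 0)) abort("tick and speed must be positive")
  if (is.null(true_influence)) {
    true_influence <- matrix(0, n_agents, n_agents)
  }
  W <- as.matrix(true_influence)
  if (!all(dim(W) == n_agents)) abort("true_influence must be n_agents x n_agents")
  if (any(!is.finite(W))) abort("true_influence must be finite")
  if (any(diag(W) != 0)) abort("diag(true_influence) must be zero")
  if (is.null(agent_ids)) {
    agent_ids <- sprintf("A%02d", seq_len(n_agents))
  }
  dimnames(W) <- list(agent_ids, agent_ids)
  structure(list(
    n_agents = as.integer(n_agents), duration = duration, tick = tick,
    speed = rep_len(speed, n_agents), true_influence = W,
    w_cm = rep_len(w_cm, n_agents), w_persist = rep_len(w_persist, n_agents),
    heading_noise_sd = heading_noise_sd, arena = arena,
    day_hours = day_hours, agent_ids = agent_ids,
    start_spread = start_spread, seed = seed,
    scenario = "custom", planted_core = character(0)
  ), class = "sim_config")
}

#' Canned influence scenarios
#'
#' Builds a [sim_config()] with a planted influence structure:
#' * `leader` -- every agent is attracted to one leader (despotic model);
#' * `core_periphery` -- a core of `ceiling(n/3)` mutually attracting agents,
#'   with the periphery attracted to core members;
#' * `diffuse` -- all pairwise weights equal (homogeneous influence);
#' * `chain` -- agent `k` follows agent `k - 1` only (used to study the
#'   downstream-influence artefact: the method sees the chain head influencing
#'   the tail even though the link is indirect).
#'
#' @param name One of `"leader"`, `"core_periphery"`, `"diffuse"`, `"chain"`.
#' @param n_agents Number of agents (>= 3).
#' @param seed Seed stored in the config.
#' @param influence Total planted attraction weight per following agent;
#'   split evenly over that agent's targets.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config` whose `planted_core` records the scenario's core
#'   (the leader for `leader`, the mutual core for `core_periphery`, empty
#'   otherwise) and whose `true_influence` is the planted `W`.
#' @export
make_scenario <- function(name, n_agents, seed = 1L, influence = 1, ...) {
  if (n_agents < 3) abort("scenarios require n_agents >= 3")
  name <- tryCatch(
    match.arg(name, c("leader", "core_periphery", "diffuse", "chain")),
    error = function(e) abort(sprintf("unknown scenario '%s'", name[1])))
  ids <- sprintf("A%02d", seq_len(n_agents))
  W <- matrix(0, n_agents, n_agents, dimnames = list(ids, ids))
  core <- character(0)
  if (name == "leader") {
    W[-1, 1] <- influence
    core <- ids[1]
  } else if (name == "core_periphery") {
    k <- ceiling(n_agents / 3)
    core_idx <- seq_len(k)
    for (i in core_idx) {
      tgt <- setdiff(core_idx, i)
      W[i, tgt] <- influence / length(tgt)
    }
    for (i in setdiff(seq_len(n_agents), core_idx)) {
      W[i, core_idx] <- influence / k
    }
    core <- ids[core_idx]
  } else if (name == "diffuse") {
    W[] <- influence / (n_agents - 1)
    diag(W) <- 0
  } else { # chain
    for (k in 2:n_agents) W[k, k - 1] <- influence
  }
  cfg <- sim_config(n_agents, true_influence = W, agent_ids = ids,
                    seed = seed, ...)
  cfg$scenario <- name
  cfg$planted_core <- core
  cfg
}

#' Rank-structured influence configuration
#'
#' Plants attraction weights that grow with the rank gap: agent `i` is
#' attracted to every agent that outranks it, with weight proportional to the
#' ordinal-rank difference. Recovering a positive rank effect from data
#' simulated under this config validates the sign convention of the dyadic
#' rank model.
#'
#' @param n_agents Number of agents; agent `k` holds ordinal rank `k`
#'   (1 = highest).
#' @param slope Weight per unit rank difference.
#' @param seed,... Passed to [sim_config()].
#' @return A `sim_config`.
#' @export
rank_structured_config <- function(n_agents, slope = 0.08, seed = 1L, ...) {
  ids <- sprintf("A%02d", seq_len(n_agents))
  ord <- seq_len(n_agents)
  W <- outer(ord, ord, function(i, j) pmax(i - j, 0) * slope)
  diag(W) <- 0
  cfg <- sim_config(n_agents, true_influence = W, agent_ids = ids,
                    seed = seed, ...)
  cfg$scenario <- "rank_structured"
  cfg
}

#' Simulate group movement
#'
#' Runs the attraction--repulsion agent-based model described in
#' [sim_config()]. Deterministic given `config$seed`. Headings are unit
#' vectors at every tick; when the weighted resultant is numerically zero the
#' agent keeps its previous heading (counted in `truth$n_heading_fallbacks`).
#'
#' @param config A [sim_config()].
#' @return A list with `trajectories` (observation tibble at full tick
#'   resolution: `animal_id, t, x, y, day_id`) and `truth` (the config, the
#'   boolean `direct_follow` matrix `W != 0`, the `planted_core`, and the
#'   heading-fallback count).
#' @export
simulate_group <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  n <- config$n_agents
  n_t <- as.integer(round(config$duration * 3600 / config$tick))
  if (n_t < 1) abort("duration must cover at least one tick")
  W <- config$true_influence
  wp <- config$w_persist
  wc <- config$w_cm
  spd <- config$speed
  nsd <- config$heading_noise_sd
  day_sec <- config$day_hours * 3600

  out <- with_seed(config$seed, {
    fallbacks <- 0L
    pos <- cbind(runif(n, -config$start_spread / 2, config$start_spread / 2),
                 runif(n, -config$start_spread / 2, config$start_spread / 2))
    ang0 <- runif(n, 0, 2 * pi)
    hd <- cbind(cos(ang0), sin(ang0))
    X <- matrix(NA_real_, n_t, n)
    Y <- matrix(NA_real_, n_t, n)
    noise <- matrix(rnorm(n_t * n, 0, nsd), n_t, n)
    for (k in seq_len(n_t)) {
      dx <- outer(pos[, 1], pos[, 1], FUN = function(a, b) b - a)
      dy <- outer(pos[, 2], pos[, 2], FUN = function(a, b) b - a)
      dist <- sqrt(dx^2 + dy^2)
      ok <- dist >= 1e-9
      ux <- ifelse(ok, dx / dist, 0)
      uy <- ifelse(ok, dy / dist, 0)
      infl_x <- rowSums(W * ux)
      infl_y <- rowSums(W * uy)
      # centroid of the OTHER agents
      cx <- (sum(pos[, 1]) - pos[, 1]) / (n - 1)
      cy <- (sum(pos[, 2]) - pos[, 2]) / (n - 1)
      cmv <- unit_vec_xy(cx - pos[, 1], cy - pos[, 2], eps = 1e-9)
      cm_x <- ifelse(is.na(cmv$ux), 0, cmv$ux)
      cm_y <- ifelse(is.na(cmv$uy), 0, cmv$uy)
      rx <- wp * hd[, 1] + infl_x + wc * cm_x
      ry <- wp * hd[, 2] + infl_y + wc * cm_y
      rlen <- sqrt(rx^2 + ry^2)
      degen <- rlen < 1e-12
      if (any(degen)) {
        fallbacks <- fallbacks + sum(degen)
        rx[degen] <- hd[degen, 1]
        ry[degen] <- hd[degen, 2]
        rlen[degen] <- 1
      }
      rx <- rx / rlen
      ry <- ry / rlen
      ca <- cos(noise[k, ]); sa <- sin(noise[k, ])
      hd <- cbind(ca * rx - sa * ry, sa * rx + ca * ry)
      pos <- pos + spd * hd
      if (!is.null(config$arena)) {
        half <- config$arena / 2
        for (d in 1:2) {
          over <- pos[, d] > half
          pos[over, d] <- 2 * half - pos[over, d]
          hd[over, d] <- -hd[over, d]
          under <- pos[, d] < -half
          pos[under, d] <- -2 * half - pos[under, d]
          hd[under, d] <- -hd[under, d]
        }
      }
      X[k, ] <- pos[, 1]
      Y[k, ] <- pos[, 2]
    }
    list(X = X, Y = Y, fallbacks = fallbacks)
  })

  t_grid <- config$tick * seq_len(n_t)
  traj <- tibble(
    animal_id = rep(config$agent_ids, each = n_t),
    t = rep(t_grid, n),
    x = as.vector(out$X),
    y = as.vector(out$Y),
    day_id = rep(floor((t_grid - config$tick) / day_sec), n)
  )
  truth <- list(config = config,
                direct_follow = config$true_influence != 0,
                planted_core = config$planted_core,
                n_heading_fallbacks = out$fallbacks)
  list(trajectories = traj, truth = truth)
}

#' Observer sweep schedule
#'
#' Describes the single-observer sampling regime: the observer cycles through
#' the group in a fixed order, spending `dwell` seconds between successive
#' fixes, so each animal's mean revisit time is `n_agents * dwell` seconds.
#' Visit times get Gaussian jitter and fixes get isotropic Gaussian GPS noise.
#' The field regime this emulates is a ~9-min mean revisit with ~5 m GPS
#' error; `dwell = 540 / n_agents` reproduces it.
#'
#' @param order Character vector: the cyclic visiting order (agent ids).
#' @param dwell Seconds between successive fixes on the sweep.
#' @param jitter_sd SD of the visit-time jitter, seconds.
#' @param gps_noise_sd SD of the per-coordinate position noise, metres.
#' @return An `observer_schedule` object.
#' @export
observer_schedule <- function(order, dwell, jitter_sd = 10, gps_noise_sd = 5) {
  if (dwell <= 0) abort("dwell must be positive")
  structure(list(order = as.character(order), dwell = dwell,
                 jitter_sd = jitter_sd, gps_noise_sd = gps_noise_sd),
            class = "observer_schedule")
}

#' Degrade full-resolution trajectories to the observer sampling regime
#'
#' Subsamples tick-resolution trajectories to one fix per animal per observer
#' sweep: visit `k` (at nominal time `k * dwell`, jittered) lands on agent
#' `order[(k - 1) %% n + 1]`, is snapped to the nearest simulated tick, and
#' the position there is perturbed by GPS noise. With zero jitter and zero GPS
#' noise the output is an exact subsample of the input. The result satisfies
#' the observation-table contract (sorted, strictly increasing within animal).
#'
#' @param trajectories Tick-resolution observation tibble from
#'   [simulate_group()].
#' @param schedule An [observer_schedule()].
#' @param seed Integer seed for jitter and GPS noise.
#' @return A degraded observation tibble.
#' @export
degrade_observations <- function(trajectories, schedule, seed = 1L) {
  if (!inherits(schedule, "observer_schedule")) {
    abort("`schedule` must be an observer_schedule")
  }
  ids <- unique(trajectories$animal_id)
  if (!setequal(schedule$order, ids)) {
    abort("schedule order must be a permutation of the trajectory animal ids")
  }
  t_grid <- sort(unique(trajectories$t))
  tick <- if (length(t_grid) > 1) min(diff(t_grid)) else t_grid[1]
  if (schedule$dwell < tick) {
    abort("dwell shorter than the simulation tick: nothing new to observe")
  }
  t_max <- max(t_grid)
  n_vis <- floor(t_max / schedule$dwell)
  if (n_vis < 1) abort("trajectory too short for a single observer visit")
  k <- seq_len(n_vis)
  who <- schedule$order[((k - 1) %% length(schedule$order)) + 1]
  fixes <- with_seed(seed, {
    t_vis <- k * schedule$dwell + rnorm(n_vis, 0, schedule$jitter_sd)
    idx <- pmin(pmax(round(t_vis / tick), 1), length(t_grid))
    t_snap <- t_grid[idx]
    key <- paste(who, t_snap)
    traj_key <- paste(trajectories$animal_id, trajectories$t)
    pos <- match(key, traj_key)
    keep <- !is.na(pos)
    tibble(
      animal_id = who[keep],
      t = t_snap[keep],
      x = trajectories$x[pos[keep]] + rnorm(sum(keep), 0, schedule$gps_noise_sd),
      y = trajectories$y[pos[keep]] + rnorm(sum(keep), 0, schedule$gps_noise_sd),
      day_id = trajectories$day_id[pos[keep]]
    )
  })
  suppressMessages(validate_observations(fixes))
}
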