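#' Build the per-focal step dataset for direction matching
#'
#' Turns an observation table into one row per usable focal step: the focal's
#' observed unit direction of travel together with every predictor unit
#' vector evaluated at the step's start time. Consecutive same-day focal
#' fixes define candidate steps; a step is retained iff
#'
#' * its displacement is at least `min_step` metres and its duration at most
#'   `max_gap` seconds (direction is undefined for stationary fixes, and very
#'   long gaps carry no directional signal),
#' * the immediately preceding step exists and passes the same filters, so it
#'   can supply the previous heading,
#' * every other adult's position can be linearly interpolated at the step's
#'   start time (complete-case: no step is fitted with missing predictors).
#'
#' Focal positions are always observed, never interpolated; only neighbour
#' positions are interpolated. The group-centroid direction points to the
#' arithmetic mean of the interpolated neighbour positions.
#'
#' @param obs Validated observation tibble ([load_observations()]).
#' @param focal Animal id of the focal.
#' @param max_gap Interpolation / step-duration gap limit, seconds. Defaults
#'   to the table's `max_gap` attribute, else 1800.
#' @param min_step Minimum focal displacement, metres (GPS noise floor).
#' @param eps Distance (m) below which a direction is undefined.
#' @return A tibble with one row per step and columns `focal, day_id, t,
#'   step_dt, step_len, obs_x, obs_y, prev_x, prev_y, cm_x, cm_y` plus a pair
#'   `to_x.<id>, to_y.<id>` per neighbour; attributes `focal` and
#'   `neighbours`. All stored vectors are unit norm.
#' @export
build_steps <- function(obs, focal, max_gap = NULL, min_step = 5, eps = 0.1) {
  stop_if_missing_cols(obs, c("animal_id", "t", "x", "y", "day_id"),
                       "observation table")
  max_gap <- max_gap %||% attr(obs, "max_gap") %||% 1800
  ids <- unique(obs$animal_id)
  if (!focal %in% ids) {
    abort(sprintf("focal '%s' has no observations", focal))
  }
  nb <- sort(setdiff(ids, focal))
  foc <- obs |> filter(.data$animal_id == focal) |> arrange(.data$t)
  nb_tracks <- lapply(setNames(nb, nb), function(id) {
    obs |> filter(.data$animal_id == id)
  })

  rows <- list()
  for (day in unique(foc$day_id)) {
    f <- foc |> filter(.data$day_id == day)
    m <- nrow(f)
    if (m < 3) next
    dx <- diff(f$x); dy <- diff(f$y)
    len <- sqrt(dx^2 + dy^2)
    dt <- diff(f$t)
    valid <- len >= max(min_step, eps) & dt <= max_gap
    s <- which(valid & c(FALSE, valid[-length(valid)]))
    if (!length(s)) next
    t0 <- f$t[s]
    px <- f$x[s]; py <- f$y[s]
    obs_x <- dx[s] / len[s]; obs_y <- dy[s] / len[s]
    prev_x <- dx[s - 1] / len[s - 1]; prev_y <- dy[s - 1] / len[s - 1]

    nx <- matrix(NA_real_, length(s), length(nb))
    ny <- matrix(NA_real_, length(s), length(nb))
    for (j in seq_along(nb)) {
      trk <- nb_tracks[[j]] |> filter(.data$day_id == day)
      if (nrow(trk) >= 2) {
        ip <- interpolate_position(trk[c("t", "x", "y")], t0, max_gap = max_gap)
        nx[, j] <- ip$x
        ny[, j] <- ip$y
      }
    }
    complete <- rowSums(is.na(nx)) == 0
    if (!any(complete)) next

    to <- unit_vec_xy(nx - px, ny - py, eps = eps)
    cmx <- rowMeans(nx); cmy <- rowMeans(ny)
    cm <- unit_vec_xy(cmx - px, cmy - py, eps = eps)
    ok <- complete & rowSums(is.na(to$ux)) == 0 & !is.na(cm$ux)
    if (!any(ok)) next

    row <- tibble(
      focal = focal, day_id = day, t = t0[ok],
      step_dt = dt[s][ok], step_len = len[s][ok],
      obs_x = obs_x[ok], obs_y = obs_y[ok],
      prev_x = prev_x[ok], prev_y = prev_y[ok],
      cm_x = cm$ux[ok], cm_y = cm$uy[ok]
    )
    for (j in seq_along(nb)) {
      row[[paste0("to_x.", nb[j])]] <- to$ux[ok, j]
      row[[paste0("to_y.", nb[j])]] <- to$uy[ok, j]
    }
    rows[[length(rows) + 1]] <- row
  }

  out <- if (length(rows)) bind_rows(rows) else {
    empty <- tibble(focal = character(), day_id = numeric(), t = numeric(),
                    step_dt = numeric(), step_len = numeric(),
                    obs_x = numeric(), obs_y = numeric(),
                    prev_x = numeric(), prev_y = numeric(),
                    cm_x = numeric(), cm_y = numeric())
    for (j in nb) {
      empty[[paste0("to_x.", j)]] <- numeric()
      empty[[paste0("to_y.", j)]] <- numeric()
    }
    empty
  }
  attr(out, "focal") <- focal
  attr(out, "neighbours") <- nb
  out
}

# rowSums on a one-column logical matrix needs the matrix kept; helper to get
# the neighbour ids back out of a steps table.
step_neighbours <- function(steps) {
  nb <- attr(steps, "neighbours")
  if (!is.null(nb)) return(nb)
  sub("^to_x\\.", "", grep("^to_x\\.", names(steps), value = TRUE))
}
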