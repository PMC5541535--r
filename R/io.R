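#' Load an asynchronous GPS observation table
#'
#' Reads a CSV of timestamped planar positions (one row per fix) and validates
#' it into the canonical observation table used throughout the package.
#' Coordinates must already be in a planar metric projection (metres);
#' timestamps are seconds. A `day_id` column, if absent, is derived from the
#' timestamp (`floor(t / 86400)`): no step or interpolation ever crosses a day
#' boundary downstream.
#'
#' Rows are sorted by `(animal_id, t)`. Duplicate `(animal_id, t)` pairs and
#' rows with non-finite coordinates are dropped with a message reporting the
#' count.
#'
#' @param path Path to a CSV with header `animal_id,t,x,y` and optionally
#'   `day_id`.
#' @param max_gap Largest within-track gap (seconds) downstream interpolation
#'   may bridge; stored as an attribute and used as the default by
#'   [build_steps()]. Default 1800 s (30 min).
#' @return A tibble with columns `animal_id` (character), `t`, `x`, `y`
#'   (double) and `day_id`, sorted by `(animal_id, t)`, with attribute
#'   `max_gap`.
#' @seealso [validate_observations()], [build_steps()]
#' @export
load_observations <- function(path, max_gap = 1800) {
  if (!file.exists(path)) abort(sprintf("observation file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  stop_if_missing_cols(raw, c("animal_id", "t", "x", "y"), "observation CSV")
  for (col in c("t", "x", "y")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad)) {
        abort(sprintf("non-numeric value in column '%s' (first at data row %d)",
                      col, bad[1]))
      }
      raw[[col]] <- conv
    }
  }
  if (nrow(raw) == 0L) {
    warn("observation file contains a header but no rows")
  }
  obs <- validate_observations(raw)
  attr(obs, "max_gap") <- max_gap
  obs
}

#' Validate an observation table
#'
#' Applies the observation-table contract to an in-memory data frame: sorts by
#' `(animal_id, t)`, derives `day_id` when missing, and drops duplicate
#' `(animal_id, t)` fixes and non-finite coordinates (reporting how many rows
#' were removed). Within an animal and day the retained timestamps are
#' strictly increasing by construction.
#'
#' @param df Data frame with columns `animal_id,t,x,y` and optional `day_id`.
#' @return A validated tibble (see [load_observations()]).
#' @export
validate_observations <- function(df) {
  stop_if_missing_cols(df, c("animal_id", "t", "x", "y"), "observation table")
  obs <- as_tibble(df) |>
    mutate(animal_id = as.character(.data$animal_id),
           t = as.double(.data$t),
           x = as.double(.data$x),
           y = as.double(.data$y))
  if (!"day_id" %in% names(obs)) {
    obs$day_id <- floor(obs$t / 86400)
  }
  n0 <- nrow(obs)
  bad <- !is.finite(obs$t) | !is.finite(obs$x) | !is.finite(obs$y)
  obs <- obs[!bad, , drop = FALSE]
  obs <- obs |>
    arrange(.data$animal_id, .data$t) |>
    distinct(.data$animal_id, .data$t, .keep_all = TRUE)
  dropped <- n0 - nrow(obs)
  if (dropped > 0) {
    inform(sprintf("validate_observations: dropped %d row(s) (duplicates or non-finite coordinates)",
                   dropped))
  }
  attr(obs, "dropped") <- dropped
  obs[c("animal_id", "t", "x", "y", "day_id")]
}

#' Write an observation table to CSV
#'
#' @param obs Observation tibble (see [load_observations()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs[c("animal_id", "t", "x", "y", "day_id")], path,
                   progress = FALSE)
  invisible(path)
}

#' Load a dominance-rank table
#'
#' Reads `animal_id,sex,rank` rows. Ranks are ordinal within sex (1 = highest)
#' and must be unique within sex; sex codes must be `M` or `F`.
#'
#' @param path Path to the rank CSV.
#' @return A tibble with columns `animal_id`, `sex`, `rank`.
#' @export
load_ranks <- function(path) {
  if (!file.exists(path)) abort(sprintf("rank file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ranks(raw)
}

#' Validate a rank table
#'
#' @param df Data frame with columns `animal_id,sex,rank`.
#' @return A validated rank tibble.
#' @export
validate_ranks <- function(df) {
  stop_if_missing_cols(df, c("animal_id", "sex", "rank"), "rank table")
  rk <- as_tibble(df) |>
    mutate(animal_id = as.character(.data$animal_id),
           sex = as.character(.data$sex),
           rank = as.integer(.data$rank))
  if (any(!rk$sex %in% c("M", "F"))) {
    abort(sprintf("unknown sex code(s): %s",
                  paste(unique(setdiff(rk$sex, c("M", "F"))), collapse = ", ")))
  }
  if (any(is.na(rk$rank)) || any(rk$rank < 1L)) {
    abort("ranks must be positive integers (1 = highest)")
  }
  dup <- rk |> group_by(.data$sex, .data$rank) |> filter(n() > 1) |> ungroup()
  if (nrow(dup)) {
    abort(sprintf("duplicate rank within sex: %s",
                  paste(unique(paste0(dup$sex, dup$rank)), collapse = ", ")))
  }
  if (anyDuplicated(rk$animal_id)) abort("duplicate animal_id in rank table")
  rk
}

#' Synthetic adult roster mirroring the study group
#'
#' A default roster of 14 adults (2 males, 12 females), labelled by sex and
#' within-sex ordinal rank, for simulation presets and examples. The roster is
#' synthetic: labels follow the field convention `M1, M2, F1, ...` but the
#' animals are simulated.
#'
#' @param n_males,n_females Number of males and females.
#' @return A rank tibble (see [load_ranks()]).
#' @export
synthetic_roster <- function(n_males = 2, n_females = 12) {
  tibble(
    animal_id = c(paste0("M", seq_len(n_males)), paste0("F", seq_len(n_females))),
    sex = c(rep("M", n_males), rep("F", n_females)),
    rank = c(seq_len(n_males), seq_len(n_females))
  )
}

#' Merge sex-specific ranks into one group-wide ordinal ordering
#'
#' Produces the single 1..n ordering used for rank differences, by default
#' males first (highest) then females, each in within-sex rank order.
#'
#' @param ranks Rank tibble.
#' @param order Character vector of sexes from top to bottom.
#' @return The tibble with an added `ordinal` column (1 = highest overall).
#' @export
merged_ordinal_ranks <- function(ranks, order = c("M", "F")) {
  ranks <- validate_ranks(ranks)
  ranks$sex <- factor(ranks$sex, levels = order)
  out <- ranks |> arrange(.data$sex, .data$rank) |>
    mutate(ordinal = row_number(), sex = as.character(.data$sex))
  out
}

#' Export an influence network
#'
#' Writes the directed weighted network either as an edge-list CSV
#' (`source,target,weight,sign`, with an accompanying `<path>.nodes` file so
#' isolated nodes survive the round trip) or as GraphML with `weight` and
#' `sign` edge attributes.
#'
#' @param network An `influence_network` (see [build_influence_network()]).
#' @param path Output file path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("csv", "graphml")) {
  if (!inherits(network, "influence_network")) {
    abort("`network` must be an influence_network")
  }
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(sprintf(
                       "unsupported network format '%s' (use 'csv' or 'graphml')",
                       format[1])))
  if (format == "csv") {
    readr::write_csv(network$edges[c("source", "target", "weight", "sign")],
                     path, progress = FALSE)
    writeLines(network$nodes, paste0(path, ".nodes"))
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import an influence network written by [export_network()]
#'
#' @param path File path.
#' @param format `"csv"` or `"graphml"`.
#' @return An `influence_network`.
#' @export
import_network <- function(path, format = c("csv", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(sprintf(
                       "unsupported network format '%s' (use 'csv' or 'graphml')",
                       format[1])))
  if (format == "csv") {
    edges <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    stop_if_missing_cols(edges, c("source", "target", "weight", "sign"),
                         "network edge CSV")
    nodes_file <- paste0(path, ".nodes")
    nodes <- if (file.exists(nodes_file)) readLines(nodes_file) else
      sort(unique(c(edges$source, edges$target)))
    new_influence_network(nodes,
                          as_tibble(edges) |>
                            mutate(source = as.character(.data$source),
                                   target = as.character(.data$target)))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    nodes <- igraph::V(g)$name
    edges <- tibble(source = as.character(ed$from),
                    target = as.character(ed$to),
                    weight = as.double(ed$weight),
                    sign = as.integer(ed$sign))
    new_influence_network(nodes, edges)
  }
}

#' Convert an influence network to an igraph object
#'
#' Edge direction is source = influencer, target = influenced; the `weight`
#' attribute is the signed posterior-mean coefficient and `sign` its sign.
#'
#' @param network An `influence_network`.
#' @return An igraph directed graph.
#' @export
as_igraph <- function(network) {
  ed <- network$edges
  igraph::graph_from_data_frame(
    data.frame(from = ed$source, to = ed$target,
               weight = ed$weight, sign = ed$sign),
    directed = TRUE, vertices = data.frame(name = network$nodes))
}
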