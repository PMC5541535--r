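#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_col
#'   geom_histogram geom_vline geom_segment geom_text labs theme_minimal
#'   coord_equal facet_wrap arrow unit position_dodge
NULL

#' Plot posterior influence coefficients
#'
#' Point estimates with HPDI error bars for every predictor of one focal's
#' direction-matching fit; intervals excluding zero (retained edges) are
#' highlighted.
#'
#' @param object An `influence_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.influence_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$term, y = .data$estimate,
                 colour = .data$excludes_zero)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$hpdi_low, ymax = .data$hpdi_high),
                  width = 0.2) +
    geom_vline(xintercept = 0, linetype = 0) +
    labs(x = NULL, y = "influence coefficient",
         colour = sprintf("%.0f%% HPDI excludes 0", 100 * object$hpdi_prob),
         title = sprintf("Direction-matching coefficients, focal %s (%s model)",
                         object$focal, object$model)) +
    theme_minimal()
}

#' Plot the weighted k-shell decomposition
#'
#' @param object A `core_decomposition`.
#' @param ... Unused.
#' @return A ggplot of shell values per node, core first.
#' @export
autoplot.core_decomposition <- function(object, ...) {
  sh <- object$shell |> arrange(dplyr::desc(.data$shell))
  sh$node <- factor(sh$node, levels = sh$node)
  ggplot(sh, aes(x = .data$node, y = .data$shell)) +
    geom_col() +
    labs(x = NULL, y = "weighted k-shell value",
         title = sprintf("Core/periphery decomposition (D_core = %.2f)",
                         object$d_core)) +
    theme_minimal()
}

#' Plot the permutation null distribution
#'
#' Histogram of the null `D_core` values with the observed value marked --
#' the standard display for the core/periphery magnitude test.
#'
#' @param object A `permutation_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_test <- function(object, ...) {
  ggplot(tibble(null_d = object$null_d), aes(x = .data$null_d)) +
    geom_histogram(bins = 40) +
    geom_vline(xintercept = object$observed_d, linetype = "dashed") +
    geom_vline(xintercept = object$q95, linetype = "dotted") +
    labs(x = "D_core under the permutation null", y = "count",
         title = sprintf(
           "Observed D_core = %.2f vs null 95%% quantile = %.2f (%d permutations)",
           object$observed_d, object$q95, object$n_perm)) +
    theme_minimal()
}

#' Plot the rank-effect fit
#'
#' Posterior-mean dyadic influence predicted per rank difference, one line
#' per influenced animal (its varying intercept), over the observed dyads.
#'
#' @param object A `rank_model_fit`.
#' @param data Optional dyad tibble to overlay as points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rank_model_fit <- function(object, data = NULL, ...) {
  dr <- seq(-max(1, nrow(object$g) - 1), max(1, nrow(object$g) - 1))
  pred <- tidyr::expand_grid(animal_id = object$g$animal_id, drank_ij = dr) |>
    left_join(object$g |> select("animal_id", g = "estimate"),
              by = "animal_id") |>
    mutate(beta_ij = object$beta_r$estimate * .data$drank_ij + .data$g)
  p <- ggplot(pred, aes(x = .data$drank_ij, y = .data$beta_ij,
                        group = .data$animal_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    labs(x = "rank difference (influenced - influencer)",
         y = "influence coefficient",
         title = sprintf("Rank effect %.4g per rank unit (R2 %.0f%% / %.0f%%)",
                         object$beta_r$estimate, 100 * object$r2_fixed,
                         100 * object$r2_full)) +
    theme_minimal()
  if (!is.null(data)) {
    p <- p + geom_point(data = data, aes(x = .data$drank_ij, y = .data$beta_ij),
                        inherit.aes = FALSE, alpha = 0.4)
  }
  p
}

#' Plot an influence network
#'
#' Draws the directed network on a circular layout: arrows run from
#' influencer to influenced, line width tracks the coefficient magnitude,
#' and the attraction and repulsion subgraphs are faceted.
#'
#' @param net An `influence_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_network <- function(net, ...) {
  n <- length(net$nodes)
  th <- 2 * pi * (seq_len(n) - 1) / n
  lay <- tibble(node = net$nodes, x = cos(th), y = sin(th))
  ed <- net$edges |>
    mutate(kind = ifelse(.data$sign > 0, "attraction", "repulsion"),
           magnitude = abs(.data$weight)) |>
    left_join(lay, by = c(source = "node")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(lay, by = c(target = "node")) |>
    mutate(xend = .data$x0 + 0.88 * (.data$x - .data$x0),
           yend = .data$y0 + 0.88 * (.data$y - .data$y0))
  p <- ggplot(lay, aes(x = .data$x, y = .data$y))
  if (nrow(ed)) {
    p <- p + geom_segment(
      data = ed,
      aes(x = .data$x0, y = .data$y0, xend = .data$xend, yend = .data$yend,
          linewidth = .data$magnitude),
      arrow = arrow(length = unit(2, "mm")), alpha = 0.6) +
      facet_wrap(~kind) +
      ggplot2::scale_linewidth(range = c(0.2, 1.5))
  }
  p + geom_point(size = 3) +
    geom_text(aes(label = .data$node), nudge_y = 0.12, size = 3) +
    coord_equal() +
    labs(title = "Influence network (arrows: influencer to influenced)",
         x = NULL, y = NULL, linewidth = "|coefficient|") +
    theme_minimal()
}

#' Plot node strengths
#'
#' In- and out-strength per node for a signed subgraph, in the stored
#' orientation (see [node_strengths()] for the field-convention mapping).
#'
#' @param net An `influence_network`.
#' @param which `"attraction"` or `"repulsion"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_strengths <- function(net, which = "attraction", ...) {
  st <- node_strengths(net, which) |>
    tidyr::pivot_longer(c("influence", "responsiveness"),
                        names_to = "measure", values_to = "strength")
  ggplot(st, aes(x = .data$node, y = .data$strength, fill = .data$measure)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = sprintf("%s strength", which),
         title = "Influence exerted vs responsiveness per animal") +
    theme_minimal()
}
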