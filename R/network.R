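new_influence_network <- function(nodes, edges) {
  structure(list(nodes = as.character(nodes),
                 edges = as_tibble(edges)),
            class = "influence_network")
}

#' Build the screened influence network
#'
#' Turns per-focal direction-matching fits into a directed weighted network:
#' for every dyadic coefficient whose HPDI excludes zero, an edge is drawn
#' from the influencer `j` (source) to the influenced animal `i` (target)
#' with the posterior mean as its signed weight. Positive weights form the
#' attraction subgraph; negative weights form the repulsion subgraph (stored
#' with magnitude weights and `sign = -1`).
#'
#' @param fits Tibble from [fit_all_focals()] or list of full-model
#'   `influence_fit`s.
#' @return An `influence_network`: `$nodes` (all animals with a fit or named
#'   as a neighbour) and `$edges` `(source, target, weight, sign)`.
#' @export
build_influence_network <- function(fits) {
  fits <- as_fit_list(fits)
  if (length(fits) < 2) abort("need fits for >= 2 focals")
  nodes <- sort(unique(unlist(lapply(fits, function(f) c(f$focal, f$neighbours)))))
  edges <- bind_rows(purrr::map(fits, function(f) {
    est <- f$summary |> filter(.data$role == "neighbour",
                               .data$hpdi_low > 0 | .data$hpdi_high < 0)
    if (!nrow(est)) return(NULL)
    tibble(source = est$term, target = f$focal, weight = est$estimate,
           sign = ifelse(est$estimate > 0, 1L, -1L))
  }))
  if (!nrow(edges)) {
    edges <- tibble(source = character(), target = character(),
                    weight = numeric(), sign = integer())
  }
  new_influence_network(nodes, edges)
}

#' @export
print.influence_network <- function(x, ...) {
  cat(sprintf("<influence_network: %d nodes, %d attraction + %d repulsion edges>\n",
              length(x$nodes), sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

# Edges of one signed subgraph, with repulsion weights stored as magnitudes.
subgraph_edges <- function(net, which = c("attraction", "repulsion")) {
  which <- match.arg(which)
  ed <- if (which == "attraction") {
    net$edges |> filter(.data$sign > 0)
  } else {
    net$edges |> filter(.data$sign < 0) |> mutate(weight = abs(.data$weight))
  }
  ed
}

#' Node strengths of a signed subgraph
#'
#' Sums of incoming and outgoing edge weights per node, in the stored
#' orientation (source = influencer, target = influenced). So `out_strength`
#' here is the total influence a node exerts on others -- what the field
#' literature reports as an animal's *in-strength* ("others were sensitive to
#' them") -- and `in_strength` is the node's total responsiveness to others.
#' The `influence` and `responsiveness` columns give the field-convention
#' reading directly.
#'
#' @param net An `influence_network`.
#' @param which `"attraction"` or `"repulsion"` (magnitude weights).
#' @return A tibble `(node, in_strength, out_strength, influence,
#'   responsiveness)` covering every node (zeros for isolates).
#' @export
node_strengths <- function(net, which = c("attraction", "repulsion")) {
  ed <- subgraph_edges(net, which)
  ins <- tapply(ed$weight, factor(ed$target, levels = net$nodes), sum)
  outs <- tapply(ed$weight, factor(ed$source, levels = net$nodes), sum)
  tibble(node = net$nodes,
         in_strength = as.double(ifelse(is.na(ins), 0, ins)),
         out_strength = as.double(ifelse(is.na(outs), 0, outs))) |>
    mutate(influence = .data$out_strength,
           responsiveness = .data$in_strength)
}

# Weighted adjacency matrix A[source, target] of a subgraph.
adjacency_matrix <- function(net, which = "attraction") {
  ed <- subgraph_edges(net, which)
  A <- matrix(0, length(net$nodes), length(net$nodes),
              dimnames = list(net$nodes, net$nodes))
  if (nrow(ed)) {
    A[cbind(match(ed$source, net$nodes), match(ed$target, net$nodes))] <- ed$weight
  }
  A
}

#' Alpha centrality (raw engine)
#'
#' Solves `x = (I - alpha * t(A))^{-1} exo` for a weighted adjacency matrix
#' `A[u, v]` = weight of edge `u -> v`; each node receives `exo` plus
#' `alpha`-discounted centrality along its incoming edges.
#'
#' @param A Weighted adjacency matrix.
#' @param alpha Attenuation; `"auto"` picks `0.9 / max(|eigenvalue|)` (1 when
#'   the spectral radius is zero).
#' @param exo Exogenous centrality, recycled over nodes (default 1).
#' @return Named numeric vector of centralities.
#' @export
alpha_centrality_matrix <- function(A, alpha = "auto", exo = 1) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (identical(alpha, "auto")) {
    lam <- max(Mod(eigen(A, only.values = TRUE)$values))
    alpha <- if (lam > 1e-12) 0.9 / lam else 1
  }
  exo <- rep_len(exo, n)
  x <- tryCatch(solve(diag(n) - alpha * t(A), exo),
                error = function(e) abort(
                  "singular system in alpha centrality; try a smaller alpha"))
  setNames(as.double(x), rownames(A))
}

#' Alpha centrality of the influence network
#'
#' Scores each animal by how much influence flows to it along the network:
#' the adjacency is oriented influenced -> influencer before applying
#' [alpha_centrality_matrix()], so influential animals (the paper's
#' high *in-strength* individuals) receive high centrality.
#'
#' @param net An `influence_network`.
#' @param which Signed subgraph to use.
#' @inheritParams alpha_centrality_matrix
#' @return A tibble `(node, alpha_centrality)`.
#' @export
alpha_centrality <- function(net, which = "attraction", alpha = "auto",
                             exo = 1) {
  A <- adjacency_matrix(net, which)
  x <- alpha_centrality_matrix(t(A), alpha = alpha, exo = exo)
  tibble(node = net$nodes, alpha_centrality = as.double(x))
}

# Undirected symmetrisation for the k-shell: reciprocal-pair weights summed.
symmetrize_weights <- function(net, which = "attraction") {
  A <- adjacency_matrix(net, which)
  S <- A + t(A)
  S
}

#' Weighted k-shell decomposition of the attraction network
#'
#' Classifies nodes into successive cores with a weighted extension of the
#' k-core algorithm. The directed attraction subgraph is first symmetrised
#' (reciprocal-pair weights summed). Each remaining node is scored
#' `k' = sqrt(k * s)` (degree times strength); pruning repeatedly removes
#' *all* nodes whose current `k'` is at or below the running shell threshold
#' (simultaneous removal, then rescoring), raising the threshold to the
#' minimum remaining `k'` when no node qualifies. A node's shell value is the
#' threshold at which it was removed; isolated nodes get shell 0. With unit
#' weights and no reciprocal edges this reduces exactly to the classic
#' k-core. The non-integer shell values it produces (e.g. `sqrt(2 * 4) =
#' 2.83` for a node with degree 2 and strength 4 in the final core) are the
#' field-standard convention.
#'
#' @param net An `influence_network`, or a symmetric weighted adjacency
#'   matrix, or an edge data frame `(source, target, weight)` treated as
#'   undirected.
#' @param which Signed subgraph when `net` is a network (default
#'   `"attraction"`; the repulsion network showed no core structure in the
#'   motivating study but can be decomposed the same way).
#' @return A `core_decomposition`: tibble `$shell` `(node, shell)` plus the
#'   `$d_core` scalar (see [d_core()]).
#' @export
weighted_kshell <- function(net, which = "attraction") {
  S <- if (inherits(net, "influence_network")) {
    symmetrize_weights(net, which)
  } else if (is.matrix(net)) {
    if (!isSymmetric(unname(net), tol = 1e-9)) {
      abort("adjacency matrix must be symmetric (undirected)")
    }
    net
  } else {
    stop_if_missing_cols(net, c("source", "target", "weight"), "edge table")
    nodes <- sort(unique(c(net$source, net$target)))
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    A[cbind(match(net$source, nodes), match(net$target, nodes))] <- net$weight
    A + t(A)
  }
  shell <- kshell_scores(S)
  res <- structure(list(
    shell = tibble(node = names(shell), shell = as.double(shell)),
    d_core = d_core(shell)
  ), class = "core_decomposition")
  res
}

# Core pruning loop on a symmetric non-negative weight matrix.
kshell_scores <- function(S) {
  n <- nrow(S)
  nodes <- rownames(S) %||% as.character(seq_len(n))
  shell <- setNames(numeric(n), nodes)
  alive <- rep(TRUE, n)
  kprime <- function() {
    k <- rowSums(S[alive, alive, drop = FALSE] > 0)
    s <- rowSums(S[alive, alive, drop = FALSE])
    sqrt(k * s)
  }
  threshold <- 0
  while (any(alive)) {
    kp <- kprime()
    if (all(kp > threshold)) {
      threshold <- min(kp)
      next
    }
    doomed <- names(kp)[kp <= threshold]
    shell[doomed] <- threshold
    alive[match(doomed, nodes)] <- FALSE
  }
  shell
}

#' @export
print.core_decomposition <- function(x, ...) {
  cat(sprintf("<core_decomposition: %d nodes, %d shell level(s), D_core = %.4g>\n",
              nrow(x$shell), length(unique(x$shell$shell)), x$d_core))
  invisible(x)
}

#' @rdname weighted_kshell
#' @param x A `core_decomposition`.
#' @param ... Unused.
#' @export
tidy.core_decomposition <- function(x, ...) x$shell

#' Magnitude of core/periphery structure
#'
#' `D_core` is the sum over all ordered node pairs (both orders, including
#' `i = j`) of the absolute difference in shell values. It is zero when all
#' shells are equal, invariant to adding a constant to every shell, and
#' scales linearly with the shells.
#'
#' @param shell Numeric vector of shell values (or a `core_decomposition`).
#' @return A single number.
#' @export
d_core <- function(shell) {
  if (inherits(shell, "core_decomposition")) shell <- shell$shell$shell
  x <- as.double(shell)
  if (!length(x)) abort("need >= 1 shell value")
  sum(abs(outer(x, x, "-")))
}

# Uniformly sample m distinct ordered non-self pairs from n nodes,
# returned as (source, target) index vectors.
sample_null_pairs <- function(n, m) {
  pair_id <- sample.int(n * (n - 1L), m)
  src <- ((pair_id - 1L) %/% (n - 1L)) + 1L
  tgt <- ((pair_id - 1L) %% (n - 1L)) + 1L
  tgt <- tgt + (tgt >= src)
  list(src = src, tgt = tgt)
}

#' Draw one network from the permutation null
#'
#' Reassigns the observed multiset of edge weights of the chosen subgraph to
#' uniformly sampled distinct directed non-self pairs of the same node set
#' (node count and weight multiset preserved exactly).
#'
#' @param net An `influence_network`.
#' @param seed Integer seed.
#' @param which Signed subgraph to permute.
#' @return An `influence_network` holding one null graph.
#' @export
permute_network <- function(net, seed = 1L, which = "attraction") {
  ed <- subgraph_edges(net, which)
  n <- length(net$nodes)
  m <- nrow(ed)
  if (m > n * (n - 1L)) abort("more edges than available ordered node pairs")
  with_seed(seed, {
    pr <- sample_null_pairs(n, m)
    w <- if (m > 1) sample(ed$weight) else ed$weight
    new_influence_network(net$nodes,
                          tibble(source = net$nodes[pr$src],
                                 target = net$nodes[pr$tgt],
                                 weight = w, sign = 1L))
  })
}

#' Permutation null for core/periphery magnitude
#'
#' Tests whether the observed `D_core` of the attraction network exceeds
#' chance by rearranging attractions without reference to identity: each
#' null graph places the observed multiset of edge weights on uniformly
#' sampled distinct directed non-self pairs of the same node set (edge count
#' fixed), then is decomposed with [weighted_kshell()] and scored with
#' [d_core()]. `exceeds` is whether the observed value lies above the 95%
#' quantile of the null distribution.
#'
#' @param net An `influence_network`.
#' @param n_perm Number of null graphs (the motivating analysis used 10 000).
#' @param seed Integer seed; the null is deterministic given it.
#' @param which Signed subgraph (default `"attraction"`).
#' @return A `permutation_test` list: `observed_d`, `null_d` (length
#'   `n_perm`), `q95`, `exceeds`, `n_perm`, `seed`.
#' @export
permutation_null <- function(net, n_perm = 1000L, seed = 1L,
                             which = "attraction") {
  if (n_perm < 1) abort("n_perm must be >= 1")
  ed <- subgraph_edges(net, which)
  nodes <- net$nodes
  n <- length(nodes)
  m <- nrow(ed)
  n_pairs <- n * (n - 1L)
  if (m > n_pairs) {
    abort("more edges than available ordered node pairs")
  }
  observed <- weighted_kshell(net, which)$d_core
  weights <- ed$weight
  null_d <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pr <- sample_null_pairs(n, m)
      w <- if (m > 1) sample(weights) else weights
      S <- matrix(0, n, n, dimnames = list(nodes, nodes))
      S[cbind(pr$src, pr$tgt)] <- w
      S <- S + t(S)
      d_core(kshell_scores(S))
    }, numeric(1))
  })
  qq <- q95(null_d)
  structure(list(observed_d = observed, null_d = null_d, q95 = qq,
                 exceeds = observed > qq, n_perm = as.integer(n_perm),
                 seed = seed, which = which),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test: observed D_core = %.4g, null 95%% quantile = %.4g (%d permutations) -> %s>\n",
              x$observed_d, x$q95, x$n_perm,
              if (x$exceeds) "exceeds null" else "within null"))
  invisible(x)
}

#' @rdname permutation_null
#' @param x A `permutation_test`.
#' @param ... Unused.
#' @export
glance.permutation_test <- function(x, ...) {
  tibble(observed_d = x$observed_d, q95 = x$q95, exceeds = x$exceeds,
         n_perm = x$n_perm, seed = x$seed)
}
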