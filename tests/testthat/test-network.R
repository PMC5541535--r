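test_that("edge screening keeps only coefficients whose HPDI excludes zero", {
  f1 <- stub_fit("A", c("B", "C", "D"),
                 estimate = c(0.05, 0.02, -0.05),
                 hpdi_low = c(0.02, -0.01, -0.08),
                 hpdi_high = c(0.09, 0.04, -0.02))
  f2 <- stub_fit("B", c("A", "C", "D"),
                 estimate = c(0.01, 0.0, 0.0),
                 hpdi_low = c(-0.02, -0.03, -0.01),
                 hpdi_high = c(0.04, 0.03, 0.02))
  net <- build_influence_network(list(f1, f2))
  expect_setequal(net$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(net$edges), 2)
  att <- net$edges[net$edges$sign > 0, ]
  expect_equal(att$source, "B")   # B -> A attraction, weight 0.05
  expect_equal(att$target, "A")
  rep_ed <- dirmatch:::subgraph_edges(net, "repulsion")
  expect_equal(rep_ed$weight, 0.05)  # stored magnitude
  expect_equal(rep_ed$source, "D")
})

test_that("node strengths sum incoming and outgoing weights and conserve total", {
  net <- net_from_edges(c("A", "B", "C"),
                        source = c("A", "C"), target = c("B", "B"),
                        weight = c(0.5, 0.3))
  st <- node_strengths(net, "attraction")
  expect_equal(st$in_strength[st$node == "B"], 0.8)
  expect_equal(st$out_strength[st$node == "B"], 0)
  expect_equal(sum(st$in_strength), sum(st$out_strength))
  expect_equal(sum(st$in_strength), sum(net$edges$weight))

  empty <- dirmatch:::new_influence_network(
    c("A", "B"), tibble::tibble(source = character(), target = character(),
                                weight = numeric(), sign = integer()))
  st0 <- node_strengths(empty, "attraction")
  expect_true(all(st0$in_strength == 0 & st0$out_strength == 0))
})

test_that("alpha centrality matches closed forms, a hand-solved chain, and igraph", {
  # zero adjacency -> exogenous input
  A0 <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  expect_equal(unname(alpha_centrality_matrix(A0, alpha = 0.5)), rep(1, 3))
  # single edge a -> b of weight w: x_b = 1 + alpha * w
  A1 <- A0; A1["a", "b"] <- 0.5
  x <- alpha_centrality_matrix(A1, alpha = 0.2)
  expect_equal(unname(x), c(1, 1.1, 1))
  # chain a -> b -> c: x_a = 1, x_b = 1 + a*w1, x_c = 1 + a*w2*(1 + a*w1)
  A2 <- A0; A2["a", "b"] <- 0.4; A2["b", "c"] <- 0.7
  x2 <- alpha_centrality_matrix(A2, alpha = 0.3)
  expect_equal(unname(x2), c(1, 1.12, 1 + 0.3 * 0.7 * 1.12), tolerance = 1e-12)

  # independent oracle on a random weighted digraph
  set.seed(5)
  n <- 7
  A <- matrix(rbinom(n^2, 1, 0.3) * runif(n^2, 0.1, 1), n, n)
  diag(A) <- 0
  dimnames(A) <- rep(list(letters[1:n]), 2)
  g <- igraph::graph_from_adjacency_matrix(A, weighted = TRUE)
  ours <- alpha_centrality_matrix(A, alpha = 0.15)
  theirs <- igraph::alpha_centrality(g, alpha = 0.15, exo = 1,
                                     weights = igraph::E(g)$weight)
  expect_equal(ours, theirs[names(ours)], tolerance = 1e-9)
})

test_that("network-level alpha centrality scores influencers highly", {
  # B influences A and C strongly; nobody influences B
  net <- net_from_edges(c("A", "B", "C"),
                        source = c("B", "B"), target = c("A", "C"),
                        weight = c(0.5, 0.5))
  ac <- alpha_centrality(net)
  expect_equal(which.max(ac$alpha_centrality), match("B", ac$node))
})

test_that("weighted k-shell reproduces classic and weighted hand oracles", {
  ids <- c("a", "b", "c")
  tri <- matrix(0, 3, 3, dimnames = list(ids, ids))
  tri[cbind(1:3, c(2, 3, 1))] <- 1
  tri <- tri + t(tri)
  expect_equal(unname(dirmatch:::kshell_scores(tri)), rep(2, 3))

  path <- matrix(0, 3, 3, dimnames = list(ids, ids))
  path[1, 2] <- 1; path[2, 3] <- 1; path <- path + t(path)
  expect_equal(unname(dirmatch:::kshell_scores(path)), rep(1, 3))

  # k = 2, s = 4 in the final core -> shell sqrt(8)
  expect_equal(unname(dirmatch:::kshell_scores(tri * 2)), rep(sqrt(8), 3))

  # isolated node -> shell 0
  net <- net_from_edges(c("a", "b", "c", "iso"),
                        source = c("a", "b"), target = c("b", "c"),
                        weight = c(1, 1))
  dec <- weighted_kshell(net)
  expect_equal(dec$shell$shell[dec$shell$node == "iso"], 0)
})

test_that("with unit weights the k-shell equals classic coreness on random graphs", {
  for (r in 1:30) {
    n <- sample(4:10, 1)
    # distinct unordered pairs, randomly oriented: symmetrisation keeps weight 1
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    if (nrow(keep) == 0) next
    flip <- runif(nrow(keep)) < 0.5
    src <- ifelse(flip, keep[, 1], keep[, 2])
    tgt <- ifelse(flip, keep[, 2], keep[, 1])
    ids <- sprintf("v%02d", 1:n)
    net <- net_from_edges(ids, ids[src], ids[tgt], rep(1, length(src)))
    ours <- weighted_kshell(net)$shell
    g <- igraph::graph_from_data_frame(
      data.frame(from = ids[src], to = ids[tgt]), directed = FALSE,
      vertices = data.frame(name = ids))
    core <- igraph::coreness(g)
    expect_equal(setNames(ours$shell, ours$node), core[ours$node])
  }
})

test_that("D_core matches hand enumeration and its invariances", {
  expect_equal(d_core(c(0, 0, 1, 1)), 8)
  expect_equal(d_core(c(0, 1, 3)), 12)
  expect_equal(d_core(c(2, 2, 2)), 0)
  x <- runif(10)
  expect_equal(d_core(x + 5), d_core(x))
  expect_equal(d_core(3 * x), 3 * d_core(x))
})

test_that("permutation null is deterministic and preserves weights and nodes", {
  net <- field_like_cp_network(seed = 2)
  p1 <- permutation_null(net, n_perm = 25, seed = 9)
  p2 <- permutation_null(net, n_perm = 25, seed = 9)
  expect_identical(p1$null_d, p2$null_d)
  expect_equal(p1$q95, unname(quantile(p1$null_d, 0.95)))

  for (s in 1:10) {
    null_net <- permute_network(net, seed = s)
    expect_setequal(null_net$nodes, net$nodes)
    expect_equal(sort(null_net$edges$weight),
                 sort(dirmatch:::subgraph_edges(net, "attraction")$weight))
    expect_true(all(null_net$edges$source != null_net$edges$target))
    expect_false(any(duplicated(paste(null_net$edges$source,
                                      null_net$edges$target))))
  }
})

test_that("a complete graph with equal weights is its own null", {
  ids <- c("a", "b", "c", "d")
  pairs <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  net <- net_from_edges(ids, pairs$s, pairs$t, rep(1, nrow(pairs)))
  p <- permutation_null(net, n_perm = 20, seed = 3)
  expect_true(all(p$null_d == p$observed_d))
  expect_false(p$exceeds)
})

test_that("the permutation test detects strong sparse core/periphery structure", {
  hits <- vapply(1:10, function(r) {
    permutation_null(field_like_cp_network(seed = r),
                     n_perm = 200, seed = 100 + r)$exceeds
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
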