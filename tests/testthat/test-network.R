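mk_log <- function(...) {
  ev <- list(...)
  tibble::tibble(time_s = seq_along(ev), team = "t",
                 passer_id = vapply(ev, `[`, "", 1),
                 receiver_id = vapply(ev, `[`, "", 2),
                 success = TRUE)
}

ten <- paste0("p", 1:10)

test_that("adjacency counts passes and conserves the log total", {
  empty <- build_adjacency(mk_log()[0, ], ten)
  expect_true(all(empty$A == 0))
  expect_equal(dim(empty$A), c(10, 10))

  log <- mk_log(c("p1", "p2"), c("p1", "p2"), c("p1", "p2"), c("p2", "p1"))
  net <- build_adjacency(log, ten)
  expect_equal(net$A["p1", "p2"], 3)
  expect_equal(net$A["p2", "p1"], 1)
  expect_equal(sum(net$A), 4)
  expect_equal(sum(upper.tri(net$A) | lower.tri(net$A)), 90)

  expect_error(build_adjacency(mk_log(c("p1", "zz")), ten), "outside the roster")
})

test_that("edge length conventions map counts to geodesic lengths", {
  net <- build_adjacency(mk_log(c("p1", "p2"), c("p1", "p2"), c("p1", "p2"),
                                c("p1", "p2"), c("p2", "p3")), ten)
  rec <- edge_distances(net, "reciprocal")
  expect_equal(rec["p1", "p2"], 0.25)
  expect_equal(rec["p2", "p3"], 1)
  expect_identical(rec["p3", "p1"], Inf)
  hop <- edge_distances(net, "hop")
  expect_equal(hop["p1", "p2"], 1)
  expect_error(edge_distances(net, "euclid"))
})

test_that("path census resolves chains, ties, and refuses negative lengths", {
  # chain A -> B -> C
  L <- matrix(Inf, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(L) <- 0
  L["A", "B"] <- 1; L["B", "C"] <- 1
  cs <- shortest_path_census(L)
  expect_equal(cs$dist["A", "C"], 2)
  expect_equal(cs$sigma["A", "C"], 1)
  expect_equal(cs$sigma_through["A", "C", "B"], 1)
  expect_equal(betweenness_centrality(cs)$betweenness, c(0, 1, 0))

  # diamond A -> {B, C} -> D: two tied geodesics
  L <- matrix(Inf, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(L) <- 0
  L["A", "B"] <- 1; L["A", "C"] <- 1; L["B", "D"] <- 1; L["C", "D"] <- 1
  cs <- shortest_path_census(L)
  expect_equal(cs$sigma["A", "D"], 2)
  expect_equal(cs$sigma_through["A", "D", "B"], 1)
  expect_equal(cs$sigma_through["A", "D", "C"], 1)

  L["A", "B"] <- -1
  expect_error(shortest_path_census(L), "negative")
})

test_that("closeness handles stars, sinks, and matches an oracle row-sum", {
  # out-star: centre p1 passes once to each of the other 9
  log <- do.call(mk_log, lapply(ten[-1], function(w) c("p1", w)))
  net <- build_adjacency(log, ten)
  cs <- shortest_path_census(edge_distances(net, "reciprocal"))
  cl <- closeness_centrality(cs)
  expect_equal(cl$closeness[cl$player_id == "p1"], 1 / 9)
  expect_equal(cl$reachable_count[cl$player_id == "p1"], 9)
  # spokes have no outgoing edges
  expect_equal(cl$closeness[cl$player_id == "p2"], 0)
  expect_equal(cl$reachable_count[cl$player_id == "p2"], 0)
})

test_that("centralities equal exhaustive path-enumeration oracles", {
  set.seed(101)
  for (rep in 1:60) {
    net <- random_pass_digraph(n = sample(3:5, 1))
    for (conv in c("reciprocal", "hop")) {
      L <- edge_distances(net, conv)
      cs <- shortest_path_census(L)
      oc <- oracle_path_census(unclass(L))
      expect_equal(unname(cs$dist), oc$dist)
      expect_equal(unname(cs$sigma), oc$sigma)
      expect_equal(closeness_centrality(cs)$closeness, oracle_closeness(oc))
      expect_equal(betweenness_centrality(cs)$betweenness,
                   oracle_betweenness(oc))
    }
  }
})

test_that("centralities agree with igraph on weighted digraphs", {
  set.seed(7)
  for (rep in 1:10) {
    net <- random_pass_digraph(n = 5, p_edge = 0.6)
    L <- edge_distances(net, "reciprocal")
    cs <- shortest_path_census(L)
    g <- igraph::graph_from_adjacency_matrix(net$A, mode = "directed",
                                             weighted = TRUE)
    W <- 1 / igraph::E(g)$weight
    d_ig <- igraph::distances(g, mode = "out", weights = W)
    expect_equal(unname(cs$dist), unname(d_ig[net$nodes, net$nodes]))
    b_ig <- igraph::betweenness(g, directed = TRUE, weights = W)
    b_us <- setNames(betweenness_centrality(cs)$betweenness, net$nodes)
    expect_equal(unname(b_us[names(b_ig)]), unname(b_ig), tolerance = 1e-9)
  }
})

test_that("complete equal-weight digraph has zero betweenness everywhere", {
  log <- do.call(mk_log, {
    prs <- expand.grid(a = ten[1:5], b = ten[1:5], stringsAsFactors = FALSE)
    prs <- prs[prs$a != prs$b, ]
    lapply(seq_len(nrow(prs)), function(i) c(prs$a[i], prs$b[i]))
  })
  net <- build_adjacency(log, ten[1:5])
  cs <- shortest_path_census(edge_distances(net, "reciprocal"))
  expect_true(all(betweenness_centrality(cs)$betweenness == 0))
})

test_that("scaling pass counts scales closeness and fixes betweenness", {
  set.seed(33)
  for (rep in 1:10) {
    net <- random_pass_digraph(n = 5, p_edge = 0.7)
    net_k <- net
    net_k$A <- net$A * 3L
    c1 <- centrality_scores(net, "reciprocal")
    c3 <- centrality_scores(net_k, "reciprocal")
    expect_equal(c3$closeness, 3 * c1$closeness)
    expect_equal(c3$betweenness, c1$betweenness)
  }
})

test_that("GraphML export round-trips the adjacency", {
  log <- mk_log(c("p1", "p2"), c("p2", "p3"), c("p3", "p1"), c("p1", "p2"))
  net <- build_adjacency(log, ten)
  sc <- centrality_scores(net)
  path <- tempfile(fileext = ".graphml")
  export_network(net, sc, path)
  back <- import_network(path)
  expect_equal(back$A[net$nodes, net$nodes], net$A)

  empty <- build_adjacency(mk_log()[0, ], ten)
  path2 <- tempfile(fileext = ".graphml")
  export_network(empty, NULL, path2)
  back2 <- import_network(path2)
  expect_equal(length(back2$nodes), 10)
  expect_true(all(back2$A == 0))
})
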