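two_triangles_bridge <- function() {
  anatomical_network(letters[1:6],
    rbind(c("a", "b"), c("b", "c"), c("a", "c"),
          c("d", "e"), c("e", "f"), c("d", "f"), c("c", "d")))
}

test_that("modularity matches hand-evaluated values", {
  net <- two_triangles_bridge()
  expect_equal(modularity_score(net, setNames(rep(0, 6), letters[1:6])), 0)
  split <- setNames(c(0, 0, 0, 1, 1, 1), letters[1:6])
  expect_equal(modularity_score(net, split), 5 / 14)
  tri <- anatomical_network(c("a", "b", "c"),
                            rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(modularity_score(tri, setNames(0:2, c("a", "b", "c"))), -1 / 3)
  expect_error(modularity_score(net, setNames(rep(0, 5), letters[1:5])),
               "missing")
  expect_error(modularity_score(anatomical_network(c("a", "b")),
                                setNames(c(0, 0), c("a", "b"))), "link")
})

test_that("modularity agrees with an independent implementation", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    net <- rand_net(sample(4:9, 1), p = 0.5, seed = seed)
    if (n_links(net) == 0) next
    p <- sample(0:2, n_nodes(net), replace = TRUE)
    names(p) <- net$nodes
    expect_equal(modularity_score(net, p),
                 igraph::modularity(as_igraph(net), p + 1),
                 tolerance = 1e-12)
    expect_equal(modularity_score(net, p), oracle_modularity(net, p),
                 tolerance = 1e-12)
  }
})

test_that("greedy detection recovers the two-triangle split and flat cliques", {
  net <- two_triangles_bridge()
  part <- detect_modules_greedy(net)
  expect_equal(n_modules(part), 2)
  expect_equal(part$Q, 5 / 14)
  expect_equal(unname(part$assignment[c("a", "b", "c")]), rep(0, 3))
  expect_equal(unname(part$assignment[c("d", "e", "f")]), rep(1, 3))

  k5 <- anatomical_network(letters[1:5], t(combn(letters[1:5], 2)))
  flat <- detect_modules_greedy(k5)
  expect_equal(n_modules(flat), 1)
  expect_equal(flat$Q, 0)
})

test_that("partition invariants hold: coverage, gap-free ids, Q bounds", {
  for (seed in 1:20) {
    net <- rand_net(sample(4:9, 1), p = 0.5, seed = seed)
    if (n_links(net) == 0) next
    part <- detect_modules_greedy(net)
    expect_setequal(names(part$assignment), net$nodes)
    ids <- sort(unique(part$assignment))
    expect_equal(ids, seq_along(ids) - 1)       # consecutive from 0
    expect_gte(part$Q, 0)                        # never worse than one module
    expect_lte(part$Q, 1)
    expect_equal(part$Q, oracle_modularity(net, part$assignment),
                 tolerance = 1e-12)
  }
})

test_that("greedy matches exhaustive search on small graphs, gap recorded", {
  gaps <- numeric(0)
  for (seed in 1:25) {
    net <- rand_net(sample(4:7, 1), p = 0.5, seed = seed, connected = TRUE)
    if (n_links(net) == 0) next
    greedy <- detect_modules_greedy(net)
    exact <- detect_modules_exhaustive(net)
    expect_lte(greedy$Q, exact$Q + 1e-12)
    gaps <- c(gaps, exact$Q - greedy$Q)
  }
  # the agglomeration is a heuristic: any optimality gap is recorded, and
  # on this suite it must at least find the optimum most of the time
  expect_gte(mean(gaps < 1e-9), 0.8)
  expect_lt(max(gaps), 0.15)
})

test_that("exhaustive optimizer certifies the two known optima", {
  net <- two_triangles_bridge()
  expect_equal(detect_modules_exhaustive(net)$Q, 5 / 14)
  k5 <- anatomical_network(letters[1:5], t(combn(letters[1:5], 2)))
  expect_equal(detect_modules_exhaustive(k5)$Q, 0)
  expect_error(detect_modules_exhaustive(rand_net(13, 0.5, seed = 1)), "capped")
})

test_that("detection is deterministic for a fixed input and node order", {
  net <- rand_net(9, 0.4, seed = 99)
  a <- detect_modules_greedy(net)
  b <- detect_modules_greedy(net)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$merge_trace, b$merge_trace)
})

test_that("adjusted Rand behaves as a chance-corrected partition distance", {
  p1 <- setNames(c(0, 0, 1, 1, 2, 2), letters[1:6])
  expect_equal(adjusted_rand(p1, p1), 1)
  relabeled <- setNames(c(7, 7, 3, 3, 5, 5), letters[1:6])
  expect_equal(adjusted_rand(p1, relabeled), 1)
  singletons <- setNames(0:5, letters[1:6])
  lumped <- setNames(rep(0, 6), letters[1:6])
  expect_lte(adjusted_rand(singletons, lumped), 0)
  expect_error(adjusted_rand(p1, setNames(c(0, 0), c("a", "b"))),
               "different node sets")
})

test_that("adjusted Rand agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:15, 1)
    p1 <- setNames(sample(0:3, n, replace = TRUE), sprintf("v%d", 1:n))
    p2 <- setNames(sample(0:3, n, replace = TRUE), sprintf("v%d", 1:n))
    expect_equal(adjusted_rand(p1, p2),
                 mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
  }
})
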