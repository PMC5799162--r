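test_that("read_adjacency builds the network a matrix describes", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 1
  m["b", "c"] <- m["c", "b"] <- 1
  net <- read_adjacency(write_matrix_file(m))
  expect_equal(n_nodes(net), 3)
  expect_equal(n_links(net), 2)
  expect_setequal(edge_keys(net), c("a|b", "b|c"))
  expect_equal(net$nodes, c("a", "b", "c"))  # header order preserved
})

test_that("K equals half the off-diagonal sum on random matrices", {
  for (seed in 1:10) {
    net <- rand_net(sample(4:9, 1), p = 0.5, seed = seed)
    m <- adj_matrix_of(net)
    back <- read_adjacency(write_matrix_file(m))
    expect_equal(n_links(back), sum(m) / 2)
    expect_setequal(edge_keys(back), edge_keys(net))
  }
})

test_that("invalid matrices are rejected with informative errors", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  bad <- m; bad["a", "b"] <- 1   # one-sided entry
  expect_error(read_adjacency(write_matrix_file(bad)), "asymmetric")
  expect_warning(
    net <- read_adjacency(write_matrix_file(bad),
                          matrix_dialect(symmetrize = "union")),
    "symmetrized")
  expect_equal(n_links(net), 1)

  bad <- m; diag(bad) <- 1
  expect_error(read_adjacency(write_matrix_file(bad)), "diagonal")
  expect_warning(
    net <- read_adjacency(write_matrix_file(bad),
                          matrix_dialect(strip_diagonal = TRUE)),
    "diagonal")
  expect_equal(n_links(net), 0)

  bad <- m; bad["a", "b"] <- bad["b", "a"] <- 2
  expect_error(read_adjacency(write_matrix_file(bad)), "binary")

  nonsq <- as.data.frame(m)[1:2, ]
  p <- tempfile(fileext = ".csv"); write.csv(nonsq, p, quote = FALSE)
  expect_error(read_adjacency(p), "non-square")

  mislab <- m; rownames(mislab) <- c("a", "b", "x")
  expect_error(read_adjacency(write_matrix_file(mislab)), "header")
})

test_that("a 37-node, 72-link skull-sized matrix reads back as N=37, K=72", {
  net <- make_fixture_network(37, 72, seed = 42, taxon_id = "Homo")
  back <- read_adjacency(write_matrix_file(adj_matrix_of(net)))
  expect_equal(n_nodes(back), 37)
  expect_equal(n_links(back), 72)
})

test_that("metadata files are validated against the vocabulary", {
  meta <- data.frame(node = c("orbicularis_oris_L", "premaxilla"),
                     tissue = c("muscle", "bone"),
                     side = c("left", "median"),
                     group = c("hyoid", "skeletal"),
                     is_facial_expression = c("true", "false"))
  p <- tempfile(fileext = ".csv"); write.csv(meta, p, row.names = FALSE)
  got <- read_metadata(p)
  expect_equal(nrow(got), 2)
  expect_true(got$is_facial_expression[1])
  expect_false(got$is_facial_expression[2])

  meta$is_facial_expression <- c("true", "true")   # facial flag on a bone
  write.csv(meta, p, row.names = FALSE)
  expect_error(read_metadata(p), "non-muscle")

  meta$is_facial_expression <- c("true", "false")
  meta$group[1] <- "mimetic"                        # not in the vocabulary
  write.csv(meta, p, row.names = FALSE)
  expect_error(read_metadata(p), "unknown group")

  meta$group[1] <- "hyoid"
  meta$node[2] <- "orbicularis_oris_L"              # duplicate node
  write.csv(meta, p, row.names = FALSE)
  expect_error(read_metadata(p), "duplicate")
})

test_that("one metadata row per node yields a complete map", {
  nodes <- sprintf("u%d", 1:6)
  meta <- toy_meta(nodes)
  p <- tempfile(fileext = ".tsv")
  write.table(meta, p, sep = "\t", row.names = FALSE, quote = FALSE)
  got <- read_metadata(p)
  expect_equal(nrow(got), 6)
  net <- anatomical_network(nodes, cbind(nodes[1:5], nodes[2:6]), got)
  expect_equal(net$n_defaulted_meta, 0)
})

test_that("missing metadata defaults are flagged and side falls back to name suffix", {
  nodes <- c("masseter_L", "masseter_R", "mandible")
  expect_warning(
    net <- anatomical_network(nodes, cbind(nodes[1:2], nodes[c(3, 3)]),
                              toy_meta("mandible")),
    "defaulted")
  expect_equal(net$n_defaulted_meta, 2)
  expect_equal(net$meta$side, c("left", "right", "median"))
})

test_that("network invariants are enforced at construction", {
  expect_error(anatomical_network(c("a", "b"), rbind(c("a", "a"))), "self-loop")
  expect_error(anatomical_network(c("a", "b"), rbind(c("a", "z"))), "unknown node")
  net <- anatomical_network(c("a", "b"), rbind(c("a", "b"), c("b", "a")))
  expect_equal(n_links(net), 1)   # duplicate unordered pair collapsed
})

test_that("round-trip identity holds for every format on random networks", {
  for (seed in 1:8) {
    net <- rand_net(sample(3:9, 1), p = 0.45, seed = seed)
    net$meta$tissue <- sample(c("bone", "muscle"), n_nodes(net), replace = TRUE)
    net$meta$is_facial_expression <- net$meta$tissue == "muscle" &
      runif(n_nodes(net)) < 0.5
    for (fmt in c("graphml", "gml", "edge_list")) {
      f <- tempfile()
      write_network(net, f, fmt)
      back <- read_network(f, fmt)
      expect_setequal(back$nodes, net$nodes)
      expect_setequal(edge_keys(back), edge_keys(net))
      if (fmt != "edge_list") {
        o <- order(net$meta$node); ob <- order(back$meta$node)
        expect_equal(back$meta[ob, ], net$meta[o, ], ignore_attr = TRUE)
        expect_equal(back$taxon_id, net$taxon_id)
      }
    }
  }
})

test_that("edge list keeps isolated nodes and an empty edge set round-trips", {
  net <- anatomical_network(c("a", "b", "c"), taxon_id = "lonely")
  f <- tempfile()
  write_network(net, f, "edge_list")
  back <- read_network(f, "edge_list")
  expect_setequal(back$nodes, c("a", "b", "c"))
  expect_equal(n_links(back), 0)
  expect_equal(back$taxon_id, "lonely")
})

test_that("unsupported format tokens are rejected", {
  net <- anatomical_network(c("a", "b"), rbind(c("a", "b")))
  expect_error(write_network(net, tempfile(), "dot"))
})
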