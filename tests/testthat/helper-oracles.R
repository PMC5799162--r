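# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (triple enumeration, Floyd-Warshall, direct formulas)
# and never call the implementation paths they are used to check.

# random simple graph as an anatomical_network
rand_net <- function(n, p = 0.4, seed = NULL, connected = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    nodes <- sprintf("v%02d", seq_len(n))
    pairs <- t(combn(seq_len(n), 2))
    on <- runif(nrow(pairs)) < p
    edges <- cbind(nodes[pairs[on, 1]], nodes[pairs[on, 2]])
    net <- suppressWarnings(anatomical_network(nodes, edges))
    if (!connected || oracle_is_connected(net)) return(net)
  }
}

adj_matrix_of <- function(net) {
  n <- length(net$nodes)
  m <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges[, 1], net$nodes)
    j <- match(net$edges[, 2], net$nodes)
    m[cbind(i, j)] <- 1
    m[cbind(j, i)] <- 1
  }
  m
}

oracle_density <- function(net) {
  n <- length(net$nodes)
  sum(adj_matrix_of(net)) / (n * (n - 1))
}

# mean local clustering by enumerating all node triples
oracle_clustering <- function(net) {
  a <- adj_matrix_of(net)
  n <- nrow(a)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (x in seq_len(k - 1)) for (y in (x + 1):k)
      links <- links + a[nb[x], nb[y]]
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(ci)
}

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(net) {
  a <- adj_matrix_of(net)
  n <- nrow(a)
  d <- ifelse(a == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_path_length <- function(net) {
  d <- oracle_distances(net)
  mean(d[upper.tri(d)])
}

oracle_is_connected <- function(net) {
  all(is.finite(oracle_distances(net)))
}

oracle_heterogeneity <- function(net) {
  k <- rowSums(adj_matrix_of(net))
  sqrt(mean((k - mean(k))^2)) / mean(k)
}

# Newman-Girvan Q evaluated directly from its definition
oracle_modularity <- function(net, assignment) {
  p <- assignment[net$nodes]
  m <- nrow(net$edges)
  deg <- rowSums(adj_matrix_of(net))
  mods <- unique(p)
  sum(vapply(mods, function(mod) {
    within <- sum(p[net$edges[, 1]] == mod & p[net$edges[, 2]] == mod) / m
    a <- sum(deg[p == mod]) / (2 * m)
    within - a^2
  }, numeric(1)))
}

# a connected network with exactly n nodes and k links:
# random spanning tree plus k - (n-1) random extra non-edges
make_fixture_network <- function(n, k, seed = 1, taxon_id = "fixture") {
  stopifnot(k >= n - 1, k <= n * (n - 1) / 2)
  set.seed(seed)
  nodes <- sprintf("unit_%03d", seq_len(n))
  ord <- sample(n)
  tree <- cbind(ord[vapply(2:n, function(i) sample(i - 1, 1), integer(1))],
                ord[2:n])
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  pairs <- t(combn(seq_len(n), 2))
  free <- pairs[!(key(pairs) %in% key(tree)), , drop = FALSE]
  extra <- free[sample(nrow(free), k - (n - 1)), , drop = FALSE]
  e <- rbind(tree, extra)
  suppressWarnings(anatomical_network(
    nodes, cbind(nodes[e[, 1]], nodes[e[, 2]]), taxon_id = taxon_id))
}

edge_keys <- function(net) {
  apply(net$edges, 1, function(r) paste(sort(r), collapse = "|"))
}

write_matrix_file <- function(m, path = tempfile(fileext = ".csv")) {
  write.csv(as.data.frame(m), path, quote = FALSE)
  path
}

toy_meta <- function(nodes, tissue = "bone", side = NULL, group = "other",
                     facial = FALSE) {
  data.frame(node = nodes, tissue = tissue,
             side = if (is.null(side))
               ifelse(grepl("_L$", nodes), "left",
                      ifelse(grepl("_R$", nodes), "right", "median"))
             else side,
             group = group, is_facial_expression = facial,
             stringsAsFactors = FALSE)
}
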