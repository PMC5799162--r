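#' Density of connections (D)
#'
#' Fraction of realized links out of all possible, `D = 2K / (N(N-1))`.
#' In AnNA, D serves as a proxy for the complexity of a morphological
#' structure: the number of potential functional interactions grows with the
#' number of connections among parts.
#'
#' @param net An [anatomical_network()].
#' @return Density in `[0, 1]`, full precision (report tables round to 3
#'   decimals, see [format_parameters()]).
#' @export
#' @examples
#' g <- anatomical_network(letters[1:4],
#'                         t(combn(letters[1:4], 2)))  # complete graph
#' net_density(g)  # 1
net_density <- function(net) {
  n <- n_nodes(net)
  if (n < 2) stop("density needs at least 2 nodes")
  2 * n_links(net) / (n * (n - 1))
}

#' Average clustering coefficient (C)
#'
#' Mean over nodes of the local clustering coefficient: for node i with
#' degree k_i >= 2, the number of links among its neighbours divided by
#' `k_i (k_i - 1) / 2`; nodes of degree 0 or 1 contribute 0. Computed on the
#' analysis component (see [parameter_set()] for the component policy).
#' Higher C accompanies higher integration.
#'
#' @param net An [anatomical_network()].
#' @return Mean local clustering coefficient in `[0, 1]`.
#' @export
avg_clustering <- function(net) {
  if (n_nodes(net) == 0) stop("empty network")
  g <- as_igraph(net)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(ci)
}

#' Characteristic path length (L)
#'
#' Mean shortest-path distance over all unordered node pairs of the graph,
#' each link counting one length unit. The graph must be connected with at
#' least two nodes; [parameter_set()] applies the largest-component policy
#' before calling this. Lower L accompanies higher integration.
#'
#' @param net An [anatomical_network()]; must be connected.
#' @return Mean geodesic length, `>= 1` for any graph with an edge.
#' @export
avg_path_length <- function(net) {
  if (n_nodes(net) < 2) stop("path length needs a component with >= 2 nodes")
  g <- as_igraph(net)
  d <- igraph::distances(g)
  ut <- d[upper.tri(d)]
  if (any(!is.finite(ut))) stop("graph is disconnected; path length undefined")
  mean(ut)
}

#' Degree heterogeneity (H)
#'
#' Coefficient of variation of the degree sequence, `H = sigma(k) / mu(k)`,
#' using the population standard deviation (the degree sequence is the whole
#' population of the network, and this keeps results bit-reproducible).
#' H = 0 exactly for degree-regular graphs; higher H indicates greater
#' anisomerism (differentiation among repeated parts).
#'
#' @param net An [anatomical_network()].
#' @return Nonnegative ratio.
#' @export
degree_heterogeneity <- function(net) {
  if (n_nodes(net) < 2) stop("heterogeneity needs at least 2 nodes")
  k <- node_degrees(net)
  mu <- mean(k)
  if (mu == 0) stop("all nodes isolated; mean degree is zero")
  sqrt(mean((k - mu)^2)) / mu
}

#' The six-parameter AnNA summary of a network
#'
#' Computes node count N, link count K, density D, mean clustering
#' coefficient C, characteristic path length L and degree heterogeneity H.
#' N, K and D describe the full graph. If the graph is disconnected, C, L and
#' H are computed on the largest connected component (with a warning); the
#' `connected` flag and `component_used` record the policy outcome so a
#' single L per network stays defined.
#'
#' @param net An [anatomical_network()].
#' @return An object of class `network_parameters`: list with `taxon_id`,
#'   `N`, `K`, `D`, `C`, `L`, `H`, `connected`, `component_used`.
#' @export
#' @examples
#' net <- anatomical_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' parameter_set(net)
parameter_set <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  n <- n_nodes(net)
  if (n < 2) stop("parameter set needs at least 2 nodes")
  comp_nodes <- largest_component(net)
  connected <- length(comp_nodes) == n
  comp <- if (connected) net else induced_network(net, comp_nodes)
  if (!connected)
    warning(sprintf(
      "disconnected graph: C, L, H computed on largest component (%d of %d nodes)",
      length(comp_nodes), n))
  structure(list(
    taxon_id = net$taxon_id,
    N = n, K = n_links(net), D = net_density(net),
    C = avg_clustering(comp),
    L = avg_path_length(comp),
    H = degree_heterogeneity(comp),
    connected = connected,
    component_used = length(comp_nodes)
  ), class = "network_parameters")
}

#' Round a parameter set to report precision
#'
#' Report tables print D to 3 decimals and C, L, H to 2, matching the
#' precision at which these statistics are conventionally published.
#'
#' @param params A `network_parameters` object (or a list with the same
#'   fields).
#' @return A one-row data frame.
#' @export
format_parameters <- function(params) {
  data.frame(
    taxon_id = params$taxon_id,
    N = params$N, K = params$K,
    D = round(params$D, 3),
    C = round(params$C, 2),
    L = round(params$L, 2),
    H = round(params$H, 2),
    connected = params$connected,
    component_used = params$component_used,
    stringsAsFactors = FALSE
  )
}

#' @export
print.network_parameters <- function(x, ...) {
  cat(sprintf("network parameters for '%s'\n", x$taxon_id))
  cat(sprintf("  N = %d, K = %d, D = %.3f, C = %.2f, L = %.2f, H = %.2f\n",
              x$N, x$K, x$D, x$C, x$L, x$H))
  if (!x$connected)
    cat(sprintf("  disconnected: C/L/H on largest component (%d nodes)\n",
                x$component_used))
  invisible(x)
}
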