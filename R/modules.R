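#' Construct a module partition
#'
#' A partition assigns every node of a network to exactly one module. Module
#' ids are renumbered to consecutive integers starting at 0, in order of
#' first appearance along the node order.
#'
#' @param assignment Named vector (names = nodes) of module labels, or an
#'   unnamed vector parallel to `nodes`.
#' @param net Optional [anatomical_network()] used to check coverage and to
#'   compute the modularity score `Q`.
#' @param method Text tag recording how the partition was obtained.
#' @param merge_trace Optional data frame of agglomeration steps.
#' @return An object of class `anna_partition` with fields `assignment`
#'   (named 0-based integers), `Q`, `method`, `merge_trace`.
#' @export
as_partition <- function(assignment, net = NULL, method = "manual",
                         merge_trace = NULL) {
  if (is.null(names(assignment))) {
    if (is.null(net)) stop("unnamed assignment needs a network for node names")
    if (length(assignment) != n_nodes(net))
      stop("assignment length does not match node count")
    names(assignment) <- net$nodes
  }
  if (!is.null(net)) {
    miss <- setdiff(net$nodes, names(assignment))
    if (length(miss) > 0)
      stop("node(s) missing from partition: ", paste(miss, collapse = ", "))
    extra <- setdiff(names(assignment), net$nodes)
    if (length(extra) > 0)
      stop("partition covers unknown node(s): ", paste(extra, collapse = ", "))
    assignment <- assignment[net$nodes]
  }
  ids <- match(assignment, unique(assignment)) - 1L
  names(ids) <- names(assignment)
  q <- if (!is.null(net) && n_links(net) > 0) modularity_score(net, ids) else NA_real_
  structure(list(assignment = ids, Q = q, method = method,
                 merge_trace = merge_trace),
            class = "anna_partition")
}

#' @export
print.anna_partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("partition (%s): %d nodes in %d module(s), Q = %s\n",
              x$method, length(x$assignment), k,
              ifelse(is.na(x$Q), "NA", sprintf("%.4f", x$Q))))
  invisible(x)
}

partition_vector <- function(partition) {
  if (inherits(partition, "anna_partition")) partition$assignment else partition
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_m (e_mm - a_m^2)` over modules m, where `e_mm` is the fraction of
#' links with both ends in m and `a_m` the fraction of link ends in m. Q is 0
#' for the single-module partition and bounded by `[-0.5, 1]`.
#'
#' @param net An [anatomical_network()] with at least one link.
#' @param partition An `anna_partition` or named module-id vector covering
#'   every node.
#' @return Modularity score.
#' @export
#' @examples
#' tri <- anatomical_network(c("a","b","c"),
#'                           rbind(c("a","b"), c("b","c"), c("a","c")))
#' modularity_score(tri, c(a = 0, b = 0, c = 0))   # 0
#' modularity_score(tri, c(a = 0, b = 1, c = 2))   # -1/3
modularity_score <- function(net, partition) {
  p <- partition_vector(partition)
  m <- n_links(net)
  if (m < 1) stop("modularity needs at least one link")
  miss <- setdiff(net$nodes, names(p))
  if (length(miss) > 0)
    stop("node(s) missing from partition: ", paste(miss, collapse = ", "))
  p <- p[net$nodes]
  mods <- unique(p)
  same <- p[net$edges[, 1]] == p[net$edges[, 2]]
  e_mm <- vapply(mods, function(mod)
    sum(same & p[net$edges[, 1]] == mod), numeric(1)) / m
  deg <- node_degrees(net)
  a_m <- vapply(mods, function(mod) sum(deg[p == mod]), numeric(1)) / (2 * m)
  sum(e_mm - a_m^2)
}

#' Greedy agglomerative module detection (CNM)
#'
#' Deterministic Clauset-Newman-Moore agglomeration: start from singleton
#' modules and repeatedly merge the pair of modules with the largest
#' modularity gain `dQ`, while the best gain is positive. At equal gain the
#' lexicographically smallest pair of module labels is merged (labels are the
#' smallest original node index in each module), so the result is fully
#' determined by the input matrix and its node order. The returned partition
#' is the one at maximal Q along the merge trace.
#'
#' @param net An [anatomical_network()] with at least one link.
#' @return An `anna_partition` with `method = "greedy_cnm"` and a
#'   `merge_trace` data frame (columns `mod_a`, `mod_b`, `dQ`, `Q_after`).
#' @export
detect_modules_greedy <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  n <- n_nodes(net)
  m <- n_links(net)
  if (n == 0) stop("empty graph")
  if (m < 1) stop("module detection needs at least one link")

  # B[i,j] = A[i,j]/(2m): fraction of link ends; rowSums give a_i
  B <- matrix(0, n, n)
  ei <- match(net$edges[, 1], net$nodes)
  ej <- match(net$edges[, 2], net$nodes)
  B[cbind(ei, ej)] <- 1 / (2 * m)
  B[cbind(ej, ei)] <- 1 / (2 * m)

  active <- rep(TRUE, n)
  label <- seq_len(n)          # module label = smallest member's node index
  member_of <- seq_len(n)      # node -> row index of its module
  a <- rowSums(B)
  diag(B) <- 0
  Q <- -sum(a^2)               # singleton partition
  best_Q <- Q
  best_membership <- member_of
  trace <- list()

  repeat {
    act <- which(active)
    if (length(act) < 2) break
    # dQ for merging i,j = 2*B[i,j] - 2*a_i*a_j; only linked pairs can gain
    dq <- 2 * B[act, act, drop = FALSE] -
      2 * outer(a[act], a[act])
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    mx <- max(dq)
    if (mx <= 1e-12) break
    cand <- which(dq >= mx - 1e-12, arr.ind = TRUE)
    lab_pairs <- cbind(pmin(label[act[cand[, 1]]], label[act[cand[, 2]]]),
                       pmax(label[act[cand[, 1]]], label[act[cand[, 2]]]))
    pick <- order(lab_pairs[, 1], lab_pairs[, 2])[1]
    i <- act[cand[pick, 1]]; j <- act[cand[pick, 2]]
    if (label[j] < label[i]) { tmp <- i; i <- j; j <- tmp }
    gain <- 2 * B[i, j] - 2 * a[i] * a[j]

    # merge j into i
    B[i, ] <- B[i, ] + B[j, ]
    B[, i] <- B[, i] + B[, j]
    B[i, i] <- 0
    a[i] <- a[i] + a[j]
    active[j] <- FALSE
    member_of[member_of == j] <- i
    Q <- Q + gain
    trace[[length(trace) + 1]] <-
      data.frame(mod_a = label[i], mod_b = label[j], dQ = gain, Q_after = Q)
    if (Q > best_Q + 1e-12) {
      best_Q <- Q
      best_membership <- member_of
    }
  }

  trace <- if (length(trace) > 0) do.call(rbind, trace) else
    data.frame(mod_a = integer(0), mod_b = integer(0),
               dQ = numeric(0), Q_after = numeric(0))
  as_partition(setNames(best_membership, net$nodes), net,
               method = "greedy_cnm", merge_trace = trace)
}

# enumerate set partitions of n items as restricted growth strings,
# calling f(assignment) for each; used by the exhaustive optimizer
for_each_partition <- function(n, f) {
  p <- integer(n)
  recurse <- function(i, kmax) {
    if (i > n) { f(p); return(invisible(NULL)) }
    for (b in seq_len(kmax + 1)) {
      p[i] <<- b
      recurse(i + 1, max(kmax, b))
    }
  }
  recurse(1L, 0L)
}

#' Exhaustive modularity optimization over all partitions
#'
#' Enumerates every set partition of the nodes (restricted growth strings)
#' and returns one with maximal Newman-Girvan Q. Intended as the exact
#' optimum for small graphs; the Bell numbers make it practical only to
#' about 10 nodes (capped at 12).
#'
#' @param net An [anatomical_network()] with 2..12 nodes and >= 1 link.
#' @return An `anna_partition` with `method = "exhaustive"`.
#' @export
detect_modules_exhaustive <- function(net) {
  n <- n_nodes(net)
  if (n > 12) stop("exhaustive search capped at 12 nodes")
  if (n_links(net) < 1) stop("module detection needs at least one link")
  deg <- node_degrees(net)
  m <- n_links(net)
  ei <- match(net$edges[, 1], net$nodes)
  ej <- match(net$edges[, 2], net$nodes)
  best <- list(Q = -Inf, p = NULL)
  for_each_partition(n, function(p) {
    within <- sum(p[ei] == p[ej]) / m
    dsum <- tapply(deg, p, sum) / (2 * m)
    q <- within - sum(dsum^2)
    if (q > best$Q + 1e-12) best <<- list(Q = q, p = p)
  })
  as_partition(setNames(best$p, net$nodes), net, method = "exhaustive")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same node set:
#' 1 iff identical up to relabeling, about 0 for independent partitions,
#' negative for less-than-chance agreement.
#'
#' @param p1,p2 `anna_partition` objects or named module-id vectors over the
#'   same nodes.
#' @return Score in `[-1, 1]`.
#' @export
adjusted_rand <- function(p1, p2) {
  v1 <- partition_vector(p1)
  v2 <- partition_vector(p2)
  if (is.null(names(v1)) || is.null(names(v2)))
    stop("partitions must be named by node")
  if (!setequal(names(v1), names(v2)))
    stop("partitions cover different node sets")
  v2 <- v2[names(v1)]
  tab <- table(v1, v2)
  nch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(nch2(tab))
  sum_a <- sum(nch2(rowSums(tab)))
  sum_b <- sum(nch2(colSums(tab)))
  n2 <- nch2(sum(tab))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)   # both trivial partitions agree perfectly
  (sum_ij - expected) / (mx - expected)
}

#' Number of modules in a partition
#'
#' @param partition An `anna_partition` or module-id vector.
#' @return Integer count.
#' @export
n_modules <- function(partition) length(unique(partition_vector(partition)))
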