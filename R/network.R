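#' Controlled vocabularies for node metadata
#'
#' Tissue classes, body sides and muscle groups recognized in node metadata.
#' Muscle groups follow the classical innervation-based grouping of head and
#' neck muscles (mandibular/V, hyoid/VII, branchial/IX-XI, extraocular,
#' hypobranchial/XII); skeletal units take group `"skeletal"`.
#'
#' @return A named list of character vectors (`tissue`, `side`, `group`).
#' @export
#' @examples
#' meta_vocabulary()$tissue
meta_vocabulary <- function() {
  list(
    tissue = c("bone", "cartilage", "muscle"),
    side   = c("left", "right", "median"),
    group  = c("mandibular", "hyoid", "branchial", "extraocular",
               "hypobranchial", "skeletal", "other")
  )
}

default_node_meta <- function(node) {
  data.frame(
    node = node,
    tissue = "bone",
    side = side_from_name(node),
    group = "other",
    is_facial_expression = FALSE,
    stringsAsFactors = FALSE
  )
}

# "_L"/"_R" name suffixes as a laterality fallback when metadata omits side
side_from_name <- function(node) {
  ifelse(grepl("_L$", node), "left",
         ifelse(grepl("_R$", node), "right", "median"))
}

canonical_edges <- function(from, to) {
  e <- cbind(pmin(from, to), pmax(from, to))
  colnames(e) <- c("from", "to")
  e <- e[!duplicated(paste(e[, 1], e[, 2], sep = "\r")), , drop = FALSE]
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Construct an anatomical network
#'
#' An anatomical network is an undirected simple labeled graph over named
#' anatomical units, with one metadata record per node (tissue, body side,
#' muscle group, facial-expression flag). Self-loops and duplicate edges are
#' rejected; edges are stored canonically as unordered pairs. Nodes without a
#' metadata record receive a flagged default (`bone`/`other`, side inferred
#' from a `_L`/`_R` name suffix, not a facial-expression muscle).
#'
#' @param nodes Character vector of unique unit names (node order is kept).
#' @param edges Two-column character matrix or data frame of node pairs.
#' @param metadata Optional data frame with columns `node`, `tissue`, `side`,
#'   `group`, `is_facial_expression` (see [meta_vocabulary()]).
#' @param taxon_id Text label for the taxon the network describes.
#'
#' @return An object of class `anatomical_network`: a list with elements
#'   `taxon_id`, `nodes`, `edges` (canonical two-column matrix), `meta`
#'   (one row per node, in node order) and `n_defaulted_meta` (number of
#'   nodes whose metadata was defaulted).
#' @export
#' @examples
#' net <- anatomical_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' net
anatomical_network <- function(nodes, edges = NULL, metadata = NULL,
                               taxon_id = "unnamed_taxon") {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (length(nodes) == 0) stop("network needs at least one node")

  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns")
    storage.mode(edges) <- "character"
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    missing <- setdiff(c(edges), nodes)
    if (length(missing) > 0)
      stop("edge references unknown node(s): ", paste(missing, collapse = ", "))
    edges <- canonical_edges(edges[, 1], edges[, 2])
  }

  n_defaulted <- 0L
  if (is.null(metadata)) {
    meta <- default_node_meta(nodes)
    n_defaulted <- length(nodes)
  } else {
    meta <- validate_metadata(metadata)
    absent <- setdiff(nodes, meta$node)
    extra <- setdiff(meta$node, nodes)
    if (length(extra) > 0)
      stop("metadata for unknown node(s): ", paste(extra, collapse = ", "))
    if (length(absent) > 0) {
      meta <- rbind(meta, default_node_meta(absent))
      n_defaulted <- length(absent)
      warning(sprintf("metadata defaulted for %d node(s)", n_defaulted))
    }
    meta <- meta[match(nodes, meta$node), , drop = FALSE]
    rownames(meta) <- NULL
  }

  structure(
    list(taxon_id = taxon_id, nodes = nodes, edges = edges, meta = meta,
         n_defaulted_meta = n_defaulted),
    class = "anatomical_network"
  )
}

validate_metadata <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needed <- c("node", "tissue", "side", "group", "is_facial_expression")
  miss <- setdiff(needed, names(meta))
  if (length(miss) > 0)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  meta <- meta[, needed]
  meta$node <- as.character(meta$node)
  if (anyDuplicated(meta$node))
    stop("duplicate node in metadata: ",
         paste(unique(meta$node[duplicated(meta$node)]), collapse = ", "))
  voc <- meta_vocabulary()
  for (col in c("tissue", "side", "group")) {
    meta[[col]] <- as.character(meta[[col]])
    bad <- setdiff(unique(meta[[col]]), voc[[col]])
    if (length(bad) > 0)
      stop(sprintf("unknown %s token(s): %s", col, paste(bad, collapse = ", ")))
  }
  meta$is_facial_expression <- parse_flag(meta$is_facial_expression)
  offenders <- meta$node[meta$is_facial_expression & meta$tissue != "muscle"]
  if (length(offenders) > 0)
    stop("facial-expression flag on non-muscle node(s): ",
         paste(offenders, collapse = ", "))
  rownames(meta) <- NULL
  meta
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) stop("unparseable is_facial_expression value(s)")
  out
}

#' @export
print.anatomical_network <- function(x, ...) {
  cat(sprintf("anatomical_network '%s': %d nodes, %d links\n",
              x$taxon_id, length(x$nodes), nrow(x$edges)))
  tt <- table(x$meta$tissue)
  cat("  tissues:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  if (x$n_defaulted_meta > 0)
    cat(sprintf("  (%d node(s) with defaulted metadata)\n", x$n_defaulted_meta))
  invisible(x)
}

#' Number of nodes and links of an anatomical network
#'
#' @param net An `anatomical_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_links <- function(net) nrow(net$edges)

#' Convert an anatomical network to an igraph object
#'
#' Node metadata becomes vertex attributes; the taxon label becomes the graph
#' attribute `taxon_id`.
#'
#' @param net An `anatomical_network`.
#' @return An undirected [igraph::igraph] graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0) {
    idx <- rbind(match(net$edges[, 1], net$nodes),
                 match(net$edges[, 2], net$nodes))
    g <- igraph::add_edges(g, as.vector(idx))
  }
  for (col in c("tissue", "side", "group", "is_facial_expression"))
    g <- igraph::set_vertex_attr(g, col, value = net$meta[[col]])
  igraph::graph_attr(g, "taxon_id") <- net$taxon_id
  g
}

#' Degree sequence of an anatomical network
#'
#' @param net An `anatomical_network`.
#' @return Named integer vector, in node order.
#' @export
node_degrees <- function(net) {
  d <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0) {
    t1 <- table(factor(net$edges[, 1], levels = net$nodes))
    t2 <- table(factor(net$edges[, 2], levels = net$nodes))
    d <- setNames(as.integer(t1 + t2), net$nodes)
  }
  d
}

# node names of the largest connected component (ties broken by first node)
largest_component <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))[1]
  net$nodes[comp$membership == big]
}

# restriction of the network to a node subset (keeps metadata)
induced_network <- function(net, keep) {
  keep <- intersect(net$nodes, keep)
  e <- net$edges[net$edges[, 1] %in% keep & net$edges[, 2] %in% keep, ,
                 drop = FALSE]
  anatomical_network(keep, e, net$meta[net$meta$node %in% keep, , drop = FALSE],
                     taxon_id = net$taxon_id)
}
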