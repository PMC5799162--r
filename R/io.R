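#' Adjacency-matrix dialect options
#'
#' Controls how [read_adjacency()] validates a connectivity matrix. AnNA
#' networks are unweighted, undirected and have no self-connections, so the
#' strict default requires values in \{0, 1\}, a zero diagonal and an exactly
#' symmetric matrix.
#'
#' @param sep Field separator; `NULL` picks `","` for `.csv` files and tab
#'   otherwise.
#' @param strip_diagonal If `TRUE`, nonzero diagonal entries are zeroed with a
#'   warning instead of raising an error (legacy hand-coded files).
#' @param symmetrize `"strict"` (default) errors on any asymmetric entry
#'   pair; `"union"` ORs the two triangles and warns, for matrices where a
#'   connection was coded on one side only.
#'
#' @return A list of class `matrix_dialect`.
#' @export
matrix_dialect <- function(sep = NULL, strip_diagonal = FALSE,
                           symmetrize = c("strict", "union")) {
  structure(list(sep = sep, strip_diagonal = strip_diagonal,
                 symmetrize = match.arg(symmetrize)),
            class = "matrix_dialect")
}

guess_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a binary connectivity matrix as an anatomical network
#'
#' The file must be a square table whose first row and first column hold the
#' same unit names in the same order; off-diagonal cells are 1 where two units
#' are physically connected (articulation, suture, muscle attachment) and 0
#' otherwise. The resulting link count K equals half the off-diagonal sum.
#'
#' @param matrix_file Path to a CSV/TSV adjacency matrix.
#' @param dialect A [matrix_dialect()].
#' @param metadata Optional metadata data frame or path readable by
#'   [read_metadata()].
#' @param taxon_id Taxon label; defaults to the file name without extension.
#'
#' @return An [anatomical_network()].
#' @export
read_adjacency <- function(matrix_file, dialect = matrix_dialect(),
                           metadata = NULL, taxon_id = NULL) {
  stopifnot(inherits(dialect, "matrix_dialect"))
  sep <- guess_sep(matrix_file, dialect$sep)
  tab <- read.table(matrix_file, sep = sep, header = TRUE, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m))
    stop(sprintf("non-square matrix: %d rows x %d columns", nrow(m), ncol(m)))
  if (!identical(rownames(m), colnames(m)))
    stop("row and column header labels differ")
  if (!is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1)))
    stop("non-binary value(s) in matrix; cells must be 0 or 1")
  if (any(diag(m) != 0)) {
    if (dialect$strip_diagonal) {
      warning(sprintf("zeroed %d nonzero diagonal entr(ies)", sum(diag(m) != 0)))
      diag(m) <- 0
    } else stop("nonzero diagonal (self-loop) not allowed by dialect")
  }
  asym <- which(m != t(m), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    if (dialect$symmetrize == "union") {
      warning(sprintf("symmetrized %d asymmetric entry pair(s) by union",
                      nrow(asym) / 2))
      m <- 1 * ((m + t(m)) > 0)
    } else {
      i <- asym[1, ]
      stop(sprintf("asymmetric entries: (%s,%s) != (%s,%s)",
                   rownames(m)[i[1]], colnames(m)[i[2]],
                   rownames(m)[i[2]], colnames(m)[i[1]]))
    }
  }
  if (is.character(metadata) && length(metadata) == 1)
    metadata <- read_metadata(metadata)
  if (is.null(taxon_id))
    taxon_id <- sub("\\.[^.]*$", "", basename(matrix_file))
  idx <- which(upper.tri(m) & m == 1, arr.ind = TRUE)
  edges <- cbind(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]])
  suppressWarnings(
    anatomical_network(rownames(m), edges, metadata, taxon_id = taxon_id)
  )
}

#' Read a node metadata table
#'
#' Expects columns `node`, `tissue`, `side`, `group`, `is_facial_expression`
#' with the vocabularies of [meta_vocabulary()]; the facial flag accepts
#' true/false, t/f, 1/0, yes/no (case-insensitive). A facial-expression flag
#' on a non-muscle node is an error.
#'
#' @param meta_file Path to a CSV/TSV file.
#' @param sep Field separator; `NULL` guesses from the extension.
#' @return A validated data frame, one row per node.
#' @export
read_metadata <- function(meta_file, sep = NULL) {
  sep <- guess_sep(meta_file, sep)
  tab <- read.table(meta_file, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, strip.white = TRUE)
  validate_metadata(tab)
}

#' Write an anatomical network to a standard graph format
#'
#' GraphML preserves node metadata attributes exactly; GML stores them under
#' GML-safe keys (`tissue`, `side`, `anatgroup`, `facialflag` as 0/1), mapped
#' back by [read_network()]; the whitespace edge list stores structure only
#' (one `from to` pair per line, isolated nodes as single-token lines).
#'
#' @param net An [anatomical_network()].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"gml"`, `"edge_list"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "gml", "edge_list")) {
  stopifnot(inherits(net, "anatomical_network"))
  format <- match.arg(format)
  if (format == "edge_list") {
    deg <- node_degrees(net)
    lines <- c(paste0("# taxon_id: ", net$taxon_id),
               names(deg)[deg == 0],
               if (nrow(net$edges) > 0)
                 paste(net$edges[, 1], net$edges[, 2]))
    writeLines(lines, path, useBytes = TRUE)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    g <- as_igraph(net)
    # GML keys must be alphanumeric and attributes numeric/string
    g <- igraph::set_vertex_attr(g, "anatgroup",
                                 value = igraph::vertex_attr(g, "group"))
    g <- igraph::set_vertex_attr(g, "facialflag",
      value = as.numeric(igraph::vertex_attr(g, "is_facial_expression")))
    g <- igraph::delete_vertex_attr(g, "group")
    g <- igraph::delete_vertex_attr(g, "is_facial_expression")
    igraph::write_graph(g, path, format = "gml")
  }
  invisible(path)
}

#' Read an anatomical network written by [write_network()]
#'
#' @param path File path.
#' @param format One of `"graphml"`, `"gml"`, `"edge_list"`.
#' @param taxon_id Overrides the stored taxon label, if given.
#' @return An [anatomical_network()]. Edge-list files carry no metadata, so
#'   nodes get flagged default metadata.
#' @export
read_network <- function(path, format = c("graphml", "gml", "edge_list"),
                         taxon_id = NULL) {
  format <- match.arg(format)
  if (format == "edge_list") {
    lines <- readLines(path, warn = FALSE)
    stored_taxon <- sub("^# taxon_id: ", "",
                        grep("^# taxon_id: ", lines, value = TRUE)[1])
    lines <- trimws(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
    toks <- strsplit(lines, "[[:space:]]+")
    nn <- lengths(toks)
    if (any(nn > 2)) stop("malformed edge list line")
    edges <- if (any(nn == 2)) do.call(rbind, toks[nn == 2]) else NULL
    nodes <- unique(c(unlist(toks[nn == 1]),
                      if (!is.null(edges)) c(t(edges))))
    if (is.null(taxon_id)) taxon_id <- if (is.na(stored_taxon)) "unnamed_taxon" else stored_taxon
    return(suppressWarnings(
      anatomical_network(nodes, edges, taxon_id = taxon_id)))
  }
  g <- igraph::read_graph(path, format = if (format == "gml") "gml" else "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  va <- igraph::vertex_attr_names(g)
  grp <- if ("anatgroup" %in% va) igraph::vertex_attr(g, "anatgroup")
         else igraph::vertex_attr(g, "group")
  flag <- if ("facialflag" %in% va)
    igraph::vertex_attr(g, "facialflag") != 0
  else igraph::vertex_attr(g, "is_facial_expression")
  meta <- NULL
  if (!is.null(igraph::vertex_attr(g, "tissue")))
    meta <- data.frame(node = nodes,
                       tissue = igraph::vertex_attr(g, "tissue"),
                       side = igraph::vertex_attr(g, "side"),
                       group = grp, is_facial_expression = flag,
                       stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (is.null(taxon_id)) {
    taxon_id <- igraph::graph_attr(g, "taxon_id")
    if (is.null(taxon_id)) taxon_id <- "unnamed_taxon"
  }
  suppressWarnings(anatomical_network(nodes, el, meta, taxon_id = taxon_id))
}

#' Write a network back out as a binary adjacency matrix
#'
#' @param net An [anatomical_network()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path) {
  n <- length(net$nodes)
  m <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges[, 1], net$nodes)
    j <- match(net$edges[, 2], net$nodes)
    m[cbind(i, j)] <- 1L
    m[cbind(j, i)] <- 1L
  }
  write.csv(as.data.frame(m), path, quote = FALSE)
  invisible(path)
}
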