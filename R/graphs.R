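#' Weighted graphs over cells, genes and spots
#'
#' A lightweight undirected weighted graph with typed nodes, the substrate for
#' the graph-convolutional models.  Edges are stored once per unordered pair;
#' self-loops are explicit.  The adjacency view used by [propagate()] is a
#' symmetric sparse matrix.
#'
#' @param node_ids character vector of node identifiers, unique.
#' @param node_roles character vector, one of `"cell"`, `"gene"`, `"spot"`.
#' @param edges data.frame with integer columns `u`, `v` (1-based node
#'   indices) and numeric `w` (finite, non-negative).
#' @param bipartite flag; when `TRUE`, no edge may join two nodes of the same
#'   role (no cell-cell and no gene-gene edges).
#' @return object of class `sc_graph`.
#' @export
sc_graph <- function(node_ids, node_roles, edges, bipartite = FALSE) {
  stopifnot(length(node_ids) == length(node_roles))
  if (anyDuplicated(node_ids)) stop("node ids must be unique")
  if (!all(node_roles %in% c("cell", "gene", "spot")))
    stop("node roles must be cell/gene/spot")
  edges <- as.data.frame(edges)
  stopifnot(all(c("u", "v", "w") %in% names(edges)))
  if (nrow(edges)) {
    if (any(!is.finite(edges$w)) || any(edges$w < 0))
      stop("edge weights must be finite and non-negative")
    n <- length(node_ids)
    if (any(edges$u < 1 | edges$u > n | edges$v < 1 | edges$v > n))
      stop("edge endpoint out of range")
    if (bipartite && any(node_roles[edges$u] == node_roles[edges$v]))
      stop("bipartite graph may not join two nodes of the same role")
  }
  structure(list(node_ids = as.character(node_ids),
                 node_roles = as.character(node_roles),
                 edges = edges[, c("u", "v", "w")],
                 bipartite = bipartite,
                 normalized = FALSE),
            class = "sc_graph")
}

#' @export
print.sc_graph <- function(x, ...) {
  cat("sc_graph:", length(x$node_ids), "nodes (",
      paste(names(table(x$node_roles)), table(x$node_roles),
            sep = ":", collapse = ", "),
      "),", nrow(x$edges), "edges",
      if (x$bipartite) "[bipartite]" else "", "\n")
  invisible(x)
}

#' Number of graph nodes
#' @param g an `sc_graph`.
#' @return integer.
#' @export
n_nodes <- function(g) length(g$node_ids)

#' Symmetric sparse adjacency matrix of a graph
#' @param g an `sc_graph`.
#' @return a `dgCMatrix`, nodes x nodes.
#' @export
graph_adjacency <- function(g) {
  n <- n_nodes(g)
  e <- g$edges
  if (!nrow(e))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  loops <- e$u == e$v
  i <- c(e$u, e$v[!loops])
  j <- c(e$v, e$u[!loops])
  x <- c(e$w, e$w[!loops])
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Weighted bipartite cell-gene graph
#'
#' Builds the heterogeneous cell-to-gene graph: one node per cell and per
#' gene, an edge between cell c and gene g iff the working matrix entry
#' `X[c,g]` is positive, with weight `X[c,g]` divided by the total counts of
#' cell c.  The weights incident to each cell therefore sum to exactly 1.
#' Cell-cell and gene-gene edges never occur.
#'
#' @param ds an [sc_dataset] with no all-zero cells.
#' @return bipartite `sc_graph` whose first `n_cells` nodes are cells.
#' @export
cell_gene_graph <- function(ds) {
  stopifnot(inherits(ds, "sc_dataset"))
  X <- ds$X
  rs <- Matrix::rowSums(X)
  if (any(rs == 0)) stop("all-zero cell present; filter cells first")
  Xs <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  nc <- nrow(X)
  edges <- data.frame(u = Xs@i + 1L,              # cell index
                      v = nc + Xs@j + 1L,         # gene node index
                      w = Xs@x / rs[Xs@i + 1L])
  sc_graph(node_ids = c(ds$cell_ids, ds$gene_ids),
           node_roles = c(rep("cell", nc), rep("gene", ncol(X))),
           edges = edges, bipartite = TRUE)
}

#' k-nearest-neighbour cell graph from an embedding
#'
#' Undirected unit-weight graph where i and j are joined iff j is among i's k
#' nearest neighbours or vice versa (the mutualized union).  Distance ties
#' break deterministically by ascending index.
#'
#' @param embedding numeric matrix, cells x d.
#' @param k neighbours per cell, `1 <= k < n_cells`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return an `sc_graph` of cell nodes.
#' @export
knn_graph <- function(embedding, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  emb <- as.matrix(embedding)
  n <- nrow(emb)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n_cells")
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(emb^2))
    nrm[nrm == 0] <- 1
    emb <- emb / nrm
  }
  d2 <- as.matrix(stats::dist(emb))^2   # cosine dist is monotone in euclidean on normalized rows
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    ord <- order(d2[i, -i], seq_len(n)[-i])  # tie-break by ascending index
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  ids <- rownames(emb)
  if (is.null(ids)) ids <- paste0("cell", seq_len(n))
  sc_graph(node_ids = ids, node_roles = rep("cell", n),
           edges = data.frame(u = pairs[, 1], v = pairs[, 2], w = 1))
}

#' Normalize graph edge weights for propagation
#'
#' `mode = "sym"` rescales each weight by the square root of both endpoint
#' degrees (the symmetric normalization used by graph convolutions);
#' `mode = "row"` divides by the source degree so that every non-isolated row
#' of the adjacency sums to 1.  Degrees are weighted and computed after the
#' optional unit self-loops.
#'
#' @param g an `sc_graph`.
#' @param mode `"sym"` or `"row"`.
#' @param add_self_loops add a unit self-loop to every node first
#'   (default `TRUE`).
#' @return a normalized `sc_graph` (flag `normalized` set).
#' @export
normalize_adjacency <- function(g, mode = c("sym", "row"),
                                add_self_loops = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "sc_graph"))
  n <- n_nodes(g)
  A <- graph_adjacency(g)
  if (add_self_loops) A <- A + Matrix::Diagonal(n)
  deg <- Matrix::rowSums(A)   # weighted degree incl. self-loop weight
  iso <- deg == 0
  if (any(iso) && mode == "row")
    stop("isolated node with row normalization is undefined; ",
         "use add_self_loops = TRUE")
  if (mode == "sym") {
    s <- ifelse(iso, 0, 1 / sqrt(deg))
    An <- Matrix::Diagonal(x = s) %*% A %*% Matrix::Diagonal(x = s)
    An <- methods::as(methods::as(An, "generalMatrix"), "TsparseMatrix")
    keep <- An@i <= An@j   # symmetric: store each unordered pair once
    g$edges <- data.frame(u = An@i[keep] + 1L, v = An@j[keep] + 1L,
                          w = An@x[keep])
    g$directed <- FALSE
  } else {
    An <- Matrix::Diagonal(x = 1 / deg) %*% A
    An <- methods::as(methods::as(An, "generalMatrix"), "TsparseMatrix")
    ## row-normalized weights are direction dependent; store directed edges
    ## with w = w_hat(u -> v) read as A[u, v].
    g$edges <- data.frame(u = An@i + 1L, v = An@j + 1L, w = An@x)
    g$directed <- TRUE
  }
  g$normalized <- TRUE
  g
}

#' @keywords internal
norm_adjacency_matrix <- function(g) {
  n <- n_nodes(g)
  e <- g$edges
  if (isTRUE(g$directed)) {
    ## stored as directed edges: out[v] = sum_u A[v,u] f[u], A[v,u] = w(u->v)
    Matrix::sparseMatrix(i = e$v, j = e$u, x = e$w, dims = c(n, n))
  } else {
    graph_adjacency(g)
  }
}

#' One step of weighted message passing
#'
#' Computes, for every node v, the weighted sum of its neighbours' feature
#' rows under the normalized adjacency: `out[v] = sum_u w_hat(u,v) f[u]`.
#' Linear in the features.
#'
#' @param features numeric matrix, nodes x f, rows in graph node order.
#' @param g a normalized `sc_graph` (see [normalize_adjacency()]).
#' @return numeric matrix, nodes x f.
#' @export
propagate <- function(features, g) {
  stopifnot(inherits(g, "sc_graph"))
  if (!isTRUE(g$normalized))
    stop("graph must be normalized (normalize_adjacency) before propagate")
  f <- as.matrix(features)
  if (nrow(f) != n_nodes(g))
    stop("features have ", nrow(f), " rows but graph has ", n_nodes(g),
         " nodes")
  as.matrix(norm_adjacency_matrix(g) %*% f)
}

#' Export a graph edge list as TSV (debugging aid)
#' @param g an `sc_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  e <- g$edges
  out <- data.frame(u_id = g$node_ids[e$u], v_id = g$node_ids[e$v], w = e$w)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
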