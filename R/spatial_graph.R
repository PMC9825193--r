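#' Build the spot-spot k-nearest-neighbour spatial graph
#'
#' Directed kNN edges are computed from the spatial coordinates (Euclidean,
#' 2D or 3D), symmetrized by union (an edge exists if either endpoint selects
#' the other), and self-loops are added. Distance ties are broken by the
#' lower spot index.
#'
#' @param coords spots x d coordinate matrix.
#' @param k neighbours per spot (default 12).
#' @return a \code{spatial_graph}: \code{adjacency} (sparse binary, with unit
#'   diagonal), \code{normalized} (NULL until [normalize_adjacency()]),
#'   \code{k}, \code{degrees}.
#' @export
build_knn_graph <- function(coords, k = 12) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k <= 0) stop("parameter error: k must be positive")
  if (k >= n) stop("parameter error: k must be < number of spots (", n, ")")
  nb <- knn_indices(coords, k)
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nb))
  a <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                            j = c(j, i, seq_len(n)),
                            x = 1, dims = c(n, n), use.last.ij = FALSE)
  a@x[] <- 1  # union symmetrization, binary
  structure(list(adjacency = a, normalized = NULL, k = as.integer(k),
                 degrees = as.integer(Matrix::rowSums(a))),
            class = "spatial_graph")
}

#' Symmetric normalization of the graph adjacency
#'
#' Fills \code{normalized} with \code{D^{-1/2} A D^{-1/2}} where \code{D} is
#' the diagonal degree matrix of the self-looped adjacency. All eigenvalues
#' of the result lie in [-1, 1].
#'
#' @param graph a \code{spatial_graph} (or a raw adjacency matrix, in which
#'   case a graph object is built around it).
#' @return the graph with \code{normalized} filled.
#' @export
normalize_adjacency <- function(graph) {
  if (!inherits(graph, "spatial_graph")) {
    a <- methods::as(Matrix::Matrix(graph, sparse = TRUE), "CsparseMatrix")
    graph <- structure(list(adjacency = a, normalized = NULL, k = NA_integer_,
                            degrees = as.integer(Matrix::rowSums(a))),
                       class = "spatial_graph")
  }
  a <- graph$adjacency
  dinv <- 1 / sqrt(Matrix::rowSums(a))
  graph$normalized <- a * tcrossprod(dinv)  # elementwise d_i^-1/2 d_j^-1/2
  graph
}

#' @export
print.spatial_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("spatial_graph: %d spots, k = %s, %d edges (incl. self-loops)%s\n",
              n, x$k, length(x$adjacency@x),
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Combine per-batch spatial graphs block-diagonally
#'
#' Used by the integration workflow: spatial edges never cross batches since
#' inter-slide distances are not comparable.
#'
#' @param graphs list of \code{spatial_graph} objects.
#' @return a single \code{spatial_graph} over the concatenated spots.
#' @export
block_diagonal_graph <- function(graphs) {
  a <- Matrix::bdiag(lapply(graphs, function(g) g$adjacency))
  a <- methods::as(a, "CsparseMatrix")
  g <- structure(list(adjacency = a, normalized = NULL,
                      k = graphs[[1L]]$k,
                      degrees = as.integer(Matrix::rowSums(a))),
                 class = "spatial_graph")
  normalize_adjacency(g)
}

#' Export the graph edge list as TSV
#'
#' @param graph a \code{spatial_graph}.
#' @param path output file; self-loops are omitted.
#' @param spot_ids optional ids replacing integer indices.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(graph, path, spot_ids = NULL) {
  tr <- Matrix::which(graph$adjacency != 0, arr.ind = TRUE)
  tr <- tr[tr[, 1L] != tr[, 2L], , drop = FALSE]
  df <- data.frame(spot_i = tr[, 1L], spot_j = tr[, 2L])
  if (!is.null(spot_ids)) {
    df$spot_i <- spot_ids[df$spot_i]
    df$spot_j <- spot_ids[df$spot_j]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
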