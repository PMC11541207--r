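# Spatial neighbor graph, normalized propagation matrix, multi-hop features.

#' Build a spatial nearest-neighbor graph
#'
#' \code{mode = "hex"} connects each spot to its six nearest neighbors (one
#' hexagonal ring on array-based platforms); \code{mode = "knn"} uses
#' \code{k} nearest neighbors, defaulting to \code{max(1, round(N/1000))}
#' (one neighbor per thousand cells, the convention for dissociated-scale
#' data). Directed edges are symmetrized by union; self-edges are excluded.
#' Distances are Euclidean on the raw coordinates; ties broken by cell index.
#'
#' @param coords cells x 2 numeric matrix.
#' @param mode \code{"knn"} or \code{"hex"}.
#' @param k neighbor count for knn mode; ignored for hex.
#' @return a \code{spatial_graph}: list with binary symmetric sparse
#'   \code{adjacency} (zero diagonal), normalized \code{propagation} matrix
#'   \eqn{S = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}}, and \code{k}.
#' @export
build_graph <- function(coords, mode = c("knn", "hex"), k = NULL) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  .assert(n >= 2, "need at least 2 cells to build a graph")
  .assert(all(is.finite(coords)), "coordinates must be finite")
  if (mode == "hex") k <- 6L
  if (is.null(k)) k <- max(1L, as.integer(round(n / 1000)))
  k <- min(as.integer(k), n - 1L)
  .assert(k >= 1, "k must be >= 1")
  # exact kNN; N is moderate (spot-level data), so a blocked distance scan is fine
  idx <- matrix(0L, n, k)
  block <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(rowSums(coords[s:e, , drop = FALSE]^2), rowSums(coords^2), "+") -
      2 * coords[s:e, , drop = FALSE] %*% t(coords)
    for (i in seq_len(e - s + 1L)) {
      d2[i, s + i - 1L] <- Inf
      # order() breaks distance ties by index
      idx[s + i - 1L, ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.integer(t(idx)),
                            x = 1, dims = c(n, n))
  A <- ((A + Matrix::t(A)) > 0) * 1  # symmetrize by union
  A <- .as_csparse(A)
  structure(list(adjacency = A, propagation = propagation_matrix(A), k = k),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d cells, %d undirected edges (k = %d)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$k))
  invisible(x)
}

#' Symmetric normalized propagation matrix
#'
#' \eqn{S = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}} with
#' \eqn{\tilde A = A + I} and \eqn{\tilde D} its diagonal degree matrix.
#' Self-loops guarantee every degree is at least one, so S is always defined;
#' its spectrum lies in [-1, 1].
#'
#' @param A binary symmetric adjacency with zero diagonal (sparse or dense).
#' @return sparse symmetric matrix S.
#' @export
propagation_matrix <- function(A) {
  A <- .as_csparse(A)
  .assert(Matrix::isSymmetric(A), "adjacency must be symmetric")
  .assert(all(Matrix::diag(A) == 0), "adjacency must have zero diagonal")
  At <- A + Matrix::Diagonal(nrow(A))
  dinv <- 1 / sqrt(Matrix::rowSums(At))
  Matrix::Diagonal(x = dinv) %*% At %*% Matrix::Diagonal(x = dinv)
}

#' Stacked multi-hop features
#'
#' Horizontal concatenation \eqn{[X, SX, S^2 X, ..., S^l X]} computed by
#' repeated sparse multiplication. This is the fixed preprocessing of the
#' simplified graph-convolution encoder: spatial smoothing happens once here,
#' so training can minibatch plain rows.
#'
#' @param S propagation matrix (from \code{\link{propagation_matrix}}).
#' @param X cells x features numeric matrix.
#' @param l number of hops, >= 0.
#' @return cells x ((l+1) * features) dense matrix.
#' @export
hop_features <- function(S, X, l = 1L) {
  .assert(l >= 0, "number of hops must be >= 0")
  X <- as.matrix(X)
  blocks <- vector("list", l + 1L)
  blocks[[1L]] <- X
  cur <- X
  for (h in seq_len(l)) {
    cur <- as.matrix(S %*% cur)
    blocks[[h + 1L]] <- cur
  }
  do.call(cbind, blocks)
}

#' Write / read a graph as an edge-list TSV
#'
#' Each line holds one undirected edge as a pair of 1-based cell indices
#' (i < j).
#' @param graph a \code{spatial_graph}.
#' @param path output TSV path.
#' @export
write_graph <- function(graph, path) {
  tr <- Matrix::which(graph$adjacency != 0, arr.ind = TRUE)
  tr <- tr[tr[, 1] < tr[, 2], , drop = FALSE]
  utils::write.table(tr, path, sep = "\t", row.names = FALSE, col.names = c("cell_i", "cell_j"))
  invisible(path)
}

#' @rdname write_graph
#' @param n_cells number of cells (edge lists do not record isolated nodes).
#' @export
read_graph <- function(path, n_cells) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  A <- Matrix::sparseMatrix(i = c(tab[[1]], tab[[2]]), j = c(tab[[2]], tab[[1]]),
                            x = 1, dims = c(n_cells, n_cells))
  A <- (A > 0) * 1
  structure(list(adjacency = A, propagation = propagation_matrix(A), k = NA_integer_),
            class = "spatial_graph")
}
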