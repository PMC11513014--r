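#' Build the spatial k-nearest-neighbor spot graph
#'
#' Spots are connected to their `k` nearest neighbors by Euclidean distance
#' on the slide coordinates; the directed kNN relation is symmetrized by
#' union, so no spot is orphaned. Distance ties are broken by lower spot
#' index. The graph carries two operators: the renormalized propagation
#' operator D^{-1/2}(A + I)D^{-1/2} used by the graph-convolution layers
#' (self-loops added here only), and the row-normalized adjacency (no
#' self-loops) used for the local-context readout and Moran's I.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k neighbor count; default 6, the physical neighbor count of a
#'   Visium hexagonal lattice.
#' @return An object of class `spot_graph` with fields `adjacency` (sparse
#'   binary symmetric), `norm_operator`, `context_operator`,
#'   `neighbor_lists`, `k`, `n`.
#' @export
build_knn_graph <- function(coords, k = 6) {
  coords <- as.matrix(coords)
  assert_finite_matrix(coords, "coordinates")
  n <- nrow(coords)
  if (k >= n) stop(sprintf("k = %d must be smaller than the number of spots (%d)", k, n))
  if (k < 1) stop("k must be a positive integer")
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  ii <- integer(n * k)
  jj <- integer(n * k)
  for (i in seq_len(n)) {
    nn <- order(D[i, ], seq_len(n))[seq_len(k)]  # ties -> lower index first
    ii[((i - 1L) * k + 1L):(i * k)] <- i
    jj[((i - 1L) * k + 1L):(i * k)] <- nn
  }
  A_dir <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A <- A_dir + Matrix::t(A_dir)
  A@x[] <- 1  # union symmetrization: max(A_dir, t(A_dir))
  A <- Matrix::drop0(A)
  graph_from_adjacency(A, coords = coords, k = k)
}

## Assemble the operators shared by propagation, readout and Moran's I.
graph_from_adjacency <- function(A, coords = NULL, k = NA_integer_) {
  n <- nrow(A)
  A_hat <- A + Matrix::Diagonal(n)
  d_hat <- Matrix::rowSums(A_hat)
  inv_sqrt <- Matrix::Diagonal(n, x = 1 / sqrt(d_hat))
  S <- inv_sqrt %*% A_hat %*% inv_sqrt
  deg <- Matrix::rowSums(A)
  ## isolated spots (deg 0) fall back to their own row in the readout
  M <- A
  if (any(deg == 0)) {
    iso <- which(deg == 0)
    M <- M + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = c(n, n))
    deg[iso] <- 1
  }
  M <- Matrix::Diagonal(n, x = 1 / deg) %*% M
  At <- methods::as(A, "TsparseMatrix")
  neighbor_lists <- split(At@j + 1L, factor(At@i + 1L, levels = seq_len(n)))
  structure(
    list(adjacency = A, norm_operator = S, context_operator = M,
         neighbor_lists = neighbor_lists, k = k, n = n, coords = coords),
    class = "spot_graph"
  )
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf("<spot_graph> %d spots, %d undirected edges (k = %s)\n",
              x$n, Matrix::nnzero(x$adjacency) / 2, x$k))
  invisible(x)
}

#' Corrupted view: shuffle feature rows across spots
#'
#' Draws a uniformly random permutation of the spots and permutes the rows of
#' the feature matrix accordingly, leaving the graph topology untouched. The
#' corrupted view supplies the negative pairs for contrastive training.
#'
#' @param expr n x g feature matrix.
#' @param seed integer seed; the permutation is drawn from a temporary RNG
#'   stream so the caller's stream is unaffected. `NULL` uses the current
#'   stream.
#' @param permutation optionally inject a specific permutation (testing).
#' @return A list with `permutation` and `shuffled_expr`.
#' @export
corrupt_features <- function(expr, seed = NULL, permutation = NULL) {
  n <- nrow(expr)
  if (n < 2) stop("need at least 2 spots to corrupt features")
  if (is.null(permutation)) {
    permutation <- if (is.null(seed)) sample.int(n) else
      with_seed(seed, sample.int(n))
  }
  stopifnot(length(permutation) == n, !anyDuplicated(permutation),
            all(permutation >= 1), all(permutation <= n))
  list(permutation = permutation,
       shuffled_expr = expr[permutation, , drop = FALSE])
}

#' Local context readout
#'
#' For each spot, the sigmoid of the mean embedding of its direct graph
#' neighbors (self excluded; an isolated spot uses its own row). This is the
#' per-spot summary each positive/negative pair is scored against in the
#' contrastive objective.
#'
#' @param Z n x d embedding matrix.
#' @param graph a [build_knn_graph()] result.
#' @return n x d matrix with entries in (0, 1).
#' @export
local_context <- function(Z, graph) {
  stopifnot(inherits(graph, "spot_graph"), nrow(Z) == graph$n)
  sigmoid(as.matrix(graph$context_operator %*% Z))
}
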