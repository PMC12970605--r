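#' kNN adjacency in the RKHS
#'
#' Builds the binary k-nearest-neighbour adjacency of the cells measured in
#' the kernel's feature space. RKHS squared distance is
#' `2 - 2 K[i, j]`, so neighbour ranking by increasing RKHS distance equals
#' ranking by decreasing kernel value. The adjacency is OR-symmetrized:
#' `W[i, j] = 1` iff j is among i's k nearest or i among j's. Ties are broken
#' by lower index and a cell is never its own neighbour.
#'
#' @param kernel a [KernelMatrix-class] (or plain symmetric Gram matrix).
#' @param kNeighbors neighbour count, `1 <= kNeighbors < n`.
#' @return binary symmetric hollow n x n matrix.
#' @seealso [laplacianFromAdjacency()], [buildGraphLaplacian()]
#' @export
rkhsKnnAdjacency <- function(kernel, kNeighbors) {
  K <- if (is(kernel, "KernelMatrix")) kernel@gram else as.matrix(kernel)
  n <- nrow(K)
  kNeighbors <- as.integer(kNeighbors)
  if (kNeighbors < 1L || kNeighbors >= n)
    stop(sprintf("'kNeighbors' must be in [1, n-1]; got %d with n = %d",
                 kNeighbors, n))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    kv <- K[i, ]
    kv[i] <- -Inf
    # order(): ties broken by lower index
    nn <- order(kv, decreasing = TRUE)[seq_len(kNeighbors)]
    W[i, nn] <- 1
  }
  W <- pmax(W, t(W)) # OR symmetrization
  W
}

#' Unnormalized graph Laplacian from an adjacency matrix
#'
#' Computes the degree vector D and L = D - W for a symmetric binary hollow
#' adjacency. Rows of L sum to zero and L is positive semidefinite.
#'
#' @param W binary symmetric hollow adjacency matrix.
#' @param kNeighbors neighbour count recorded on the result (metadata only).
#' @return A [GraphLaplacian-class] object.
#' @examples
#' W <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3) # path graph
#' laplacianMatrix(laplacianFromAdjacency(W))
#' @export
laplacianFromAdjacency <- function(W, kNeighbors = NA_integer_) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("'W' must be square")
  if (max(abs(W - t(W))) > 0) stop("'W' must be symmetric")
  if (any(W != 0 & W != 1)) stop("'W' must be binary")
  if (any(diag(W) != 0)) stop("'W' must have a zero diagonal")
  deg <- rowSums(W)
  L <- diag(deg, nrow(W)) - W
  new("GraphLaplacian", adjacency = W, degree = deg, laplacian = L,
      kNeighbors = as.integer(kNeighbors))
}

#' Build the kNN graph Laplacian of a kernel in one call
#'
#' @inheritParams rkhsKnnAdjacency
#' @return A [GraphLaplacian-class] object.
#' @export
buildGraphLaplacian <- function(kernel, kNeighbors = 5L) {
  laplacianFromAdjacency(rkhsKnnAdjacency(kernel, kNeighbors),
                         kNeighbors = kNeighbors)
}

#' Laplacian smoothness penalty of an embedding
#'
#' Evaluates the quadratic form Tr(E' L E), equal to half the adjacency-
#' weighted sum of squared embedding differences between neighbours. Used as
#' the local-geometry (topology) penalty of the integration objective.
#'
#' @param embedding n x k numeric matrix.
#' @param laplacian a [GraphLaplacian-class] or plain Laplacian matrix.
#' @return nonnegative scalar.
#' @export
smoothnessPenalty <- function(embedding, laplacian) {
  L <- if (is(laplacian, "GraphLaplacian")) laplacian@laplacian
       else as.matrix(laplacian)
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != nrow(L))
    stop(sprintf("embedding has %d rows but Laplacian is %d x %d",
                 nrow(embedding), nrow(L), ncol(L)))
  sum(embedding * (L %*% embedding))
}
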