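#' Data-driven Gaussian bandwidth
#'
#' Sets the kernel bandwidth to the mean of the pairwise Euclidean distances
#' between cells, computed over the n(n-1)/2 unordered distinct pairs
#' (self-distances excluded: a zero self-distance would shrink the bandwidth
#' with no informational content). This adapts the kernel to the average
#' spatial dispersion of each dataset.
#'
#' @param values numeric cells x features matrix (or [ModalityData-class]),
#'   n >= 2.
#' @return positive scalar bandwidth sigma.
#' @examples
#' meanPairwiseBandwidth(matrix(c(0, 1, 2), ncol = 1)) # (1 + 2 + 1)/3
#' @export
meanPairwiseBandwidth <- function(values) {
  values <- asValuesMatrix(values)
  if (nrow(values) < 2L) stop("bandwidth needs at least 2 cells")
  sigma <- mean(stats::dist(values))
  if (sigma <= 0)
    stop("degenerate data: all cells identical, bandwidth would be 0")
  sigma
}

#' Gaussian Gram matrix of one dataset
#'
#' Computes `K[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))` for all cell
#' pairs.
#' Squared distances use the expanded form ||a||^2 + ||b||^2 - 2 a.b with
#' clamping at zero, and the diagonal is set to exactly 1.
#'
#' @param values numeric cells x features matrix (or [ModalityData-class]).
#' @param sigma positive bandwidth; defaults to [meanPairwiseBandwidth()].
#' @return A [KernelMatrix-class] object.
#' @examples
#' K <- gaussianGram(matrix(c(0, 1, 2), ncol = 1), sigma = 1)
#' gramMatrix(K)[1, 2] # exp(-1/2)
#' @export
gaussianGram <- function(values, sigma = meanPairwiseBandwidth(values)) {
  values <- asValuesMatrix(values)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  d2 <- squaredDistances(values, values)
  K <- exp(-d2 / (2 * sigma^2))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  new("KernelMatrix", gram = K, sigma = sigma, gamma = 1 / (2 * sigma^2))
}

#' Cross-kernel between training cells and query points
#'
#' Evaluates the Gaussian kernel between m query points and the n training
#' cells, as needed to embed out-of-sample points through the representer
#' expansion (each latent coordinate is a kernel-weighted sum over training
#' cells).
#'
#' @param valuesTrain n x d training matrix.
#' @param valuesQuery m x d query matrix (same feature dimension).
#' @param sigma positive bandwidth.
#' @return m x n matrix with entry `[q, i] = exp(-||query_q - train_i||^2 /
#'   (2 sigma^2))`. When `valuesQuery` equals `valuesTrain` this reproduces
#'   the Gram matrix.
#' @export
kernelCross <- function(valuesTrain, valuesQuery, sigma) {
  valuesTrain <- asValuesMatrix(valuesTrain)
  valuesQuery <- asValuesMatrix(valuesQuery, minCells = 1L)
  if (ncol(valuesQuery) != ncol(valuesTrain))
    stop(sprintf("feature dimension mismatch: query has %d, train has %d",
                 ncol(valuesQuery), ncol(valuesTrain)))
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  exp(-squaredDistances(valuesQuery, valuesTrain) / (2 * sigma^2))
}

# pairwise squared Euclidean distances, clamped at 0 against float negatives
squaredDistances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

asValuesMatrix <- function(x, minCells = 2L) {
  if (is(x, "ModalityData")) x <- x@values
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("input matrix must be numeric and finite")
  if (nrow(x) < minCells)
    stop(sprintf("need at least %d rows", minCells))
  x
}
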