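#' @useDynLib scGraphOT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' One modality's cells-by-features matrix
#'
#' Container for a single modality (e.g. an scRNA-seq gene expression matrix or
#' an scATAC-seq peak matrix): a dense numeric matrix with cells as rows and
#' features as columns, optional cell/feature names stored as dimnames, and an
#' optional per-cell categorical label vector. Labels are evaluation/tuning
#' metadata only; they are never consumed by the alignment itself.
#'
#' @slot values numeric matrix, cells x features, all entries finite.
#' @slot labels character vector of per-cell labels; length 0 when absent,
#'   otherwise exactly one label per cell.
#'
#' @seealso [ModalityData()] for the validating constructor,
#'   [readMatrix()] to load one from disk.
#' @export
setClass("ModalityData",
  representation(values = "matrix", labels = "character"))

setValidity("ModalityData", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 2L) return("need at least 2 cells (rows)")
  if (ncol(v) < 1L) return("need at least 1 feature (column)")
  if (!all(is.finite(v))) return("'values' contains NA/NaN/Inf entries")
  if (length(object@labels) > 0L && length(object@labels) != nrow(v))
    return(sprintf("labels length (%d) != number of cells (%d)",
                   length(object@labels), nrow(v)))
  TRUE
})

#' Construct a ModalityData object
#'
#' @param values numeric cells x features matrix (all finite).
#' @param cellNames,featureNames optional character vectors attached as
#'   dimnames.
#' @param labels optional per-cell categorical labels (character or factor),
#'   used only for semi-supervised tuning and evaluation.
#' @return A validated [ModalityData-class] object.
#' @examples
#' m <- ModalityData(matrix(rnorm(12), 3, 4), labels = c("T", "B", "T"))
#' nCells(m)
#' @export
ModalityData <- function(values, cellNames = NULL, featureNames = NULL,
                         labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(cellNames)) rownames(values) <- cellNames
  if (!is.null(featureNames)) colnames(values) <- featureNames
  if (is.null(labels)) labels <- character(0)
  new("ModalityData", values = values, labels = as.character(labels))
}

#' Gaussian kernel Gram matrix with its bandwidth
#'
#' @slot gram symmetric n x n Gram matrix with unit diagonal, entries in (0,1].
#' @slot sigma Gaussian bandwidth (units of the input feature distances).
#' @slot gamma derived scalar 1/(2 sigma^2), the parameterization used by the
#'   feature-attribution derivatives.
#' @seealso [gaussianGram()], [meanPairwiseBandwidth()]
#' @export
setClass("KernelMatrix",
  representation(gram = "matrix", sigma = "numeric", gamma = "numeric"))

setValidity("KernelMatrix", function(object) {
  K <- object@gram
  if (nrow(K) != ncol(K)) return("'gram' must be square")
  if (length(object@sigma) != 1L || object@sigma <= 0)
    return("'sigma' must be a single positive number")
  if (max(abs(K - t(K))) > 1e-12) return("'gram' must be symmetric")
  if (max(abs(diag(K) - 1)) > 0) return("'gram' diagonal must be exactly 1")
  if (any(K <= 0) || any(K > 1)) return("'gram' entries must lie in (0, 1]")
  if (abs(object@gamma - 1 / (2 * object@sigma^2)) > 1e-12 * object@gamma)
    return("'gamma' must equal 1/(2 sigma^2)")
  TRUE
})

#' kNN graph adjacency, degrees and unnormalized Laplacian
#'
#' @slot adjacency binary symmetric hollow n x n matrix W (OR-symmetrized kNN).
#' @slot degree numeric vector of row sums of W (diagonal of D).
#' @slot laplacian L = D - W; symmetric PSD, rows sum to zero.
#' @slot kNeighbors neighbor count used to build W.
#' @seealso [rkhsKnnAdjacency()], [laplacianFromAdjacency()]
#' @export
setClass("GraphLaplacian",
  representation(adjacency = "matrix", degree = "numeric",
                 laplacian = "matrix", kNeighbors = "integer"))

setValidity("GraphLaplacian", function(object) {
  W <- object@adjacency
  if (nrow(W) != ncol(W)) return("'adjacency' must be square")
  if (any(W != 0 & W != 1)) return("'adjacency' must be binary")
  if (any(diag(W) != 0)) return("'adjacency' must have zero diagonal")
  if (max(abs(W - t(W))) > 0) return("'adjacency' must be symmetric")
  if (!isTRUE(all.equal(object@degree, rowSums(W), check.attributes = FALSE)))
    return("'degree' must equal rowSums(adjacency)")
  L <- object@laplacian
  if (max(abs(L - (diag(object@degree, nrow(W)) - W))) > 0)
    return("'laplacian' must equal D - W")
  TRUE
})

#' Entropic optimal-transport coupling between two cell sets
#'
#' The nonnegative coupling matrix distributing mass between the n_x cells of
#' one modality and the n_y cells of the other, together with the marginals
#' and regularization parameters it was solved under. In balanced mode
#' (reach = Inf) the row/column sums match the prescribed marginals; in
#' unbalanced mode marginal deviations are penalized at strength reach^2
#' rather than enforced.
#'
#' @slot plan nonnegative n_x x n_y matrix.
#' @slot marginalA,marginalB prescribed marginal weight vectors.
#' @slot epsilon entropic regularization (> 0).
#' @slot reach unbalancedness scale; `Inf` means balanced.
#' @slot cost converged value of the regularized transport objective.
#' @slot converged whether the stopping tolerance was reached.
#' @slot iterations Sinkhorn sweeps performed.
#' @seealso [entropicOTCost()], [extractPlan()]
#' @export
setClass("TransportPlan",
  representation(plan = "matrix", marginalA = "numeric", marginalB = "numeric",
                 epsilon = "numeric", reach = "numeric", cost = "numeric",
                 converged = "logical", iterations = "integer"))

setValidity("TransportPlan", function(object) {
  T <- object@plan
  if (any(T < 0)) return("plan entries must be nonnegative")
  if (nrow(T) != length(object@marginalA) || ncol(T) != length(object@marginalB))
    return("plan shape does not match marginals")
  if (object@epsilon <= 0) return("'epsilon' must be positive")
  if (is.infinite(object@reach) && isTRUE(object@converged)) {
    if (max(abs(rowSums(T) - object@marginalA)) > 1e-6)
      return("balanced plan row sums deviate from marginalA by > 1e-6")
    if (max(abs(colSums(T) - object@marginalB)) > 1e-6)
      return("balanced plan column sums deviate from marginalB by > 1e-6")
  }
  TRUE
})

#' Trained kernel mapping model for two modalities
#'
#' Holds the learned coefficient matrices P_X and P_Y (the representer-theorem
#' coefficients) together with the kernels, graph Laplacians, standardization
#' parameters and training configuration needed to embed training or new
#' cells. Embeddings are X~ = K_X P_X and Y~ = K_Y P_Y; see
#' [latentEmbedding()].
#'
#' @slot pX,pY coefficient matrices (n_x x k and n_y x k).
#' @slot kernelX,kernelY training [KernelMatrix-class] objects.
#' @slot laplacianX,laplacianY training [GraphLaplacian-class] objects.
#' @slot trainX,trainY standardized training matrices (cells x features).
#' @slot centerX,scaleX,centerY,scaleY per-feature standardization applied to
#'   the raw inputs (identity transform when standardization was disabled).
#' @slot labelsX,labelsY per-cell labels carried through from the inputs
#'   (possibly empty); evaluation metadata only.
#' @slot config resolved [otConfig()] list used for training.
#' @slot trace per-epoch data.frame of loss components and learning rate.
#' @seealso [fitIntegration()], [transformPoints()], [extractPlan()]
#' @export
setClass("OTIntegration",
  representation(pX = "matrix", pY = "matrix",
                 kernelX = "KernelMatrix", kernelY = "KernelMatrix",
                 laplacianX = "GraphLaplacian", laplacianY = "GraphLaplacian",
                 trainX = "matrix", trainY = "matrix",
                 centerX = "numeric", scaleX = "numeric",
                 centerY = "numeric", scaleY = "numeric",
                 labelsX = "character", labelsY = "character",
                 config = "list", trace = "data.frame"))

#' Per-dimension feature importances
#'
#' Nonnegative scores `I[d, g]`: the average absolute partial derivative of
#' latent dimension d with respect to original feature g across all cells.
#'
#' @slot scores k_latent x d nonnegative matrix.
#' @slot featureNames length-d feature names (generated when absent upstream).
#' @slot domain `"x"` or `"y"`.
#' @seealso [embeddingJacobianScores()], [topFeatures()]
#' @export
setClass("ImportanceMatrix",
  representation(scores = "matrix", featureNames = "character",
                 domain = "character"))

setValidity("ImportanceMatrix", function(object) {
  if (any(object@scores < 0)) return("importance scores must be nonnegative")
  if (length(object@featureNames) != ncol(object@scores))
    return("featureNames length must match score columns")
  if (!object@domain %in% c("x", "y")) return("domain must be 'x' or 'y'")
  TRUE
})

#' Co-clustering of the two cell sets from a transport plan
#'
#' Joint row/column partition of a transport plan treated as a bipartite
#' graph. Assignments use integer cluster ids `1..nClusters`; cells removed by
#' [pruneSmall()] carry `NA`.
#'
#' @slot rowAssignments,colAssignments integer assignments (NA = pruned).
#' @slot nClusters number of surviving clusters.
#' @slot modularity bipartite modularity of the partition.
#' @slot pruned integer ids of clusters removed as noise (in the pre-pruning
#'   labeling).
#' @seealso [coCluster()], [bipartiteModularity()], [selectKElbow()]
#' @export
setClass("CoClustering",
  representation(rowAssignments = "integer", colAssignments = "integer",
                 nClusters = "integer", modularity = "numeric",
                 pruned = "integer"))

#' A simulated two-domain dataset with ground truth
#'
#' Two modalities generated from the same latent manifold, each independently
#' row-shuffled, with the true pairing and cluster labels retained for
#' evaluation only.
#'
#' @slot x,y [ModalityData-class] objects (labels filled in).
#' @slot latent n x p manifold coordinates in the row order of `x`.
#' @slot trueMatch integer vector: `trueMatch[i]` is the row of `y` paired
#'   with row i of `x`.
#' @slot design one of `"branch"`, `"swiss_roll"`, `"circular_frustum"`,
#'   `"synthetic_counts"`.
#' @seealso [simulatePair()]
#' @export
setClass("SimulatedPair",
  representation(x = "ModalityData", y = "ModalityData", latent = "matrix",
                 trueMatch = "integer", design = "character"))

setValidity("SimulatedPair", function(object) {
  n <- nrow(object@x@values)
  if (length(object@trueMatch) != n) return("trueMatch length must equal n_x")
  if (!setequal(object@trueMatch, seq_len(nrow(object@y@values))))
    return("trueMatch must be a permutation of the rows of y")
  TRUE
})
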