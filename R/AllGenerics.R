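#' @name accessors
#' @title Accessors for scGraphOT objects
#' @description Slot access for the package's S4 containers goes through these
#'   accessor generics rather than `@`.
#' @param x an scGraphOT S4 object.
#' @return `cellValues` the numeric matrix; `cellLabels` the label vector
#'   (length 0 when absent); `nCells`/`nFeatures` integers; `gramMatrix` the
#'   Gram matrix; `bandwidth` sigma; `adjacency`/`laplacianMatrix` graph
#'   matrices; `planMatrix` the coupling; `importanceScores` the k x d score
#'   matrix; `clusterAssignments` a list with `rows` and `cols`.
NULL

#' @rdname accessors
#' @export
setGeneric("cellValues", function(x) standardGeneric("cellValues"))
#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))
#' @rdname accessors
#' @export
setGeneric("gramMatrix", function(x) standardGeneric("gramMatrix"))
#' @rdname accessors
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))
#' @rdname accessors
#' @export
setGeneric("planMatrix", function(x) standardGeneric("planMatrix"))
#' @rdname accessors
#' @export
setGeneric("importanceScores", function(x) standardGeneric("importanceScores"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' Latent embedding of a trained model
#'
#' Returns the trained latent coordinates K P of one domain (rows are cells of
#' that modality, columns the k latent dimensions).
#'
#' @param object an [OTIntegration-class] model.
#' @param domain `"x"` or `"y"`.
#' @return numeric matrix, cells x k_latent.
#' @export
setGeneric("latentEmbedding",
           function(object, domain = c("x", "y"))
             standardGeneric("latentEmbedding"))

#' @rdname accessors
setMethod("cellValues", "ModalityData", function(x) x@values)
#' @rdname accessors
setMethod("cellLabels", "ModalityData", function(x) x@labels)
#' @rdname accessors
setMethod("nCells", "ModalityData", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nFeatures", "ModalityData", function(x) ncol(x@values))
#' @rdname accessors
setMethod("gramMatrix", "KernelMatrix", function(x) x@gram)
#' @rdname accessors
setMethod("bandwidth", "KernelMatrix", function(x) x@sigma)
#' @rdname accessors
setMethod("adjacency", "GraphLaplacian", function(x) x@adjacency)
#' @rdname accessors
setMethod("laplacianMatrix", "GraphLaplacian", function(x) x@laplacian)
#' @rdname accessors
setMethod("planMatrix", "TransportPlan", function(x) x@plan)
#' @rdname accessors
setMethod("importanceScores", "ImportanceMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("clusterAssignments", "CoClustering",
          function(x) list(rows = x@rowAssignments, cols = x@colAssignments))

#' @rdname latentEmbedding
setMethod("latentEmbedding", "OTIntegration", function(object, domain = c("x", "y")) {
  domain <- match.arg(domain)
  if (domain == "x") object@kernelX@gram %*% object@pX
  else object@kernelY@gram %*% object@pY
})

setMethod("show", "ModalityData", function(object) {
  cat(sprintf("ModalityData: %d cells x %d features%s\n",
              nrow(object@values), ncol(object@values),
              if (length(object@labels)) sprintf(", %d label classes",
                                                 length(unique(object@labels)))
              else ", unlabeled"))
})

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix: %d x %d Gaussian Gram, sigma = %.4g (gamma = %.4g)\n",
              nrow(object@gram), ncol(object@gram), object@sigma, object@gamma))
})

setMethod("show", "GraphLaplacian", function(object) {
  cat(sprintf("GraphLaplacian: %d nodes, k = %d, %d edges\n",
              nrow(object@adjacency), object@kNeighbors,
              sum(object@adjacency) / 2))
})

setMethod("show", "TransportPlan", function(object) {
  cat(sprintf(
    "TransportPlan: %d x %d, epsilon = %.4g, reach = %s, mass = %.6g (%s, %d iter)\n",
    nrow(object@plan), ncol(object@plan), object@epsilon,
    if (is.infinite(object@reach)) "Inf (balanced)" else format(object@reach),
    sum(object@plan),
    if (object@converged) "converged" else "max_iter reached",
    object@iterations))
})

setMethod("show", "OTIntegration", function(object) {
  tr <- object@trace
  cat(sprintf("OTIntegration: %d + %d cells -> %d latent dims\n",
              nrow(object@pX), nrow(object@pY), ncol(object@pX)))
  if (nrow(tr)) {
    cat(sprintf("  epochs: %d, final loss %.6g (ot %.4g, topo %.4g, ortho %.4g)\n",
                nrow(tr), tr$total[nrow(tr)], tr$ot[nrow(tr)],
                tr$topo[nrow(tr)], tr$ortho[nrow(tr)]))
  }
  cat(sprintf("  epsilon = %.4g, reach = %s, lambda_topo = %.3g, lambda_ortho = %.3g\n",
              object@config$epsilon,
              if (is.infinite(object@config$reach)) "Inf"
              else format(object@config$reach),
              object@config$lambda_topo, object@config$lambda_ortho))
})

setMethod("show", "CoClustering", function(object) {
  cat(sprintf("CoClustering: %d clusters, Q = %.4f, %d/%d rows and %d/%d cols assigned\n",
              object@nClusters, object@modularity,
              sum(!is.na(object@rowAssignments)), length(object@rowAssignments),
              sum(!is.na(object@colAssignments)), length(object@colAssignments)))
})

setMethod("show", "ImportanceMatrix", function(object) {
  cat(sprintf("ImportanceMatrix (domain %s): %d latent dims x %d features\n",
              object@domain, nrow(object@scores), ncol(object@scores)))
})

setMethod("show", "SimulatedPair", function(object) {
  cat(sprintf("SimulatedPair '%s': %d x-cells (%d features), %d y-cells (%d features)\n",
              object@design, nrow(object@x@values), ncol(object@x@values),
              nrow(object@y@values), ncol(object@y@values)))
})
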