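#' Fraction of samples closer than the true match
#'
#' For paired evaluation data embedded in a common space, computes for every
#' x-cell the fraction of y-cells (other than its true match) lying strictly
#' closer than the true match, and averages these fractions. 0 means perfect
#' alignment; 0.5 is the expectation under random alignment. Distances are
#' Euclidean in the shared space; the normalization is `1/(n - 1)` with the
#' true-match column excluded from the count, and equidistant samples do not
#' count against the match (strict inequality). The score is directional
#' (x towards y); `symmetric = TRUE` averages both directions.
#'
#' @param xe,ye n x k embeddings of the two domains (equal cell counts).
#' @param trueMatch integer permutation: `trueMatch[i]` is the row of `ye`
#'   truly paired with row i of `xe` (default identity).
#' @param symmetric also compute the y-towards-x direction and average.
#' @return list with `foscttm` (the mean), `perSample` (vector of per-cell
#'   fractions, x-direction).
#' @export
foscttm <- function(xe, ye, trueMatch = seq_len(nrow(xe)), symmetric = FALSE) {
  xe <- as.matrix(xe); ye <- as.matrix(ye)
  if (nrow(xe) != nrow(ye))
    stop("FOSCTTM needs equally sized, paired domains")
  n <- nrow(xe)
  trueMatch <- as.integer(trueMatch)
  if (!setequal(trueMatch, seq_len(n)))
    stop("'trueMatch' must be a permutation of 1..n")
  D <- squaredDistances(xe, ye)  # monotone in Euclidean distance
  dstar <- D[cbind(seq_len(n), trueMatch)]
  # the true-match column is never strictly below dstar, so the row count
  # already excludes it
  perSample <- rowSums(D < dstar) / (n - 1)
  out <- list(foscttm = mean(perSample), perSample = perSample)
  if (symmetric) {
    rev <- foscttm(ye, xe, trueMatch = order(trueMatch), symmetric = FALSE)
    out$foscttm <- (out$foscttm + rev$foscttm) / 2
  }
  out
}

#' Label transfer accuracy across the shared space
#'
#' Predicts each x-cell's label as the modal label of its k nearest y-cells
#' in the shared embedding and scores exact agreement with the x-cell's own
#' label. Distance ties are broken by lower index; modal ties by the smallest
#' label in sort order.
#'
#' @param xe,ye embeddings of the two domains.
#' @param labelsX,labelsY per-cell labels.
#' @param k neighbour count (default 5).
#' @return scalar accuracy in `[0, 1]`.
#' @export
labelTransferAccuracy <- function(xe, ye, labelsX, labelsY, k = 5L) {
  xe <- as.matrix(xe); ye <- as.matrix(ye)
  k <- as.integer(k)
  if (k < 1L || k > nrow(ye)) stop("'k' must be in [1, nrow(ye)]")
  if (length(labelsX) != nrow(xe) || length(labelsY) != nrow(ye))
    stop("label lengths must match the embeddings")
  labelsX <- as.character(labelsX); labelsY <- as.character(labelsY)
  D <- squaredDistances(xe, ye)
  correct <- vapply(seq_len(nrow(xe)), function(i) {
    nn <- order(D[i, ], seq_len(ncol(D)))[seq_len(k)]
    tab <- table(labelsY[nn])
    pred <- names(tab)[tab == max(tab)][1]  # smallest label on modal ties
    pred == labelsX[i]
  }, logical(1))
  mean(correct)
}

#' Clustering agreement scores
#'
#' Standard external clustering metrics between a predicted and a true
#' assignment: adjusted Rand index, normalized mutual information with
#' arithmetic normalization `2 I / (H_pred + H_true)`, and purity
#' `sum_c max_t |c intersect t| / N`. Cells with `NA` in either vector
#' (e.g. pruned co-cluster members) are excluded pairwise.
#'
#' @param pred,truth assignment vectors of equal length.
#' @return list with `ari`, `nmi`, `purity`.
#' @export
clusteringScores <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("assignment lengths differ")
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) stop("no jointly assigned cells (all pruned?)")
  pred <- as.character(pred[ok]); truth <- as.character(truth[ok])
  n <- length(pred)
  tab <- table(pred, truth)
  # each predicted cluster claims its majority true class
  purity <- sum(apply(tab, 1, max)) / n
  list(ari = mclust::adjustedRandIndex(pred, truth),
       nmi = nmiArithmetic(tab, n),
       purity = purity)
}

nmiArithmetic <- function(tab, n) {
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pr, pc)[nz]))
  hr <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  hc <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  if (hr + hc == 0) return(if (mi == 0) 1 else 0)  # both single-cluster
  2 * mi / (hr + hc)
}

#' Null distribution of FOSCTTM under random pairing
#'
#' Draws random permutations as surrogate "true matches" and recomputes
#' FOSCTTM for each, giving the distribution the observed score is compared
#' against (its 1st percentile is the usual significance cutoff for claiming
#' alignment).
#'
#' @param xe,ye embeddings of the two (equally sized) domains.
#' @param nPerm number of random pairings.
#' @param seed RNG seed.
#' @return numeric vector of `nPerm` null FOSCTTM values.
#' @export
foscttmNull <- function(xe, ye, nPerm = 1000L, seed = 1L) {
  n <- nrow(as.matrix(xe))
  set.seed(seed)
  vapply(seq_len(nPerm), function(p)
    foscttm(xe, ye, trueMatch = sample.int(n))$foscttm, numeric(1))
}
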