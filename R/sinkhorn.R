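#' Scale-aware default entropic regularization
#'
#' The default epsilon is 5% of the mean pairwise squared Euclidean distance
#' of the pooled embedding, making the amount of entropic blur proportional
#' to the scale of the point clouds.
#'
#' @param xe,ye numeric point matrices sharing a column dimension.
#' @return positive scalar epsilon.
#' @export
defaultEpsilon <- function(xe, ye) {
  joint <- rbind(as.matrix(xe), as.matrix(ye))
  eps <- 0.05 * mean(stats::dist(joint)^2)
  if (!is.finite(eps) || eps <= 0) eps <- 0.05
  eps
}

#' Entropic optimal-transport cost between two embedded point clouds
#'
#' Solves the entropically regularized transport problem between the rows of
#' `xe` and `ye` under squared Euclidean cost `C[i, j] = ||x_i - y_j||^2`,
#' using log-domain Sinkhorn iterations. The regularizer is epsilon times the
#' relative entropy of the coupling against the product of the marginals
#' (equivalent, up to a marginal-only constant, to the plain coupling-entropy
#' convention in balanced mode). With a finite `reach`, the marginal
#' constraints are replaced by KL penalties of strength `reach^2`
#' (unbalanced transport); `reach = Inf` enforces them exactly.
#'
#' Balanced runs are declared converged when the row-marginal violation drops
#' below `tol` in sup norm (columns are exact after each sweep); unbalanced
#' runs when the potentials change by less than `tol`.
#'
#' @param xe,ye n_x x k and n_y x k embedding matrices.
#' @param epsilon entropic regularization, > 0.
#' @param reach unbalancedness scale; `Inf` (default) = balanced.
#' @param a,b marginal weight vectors (default uniform, summing to 1).
#' @param maxIter,tol iteration budget and stopping tolerance.
#' @param fInit,gInit optional warm-start dual potentials.
#' @return list with `cost` (converged regularized objective), `plan` (a
#'   [TransportPlan-class]), the dual potentials `f`, `g`, `iterations` and
#'   `converged`.
#' @examples
#' p <- matrix(0, 1, 1); q <- matrix(2, 1, 1)
#' entropicOTCost(p, q, epsilon = 0.1)$cost # == 4 = |p - q|^2
#' @export
entropicOTCost <- function(xe, ye, epsilon, reach = Inf, a = NULL, b = NULL,
                           maxIter = 1000L, tol = 1e-6,
                           fInit = NULL, gInit = NULL) {
  xe <- as.matrix(xe); ye <- as.matrix(ye)
  if (ncol(xe) != ncol(ye)) stop("embedding dimensions differ")
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a single positive number")
  if (!(is.infinite(reach) || reach > 0))
    stop("'reach' must be positive or Inf")
  nx <- nrow(xe); ny <- nrow(ye)
  if (is.null(a)) a <- rep(1 / nx, nx)
  if (is.null(b)) b <- rep(1 / ny, ny)
  if (any(a < 0) || any(b < 0)) stop("marginals must be nonnegative")

  C <- squaredDistances(xe, ye)
  lam <- if (is.infinite(reach)) 1 else reach^2 / (reach^2 + epsilon)
  if (is.null(fInit)) fInit <- numeric(nx)
  if (is.null(gInit)) gInit <- numeric(ny)

  raw <- sinkhornRaw(C, a, b, epsilon, lam, reach, maxIter, tol, fInit, gInit)
  f <- raw$f; g <- raw$g; T <- raw$T; cost <- raw$cost
  res <- raw$res
  plan <- new("TransportPlan", plan = T, marginalA = a, marginalB = b,
              epsilon = epsilon, reach = reach, cost = cost,
              converged = isTRUE(res$converged),
              iterations = as.integer(res$iterations))
  list(cost = cost, plan = plan, f = f, g = g,
       iterations = as.integer(res$iterations),
       converged = isTRUE(res$converged))
}

# solver core shared by entropicOTCost() and internal coarse evaluations
sinkhornRaw <- function(C, a, b, epsilon, lam, reach, maxIter, tol,
                        fInit, gInit) {
  res <- sinkhorn_log_cpp(C, log(a), log(b), epsilon, lam,
                          as.integer(maxIter), tol,
                          as.numeric(fInit), as.numeric(gInit))
  if (isTRUE(res$diverged))
    stop("Sinkhorn iterations diverged (non-finite scalings); ",
         "try a larger epsilon")
  f <- as.numeric(res$f); g <- as.numeric(res$g)
  logT <- outer(log(a) + f / epsilon, log(b) + g / epsilon, "+") - C / epsilon
  T <- exp(logT)
  cost <- transportObjective(T, C, a, b, epsilon, reach, logT_centered =
                               outer(f, g, "+") / epsilon - C / epsilon)
  list(f = f, g = g, T = T, cost = cost, res = res)
}

# <C,T> + eps * KL(T | a x b) + reach^2 * [KL(T1|a) + KL(T'1|b)]
# logT_centered = log(T / (a x b)), supplied to avoid log(0) issues.
transportObjective <- function(T, C, a, b, epsilon, reach, logT_centered) {
  ent <- sum(T * logT_centered) - sum(T) + sum(a) * sum(b)
  val <- sum(C * T) + epsilon * ent
  if (is.finite(reach)) {
    r <- rowSums(T); cs <- colSums(T)
    val <- val + reach^2 * (klDiv(r, a) + klDiv(cs, b))
  }
  val
}

klDiv <- function(u, v) {
  pos <- u > 0
  sum(u[pos] * log(u[pos] / v[pos])) - sum(u) + sum(v)
}

#' Debiased Sinkhorn divergence between two embedded point clouds
#'
#' Computes `OT_eps(X, Y) - (OT_eps(X, X) + OT_eps(Y, Y)) / 2`, the debiased
#' entropic transport cost. It is symmetric in its arguments, vanishes when
#' the two clouds coincide, and has well-defined gradients with respect to
#' both point sets (obtained from the converged transport plans).
#'
#' Symmetry is made exact by evaluating the arguments in a canonical order,
#' so swapping `xe` and `ye` returns a bitwise-identical value.
#'
#' @inheritParams entropicOTCost
#' @param gradient if `TRUE`, also return the gradients of the divergence
#'   with respect to `xe` and `ye`.
#' @param warmStart optional list of dual potentials from a previous call on
#'   the same problem sizes (fields `xy`, `xx`, `yy`, each `list(f, g)`).
#' @return scalar divergence, or (with `gradient = TRUE`) a list with
#'   `value`, `gradX`, `gradY`, `plan` (the cross coupling matrix) and
#'   `state` (the potentials, reusable as `warmStart`).
#' @export
sinkhornDivergence <- function(xe, ye, epsilon, reach = Inf,
                               maxIter = 1000L, tol = 1e-6,
                               gradient = FALSE, warmStart = NULL) {
  xe <- as.matrix(xe); ye <- as.matrix(ye)
  if (!gradient && swapForCanonicalOrder(xe, ye)) {
    tmp <- xe; xe <- ye; ye <- tmp
  }
  nx <- nrow(xe); ny <- nrow(ye)
  a <- rep(1 / nx, nx); b <- rep(1 / ny, ny)
  lam <- if (is.infinite(reach)) 1 else reach^2 / (reach^2 + epsilon)
  ws <- function(part, len) {
    w <- if (is.null(warmStart)) NULL else warmStart[[part]]
    if (is.null(w)) list(f = numeric(len[1]), g = numeric(len[2])) else w
  }
  wxy <- ws("xy", c(nx, ny)); wxx <- ws("xx", c(nx, nx))
  wyy <- ws("yy", c(ny, ny))
  oxy <- sinkhornRaw(squaredDistances(xe, ye), a, b, epsilon, lam, reach,
                     maxIter, tol, wxy$f, wxy$g)
  oxx <- sinkhornRaw(squaredDistances(xe, xe), a, a, epsilon, lam, reach,
                     maxIter, tol, wxx$f, wxx$g)
  oyy <- sinkhornRaw(squaredDistances(ye, ye), b, b, epsilon, lam, reach,
                     maxIter, tol, wyy$f, wyy$g)
  value <- oxy$cost - (oxx$cost + oyy$cost) / 2
  if (!gradient) return(value)

  gradX <- crossGradFirst(xe, ye, oxy$T) - 0.5 * selfGrad(xe, oxx$T)
  gradY <- crossGradSecond(xe, ye, oxy$T) - 0.5 * selfGrad(ye, oyy$T)
  list(value = value, gradX = gradX, gradY = gradY, plan = oxy$T,
       state = list(xy = list(f = oxy$f, g = oxy$g),
                    xx = list(f = oxx$f, g = oxx$g),
                    yy = list(f = oyy$f, g = oyy$g)))
}

# envelope-theorem gradients of <C, T> at the converged plan
crossGradFirst <- function(xe, ye, T) 2 * (xe * rowSums(T) - T %*% ye)
crossGradSecond <- function(xe, ye, T) 2 * (ye * colSums(T) - crossprod(T, xe))
selfGrad <- function(e, T) {
  2 * (e * rowSums(T) - T %*% e) + 2 * (e * colSums(T) - crossprod(T, e))
}

# deterministic canonical ordering key: larger problem (then lexicographically
# larger values) goes first, so divergence(x, y) == divergence(y, x) bitwise.
swapForCanonicalOrder <- function(xe, ye) {
  if (nrow(xe) != nrow(ye)) return(nrow(xe) < nrow(ye))
  if (ncol(xe) != ncol(ye)) return(ncol(xe) < ncol(ye))
  vx <- as.vector(xe); vy <- as.vector(ye)
  i <- which(vx != vy)
  if (!length(i)) return(FALSE)
  vx[i[1L]] < vy[i[1L]]
}

#' Transport plan of a trained integration model
#'
#' Recomputes the converged coupling between the trained embeddings of the
#' two modalities at the training epsilon and reach. This coupling quantifies
#' the soft cell-cell correspondence between the modalities and is the input
#' to [coCluster()].
#'
#' @param model a trained [OTIntegration-class].
#' @param maxIter,tol Sinkhorn iteration controls.
#' @return A [TransportPlan-class] object.
#' @export
extractPlan <- function(model, maxIter = 1000L, tol = 1e-6) {
  stopifnot(is(model, "OTIntegration"))
  xe <- latentEmbedding(model, "x")
  ye <- latentEmbedding(model, "y")
  entropicOTCost(xe, ye, epsilon = model@config$epsilon,
                 reach = model@config$reach,
                 maxIter = maxIter, tol = tol)$plan
}
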