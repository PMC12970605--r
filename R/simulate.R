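#' Sample latent manifold coordinates with cluster labels
#'
#' Generates the low-dimensional ground-truth geometry of the simulation
#' designs:
#' * `branch`: a 2-D tree of three straight arms radiating from the origin
#'   with distinct lengths (1, 0.75, 0.5), unequal arm abundances
#'   (0.5/0.3/0.2, as real cell-type proportions are rarely balanced) and
#'   isotropic Gaussian jitter of sd `noiseSd` times the longest arm; labels
#'   are the arms. Unequal lengths and abundances make the arm-to-arm
#'   correspondence identifiable from distributional structure alone, which
#'   unpaired alignment requires.
#' * `swiss_roll`: the standard 3-D roll `(t cos t, h, t sin t)` with
#'   `t ~ U(1.5 pi, 4.5 pi)` and `h ~ U(0, 21)`; labels are t-tertiles.
#' * `circular_frustum`: points on a cone frustum surface (radius falling
#'   linearly from 1 to 0.5 with height, jitter `noiseSd`); labels are three
#'   angular sectors sampled with unequal weights (0.5/0.3/0.2) so that the
#'   angular density — and hence the sector correspondence — is identifiable
#'   despite the frustum's rotational geometry.
#'
#' Deterministic under `seed`.
#'
#' @param design one of `"branch"`, `"swiss_roll"`, `"circular_frustum"`.
#' @param n number of cells (>= 30).
#' @param seed RNG seed.
#' @param noiseSd jitter scale for branch/frustum (fraction of the structure
#'   scale).
#' @param clusterProbs abundance of the three clusters (branch arms /
#'   frustum sectors). The skewed default makes the cluster correspondence
#'   identifiable from mass alone; balanced probabilities leave only the
#'   geometry to identify it.
#' @return list with `latent` (n x 2 or n x 3 matrix) and `labels`
#'   (character vector, 3 classes).
#' @export
sampleManifold <- function(design = c("branch", "swiss_roll",
                                      "circular_frustum"),
                           n, seed = 1L, noiseSd = 0.05,
                           clusterProbs = c(0.5, 0.3, 0.2)) {
  design <- match.arg(design)
  n <- as.integer(n)
  if (n < 30L) stop("'n' must be at least 30")
  set.seed(seed)
  if (design == "branch") {
    arm <- sample(1:3, n, replace = TRUE, prob = clusterProbs)
    angles <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
    lengths <- c(1, 0.75, 0.5)
    t <- stats::runif(n) * lengths[arm]
    latent <- cbind(t * cos(angles[arm]), t * sin(angles[arm])) +
      matrix(stats::rnorm(2 * n, sd = noiseSd), n, 2)
    labels <- paste0("arm", arm)
  } else if (design == "swiss_roll") {
    t <- stats::runif(n, 1.5 * pi, 4.5 * pi)
    h <- stats::runif(n, 0, 21)
    latent <- cbind(t * cos(t), h, t * sin(t))
    tertile <- cut(t, stats::quantile(t, c(0, 1/3, 2/3, 1)),
                   include.lowest = TRUE, labels = FALSE)
    labels <- paste0("roll", tertile)
  } else {
    bounds <- c(0, 2 * pi / 3, 4 * pi / 3, 2 * pi)
    sector <- sample(1:3, n, replace = TRUE, prob = clusterProbs)
    theta <- stats::runif(n, bounds[sector], bounds[sector + 1L])
    h <- stats::runif(n)
    r <- 1 - 0.5 * h
    latent <- cbind(r * cos(theta), r * sin(theta), h) +
      matrix(stats::rnorm(3 * n, sd = noiseSd), n, 3)
    labels <- paste0("sector", sector)
  }
  list(latent = latent, labels = labels)
}

#' Nonlinear lift of latent coordinates into a high-dimensional feature space
#'
#' Projects manifold coordinates through a random one-hidden-layer map
#' `z -> tanh(z A1 + b1) A2` with seeded Gaussian weights (hidden width
#' `hidden`), plus additive Gaussian observation noise. Different seeds give
#' the independent per-domain lifts that emulate distinct modalities sharing
#' one latent manifold.
#'
#' @param latent n x p latent matrix.
#' @param targetDim output feature dimension (> p), e.g. 100, 1000 or 2000.
#' @param seed RNG seed (controls the weights and the noise).
#' @param hidden hidden-layer width.
#' @param noiseSd observation noise sd (0 disables noise).
#' @return n x targetDim numeric matrix.
#' @export
nonlinearLift <- function(latent, targetDim, seed = 1L, hidden = 50L,
                          noiseSd = 0.05) {
  latent <- as.matrix(latent)
  p <- ncol(latent)
  targetDim <- as.integer(targetDim)
  if (targetDim <= p) stop("'targetDim' must exceed the latent dimension")
  set.seed(seed)
  A1 <- matrix(stats::rnorm(p * hidden), p, hidden) / sqrt(p)
  b1 <- stats::rnorm(hidden, sd = 0.5)
  A2 <- matrix(stats::rnorm(hidden * targetDim), hidden, targetDim) /
    sqrt(hidden)
  H <- tanh(sweep(latent %*% A1, 2, b1, "+"))
  out <- H %*% A2
  if (noiseSd > 0)
    out <- out + matrix(stats::rnorm(length(out), sd = noiseSd),
                        nrow(out), ncol(out))
  out
}

#' Simulate a paired two-domain dataset from one manifold design
#'
#' Samples latent coordinates once, lifts them into two different
#' high-dimensional feature spaces (independent random lifts per domain),
#' then independently shuffles each domain's rows — retaining the true
#' pairing and the cluster labels for evaluation only. For
#' `design = "synthetic_counts"` the two domains are count matrices from the
#' gamma-Poisson hierarchy of [sampleSyntheticCounts()] instead of lifted
#' manifolds.
#'
#' @param design `"branch"`, `"swiss_roll"`, `"circular_frustum"` or
#'   `"synthetic_counts"`.
#' @param n cells per domain (default 300, the desk-scale size; the
#'   count design defaults to its own published scale when called through
#'   [sampleSyntheticCounts()]).
#' @param liftDim feature dimension of each lifted domain (e.g. 100 for
#'   desk-scale runs, 1000/2000 for full-scale).
#' @param seed RNG seed.
#' @param noiseSd jitter/observation noise scale passed to the generators.
#' @param clusterProbs cluster abundances for branch/frustum (see
#'   [sampleManifold()]).
#' @param nFeaturesCounts feature count for the count design (50 or 500).
#' @return A [SimulatedPair-class]; `x`/`y` carry labels, `trueMatch[i]`
#'   gives the y-row paired with x-row i.
#' @examples
#' sim <- simulatePair("branch", n = 60, liftDim = 20, seed = 7)
#' sim
#' @export
simulatePair <- function(design = c("branch", "swiss_roll",
                                    "circular_frustum", "synthetic_counts"),
                         n = 300L, liftDim = 100L, seed = 1L, noiseSd = 0.05,
                         clusterProbs = c(0.5, 0.3, 0.2),
                         nFeaturesCounts = 50L) {
  design <- match.arg(design)
  if (design == "synthetic_counts")
    return(sampleSyntheticCounts(n = n, d = nFeaturesCounts, seed = seed))
  man <- sampleManifold(design, n = n, seed = seed, noiseSd = noiseSd,
                        clusterProbs = clusterProbs)
  vx <- nonlinearLift(man$latent, liftDim, seed = seed * 1000L + 1L,
                      noiseSd = noiseSd)
  vy <- nonlinearLift(man$latent, liftDim, seed = seed * 1000L + 2L,
                      noiseSd = noiseSd)
  shufflePair(vx, vy, man$labels, man$latent, design, seed)
}

# independently permute both domains' rows, keeping the ground truth
shufflePair <- function(vx, vy, labels, latent, design, seed) {
  n <- nrow(vx)
  set.seed(seed + 17L)
  permX <- sample.int(n)
  permY <- sample.int(n)
  # x row i is original cell permX[i]; its partner sits at the y row holding
  # the same original cell: trueMatch[i] = position of permX[i] in permY
  posY <- integer(n); posY[permY] <- seq_len(n)
  trueMatch <- posY[permX]
  x <- ModalityData(vx[permX, , drop = FALSE], labels = labels[permX])
  y <- ModalityData(vy[permY, , drop = FALSE], labels = labels[permY])
  new("SimulatedPair", x = x, y = y,
      latent = as.matrix(latent)[permX, , drop = FALSE],
      trueMatch = as.integer(trueMatch), design = design)
}

#' Library-size normalize and log-transform a count matrix
#'
#' The standard RNA-seq preprocessing applied before distance-based analysis
#' of count data: counts are scaled to a common library size and
#' log1p-transformed. Without this step the leading principal component of a
#' count matrix is typically the per-cell sequencing depth rather than any
#' biological signal.
#'
#' @param counts cells x features count matrix (or [ModalityData-class]).
#' @param scaleTo target library size (default 1e4).
#' @return matrix (or [ModalityData-class], matching the input) of
#'   log-normalized values.
#' @export
logNormalizeCounts <- function(counts, scaleTo = 1e4) {
  wrap <- is(counts, "ModalityData")
  m <- if (wrap) counts@values else as.matrix(counts)
  lib <- pmax(rowSums(m), 1)
  out <- log1p(m / lib * scaleTo)
  if (wrap) ModalityData(out, labels = counts@labels) else out
}

#' Simulate paired RNA-seq-like count matrices
#'
#' A gamma-Poisson hierarchy emulating droplet RNA-seq counts with discrete
#' cell groups: per-feature baseline means are log-normal, a fraction
#' `deProb` of features carries a group-specific fold change of `foldChange`,
#' per-cell scale factors are gamma with unit mean, and expected feature
#' means are rescaled so each cell's expected library size equals
#' `librarySize` times its scale factor. The second domain uses the same
#' cells and group structure but independently drawn feature means and scale
#' factors, emulating a second modality. Both domains are independently
#' row-shuffled with the pairing retained.
#'
#' @param n cells per domain (default 5000).
#' @param d features per domain (50 or 500).
#' @param nGroups number of cell groups (>= 2 for group structure; 1 gives a
#'   single homogeneous population).
#' @param seed RNG seed.
#' @param deProb fraction of features that are differentially expressed per
#'   group.
#' @param foldChange fold change of DE features.
#' @param librarySize mean expected total counts per cell.
#' @return A [SimulatedPair-class] with integer count matrices in
#'   `x`/`y` and group labels attached.
#' @export
sampleSyntheticCounts <- function(n = 5000L, d = 50L, nGroups = 5L,
                                  seed = 1L, deProb = 0.2, foldChange = 4,
                                  librarySize = 2000) {
  n <- as.integer(n); d <- as.integer(d); nGroups <- as.integer(nGroups)
  if (nGroups < 1L) stop("'nGroups' must be >= 1")
  if (deProb < 0 || deProb > 1) stop("'deProb' must be in [0, 1]")
  if (foldChange <= 0 || librarySize <= 0)
    stop("'foldChange' and 'librarySize' must be positive")
  set.seed(seed)
  # unequal group abundances (geometric decay, as real cell-type frequencies
  # are skewed); the abundance profile is what identifies group-to-group
  # correspondence across modalities with independent feature spaces
  props <- 0.6^(seq_len(nGroups) - 1)
  group <- sample(seq_len(nGroups), n, replace = TRUE, prob = props)

  domainCounts <- function() {
    base <- stats::rlnorm(d, meanlog = 0, sdlog = 0.5)
    mu <- matrix(base, nGroups, d, byrow = TRUE)
    if (nGroups > 1L) {
      for (gId in seq_len(nGroups)) {
        de <- stats::runif(d) < deProb
        up <- stats::runif(d) < 0.5
        mu[gId, de & up] <- mu[gId, de & up] * foldChange
        mu[gId, de & !up] <- mu[gId, de & !up] / foldChange
      }
    }
    sizeFactor <- stats::rgamma(n, shape = 10, rate = 10)  # unit mean
    M <- mu[group, , drop = FALSE]
    M <- M / rowSums(M) * librarySize * sizeFactor
    counts <- matrix(stats::rpois(n * d, lambda = M), n, d)
    colnames(counts) <- paste0("feat", seq_len(d))
    counts
  }
  vx <- domainCounts()
  vy <- domainCounts()
  shufflePair(vx, vy, paste0("group", group),
              latent = matrix(as.numeric(group), n, 1),
              design = "synthetic_counts", seed = seed)
}
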