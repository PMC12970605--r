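#' Bipartite modularity of a joint row/column partition
#'
#' Treats the transport plan as a weighted bipartite graph and scores a
#' simultaneous partition of its rows and columns against the degree-product
#' null model:
#' `Q = (1/m) sum_ij (T_ij - r_i c_j / m) 1[rowAssign_i == colAssign_j]`,
#' with `m` the total mass and `r`, `c` the row/column masses. Q lies in
#' `[-1, 1]`; a single all-in-one cluster scores exactly 0.
#'
#' @param plan a [TransportPlan-class] or nonnegative matrix.
#' @param rowAssign,colAssign integer cluster ids (same label space for rows
#'   and columns); `NA` entries are excluded.
#' @return scalar modularity.
#' @export
bipartiteModularity <- function(plan, rowAssign, colAssign) {
  T <- if (is(plan, "TransportPlan")) plan@plan else as.matrix(plan)
  m <- sum(T)
  if (m <= 0) stop("empty plan: total mass must be positive")
  if (length(rowAssign) != nrow(T) || length(colAssign) != ncol(T))
    stop("assignment lengths must match the plan dimensions")
  B <- T - outer(rowSums(T), colSums(T)) / m
  labs <- sort(unique(c(rowAssign, colAssign)))
  labs <- labs[!is.na(labs)]
  q <- 0
  for (l in labs) {
    ri <- which(rowAssign == l); cj <- which(colAssign == l)
    if (length(ri) && length(cj))
      q <- q + sum(B[ri, cj, drop = FALSE])
  }
  q / m
}

#' Co-cluster the two cell sets through the transport plan
#'
#' Alternating maximization of bipartite modularity on the transport plan:
#' with column assignments fixed, every row moves to the cluster maximizing
#' its modularity contribution (ties to the lower cluster id), then the
#' columns move symmetrically; sweeps repeat until no assignment changes or
#' `maxSweeps` is reached. Modularity never decreases across sweeps. The best
#' partition over `nRestarts` seeded initializations is kept (the first
#' restart is a k-means start on the plan profiles, the rest are uniform
#' random).
#'
#' @param plan a [TransportPlan-class] or nonnegative matrix.
#' @param nClusters number of clusters, `2 <= nClusters <= min(n_x, n_y)`.
#' @param seed RNG seed controlling the restarts.
#' @param nRestarts number of initializations.
#' @param maxSweeps sweep budget per restart.
#' @return A [CoClustering-class] object.
#' @export
coCluster <- function(plan, nClusters, seed = 1L, nRestarts = 100L,
                      maxSweeps = 100L) {
  T <- if (is(plan, "TransportPlan")) plan@plan else as.matrix(plan)
  nClusters <- as.integer(nClusters)
  if (nClusters < 2L) stop("'nClusters' must be >= 2")
  if (nClusters > min(dim(T)))
    stop("'nClusters' exceeds min(n_x, n_y)")
  m <- sum(T)
  if (m <= 0) stop("empty plan: total mass must be positive")
  B <- (T - outer(rowSums(T), colSums(T)) / m) / m
  nx <- nrow(T); ny <- ncol(T)

  set.seed(seed)
  bestQ <- -Inf; bestRa <- NULL; bestCa <- NULL
  for (r in seq_len(nRestarts)) {
    if (r == 1L) {
      ra <- tryCatch(suppressWarnings(
        stats::kmeans(T / pmax(rowSums(T), .Machine$double.eps), nClusters,
                      nstart = 5L)$cluster),
        error = function(e) sample.int(nClusters, nx, replace = TRUE))
      ca <- maxAssign(t(B), ra, nClusters)
    } else {
      ra <- sample.int(nClusters, nx, replace = TRUE)
      ca <- sample.int(nClusters, ny, replace = TRUE)
    }
    q <- sweepModularity(B, ra, ca)
    for (s in seq_len(maxSweeps)) {
      ra2 <- maxAssign(B, ca, nClusters)
      ca2 <- maxAssign(t(B), ra2, nClusters)
      q2 <- sweepModularity(B, ra2, ca2)
      unchanged <- all(ra2 == ra) && all(ca2 == ca)
      ra <- ra2; ca <- ca2; q <- q2
      if (unchanged) break
    }
    if (q > bestQ) { bestQ <- q; bestRa <- ra; bestCa <- ca }
  }
  new("CoClustering", rowAssignments = as.integer(bestRa),
      colAssignments = as.integer(bestCa), nClusters = nClusters,
      modularity = bestQ, pruned = integer(0))
}

# assign each row of B to the cluster maximizing its summed contribution
# against the fixed partner assignments; ties to the lower cluster id
maxAssign <- function(B, partnerAssign, nClusters) {
  G <- matrix(0, length(partnerAssign), nClusters)
  G[cbind(seq_along(partnerAssign), partnerAssign)] <- 1
  S <- B %*% G
  max.col(S, ties.method = "first")
}

sweepModularity <- function(B, ra, ca) {
  q <- 0
  for (l in unique(c(ra, ca))) {
    ri <- which(ra == l); cj <- which(ca == l)
    if (length(ri) && length(cj)) q <- q + sum(B[ri, cj, drop = FALSE])
  }
  q
}

#' Choose the cluster count by a reconstruction-error elbow
#'
#' For each candidate k, co-clusters the plan by a reconstruction-minimizing
#' alternating block-means procedure (each co-cluster block of the plan is
#' replaced by its mean) and records the Frobenius reconstruction error
#' `e(k) = ||T - That_k||_F`. Candidates are initialized by refining the
#' previous k's solution (splitting the cluster contributing most residual),
#' so `e(k)` is non-increasing in k by construction. The selected `kStar`
#' maximizes the discrete curvature (second difference) of the error curve; a
#' flat or linear curve has no elbow and returns the smallest k with a
#' warning.
#'
#' @param plan a [TransportPlan-class] or nonnegative matrix.
#' @param kRange increasing integer vector of at least 3 candidate values.
#' @param seed RNG seed for the per-k restarts.
#' @param nRestarts extra random restarts per k beyond the nested start.
#' @return list with `kStar` and `errorCurve` (data.frame `k`, `error`).
#' @export
selectKElbow <- function(plan, kRange, seed = 1L, nRestarts = 3L) {
  T <- if (is(plan, "TransportPlan")) plan@plan else as.matrix(plan)
  kRange <- sort(unique(as.integer(kRange)))
  if (length(kRange) < 3L) stop("'kRange' needs at least 3 values")
  set.seed(seed)
  errs <- numeric(length(kRange))
  prev <- NULL
  for (idx in seq_along(kRange)) {
    k <- kRange[idx]
    sol <- blockMeansCocluster(T, k, prev = prev, nRestarts = nRestarts)
    errs[idx] <- sol$error
    prev <- sol
  }
  curve <- data.frame(k = kRange, error = errs)
  scale <- max(errs[1], .Machine$double.eps)
  if (length(kRange) < 3L || diff(range(errs)) <= 1e-12 * scale) {
    warning("flat reconstruction-error curve: no elbow, returning smallest k")
    return(list(kStar = kRange[1], errorCurve = curve))
  }
  curv <- errs[-c(length(errs) - 1L, length(errs))] -
    2 * errs[-c(1L, length(errs))] + errs[-(1:2)]
  if (max(curv) <= 1e-12 * scale) {
    warning("no distinct elbow in the error curve, returning smallest k")
    return(list(kStar = kRange[1], errorCurve = curve))
  }
  list(kStar = kRange[1L + which.max(curv)], errorCurve = curve)
}

# alternating block-means co-clustering minimizing ||T - That||_F^2
blockMeansCocluster <- function(T, k, prev = NULL, nRestarts = 3L,
                                maxSweeps = 50L) {
  nx <- nrow(T); ny <- ncol(T)
  starts <- list()
  if (!is.null(prev)) starts[[length(starts) + 1L]] <-
      splitWorstCluster(T, prev$ra, prev$ca, k)
  km <- tryCatch(list(
    ra = stats::kmeans(T, min(k, nx - 1L), nstart = 1L)$cluster,
    ca = stats::kmeans(t(T), min(k, ny - 1L), nstart = 1L)$cluster),
    error = function(e) NULL)
  if (!is.null(km)) starts[[length(starts) + 1L]] <- km
  for (r in seq_len(nRestarts))
    starts[[length(starts) + 1L]] <- list(
      ra = sample.int(k, nx, replace = TRUE),
      ca = sample.int(k, ny, replace = TRUE))

  best <- NULL
  for (st in starts) {
    ra <- st$ra; ca <- st$ca
    for (s in seq_len(maxSweeps)) {
      M <- blockMeans(T, ra, ca, k)
      ra2 <- assignRowsToBlocks(T, M, ca, k)
      M <- blockMeans(T, ra2, ca, k)
      ca2 <- assignRowsToBlocks(t(T), t(M), ra2, k)
      unchanged <- all(ra2 == ra) && all(ca2 == ca)
      ra <- ra2; ca <- ca2
      if (unchanged) break
    }
    That <- blockMeans(T, ra, ca, k)[cbind(rep(ra, ny), rep(ca, each = nx))]
    err <- sqrt(sum((T - matrix(That, nx, ny))^2))
    if (is.null(best) || err < best$error)
      best <- list(ra = ra, ca = ca, error = err)
  }
  best
}

blockMeans <- function(T, ra, ca, k) {
  Gr <- matrix(0, nrow(T), k); Gr[cbind(seq_len(nrow(T)), ra)] <- 1
  Gc <- matrix(0, ncol(T), k); Gc[cbind(seq_len(ncol(T)), ca)] <- 1
  sums <- crossprod(Gr, T) %*% Gc
  cnt <- outer(colSums(Gr), colSums(Gc))
  M <- sums / ifelse(cnt > 0, cnt, 1)
  M
}

assignRowsToBlocks <- function(T, M, ca, k) {
  # squared error of putting row i in row-cluster c: sum_j (T_ij - M[c, ca_j])^2
  Gc <- matrix(0, ncol(T), k); Gc[cbind(seq_len(ncol(T)), ca)] <- 1
  nc <- colSums(Gc)
  Mc <- M %*% t(Gc)                               # k x ny expanded means
  err <- matrix(rowSums(Mc^2), nrow(T), k, byrow = TRUE) - 2 * T %*% t(Mc)
  max.col(-err, ties.method = "first")
}

splitWorstCluster <- function(T, ra, ca, k) {
  # refine a (k-1)-solution: split the cluster with the largest residual
  kPrev <- max(c(ra, ca))
  M <- blockMeans(T, ra, ca, kPrev)
  res <- numeric(kPrev)
  for (l in seq_len(kPrev)) {
    ri <- which(ra == l); cj <- which(ca == l)
    sub <- T[ri, , drop = FALSE]
    if (length(ri))
      res[l] <- res[l] + sum((sub - matrix(M[l, ca], length(ri),
                                           ncol(T), byrow = TRUE))^2)
  }
  worst <- which.max(res)
  ra2 <- ra; ca2 <- ca
  ri <- which(ra == worst)
  if (length(ri) >= 2L) {
    ord <- order(rowSums(T[ri, , drop = FALSE]))
    ra2[ri[ord[seq_len(floor(length(ri) / 2))]]] <- k
  }
  cj <- which(ca == worst)
  if (length(cj) >= 2L) {
    ord <- order(colSums(T[, cj, drop = FALSE]))
    ca2[cj[ord[seq_len(floor(length(cj) / 2))]]] <- k
  }
  list(ra = ra2, ca = ca2)
}

#' Prune small co-clusters as noise
#'
#' Removes clusters whose combined row + column membership is below
#' `minCells`: their members are flagged `NA` and the surviving clusters are
#' re-indexed densely (ascending original id).
#'
#' @param clusters a [CoClustering-class].
#' @param minCells minimum combined size to survive (default 20).
#' @return A [CoClustering-class] with pruned members set to `NA` and the
#'   `pruned` slot listing removed original cluster ids.
#' @export
pruneSmall <- function(clusters, minCells = 20L) {
  stopifnot(is(clusters, "CoClustering"))
  ra <- clusters@rowAssignments; ca <- clusters@colAssignments
  ids <- sort(unique(c(ra, ca)))
  ids <- ids[!is.na(ids)]
  sizes <- vapply(ids, function(l)
    sum(ra == l, na.rm = TRUE) + sum(ca == l, na.rm = TRUE), integer(1))
  drop <- ids[sizes < minCells]
  keep <- ids[sizes >= minCells]
  remap <- rep(NA_integer_, max(ids))
  remap[keep] <- seq_along(keep)
  ra2 <- ifelse(is.na(ra) | ra %in% drop, NA_integer_, remap[ra])
  ca2 <- ifelse(is.na(ca) | ca %in% drop, NA_integer_, remap[ca])
  new("CoClustering", rowAssignments = as.integer(ra2),
      colAssignments = as.integer(ca2), nClusters = length(keep),
      modularity = clusters@modularity,
      pruned = as.integer(c(clusters@pruned, drop)))
}
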