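# Independent oracle implementations used to check the vectorized paths.
# These are deliberately written as plain double loops / direct minimization
# and must stay independent of the package internals they verify.

# entrywise Gaussian Gram by explicit double loop
gramOracle <- function(x, sigma) {
  n <- nrow(x)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-sum((x[i, ] - x[j, ])^2) / (2 * sigma^2))
  K
}

crossKernelOracle <- function(train, query, sigma) {
  K <- matrix(0, nrow(query), nrow(train))
  for (q in seq_len(nrow(query))) for (i in seq_len(nrow(train)))
    K[q, i] <- exp(-sum((query[q, ] - train[i, ])^2) / (2 * sigma^2))
  K
}

# half the adjacency-weighted sum of squared embedding differences
smoothnessOracle <- function(emb, W) {
  v <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W)))
    v <- v + W[i, j] * sum((emb[i, ] - emb[j, ])^2)
  v / 2
}

# entropic OT between two 2-point clouds with uniform marginals: the
# transport polytope is one-dimensional, parameterized by t = T[1, 1];
# minimize <C,T> + eps * KL(T | a x b) directly on the segment.
entropic2x2Oracle <- function(xe, ye, eps) {
  C <- outer(seq_len(2), seq_len(2),
             Vectorize(function(i, j) sum((xe[i, ] - ye[j, ])^2)))
  ab <- 0.25
  obj <- function(t) {
    T <- matrix(c(t, 0.5 - t, 0.5 - t, t), 2, 2)
    kl <- sum(ifelse(T > 0, T * log(T / ab), 0)) - sum(T) + 1
    sum(C * T) + eps * kl
  }
  opt <- stats::optimize(obj, c(1e-12, 0.5 - 1e-12), tol = 1e-12)
  t <- opt$minimum
  list(plan = matrix(c(t, 0.5 - t, 0.5 - t, t), 2, 2), cost = opt$objective)
}

# FOSCTTM by explicit double loop
foscttmOracle <- function(xe, ye, trueMatch = seq_len(nrow(xe))) {
  n <- nrow(xe)
  r <- numeric(n)
  for (i in seq_len(n)) {
    dstar <- sqrt(sum((xe[i, ] - ye[trueMatch[i], ])^2))
    cnt <- 0
    for (j in seq_len(n)) {
      if (j == trueMatch[i]) next
      if (sqrt(sum((xe[i, ] - ye[j, ])^2)) < dstar) cnt <- cnt + 1
    }
    r[i] <- cnt / (n - 1)
  }
  mean(r)
}

# bipartite modularity by direct formula
modularityOracle <- function(T, ra, ca) {
  m <- sum(T)
  r <- rowSums(T); cs <- colSums(T)
  q <- 0
  for (i in seq_len(nrow(T))) for (j in seq_len(ncol(T)))
    if (ra[i] == ca[j]) q <- q + T[i, j] - r[i] * cs[j] / m
  q / m
}

# best bipartite modularity over all assignments of a small plan into
# nClusters labels (exhaustive search)
bestModularityExhaustive <- function(T, nClusters) {
  nx <- nrow(T); ny <- ncol(T)
  gridRows <- expand.grid(rep(list(seq_len(nClusters)), nx))
  gridCols <- expand.grid(rep(list(seq_len(nClusters)), ny))
  best <- -Inf
  for (i in seq_len(nrow(gridRows))) for (j in seq_len(nrow(gridCols))) {
    q <- modularityOracle(T, as.integer(gridRows[i, ]),
                          as.integer(gridCols[j, ]))
    if (q > best) best <- q
  }
  best
}

# fixture: a noisy block plan with nb blocks of the given sizes
blockPlan <- function(rowSizes, colSizes, noise = 0, seed = 1) {
  set.seed(seed)
  nb <- length(rowSizes)
  T <- matrix(noise * runif(sum(rowSizes) * sum(colSizes)),
              sum(rowSizes), sum(colSizes))
  r0 <- c(0, cumsum(rowSizes)); c0 <- c(0, cumsum(colSizes))
  for (b in seq_len(nb))
    T[(r0[b] + 1):r0[b + 1], (c0[b] + 1):c0[b + 1]] <- 1
  T / sum(T)
}
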