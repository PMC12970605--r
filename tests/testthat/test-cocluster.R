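test_that("bipartite modularity matches the direct formula and anchors", {
  set.seed(61)
  T <- matrix(runif(20), 4, 5)
  ra <- c(1, 2, 1, 2); ca <- c(1, 1, 2, 2, 1)
  expect_equal(bipartiteModularity(T, ra, ca),
               modularityOracle(T, ra, ca), tolerance = 1e-12)
  # everything in one cluster: null-model mass equals total mass
  expect_equal(bipartiteModularity(T, rep(1, 4), rep(1, 5)), 0,
               tolerance = 1e-12)
  # exact 2-block diagonal with equal blocks: Q = 1 - 2 * (1/2)^2 = 0.5
  B <- blockPlan(c(2, 2), c(2, 2))
  expect_equal(bipartiteModularity(B, c(1, 1, 2, 2), c(1, 1, 2, 2)), 0.5,
               tolerance = 1e-12)
  expect_error(bipartiteModularity(matrix(0, 2, 2), c(1, 1), c(1, 1)),
               "mass")
})

test_that("alternating sweeps reach near-optimal modularity on 4x4 plans", {
  set.seed(62)
  for (rep in 1:3) {
    T <- matrix(runif(16), 4, 4)
    best <- bestModularityExhaustive(T, 2)
    cc <- coCluster(T, 2, seed = rep, nRestarts = 20)
    expect_gte(cc@modularity, 0.95 * best)
    # random assignments never beat the exhaustive optimum
    expect_lte(bipartiteModularity(T, sample(1:2, 4, TRUE),
                                   sample(1:2, 4, TRUE)), best + 1e-12)
  }
})

test_that("modularity never decreases across alternating sweeps", {
  set.seed(63)
  T <- blockPlan(c(6, 5, 4), c(5, 5, 5), noise = 0.15, seed = 2)
  m <- sum(T)
  B <- (T - outer(rowSums(T), colSums(T)) / m) / m
  ra <- sample(1:3, nrow(T), TRUE); ca <- sample(1:3, ncol(T), TRUE)
  q <- scGraphOT:::sweepModularity(B, ra, ca)
  for (s in 1:10) {
    ra <- scGraphOT:::maxAssign(B, ca, 3)
    ca <- scGraphOT:::maxAssign(t(B), ra, 3)
    q2 <- scGraphOT:::sweepModularity(B, ra, ca)
    expect_gte(q2, q - 1e-12)
    q <- q2
  }
})

test_that("separable block plans are recovered exactly", {
  T <- blockPlan(c(8, 7), c(6, 9))
  truthR <- rep(1:2, c(8, 7)); truthC <- rep(1:2, c(6, 9))
  for (seed in 1:5) {
    cc <- coCluster(T, 2, seed = seed, nRestarts = 3)
    sc <- clusteringScores(c(cc@rowAssignments, cc@colAssignments),
                           c(truthR, truthC))
    expect_equal(sc$ari, 1)
  }
})

test_that("noisy 3-block plans are recovered and row permutation commutes", {
  T <- blockPlan(c(10, 8, 7), c(9, 8, 8), noise = 0.05, seed = 3)
  truthR <- rep(1:3, c(10, 8, 7)); truthC <- rep(1:3, c(9, 8, 8))
  cc <- coCluster(T, 3, seed = 1)
  sc <- clusteringScores(c(cc@rowAssignments, cc@colAssignments),
                         c(truthR, truthC))
  expect_gte(sc$ari, 0.9)
  # permuting the plan rows permutes the row assignments identically
  perm <- sample(nrow(T))
  ccP <- coCluster(T[perm, ], 3, seed = 1)
  expect_equal(clusteringScores(ccP@rowAssignments,
                                cc@rowAssignments[perm])$ari, 1)
})

test_that("reconstruction-error elbow finds the true block count", {
  T <- blockPlan(c(9, 8, 8), c(8, 9, 8), seed = 4)
  sel <- selectKElbow(T, 2:6, seed = 1)
  expect_equal(sel$kStar, 3)
  e <- sel$errorCurve$error
  expect_equal(e[sel$errorCurve$k == 3], 0, tolerance = 1e-10)
  expect_true(all(diff(e) <= 1e-10))  # monotone non-increasing
  # a structureless constant plan has no elbow
  flat <- matrix(1 / 120, 10, 12)
  expect_warning(self <- selectKElbow(flat, 2:5, seed = 1), "elbow|flat")
  expect_equal(self$kStar, 2)
  expect_error(selectKElbow(T, 2:3), "3 values")
})

test_that("elbow errors are monotone on noisy plans too", {
  T <- blockPlan(c(10, 9, 8), c(9, 9, 9), noise = 0.2, seed = 5)
  sel <- selectKElbow(T, 2:7, seed = 2)
  expect_true(all(diff(sel$errorCurve$error) <= 1e-10))
})

test_that("small co-clusters are pruned at the documented boundary", {
  mk <- function(sizes) {
    ra <- rep(seq_along(sizes), sizes)
    new("CoClustering", rowAssignments = as.integer(ra),
        colAssignments = as.integer(ra), nClusters = length(sizes),
        modularity = 0.5, pruned = integer(0))
  }
  # combined membership: rows + cols; cluster 2 has 2 * 9 = 18 < 20 members
  cc <- pruneSmall(mk(c(12, 9)), minCells = 20)
  expect_equal(cc@nClusters, 1L)
  expect_true(all(is.na(cc@rowAssignments[13:21])))
  expect_equal(cc@pruned, 2L)
  # exactly 20 combined members survives
  cc2 <- pruneSmall(mk(c(12, 10)), minCells = 20)
  expect_equal(cc2@nClusters, 2L)
  expect_false(anyNA(cc2@rowAssignments))
  # all clusters large: identity transformation
  cc3 <- pruneSmall(mk(c(15, 15)), minCells = 20)
  expect_identical(cc3@rowAssignments, mk(c(15, 15))@rowAssignments)
})
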