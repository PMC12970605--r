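test_that("FOSCTTM anchors: perfect, anti-matched and random alignments", {
  set.seed(71)
  xe <- matrix(rnorm(40), 20, 2)
  expect_equal(foscttm(xe, xe)$foscttm, 0)
  # two points swapped: every other sample is closer than the true match
  a <- matrix(c(0, 1), 2, 1); b <- matrix(c(1, 0), 2, 1)
  f <- foscttm(a, b)
  expect_equal(f$perSample, c(1, 1))
  expect_equal(f$foscttm, 1)
  # independent clouds sit at the exchangeable baseline of one half
  x5 <- matrix(rnorm(500 * 3), 500, 3)
  y5 <- matrix(rnorm(500 * 3), 500, 3)
  expect_lt(abs(foscttm(x5, y5)$foscttm - 0.5), 0.03)
  expect_error(foscttm(xe, xe[1:10, ]), "equally sized")
})

test_that("vectorized FOSCTTM equals the double loop exactly", {
  set.seed(72)
  for (n in c(10, 40, 100)) {
    xe <- matrix(rnorm(n * 2), n, 2)
    ye <- xe + matrix(rnorm(n * 2, sd = 0.5), n, 2)
    tm <- sample(n)
    expect_identical(foscttm(xe, ye, tm)$foscttm, foscttmOracle(xe, ye, tm))
  }
})

test_that("FOSCTTM is invariant under joint isometries", {
  set.seed(73)
  xe <- matrix(rnorm(30 * 3), 30, 3)
  ye <- xe + matrix(rnorm(90, sd = 0.3), 30, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  shift <- matrix(rep(c(2, -1, 5), each = 30), 30, 3)
  f0 <- foscttm(xe, ye)$foscttm
  f1 <- foscttm(xe %*% Q + shift, ye %*% Q + shift)$foscttm
  expect_equal(f0, f1)
})

test_that("symmetric FOSCTTM averages the two directions", {
  set.seed(74)
  xe <- matrix(rnorm(20), 10, 2); ye <- matrix(rnorm(20), 10, 2)
  tm <- sample(10)
  fwd <- foscttm(xe, ye, tm)$foscttm
  rev <- foscttm(ye, xe, order(tm))$foscttm
  expect_equal(foscttm(xe, ye, tm, symmetric = TRUE)$foscttm,
               (fwd + rev) / 2)
})

test_that("label transfer accuracy matches hand computation", {
  xe <- matrix(rnorm(20), 10, 2)
  expect_equal(labelTransferAccuracy(xe, xe, rep(c("A", "B"), 5),
                                     rep(c("A", "B"), 5), k = 1), 1)
  # adversarial labels: no neighbor ever shares the query label
  labs <- rep(c("A", "B"), each = 3)
  pts <- matrix(c(0, 0, 0.1, 0, 0.2, 0, 5, 0, 5.1, 0, 5.2, 0),
                6, 2, byrow = TRUE)
  expect_equal(labelTransferAccuracy(pts, pts, labs, rev(labs), k = 1), 0)
  # 6-point two-cluster toy with k = 3, checked against enumerated neighbors
  ly <- c("A", "A", "B", "A", "B", "B")
  got <- labelTransferAccuracy(pts, pts, labs, ly, k = 3)
  # cluster 1 neighbors = {1,2,3} -> mode A; cluster 2 = {4,5,6} -> mode B
  expect_equal(got, mean(c("A", "A", "A", "B", "B", "B") == labs))
  expect_error(labelTransferAccuracy(pts, pts, labs, ly, k = 9), "k")
})

test_that("label transfer with k = |Y| degenerates to the global mode", {
  set.seed(75)
  xe <- matrix(rnorm(24), 12, 2); ye <- matrix(rnorm(24), 12, 2)
  lx <- sample(c("A", "B", "C"), 12, TRUE)
  ly <- c(rep("A", 7), rep("B", 5))  # global mode is A
  expect_equal(labelTransferAccuracy(xe, ye, lx, ly, k = 12),
               mean(lx == "A"))
})

test_that("clustering scores match hand-computed contingency values", {
  p <- c(1, 1, 1, 2, 2, 2)
  expect_equal(clusteringScores(p, p), list(ari = 1, nmi = 1, purity = 1))
  # one predicted cluster against two balanced classes
  sc <- clusteringScores(rep(1, 8), rep(1:2, each = 4))
  expect_equal(sc$ari, 0)
  expect_equal(sc$purity, 0.5)
  expect_equal(sc$nmi, 0)
  # 8-point toy: contingency [[3, 1], [0, 4]]
  pred <- c(1, 1, 1, 1, 2, 2, 2, 2)
  truth <- c("a", "a", "a", "b", "b", "b", "b", "b")
  sc2 <- clusteringScores(pred, truth)
  expect_equal(sc2$purity, (3 + 4) / 8)
  pij <- matrix(c(3, 0, 1, 4), 2, 2) / 8
  pr <- rowSums(pij); pc <- colSums(pij)
  mi <- sum(pij[pij > 0] * log(pij[pij > 0] /
                                 outer(pr, pc)[pij > 0]))
  expect_equal(sc2$nmi, 2 * mi / (-sum(pr * log(pr)) - sum(pc * log(pc))))
  # pruned cells are excluded pairwise
  expect_equal(clusteringScores(c(p, NA), c(p, 1))$ari, 1)
  expect_error(clusteringScores(c(NA, NA), c(1, 2)), "pruned")
})

test_that("arithmetic-normalized NMI agrees with igraph's implementation", {
  skip_if_not_installed("igraph")
  set.seed(76)
  for (rep in 1:4) {
    a <- sample(1:3, 30, TRUE); b <- sample(1:4, 30, TRUE)
    expect_equal(clusteringScores(a, b)$nmi,
                 igraph::compare(a, b, method = "nmi"), tolerance = 1e-12)
  }
})

test_that("the random-pairing null distribution centers at one half", {
  set.seed(77)
  xe <- matrix(rnorm(120), 60, 2)
  ye <- xe + matrix(rnorm(120, sd = 0.1), 60, 2)
  null <- foscttmNull(xe, ye, nPerm = 200, seed = 4)
  expect_equal(length(null), 200L)
  expect_lt(abs(mean(null) - 0.5), 0.05)
  expect_lt(foscttm(xe, ye)$foscttm, quantile(null, 0.01))
})
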