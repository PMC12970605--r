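test_that("entropic OT on singletons and identical clouds is exact", {
  p <- matrix(c(0.5, -1), 1, 2); q <- matrix(c(2, 1), 1, 2)
  o <- entropicOTCost(p, q, epsilon = 0.1)
  expect_equal(planMatrix(o$plan), matrix(1, 1, 1))
  expect_equal(o$cost, sum((p - q)^2), tolerance = 1e-12)

  set.seed(31)
  xe <- matrix(rnorm(12), 6, 2)
  o2 <- entropicOTCost(xe, xe, epsilon = 0.01)
  # self-coupling at small blur concentrates on the diagonal
  expect_equal(unname(apply(planMatrix(o2$plan), 1, which.max)), 1:6)
  expect_lt(sum(diag(planMatrix(o2$plan)) < 1 / 6 * 0.9), 1)
})

test_that("2x2 entropic plan and cost match a direct-minimization oracle", {
  xe <- matrix(c(0, 1), 2, 1); ye <- matrix(c(0, 1), 2, 1)
  o <- entropicOTCost(xe, ye, epsilon = 0.05)
  orc <- entropic2x2Oracle(xe, ye, 0.05)
  expect_equal(planMatrix(o$plan), orc$plan, tolerance = 1e-4)
  expect_equal(o$cost, orc$cost, tolerance = 1e-4)
  # a second geometry
  ye2 <- matrix(c(0.3, 1.4), 2, 1)
  o2 <- entropicOTCost(xe, ye2, epsilon = 0.1, tol = 1e-10,
                       maxIter = 1e5)
  orc2 <- entropic2x2Oracle(xe, ye2, 0.1)
  expect_equal(o2$cost, orc2$cost, tolerance = 1e-4)
})

test_that("balanced plans conserve their marginals and total mass", {
  set.seed(32)
  xe <- matrix(rnorm(14), 7, 2); ye <- matrix(rnorm(10), 5, 2)
  o <- entropicOTCost(xe, ye, epsilon = 0.2)
  T <- planMatrix(o$plan)
  expect_lt(max(abs(rowSums(T) - 1 / 7)), 1e-6)
  expect_lt(max(abs(colSums(T) - 1 / 5)), 1e-6)
  expect_equal(sum(T), 1, tolerance = 1e-6)
  expect_true(all(T >= 0))
})

test_that("very large blur drives the plan to the independent coupling", {
  set.seed(33)
  xe <- matrix(rnorm(8), 4, 2); ye <- matrix(rnorm(8), 4, 2)
  o <- entropicOTCost(xe, ye, epsilon = 1e4)
  expect_equal(planMatrix(o$plan), matrix(1 / 16, 4, 4), tolerance = 1e-3)
})

test_that("unbalanced mode relaxes marginals but keeps mass bounded", {
  set.seed(34)
  xe <- matrix(rnorm(10), 5, 2)
  ye <- matrix(rnorm(10) + 3, 5, 2)  # far cloud: unbalanced drops mass
  o <- entropicOTCost(xe, ye, epsilon = 0.1, reach = 0.5)
  expect_true(all(planMatrix(o$plan) >= 0))
  expect_lte(sum(planMatrix(o$plan)), 1 + 1e-6)
  expect_lt(sum(planMatrix(o$plan)), 0.9)  # deviation is penalized, not forced
})

test_that("Sinkhorn divergence is debiased, symmetric and nonnegative", {
  set.seed(35)
  xe <- matrix(rnorm(16), 8, 2); ye <- matrix(rnorm(16) + 0.5, 8, 2)
  expect_lte(abs(sinkhornDivergence(xe, xe, 0.1)), 1e-6)
  d1 <- sinkhornDivergence(xe, ye, 0.1)
  d2 <- sinkhornDivergence(ye, xe, 0.1)
  expect_lte(abs(d1 - d2), 1e-9)
  for (rep in 1:5) {
    a <- matrix(rnorm(10), 5, 2); b <- matrix(rnorm(10), 5, 2)
    expect_gte(sinkhornDivergence(a, b, 0.3), -1e-6)
  }
  # separated clusters diverge more than co-located ones
  near <- matrix(rnorm(20, sd = 0.1), 10, 2)
  far <- near + 5
  expect_gt(sinkhornDivergence(near, far, 0.1),
            sinkhornDivergence(near, near + 0.01, 0.1))
})

test_that("increasing blur never sharpens the plan", {
  set.seed(36)
  xe <- matrix(rnorm(12), 6, 2); ye <- matrix(rnorm(12), 6, 2)
  sharp <- vapply(c(0.05, 0.2, 1, 5), function(e)
    max(planMatrix(entropicOTCost(xe, ye, e)$plan)), numeric(1))
  expect_true(all(diff(sharp) <= 1e-12))
})

test_that("divergence gradients match central finite differences", {
  set.seed(37)
  xe <- matrix(rnorm(10), 5, 2); ye <- matrix(rnorm(10), 5, 2)
  eps <- 0.3; h <- 1e-6
  g <- sinkhornDivergence(xe, ye, eps, gradient = TRUE,
                          tol = 1e-10, maxIter = 5000)
  num <- xe * 0
  for (i in 1:5) for (j in 1:2) {
    xp <- xe; xp[i, j] <- xp[i, j] + h
    xm <- xe; xm[i, j] <- xm[i, j] - h
    num[i, j] <- (sinkhornDivergence(xp, ye, eps, tol = 1e-10,
                                     maxIter = 5000) -
                  sinkhornDivergence(xm, ye, eps, tol = 1e-10,
                                     maxIter = 5000)) / (2 * h)
  }
  expect_lt(max(abs(g$gradX - num) / (abs(num) + 1e-8)), 1e-3)
})

test_that("invalid transport parameters are rejected up front", {
  xe <- matrix(c(0, 1), 2, 1); ye <- matrix(c(0, 1), 2, 1)
  expect_error(entropicOTCost(xe, ye, epsilon = 0), "epsilon")
  expect_error(entropicOTCost(xe, ye, epsilon = 0.1, reach = -1), "reach")
  expect_error(entropicOTCost(xe, matrix(0, 2, 2), 0.1), "dimensions differ")
})

test_that("the plan of a trained model recovers true partners", {
  # perfectly aligned paired data: the second domain is a shuffled copy of
  # the first, so the true partner sits at zero distance once aligned
  sim <- simulatePair("branch", n = 80, liftDim = 30, seed = 11)
  vals <- cellValues(sim@x)
  set.seed(1)
  perm <- sample(80)
  fit <- fitIntegration(vals, vals[perm, ],
                        otConfig(lambda_ortho = 1, max_epochs = 60))
  plan <- extractPlan(fit)
  expect_s4_class(plan, "TransportPlan")
  T <- planMatrix(plan)
  expect_lt(max(abs(rowSums(T) - 1 / 80)), 1e-6)
  trueMatch <- order(perm)  # y-row holding x-row i
  hits <- mean(apply(T, 1, which.max) == trueMatch)
  expect_gte(hits, 0.95)
})
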