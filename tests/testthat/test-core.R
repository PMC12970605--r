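# small paired fixture shared across the blocks below
coreSim <- simulatePair("branch", n = 60, liftDim = 20, seed = 41)

test_that("objective decomposes exactly into its weighted components", {
  fit <- fitIntegration(coreSim@x, coreSim@y,
                        otConfig(max_epochs = 10, lambda_topo = 1e-3,
                                 lambda_ortho = 0.5))
  ob <- integrationObjective(fit)
  expect_equal(ob$total, ob$ot + 1e-3 * ob$topo + 0.5 * ob$ortho,
               tolerance = 1e-9)
  # with both weights zero the total is the Sinkhorn divergence alone
  fit0 <- fitIntegration(coreSim@x, coreSim@y,
                         otConfig(max_epochs = 5, lambda_topo = 0,
                                  lambda_ortho = 0))
  ob0 <- integrationObjective(fit0)
  expect_equal(ob0$total, ob0$ot, tolerance = 1e-12)
})

test_that("orthogonality component is 2k at P = 0 and 0 at spectral P", {
  fit <- fitIntegration(coreSim@x, coreSim@y, otConfig(max_epochs = 2))
  k <- ncol(fit@pX)
  Kx <- gramMatrix(fit@kernelX); Ky <- gramMatrix(fit@kernelY)
  Lx <- laplacianMatrix(fit@laplacianX); Ly <- laplacianMatrix(fit@laplacianY)
  atP <- function(Px, Py)
    scGraphOT:::objectiveParts(Px, Py, Kx, Ky, Lx, Ly, fit@config)
  zero <- atP(fit@pX * 0, fit@pY * 0)
  expect_equal(zero$ortho, 2 * k, tolerance = 1e-12)
  expect_equal(zero$topo, 0, tolerance = 1e-12)
  # P built from the top-k eigenpairs satisfies P' K P = I exactly
  eg <- eigen(Kx, symmetric = TRUE)
  Px <- eg$vectors[, 1:k] %*% diag(1 / sqrt(eg$values[1:k]))
  expect_lt(max(abs(crossprod(Px, Kx %*% Px) - diag(k))), 1e-8)
})

test_that("objective gradients match finite differences on a tiny problem", {
  sim <- simulatePair("branch", n = 30, liftDim = 8, seed = 42)
  fit <- fitIntegration(sim@x, sim@y,
                        otConfig(max_epochs = 3, k_latent = 2,
                                 lambda_topo = 1e-3, lambda_ortho = 0.5))
  cfg <- fit@config
  cfg$sinkhorn_tol <- 1e-11; cfg$sinkhorn_max_iter <- 20000L
  Kx <- gramMatrix(fit@kernelX); Ky <- gramMatrix(fit@kernelY)
  Lx <- laplacianMatrix(fit@laplacianX); Ly <- laplacianMatrix(fit@laplacianY)
  Px <- fit@pX; Py <- fit@pY
  parts <- scGraphOT:::objectiveParts(Px, Py, Kx, Ky, Lx, Ly, cfg,
                                      gradient = TRUE)
  h <- 1e-6
  for (idx in list(c(1, 1), c(7, 2), c(30, 1))) {
    Pp <- Px; Pp[idx[1], idx[2]] <- Pp[idx[1], idx[2]] + h
    Pm <- Px; Pm[idx[1], idx[2]] <- Pm[idx[1], idx[2]] - h
    fd <- (scGraphOT:::objectiveParts(Pp, Py, Kx, Ky, Lx, Ly, cfg)$total -
           scGraphOT:::objectiveParts(Pm, Py, Kx, Ky, Lx, Ly, cfg)$total) /
      (2 * h)
    an <- parts$gradPx[idx[1], idx[2]]
    expect_lt(abs(an - fd) / (abs(fd) + 1e-8), 1e-3)
  }
})

test_that("training is reproducible bitwise and never ends above its start", {
  cfg <- otConfig(max_epochs = 40, seed = 7)
  f1 <- fitIntegration(coreSim@x, coreSim@y, cfg)
  f2 <- fitIntegration(coreSim@x, coreSim@y, cfg)
  expect_identical(f1@pX, f2@pX)
  expect_identical(f1@pY, f2@pY)
  expect_identical(latentEmbedding(f1, "x"), latentEmbedding(f2, "x"))
  expect_lte(min(f1@trace$total), f1@trace$total[1])
  # returned parameters are those of the best epoch (integrationObjective
  # re-evaluates at the tighter reporting tolerance, hence the slack)
  ob <- integrationObjective(f1)
  expect_lte(ob$total, f1@trace$total[1] + 1e-3 * (1 + abs(ob$total)))
})

test_that("random initialization also trains down and stays finite", {
  fit <- fitIntegration(coreSim@x, coreSim@y,
                        otConfig(max_epochs = 150, init = "random",
                                 epsilon_anneal = TRUE, seed = 3))
  tr <- fit@trace
  expect_true(all(is.finite(tr$total)))
  expect_lt(min(tr$total), tr$total[1])
})

test_that("out-of-sample embedding reproduces and extends the training map", {
  fit <- fitIntegration(coreSim@x, coreSim@y, otConfig(max_epochs = 10))
  xe <- latentEmbedding(fit, "x")
  back <- transformPoints(fit, cellValues(coreSim@x), "x")
  expect_equal(back, xe, tolerance = 1e-10)
  one <- transformPoints(fit, cellValues(coreSim@x)[3, , drop = FALSE], "x")
  expect_equal(one[1, ], xe[3, ], tolerance = 1e-10)
  expect_error(transformPoints(fit, matrix(0, 2, 3), "x"), "features")
})

test_that("a two-point toy transform matches the closed-form kernel sum", {
  x <- matrix(c(0, 1), 2, 1)
  y <- matrix(c(0, 2, 1, 3), 2, 2)
  fit <- fitIntegration(x, y, otConfig(max_epochs = 2, k_latent = 1,
                                       k_neighbors = 1, standardize = FALSE))
  sigma <- bandwidth(fit@kernelX)
  P <- fit@pX
  mid <- matrix(0.5, 1, 1)
  expected <- sum(exp(-c(0.25, 0.25) / (2 * sigma^2)) * P[, 1])
  expect_equal(transformPoints(fit, mid, "x")[1, 1], expected,
               tolerance = 1e-12)
})

test_that("unsupervised search selects the minimum-objective configuration", {
  grid <- list(lambda_ortho = c(1, 0.1), lambda_topo = 1e-4)
  sr <- searchHyperparameters(coreSim@x, coreSim@y, grid,
                              mode = "unsupervised",
                              baseConfig = otConfig(max_epochs = 15))
  tab <- sr$table
  expect_identical(which(tab$selected), which.min(tab$total))
  best <- integrationObjective(sr$best)
  expect_equal(best$total, min(tab$total), tolerance = 1e-9)
})

test_that("the search grid drops combinations violating ortho > topo", {
  grid <- list(lambda_ortho = c(1e-3, 1), lambda_topo = c(1e-3, 1e-4))
  sr <- searchHyperparameters(coreSim@x, coreSim@y, grid,
                              mode = "unsupervised",
                              baseConfig = otConfig(max_epochs = 3))
  tab <- sr$table
  expect_true(all(tab$lambda_ortho > tab$lambda_topo))
  expect_false(any(tab$lambda_ortho == 1e-3 & tab$lambda_topo == 1e-3))
  expect_error(
    searchHyperparameters(coreSim@x, coreSim@y,
                          list(lambda_ortho = 1e-4, lambda_topo = 1e-3),
                          baseConfig = otConfig(max_epochs = 2)),
    "lambda_ortho")
})

test_that("semisupervised search maximizes held-out label transfer", {
  sr <- searchHyperparameters(coreSim@x, coreSim@y,
                              list(lambda_ortho = c(1, 0.1),
                                   lambda_topo = 1e-4),
                              mode = "semisupervised",
                              baseConfig = otConfig(max_epochs = 15))
  tab <- sr$table
  expect_identical(which(tab$selected), which.max(tab$val_lta))
  unl <- ModalityData(cellValues(coreSim@x))
  expect_error(
    searchHyperparameters(unl, unl, list(lambda_ortho = 1),
                          mode = "semisupervised",
                          baseConfig = otConfig(max_epochs = 2)),
    "labels")
})
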