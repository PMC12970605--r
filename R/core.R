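#' Training configuration for the integration model
#'
#' Collects every tunable of the alignment objective and optimizer with
#' validated defaults. The objective combines three terms: the Sinkhorn
#' divergence between the two latent embeddings (global alignment), the graph
#' Laplacian smoothness of each embedding scaled by `lambda_topo` (local
#' geometry), and the RKHS orthogonality penalty
#' `||P' K P - I||_F^2` scaled by `lambda_ortho` (well-conditioned maps).
#'
#' @param k_latent latent dimensionality of the shared space (default 8; the
#'   method is robust between 5 and 8).
#' @param lambda_topo weight of the Laplacian smoothness penalty (>= 0).
#' @param lambda_ortho weight of the orthogonality penalty (>= 0); grid
#'   searches constrain `lambda_ortho > lambda_topo`.
#' @param epsilon entropic regularization of the Sinkhorn terms; `NULL`
#'   resolves to `epsilon_scale` times the mean pairwise squared distance of
#'   the initial joint embedding (see [defaultEpsilon()]).
#' @param epsilon_scale fraction of the initial embedding scale used when
#'   `epsilon` is `NULL` (default 0.05).
#' @param epsilon_anneal anneal the entropic blur during training: epsilon
#'   decays geometrically from its starting value to `epsilon_final_frac`
#'   times that value over the first 60% of `max_epochs`, then stays there.
#'   Coarse-to-fine blur first matches the global distributions, then
#'   resolves point-level structure; useful with `init = "random"`, off by
#'   default because the spectral initialization already starts aligned at
#'   fine scale.
#' @param epsilon_final_frac final epsilon as a fraction of the starting
#'   epsilon when annealing (default 0.1).
#' @param reach unbalancedness scale of the Sinkhorn loss; `Inf` = balanced.
#' @param k_neighbors neighbour count of the kNN graphs (default 5).
#' @param learning_rate Adam step size.
#' @param max_epochs optimizer epoch budget.
#' @param plateau_patience epochs without relative improvement > 1e-4 before
#'   the learning rate is halved; training stops after 3 consecutive halvings
#'   without improvement.
#' @param sinkhorn_max_iter,sinkhorn_tol inner Sinkhorn solver controls used
#'   when evaluating or extracting converged transport quantities.
#' @param train_sinkhorn_max_iter,train_sinkhorn_tol looser inner solver
#'   controls used inside the training loop, where successive epochs warm
#'   start each other and gradient accuracy at 1e-4 is ample.
#' @param standardize z-score each feature before building kernels.
#' @param init coefficient initialization: `"spectral"` (default) starts
#'   both domains from their kernel-PCA coordinates (exactly orthonormal in
#'   the RKHS), with the per-coordinate sign ambiguity of the second domain
#'   resolved by minimizing the cross OT cost — for datasets sharing a
#'   manifold the leading kernel harmonics agree up to signs, so training
#'   starts near the aligned configuration; `"random"` uses iid Gaussian
#'   entries scaled by `1/sqrt(n)`.
#' @param seed RNG seed for the coefficient initialization.
#' @return named list of validated settings.
#' @export
otConfig <- function(k_latent = 8L, lambda_topo = 1e-4, lambda_ortho = 0.1,
                     epsilon = NULL, epsilon_scale = 0.05,
                     epsilon_anneal = FALSE, epsilon_final_frac = 0.1,
                     reach = Inf, k_neighbors = 5L,
                     learning_rate = 0.01, max_epochs = 500L,
                     plateau_patience = 50L, sinkhorn_max_iter = 1000L,
                     sinkhorn_tol = 1e-6, train_sinkhorn_max_iter = 300L,
                     train_sinkhorn_tol = 1e-4, standardize = TRUE,
                     init = c("spectral", "random"), seed = 1L) {
  cfg <- list(k_latent = as.integer(k_latent), lambda_topo = lambda_topo,
              lambda_ortho = lambda_ortho, epsilon = epsilon,
              epsilon_scale = epsilon_scale,
              epsilon_anneal = isTRUE(epsilon_anneal),
              epsilon_final_frac = epsilon_final_frac, reach = reach,
              k_neighbors = as.integer(k_neighbors),
              learning_rate = learning_rate,
              max_epochs = as.integer(max_epochs),
              plateau_patience = as.integer(plateau_patience),
              sinkhorn_max_iter = as.integer(sinkhorn_max_iter),
              sinkhorn_tol = sinkhorn_tol,
              train_sinkhorn_max_iter = as.integer(train_sinkhorn_max_iter),
              train_sinkhorn_tol = train_sinkhorn_tol,
              standardize = isTRUE(standardize),
              init = match.arg(init), seed = as.integer(seed))
  if (cfg$k_latent < 1L) stop("'k_latent' must be >= 1")
  if (cfg$lambda_topo < 0 || cfg$lambda_ortho < 0)
    stop("regularization weights must be >= 0")
  if (!is.null(cfg$epsilon) && cfg$epsilon <= 0)
    stop("'epsilon' must be positive")
  if (!(is.infinite(cfg$reach) || cfg$reach > 0))
    stop("'reach' must be positive or Inf")
  if (cfg$learning_rate <= 0) stop("'learning_rate' must be positive")
  cfg
}

#' Objective of a trained (or initialized) model
#'
#' Evaluates the full training objective at the model's current coefficients
#' and returns the total together with its three components: `ot` (Sinkhorn
#' divergence between the embeddings), `topo` (sum of the two Laplacian
#' quadratic forms) and `ortho` (sum of the two squared orthogonality
#' residuals). The total is exactly
#' `ot + lambda_topo * topo + lambda_ortho * ortho`.
#'
#' @param model an [OTIntegration-class].
#' @return list with `total`, `ot`, `topo`, `ortho`.
#' @export
integrationObjective <- function(model) {
  stopifnot(is(model, "OTIntegration"))
  cfg <- model@config
  objectiveParts(model@pX, model@pY,
                 model@kernelX@gram, model@kernelY@gram,
                 model@laplacianX@laplacian, model@laplacianY@laplacian,
                 cfg)[c("total", "ot", "topo", "ortho")]
}

objectiveParts <- function(Px, Py, Kx, Ky, Lx, Ly, cfg, warmStart = NULL,
                           gradient = FALSE) {
  Xe <- Kx %*% Px
  Ye <- Ky %*% Py
  div <- sinkhornDivergence(Xe, Ye, epsilon = cfg$epsilon, reach = cfg$reach,
                            maxIter = cfg$sinkhorn_max_iter,
                            tol = cfg$sinkhorn_tol,
                            gradient = TRUE, warmStart = warmStart)
  topo <- smoothnessPenalty(Xe, Lx) + smoothnessPenalty(Ye, Ly)
  Mx <- crossprod(Px, Kx %*% Px) - diag(ncol(Px))
  My <- crossprod(Py, Ky %*% Py) - diag(ncol(Py))
  ortho <- sum(Mx^2) + sum(My^2)
  out <- list(total = div$value + cfg$lambda_topo * topo +
                cfg$lambda_ortho * ortho,
              ot = div$value, topo = topo, ortho = ortho,
              state = div$state)
  if (gradient) {
    # chain rule through Xe = Kx Px; K symmetric
    gXe <- div$gradX + cfg$lambda_topo * 2 * (Lx %*% Xe)
    gYe <- div$gradY + cfg$lambda_topo * 2 * (Ly %*% Ye)
    out$gradPx <- crossprod(Kx, gXe) + cfg$lambda_ortho * 4 * (Kx %*% Px %*% Mx)
    out$gradPy <- crossprod(Ky, gYe) + cfg$lambda_ortho * 4 * (Ky %*% Py %*% My)
  }
  out
}

#' Fit the graph-regularized optimal-transport integration
#'
#' Learns coefficient matrices P_X and P_Y minimizing the Sinkhorn divergence
#' between the kernel embeddings K_X P_X and K_Y P_Y, plus the Laplacian
#' smoothness and RKHS orthogonality penalties, by Adam over both coefficient
#' matrices jointly. When the loss plateaus (no relative improvement > 1e-4
#' over `plateau_patience` epochs) the learning rate is halved; training
#' stops after three consecutive halvings without improvement or at
#' `max_epochs`. The returned model carries the parameters of the best epoch,
#' so its final loss never exceeds the initial one. Runs are deterministic
#' under a fixed seed.
#'
#' @param x,y the two modalities: [ModalityData-class] objects or plain
#'   cells x features matrices (feature spaces may differ).
#' @param config an [otConfig()] list.
#' @param verbose print the loss every 50 epochs.
#' @param initState advanced: a precomputed initialization as returned in the
#'   `initState` attribute of a previous fit on the same data (used by
#'   [searchHyperparameters()] to share the spectral alignment across grid
#'   points, since it depends only on the kernels and `k_latent`).
#' @return A trained [OTIntegration-class] model; its `trace` slot logs
#'   per-epoch loss components and the learning rate.
#' @examples
#' sim <- simulatePair("branch", n = 60, liftDim = 20, seed = 1)
#' fit <- fitIntegration(sim@x, sim@y, otConfig(max_epochs = 30))
#' integrationObjective(fit)$total
#' @export
fitIntegration <- function(x, y, config = otConfig(), verbose = FALSE,
                           initState = NULL) {
  x <- asModality(x)
  y <- asModality(y)
  cfg <- config
  set.seed(cfg$seed)

  sx <- standardizeFeatures(x@values, cfg$standardize)
  sy <- standardizeFeatures(y@values, cfg$standardize)
  kx <- gaussianGram(sx$values)
  ky <- gaussianGram(sy$values)
  lx <- buildGraphLaplacian(kx, cfg$k_neighbors)
  ly <- buildGraphLaplacian(ky, cfg$k_neighbors)
  Kx <- kx@gram; Ky <- ky@gram
  nx <- nrow(Kx); ny <- nrow(Ky); k <- cfg$k_latent

  if (!is.null(initState) && identical(dim(initState$Px), c(nx, k)) &&
      identical(dim(initState$Py), c(ny, k))) {
    Px <- initState$Px; Py <- initState$Py
  } else {
    ix <- initCoefficients(Kx, k, cfg$init)
    iy <- initCoefficients(Ky, k, cfg$init)
    Px <- ix$P; Py <- iy$P
    if (cfg$init == "spectral") {
      Xe0 <- Kx %*% Px; Ye0 <- Ky %*% Py
      Q <- matchSpectralBasis(Xe0, Ye0, defaultEpsilon(Xe0, Ye0))
      Py <- Py %*% Q
    }
  }
  usedInit <- list(Px = Px, Py = Py)
  if (is.null(cfg$epsilon))
    cfg$epsilon <- defaultEpsilon(Kx %*% Px, Ky %*% Py) / 0.05 *
      cfg$epsilon_scale
  # coarse-to-fine blur schedule; cfg$epsilon is the final (sharp) value
  epsStart <- cfg$epsilon
  annealEnd <- 1L
  if (cfg$epsilon_anneal && cfg$epsilon_final_frac < 1) {
    cfg$epsilon <- epsStart * cfg$epsilon_final_frac
    annealEnd <- max(1L, as.integer(0.6 * cfg$max_epochs))
  }

  # Adam state over the concatenated parameters
  adam <- list(mx = Px * 0, vx = Px * 0, my = Py * 0, vy = Py * 0,
               b1 = 0.9, b2 = 0.999, eps = 1e-8)
  lr <- cfg$learning_rate
  state <- NULL
  best <- list(total = Inf, Px = Px, Py = Py)
  sinceImprove <- 0L; halvings <- 0L
  trace <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    cfgEpoch <- cfg
    cfgEpoch$sinkhorn_max_iter <- cfg$train_sinkhorn_max_iter
    cfgEpoch$sinkhorn_tol <- cfg$train_sinkhorn_tol
    if (epoch < annealEnd)
      cfgEpoch$epsilon <- epsStart *
        cfg$epsilon_final_frac^((epoch - 1) / (annealEnd - 1))
    parts <- objectiveParts(Px, Py, Kx, Ky, lx@laplacian, ly@laplacian,
                            cfgEpoch, warmStart = state, gradient = TRUE)
    state <- parts$state
    if (!is.finite(parts$total))
      stop("non-finite training loss at epoch ", epoch,
           "; try a larger epsilon or a smaller learning rate")
    trace[[epoch]] <- data.frame(epoch = epoch, total = parts$total,
                                 ot = parts$ot, topo = parts$topo,
                                 ortho = parts$ortho, lr = lr)
    if (verbose && (epoch == 1L || epoch %% 50L == 0L))
      message(sprintf("epoch %4d  loss %.6g (ot %.4g topo %.4g ortho %.4g)",
                      epoch, parts$total, parts$ot, parts$topo, parts$ortho))

    # plateau/best-tracking only once the blur has reached its final value
    # (loss values at different epsilon are not comparable)
    if (epoch >= annealEnd) {
      improved <- parts$total <
        best$total - 1e-4 * max(abs(best$total), 1e-8)
      if (improved || epoch == annealEnd) {
        sinceImprove <- 0L; halvings <- 0L
      } else {
        sinceImprove <- sinceImprove + 1L
      }
      if (parts$total < best$total)
        best <- list(total = parts$total, Px = Px, Py = Py)
      if (sinceImprove >= cfg$plateau_patience) {
        lr <- lr / 2
        halvings <- halvings + 1L
        sinceImprove <- 0L
        if (halvings >= 3L) { trace <- trace[seq_len(epoch)]; break }
      }
    }

    t <- epoch
    warmup <- min(1, epoch / 20)  # ramp Adam in gently near a structured init
    gx <- parts$gradPx; gy <- parts$gradPy
    adam$mx <- adam$b1 * adam$mx + (1 - adam$b1) * gx
    adam$vx <- adam$b2 * adam$vx + (1 - adam$b2) * gx^2
    adam$my <- adam$b1 * adam$my + (1 - adam$b1) * gy
    adam$vy <- adam$b2 * adam$vy + (1 - adam$b2) * gy^2
    bc1 <- 1 - adam$b1^t; bc2 <- 1 - adam$b2^t
    Px <- Px - warmup * lr * (adam$mx / bc1) / (sqrt(adam$vx / bc2) + adam$eps)
    Py <- Py - warmup * lr * (adam$my / bc1) / (sqrt(adam$vy / bc2) + adam$eps)
  }

  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  model <- new("OTIntegration", pX = best$Px, pY = best$Py,
      kernelX = kx, kernelY = ky, laplacianX = lx, laplacianY = ly,
      trainX = sx$values, trainY = sy$values,
      centerX = sx$center, scaleX = sx$scale,
      centerY = sy$center, scaleY = sy$scale,
      labelsX = x@labels, labelsY = y@labels,
      config = cfg, trace = trace)
  attr(model, "initState") <- usedInit
  model
}

# "spectral": kernel-PCA coordinates P = U_k Lambda_k^{-1/2}, so P' K P = I
# exactly at initialization and the embedding K P = U_k Lambda_k^{1/2} starts
# from the kernel's leading harmonics. For two domains sharing a manifold,
# these harmonics agree up to per-coordinate sign flips, resolved afterwards
# by matchSpectralSigns(). "random": iid Gaussian / sqrt(n).
initCoefficients <- function(K, k, init) {
  if (init == "random")
    return(list(P = matrix(stats::rnorm(nrow(K) * k), nrow(K), k) /
                  sqrt(nrow(K)), values = NULL))
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values[seq_len(k)], 1e-12)
  list(P = eig$vectors[, seq_len(k), drop = FALSE] %*% diag(1 / sqrt(ev), k),
       values = ev)
}

# Align the second domain's spectral coordinates to the first's by
# minimizing the cross entropic OT cost, resolving the two discrete/continuous
# ambiguities of kernel eigenfunctions on a shared manifold:
#  (1) per-coordinate sign flips — searched exhaustively over all 2^k
#      patterns for k <= 8 (flips interact, e.g. reflections of a closed
#      curve need joint flips), greedy coordinate descent beyond;
#  (2) a general orthogonal rotation, because near-degenerate eigen-blocks
#      (circular harmonics and the like) are only defined up to rotation
#      within the block — resolved by OT-Procrustes alternation.
# Costs are ranked on a deterministic subsample of cells with a coarse
# solver tolerance; the procedure is fully unsupervised. Returns a k x k
# orthogonal matrix to right-multiply the second domain's coefficients.
matchSpectralBasis <- function(Xe, Ye, epsilon, maxCells = 200L) {
  k <- ncol(Ye)
  sub <- function(m) {
    n <- nrow(m)
    if (n <= maxCells) return(m)
    m[round(seq(1, n, length.out = maxCells)), , drop = FALSE]
  }
  Xs <- sub(Xe); Ys <- sub(Ye)
  a <- rep(1 / nrow(Xs), nrow(Xs)); b <- rep(1 / nrow(Ys), nrow(Ys))
  evalCost <- function(Q, eps = epsilon) {
    sinkhornRaw(squaredDistances(Xs, Ys %*% Q), a, b, eps, 1, Inf,
                400L, 1e-3, numeric(nrow(Xs)), numeric(nrow(Ys)))$cost
  }
  # stage 1: signs
  if (k <= 8L) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
    costs <- apply(signs, 1, function(sv) evalCost(diag(sv, k)))
    s <- as.numeric(signs[which.min(costs), ])
  } else {
    s <- rep(1, k)
    for (pass in 1:2) for (j in seq_len(k)) {
      sPlus <- s; sPlus[j] <- 1
      sMinus <- s; sMinus[j] <- -1
      s[j] <- if (evalCost(diag(sPlus, k)) <= evalCost(diag(sMinus, k)))
        1 else -1
    }
  }
  # stage 2: general orthogonal alignment by OT-Procrustes alternation —
  # near-degenerate eigen-blocks are only defined up to rotation, so the two
  # domains' bases can mix arbitrarily within blocks; alternating between
  # the transport plan and the closed-form best orthogonal rotation (SVD
  # polar factor) resolves this. The blur is annealed coarse-to-fine: at
  # large epsilon nearby rotations of a near-symmetric shape are
  # indistinguishable (the wrong one can even score better), while the
  # sharp blur ranks them correctly. Best of several starts is kept.
  scales <- c(1, 0.2, 0.05)
  procrustes <- function(Q0) {
    Q <- Q0
    for (eScale in scales) {
      prev <- Inf
      for (it in 1:15) {
        raw <- sinkhornRaw(squaredDistances(Xs, Ys %*% Q), a, b,
                           epsilon * eScale, 1, Inf, 400L, 1e-3,
                           numeric(nrow(Xs)), numeric(nrow(Ys)))
        M <- crossprod(Ys, crossprod(raw$T, Xs))
        sv <- svd(M)
        Q <- sv$u %*% t(sv$v)
        if (abs(prev - raw$cost) < 1e-8 * max(1, abs(raw$cost))) break
        prev <- raw$cost
      }
    }
    list(Q = Q, cost = evalCost(Q, epsilon * min(scales)))
  }
  starts <- list(diag(s, k), diag(1, k))
  for (r in 1:3)
    starts[[length(starts) + 1L]] <-
      qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  best <- NULL
  for (Q0 in starts) {
    cand <- procrustes(Q0)
    if (is.null(best) || cand$cost < best$cost) best <- cand
  }
  best$Q
}

asModality <- function(x) {
  if (is(x, "ModalityData")) x else ModalityData(x)
}

standardizeFeatures <- function(values, standardize) {
  if (!standardize) {
    return(list(values = values, center = rep(0, ncol(values)),
                scale = rep(1, ncol(values))))
  }
  ctr <- colMeans(values)
  scl <- apply(values, 2, stats::sd)
  scl[scl == 0] <- 1  # constant features stay at 0 rather than dividing by 0
  list(values = sweep(sweep(values, 2, ctr), 2, scl, "/"),
       center = ctr, scale = scl)
}

#' Embed new points with a trained model
#'
#' Applies the learned representer-theorem map to out-of-sample points: each
#' latent coordinate is the kernel-weighted combination of the training
#' coefficients, `kernelCross(train, new, sigma) %*% P`. New points are first
#' standardized with the training standardization of the chosen domain.
#' Evaluating on the training points reproduces the training embedding.
#'
#' @param model a trained [OTIntegration-class].
#' @param newPoints m x d matrix in the original feature space of `domain`.
#' @param domain `"x"` or `"y"`.
#' @return m x k_latent embedding matrix.
#' @export
transformPoints <- function(model, newPoints, domain = c("x", "y")) {
  stopifnot(is(model, "OTIntegration"))
  domain <- match.arg(domain)
  newPoints <- as.matrix(newPoints)
  train <- if (domain == "x") model@trainX else model@trainY
  if (ncol(newPoints) != ncol(train))
    stop(sprintf("new points have %d features but domain '%s' has %d",
                 ncol(newPoints), domain, ncol(train)))
  ctr <- if (domain == "x") model@centerX else model@centerY
  scl <- if (domain == "x") model@scaleX else model@scaleY
  np <- sweep(sweep(newPoints, 2, ctr), 2, scl, "/")
  sigma <- if (domain == "x") model@kernelX@sigma else model@kernelY@sigma
  P <- if (domain == "x") model@pX else model@pY
  kernelCross(train, np, sigma) %*% P
}

#' Grid search over the objective hyperparameters
#'
#' Fits the model for every combination in `grid` (after removing
#' combinations violating `lambda_ortho > lambda_topo`) and selects the best
#' configuration. In `"unsupervised"` mode the winner minimizes the final
#' total objective — no labels are consulted. In `"semisupervised"` mode the
#' winner maximizes label transfer accuracy (k = 5) on a held-out validation
#' split of the x-side cells; labels are used only for this selection, never
#' inside the model.
#'
#' @param x,y the two modalities ([ModalityData-class] or matrices).
#' @param grid named list of parameter vectors (any [otConfig()] fields, e.g.
#'   `list(lambda_ortho = c(1, 0.1), lambda_topo = 1e-4, reach = c(1, Inf))`).
#' @param mode `"unsupervised"` or `"semisupervised"`.
#' @param labelsX,labelsY per-cell labels, required in semisupervised mode
#'   (taken from the inputs when they are labeled [ModalityData-class]).
#' @param baseConfig settings shared by every grid point.
#' @param valFraction fraction of x cells held out for semisupervised
#'   selection.
#' @param verbose print one line per configuration.
#' @return list with `best` (the winning fitted [OTIntegration-class]) and
#'   `table` (a data.frame of every configuration with its final objective
#'   components and, in semisupervised mode, its validation accuracy).
#' @export
searchHyperparameters <- function(x, y, grid,
                                  mode = c("unsupervised", "semisupervised"),
                                  labelsX = NULL, labelsY = NULL,
                                  baseConfig = otConfig(),
                                  valFraction = 0.3, verbose = FALSE) {
  mode <- match.arg(mode)
  x <- asModality(x); y <- asModality(y)
  if (is.null(labelsX) && length(x@labels)) labelsX <- x@labels
  if (is.null(labelsY) && length(y@labels)) labelsY <- y@labels
  if (mode == "semisupervised" && (is.null(labelsX) || is.null(labelsY)))
    stop("semisupervised search requires labels for both domains")

  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(combos))
  lo <- if ("lambda_ortho" %in% names(combos)) combos$lambda_ortho
        else baseConfig$lambda_ortho
  lt <- if ("lambda_topo" %in% names(combos)) combos$lambda_topo
        else baseConfig$lambda_topo
  keep <- lo > lt
  combos <- combos[keep, , drop = FALSE]
  if (!nrow(combos))
    stop("no grid combination satisfies lambda_ortho > lambda_topo")

  valIdx <- NULL
  if (mode == "semisupervised") {
    set.seed(baseConfig$seed)
    nx <- nrow(x@values)
    valIdx <- sort(sample.int(nx, max(1L, round(valFraction * nx))))
  }

  rows <- vector("list", nrow(combos))
  best <- NULL; bestScore <- Inf; bestIdx <- NA_integer_
  # the spectral initialization depends only on the kernels and k_latent,
  # so it is shared across grid points unless k_latent itself is searched
  shareInit <- !("k_latent" %in% names(combos)) &&
    !("standardize" %in% names(combos))
  initState <- NULL
  for (i in seq_len(nrow(combos))) {
    cfg <- baseConfig
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][i]
    model <- fitIntegration(x, y, config = do.call(otConfig, cfg),
                            initState = if (shareInit) initState)
    if (shareInit && is.null(initState))
      initState <- attr(model, "initState")
    obj <- integrationObjective(model)
    row <- cbind(combos[i, , drop = FALSE],
                 data.frame(total = obj$total, ot = obj$ot, topo = obj$topo,
                            ortho = obj$ortho))
    if (mode == "semisupervised") {
      xe <- latentEmbedding(model, "x")
      ye <- latentEmbedding(model, "y")
      lta <- labelTransferAccuracy(xe[valIdx, , drop = FALSE], ye,
                                   labelsX[valIdx], labelsY, k = 5L)
      row$val_lta <- lta
      score <- -lta  # maximize accuracy
    } else {
      score <- obj$total  # minimize final objective
    }
    rows[[i]] <- row
    if (score < bestScore) { bestScore <- score; best <- model; bestIdx <- i }
    if (verbose)
      message(sprintf("config %d/%d: total %.6g%s", i, nrow(combos),
                      obj$total,
                      if (mode == "semisupervised")
                        sprintf(", val LTA %.3f", row$val_lta) else ""))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  table$selected <- seq_len(nrow(table)) == bestIdx
  list(best = best, table = table)
}
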