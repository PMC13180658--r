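# tiny deterministic graph over 4 cells: edges 1-2 and 3-4
fourCellGraph <- function() {
  A <- Matrix::sparseMatrix(i = c(1, 2, 3, 4), j = c(2, 1, 4, 3), x = 1,
                            dims = c(4, 4))
  new("CellGraph", adjacency = A, laplacian = normLaplacian(A),
      degrees = Matrix::rowSums(A), k = 1L)
}

test_that("forward pass matches a hand computation", {
  g <- fourCellGraph()
  N <- 2; M <- 4; Fd <- 3
  X <- array(seq_len(N * M * Fd) / 10, c(N, M, Fd))
  par <- list(W0 = c(0.5, -0.25, 1), w1 = -0.5, w2 = 2, beta = c(1, 0, -1, 2),
              b = 0.1, gamma = numeric(0))
  fw <- scprsForward(par, X, g, task = "regression", alpha = 0.1)
  # hand computation with abs() weights and leaky ReLU
  H0 <- apply(X, 1:2, function(f) sum(f * abs(par$W0)))
  Gp <- H0
  for (v in 1:4) {
    nb <- c(2, 1, 4, 3)[v]
    Gp[, v] <- (abs(par$w1) * H0[, nb] + abs(par$w2) * H0[, v]) / 1
  }
  H1 <- pmax(0.1 * Gp, Gp)
  want <- drop(H1 %*% par$beta) + 0.1
  expect_equal(fw$scores, want, tolerance = 1e-12)
  expect_equal(fw$latent, H1, tolerance = 1e-12)
  # binary task wraps the same linear score in a logistic link
  fwb <- scprsForward(par, X, g, task = "binary")
  expect_equal(fwb$scores, plogis(want), tolerance = 1e-12)
})

test_that("leaky ReLU slope and zero-model baseline are as specified", {
  expect_equal(scPRS:::.leaky(-1, 0.1), -0.1)
  expect_equal(scPRS:::.leaky(2, 0.1), 2)
  g <- fourCellGraph()
  X <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  par <- list(W0 = rep(0.2, 3), w1 = numeric(0), w2 = numeric(0),
              beta = rep(0, 4), b = 0, gamma = numeric(0))
  fw <- scprsForward(par, X, g, task = "binary")
  expect_equal(fw$scores, rep(0.5, 2))
})

test_that("latent features never decrease when an input increases", {
  set.seed(31)
  g <- fourCellGraph()
  X <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  par <- list(W0 = rnorm(5), w1 = rnorm(2), w2 = rnorm(2),
              beta = rnorm(4), b = 0, gamma = numeric(0))
  base <- scprsForward(par, X, g, task = "regression")$latent
  for (probe in 1:10) {
    X2 <- X
    n <- sample(3, 1); m <- sample(4, 1); f <- sample(5, 1)
    X2[n, m, f] <- X2[n, m, f] + 1
    lat <- scprsForward(par, X2, g, task = "regression")$latent
    expect_true(all(lat - base >= -1e-12))
  }
})

test_that("the loss combines data term and the three penalties", {
  GL <- normLaplacian(fourCellGraph()@adjacency)
  # perfect predictions, no penalties -> ~0
  expect_lt(scprsLoss(c(1 - 1e-12, 1e-12), c(1, 0), rep(0, 4), GL), 1e-9)
  expect_equal(scprsLoss(c(0.3, 0.7), c(0.3, 0.7), rep(0, 4), GL,
                         lambda1 = 5, lambda2 = 5, lambda3 = 5,
                         task = "regression"), 0)
  # the Laplacian term equals the edge-sum form
  set.seed(32)
  beta <- rnorm(4)
  l <- scprsLoss(c(0.5, 0.5), c(0.5, 0.5), beta, GL, lambda3 = 2,
                 task = "regression")
  expect_equal(l, 2 * oracleEdgeSum(fourCellGraph()@adjacency, beta),
               tolerance = 1e-10)
  # unsquared L2 behind the flag
  l2 <- scprsLoss(c(0.5), c(0.5), beta, GL, lambda2 = 3,
                  task = "regression", l2Squared = FALSE)
  expect_equal(l2, 3 * sqrt(sum(beta^2)), tolerance = 1e-12)
})

test_that("splits partition the cohort with stratified proportions", {
  y <- rep(c(0, 1), c(60, 40))
  sp <- splitData(y, seed = 4)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(y))
  expect_equal(length(sp$train), 60)
  expect_equal(mean(y[sp$train]), 0.4, tolerance = 0.05)
  expect_equal(mean(y[sp$val]), 0.4, tolerance = 0.05)
  # deterministic under the seed
  expect_identical(sp, splitData(y, seed = 4))
  expect_false(identical(sp, splitData(y, seed = 5)))
  expect_error(splitData(c(0, 0, 0, 1, 1, 1, 1, 0, 1, 0)[1:5], seed = 1),
               "at least")
  expect_error(splitData(rep(c(0, 1), c(8, 2)), seed = 1), "class")
})

test_that("training separates a separable toy and is reproducible", {
  set.seed(33)
  N <- 60; M <- 20; Fd <- 21
  lab <- rep(c(0, 1), each = N / 2)
  X <- array(rnorm(N * M * Fd, sd = 0.3), c(N, M, Fd))
  X[lab == 1, 3, ] <- X[lab == 1, 3, ] + 1.5   # cell 3 carries the signal
  emb <- matrix(rnorm(M * 3), M, 3)
  g <- buildCellGraph(NULL, k = 3, embedding = emb)
  cfg <- scprsConfig(T = 0, lambda2 = 0.1, lambda3 = 0, epochs = 60,
                     seed = 5)
  fit <- scprsFit(X, g, lab, cfg)
  expect_true(all(diff(fit@lossTrace[1:10]) < 0))
  sc <- scprsPredict(fit, X, g)
  expect_equal(evaluateScores(sc, lab)$auroc, 1.0)
  # rank-1 concentration: the signal cell takes the largest |beta|
  expect_equal(which.max(abs(fit@params$beta)), 3L)
  # determinism: identical config and seed give identical traces
  fit2 <- scprsFit(X, g, lab, cfg)
  expect_identical(fit@lossTrace, fit2@lossTrace)
  expect_identical(fit@params, fit2@params)
  # a huge ridge penalty shrinks the readout
  cfgBig <- scprsConfig(T = 0, lambda2 = 1e6, lambda3 = 0, epochs = 60,
                        seed = 5)
  fitBig <- scprsFit(X, g, lab, cfgBig)
  expect_lt(sqrt(sum(fitBig@params$beta^2)),
            sqrt(sum(fit@params$beta^2)) / 5)
})

test_that("regression recovers a noiseless synthetic phenotype", {
  s <- tinyStudy()
  st <- s$st
  y <- st$phenotype$y               # sigma enters later; y is noiseless
  sp <- splitData(y, seed = 2, stratify = FALSE)
  tn <- normalizePRS(s$tensor, fitSamples = sp$train)
  cfg <- scprsConfig(T = 1, lambda1 = 0, lambda2 = 1, lambda3 = 1,
                     task = "regression", epochs = 200, seed = 3)
  fit <- scprsFit(prsScores(tn), s$graph, y, cfg, splits = sp)
  sc <- scprsPredict(fit, prsScores(tn)[sp$test, , , drop = FALSE], s$graph)
  expect_gt(cor(sc, y[sp$test]), 0.9)
})

test_that("extra feature blocks contribute through their own coefficients", {
  set.seed(34)
  N <- 50; M <- 6; Fd <- 4
  X <- array(rnorm(N * M * Fd, sd = 0.1), c(N, M, Fd))
  extra <- matrix(rnorm(N), N, 1)
  y <- drop(extra) * 0.5
  emb <- matrix(rnorm(M * 2), M, 2)
  g <- buildCellGraph(NULL, k = 2, embedding = emb)
  cfg <- scprsConfig(T = 0, lambda2 = 0, lambda3 = 0, task = "regression",
                     epochs = 300, batchSize = 10, seed = 6)
  fit <- scprsFit(X, g, y, cfg, extra = extra)
  expect_gt(abs(fit@params$gamma), 0.2)
  sc <- scprsPredict(fit, X, g, extra = extra)
  expect_gt(cor(sc, y), 0.9)
})

test_that("metrics match brute-force pair counting", {
  expect_equal(evaluateScores(c(1, 2, 3, 4), c(0, 0, 1, 1))$auroc, 1)
  expect_equal(evaluateScores(c(1, 2, 3, 4), c(0, 0, 1, 1))$auprc, 1)
  set.seed(35)
  for (rep in 1:5) {
    sc <- sample(1:5, 10, TRUE)          # ties included
    lab <- rbinom(10, 1, 0.5)
    if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
    expect_equal(evaluateScores(sc, lab)$auroc, oracleAUROC(sc, lab),
                 tolerance = 1e-12)
  }
  # independent scores give AUROC near 1/2
  sc <- rnorm(4000); lab <- rbinom(4000, 1, 0.5)
  expect_equal(evaluateScores(sc, lab)$auroc, 0.5, tolerance = 0.05)
  expect_error(evaluateScores(1:3, c(1, 1, 1)), "single class")
  # regression branch
  expect_equal(evaluateScores(1:4, c(2, 4, 6, 8), task = "regression")$pearson,
               1)
})

test_that("grid search selects the validation winner", {
  set.seed(36)
  N <- 60; M <- 8; Fd <- 3
  lab <- rep(c(0, 1), each = 30)
  X <- array(rnorm(N * M * Fd, sd = 0.2), c(N, M, Fd))
  X[lab == 1, 2, ] <- X[lab == 1, 2, ] + 1
  emb <- matrix(rnorm(M * 2), M, 2)
  g <- buildCellGraph(NULL, k = 2, embedding = emb)
  sp <- splitData(lab, seed = 7)
  base <- scprsConfig(T = 0, lambda3 = 0, epochs = 40, seed = 8)
  # single-config grid reduces to fit
  gs1 <- gridSearch(X, g, lab, data.frame(lambda2 = 1), base, sp)
  fitRef <- scprsFit(X, g, lab, modifyList(base, list(lambda2 = 1)),
                     splits = sp)
  expect_equal(gs1$best@valMetric, fitRef@valMetric)
  # a crippled config (enormous ridge) is dominated
  gs2 <- gridSearch(X, g, lab, data.frame(lambda2 = c(0.1, 1e7)), base, sp)
  expect_equal(gs2$bestIndex, 1L)
  expect_equal(gs2$valMetrics[gs2$bestIndex], max(gs2$valMetrics))
  expect_true(!is.null(gs2$testMetrics$auroc))
})

test_that("cross-validation averages fold metrics and refits on all data", {
  set.seed(37)
  N <- 50; M <- 6; Fd <- 3
  lab <- rep(c(0, 1), each = 25)
  X <- array(rnorm(N * M * Fd, sd = 0.2), c(N, M, Fd))
  X[lab == 1, 1, ] <- X[lab == 1, 1, ] + 1
  emb <- matrix(rnorm(M * 2), M, 2)
  g <- buildCellGraph(NULL, k = 2, embedding = emb)
  base <- scprsConfig(T = 0, lambda3 = 0, epochs = 30, seed = 1)
  cv <- crossValidate(X, g, lab, data.frame(lambda2 = c(0.1, 1e7)), base,
                      folds = 5, repeats = 2, seed = 9)
  expect_equal(cv$bestIndex, which.max(cv$meanMetrics))
  expect_equal(cv$bestConfig$lambda2, 0.1)
  expect_s4_class(cv$finalFit, "ScprsFit")
  # single config: returned unconditionally
  cv1 <- crossValidate(X, g, lab, data.frame(lambda2 = 1), base,
                       folds = 5, repeats = 1, seed = 9)
  expect_equal(cv1$bestIndex, 1L)
})
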