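#' Training configuration
#'
#' Assembles the model/optimizer configuration with the defaults used
#' throughout: T graph-propagation layers, the three penalty weights
#' (lasso on the readout, ridge on the readout, Laplacian smoothness),
#' Adam with learning rate 1e-3, batch size 32, 200 epochs.
#'
#' @param T number of propagation layers (0, 1 or 2 in the search grid).
#' @param lambda1 L1 penalty weight on the readout coefficients beta.
#' @param lambda2 L2 penalty weight on beta (squared norm by default, see
#'   `l2Squared`).
#' @param lambda3 Laplacian penalty weight on beta.
#' @param lr Adam learning rate.
#' @param batchSize mini-batch size.
#' @param epochs training epochs (fixed schedule; no early stopping).
#' @param task "binary" (cross-entropy + logistic readout) or "regression"
#'   (mean squared error + identity readout).
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param l2Squared if TRUE the L2 penalty is the squared norm (ridge); if
#'   FALSE the unsquared norm.
#' @param alpha leaky-ReLU negative slope.
#' @return named list.
#' @export
scprsConfig <- function(T = 1, lambda1 = 0, lambda2 = 1, lambda3 = 1,
                        lr = 1e-3, batchSize = 32, epochs = 200,
                        task = c("binary", "regression"), seed = 1,
                        l2Squared = TRUE, alpha = 0.1) {
  task <- match.arg(task)
  list(T = as.integer(T), lambda1 = lambda1, lambda2 = lambda2,
       lambda3 = lambda3, lr = lr, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), task = task, seed = as.integer(seed),
       l2Squared = isTRUE(l2Squared), alpha = alpha)
}

# column-normalized adjacency: An[u, v] = A[u, v] / deg(v); zero column for
# isolated cells (their propagation reduces to the self term alone)
.colNormAdj <- function(graph) {
  A <- graph@adjacency
  d <- graph@degrees
  inv <- ifelse(d > 0, 1 / d, 0)
  methods::as(A %*% Matrix::Diagonal(x = inv), "CsparseMatrix")
}

.leaky <- function(x, alpha) pmax(alpha * x, x)

#' Forward pass of the scPRS model
#'
#' h(0) = X . abs(W0) maps the 21 PRS features of every cell to one scalar;
#' T propagation layers average abs(w1)-weighted neighbour features with an
#' abs(w2)-weighted self term over the mutual-kNN graph, through a leaky
#' ReLU; the readout maps the latent cell features through beta (plus
#' coefficients gamma for optional concatenated extra features) and the bias
#' to a score per individual -- a probability under the logistic link for
#' binary tasks, the identity for regression. All embedding/propagation
#' weights enter through abs(), so the map from X to the latent features is
#' monotonically increasing.
#'
#' @param params list with W0, w1, w2, beta, b, gamma (as in
#'   [modelParams()]).
#' @param X normalized feature array, individuals x cells x grid.
#' @param graph a [CellGraph-class] over the same cells.
#' @param extra optional individuals x p matrix of extra features (nonpeak
#'   PRS block, covariates) concatenated at the readout.
#' @param task "binary" or "regression".
#' @param alpha leaky-ReLU negative slope.
#' @return list with `scores` (length-N vector) and `latent` (N x M matrix
#'   h(T)).
#' @export
scprsForward <- function(params, X, graph, extra = NULL,
                         task = "binary", alpha = 0.1) {
  d <- dim(X)
  if (length(d) != 3) stop("X must be individuals x cells x features")
  if (d[2] != nrow(graph@adjacency)) stop("graph does not match cell count")
  if (d[3] != length(params$W0)) stop("W0 length does not match features")
  An <- .colNormAdj(graph)
  H <- matrix(matrix(X, nrow = d[1] * d[2]) %*% abs(params$W0), d[1], d[2])
  for (t in seq_len(length(params$w1))) {
    G <- abs(params$w1[t]) * as.matrix(H %*% An) + abs(params$w2[t]) * H
    H <- .leaky(G, alpha)
  }
  lin <- drop(H %*% params$beta) + params$b
  if (!is.null(extra) && length(params$gamma))
    lin <- lin + drop(extra %*% params$gamma)
  scores <- if (task == "binary") stats::plogis(lin) else lin
  list(scores = scores, latent = H)
}

#' scPRS loss
#'
#' Mean binary cross-entropy (or mean squared error for regression) plus
#' lambda1 * ||beta||_1 + lambda2 * ||beta||_2 (squared norm by default) +
#' lambda3 * beta' G_L beta.
#'
#' @param scores predicted probabilities (binary) or values (regression).
#' @param labels observed 0/1 labels or continuous outcomes.
#' @param beta readout coefficients.
#' @param GL symmetric normalized Laplacian.
#' @param lambda1,lambda2,lambda3 penalty weights.
#' @param task "binary" or "regression".
#' @param l2Squared squared (ridge) versus unsquared L2 norm.
#' @return scalar loss.
#' @export
scprsLoss <- function(scores, labels, beta, GL, lambda1 = 0, lambda2 = 0,
                      lambda3 = 0, task = "binary", l2Squared = TRUE) {
  data <- if (task == "binary") {
    p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
    -mean(labels * log(p) + (1 - labels) * log(1 - p))
  } else {
    mean((labels - scores)^2)
  }
  l2 <- if (l2Squared) sum(beta^2) else sqrt(sum(beta^2))
  pen <- lambda1 * sum(abs(beta)) + lambda2 * l2 +
    lambda3 * as.numeric(crossprod(beta, GL %*% beta))
  data + pen
}

#' Train/validation/test split
#'
#' Random 60/20/20 partition (configurable), stratified by label for binary
#' tasks, deterministic under `seed`. The three sets partition the cohort.
#'
#' @param labels outcome vector.
#' @param seed RNG seed.
#' @param fractions length-3 fractions summing to 1.
#' @param stratify stratify by class (binary labels only).
#' @return list of integer index vectors train, val, test.
#' @export
splitData <- function(labels, seed = 1, fractions = c(0.6, 0.2, 0.2),
                      stratify = TRUE) {
  n <- length(labels)
  if (n < 5) stop("need at least 5 samples to split")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  binary <- length(unique(labels)) == 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  alloc <- function(idx) {
    m <- length(idx)
    idx <- sample(idx)
    nTr <- round(fractions[1] * m)
    nVa <- round(fractions[2] * m)
    list(train = idx[seq_len(nTr)],
         val = idx[nTr + seq_len(nVa)],
         test = idx[setdiff(seq_len(m), seq_len(nTr + nVa))])
  }
  if (binary && stratify) {
    tab <- table(labels)
    if (any(tab < 3)) stop("each class needs at least 3 members to stratify")
    parts <- lapply(split(seq_len(n), labels), alloc)
    out <- list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
                val = unlist(lapply(parts, `[[`, "val"), use.names = FALSE),
                test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
  } else {
    out <- alloc(seq_len(n))
  }
  lapply(out, sort)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit the scPRS model
#'
#' Minimizes the regularized loss by mini-batch Adam (learning rate 1e-3,
#' batch size 32, 200 epochs by default; fixed schedule, no early stopping).
#' Gradients are computed analytically; the abs() reparameterization keeps
#' the stored weights unconstrained while the forward pass uses their
#' magnitudes. Fully reproducible given `config$seed` (initialization and
#' per-epoch batch shuffling both derive from it). The per-epoch trace
#' records the full training loss after each epoch; non-finite loss aborts
#' with diagnostics.
#'
#' @param X normalized feature array (individuals x cells x grid), scaled
#'   with training-sample statistics (see [normalizePRS()]).
#' @param graph a [CellGraph-class].
#' @param labels outcome vector (0/1 or continuous).
#' @param config list from [scprsConfig()].
#' @param extra optional extra feature matrix (z-scored with training
#'   statistics by the caller).
#' @param splits list from [splitData()]; defaults to training on all
#'   samples with no validation metric.
#' @return a [ScprsFit-class].
#' @export
scprsFit <- function(X, graph, labels, config = scprsConfig(),
                     extra = NULL, splits = NULL) {
  d <- dim(X)
  N <- d[1]; M <- d[2]; Fdim <- d[3]
  if (is.null(splits))
    splits <- list(train = seq_len(N), val = integer(0), test = integer(0))
  tr <- splits$train
  An <- .colNormAdj(graph)
  Ant <- Matrix::t(An)
  GL <- graph@laplacian
  Xflat <- matrix(X, nrow = N * M)       # (n, m) pairs row-major in n
  nExtra <- if (is.null(extra)) 0L else ncol(extra)
  alpha <- config$alpha
  Tn <- config$T
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  par <- list(W0 = runif(Fdim, 0.05, 0.15),
              w1 = runif(Tn, 0.4, 0.6), w2 = runif(Tn, 0.4, 0.6),
              beta = rep(0, M), b = 0, gamma = rep(0, nExtra))
  adamM <- lapply(par, function(p) p * 0)
  adamV <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; stepN <- 0
  lossTrace <- numeric(config$epochs)
  batchRows <- function(b) as.vector(outer(b, (seq_len(M) - 1L) * N, `+`))
  XflatTr <- Xflat[batchRows(tr), , drop = FALSE]
  trainLoss <- function() {
    H <- matrix(XflatTr %*% abs(par$W0), length(tr), M)
    for (t in seq_len(Tn))
      H <- .leaky(abs(par$w1[t]) * as.matrix(H %*% An) +
                    abs(par$w2[t]) * H, alpha)
    lin <- drop(H %*% par$beta) + par$b
    if (nExtra) lin <- lin + drop(extra[tr, , drop = FALSE] %*% par$gamma)
    scores <- if (config$task == "binary") stats::plogis(lin) else lin
    scprsLoss(scores, labels[tr], par$beta, GL, config$lambda1,
              config$lambda2, config$lambda3, config$task, config$l2Squared)
  }
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    starts <- seq(1, length(ord), by = config$batchSize)
    for (s in starts) {
      b <- ord[s:min(length(ord), s + config$batchSize - 1L)]
      B <- length(b)
      Xb <- Xflat[batchRows(b), , drop = FALSE]
      H <- matrix(Xb %*% abs(par$W0), B, M)
      Hs <- vector("list", Tn + 1); Gs <- vector("list", Tn)
      Hs[[1]] <- H
      for (t in seq_len(Tn)) {
        G <- abs(par$w1[t]) * as.matrix(H %*% An) + abs(par$w2[t]) * H
        H <- .leaky(G, alpha)
        Gs[[t]] <- G; Hs[[t + 1]] <- H
      }
      lin <- drop(H %*% par$beta) + par$b
      if (nExtra) lin <- lin + drop(extra[b, , drop = FALSE] %*% par$gamma)
      dLin <- if (config$task == "binary")
        (stats::plogis(lin) - labels[b]) / B
      else 2 * (lin - labels[b]) / B
      gBeta <- drop(crossprod(H, dLin)) +
        config$lambda1 * sign(par$beta) +
        (if (config$l2Squared) 2 * config$lambda2 * par$beta
         else if (sum(par$beta^2) > 0)
           config$lambda2 * par$beta / sqrt(sum(par$beta^2))
         else par$beta * 0) +
        2 * config$lambda3 * as.numeric(GL %*% par$beta)
      gB <- sum(dLin)
      gGamma <- if (nExtra) drop(crossprod(extra[b, , drop = FALSE], dLin))
                else numeric(0)
      dH <- outer(dLin, par$beta)
      gW1 <- numeric(Tn); gW2 <- numeric(Tn)
      for (t in rev(seq_len(Tn))) {
        fp <- ifelse(Gs[[t]] > 0, 1, alpha)
        dG <- dH * fp
        HA <- as.matrix(Hs[[t]] %*% An)
        gW1[t] <- sum(dG * HA) * sign(par$w1[t])
        gW2[t] <- sum(dG * Hs[[t]]) * sign(par$w2[t])
        dH <- abs(par$w1[t]) * as.matrix(dG %*% Ant) + abs(par$w2[t]) * dG
      }
      gW0 <- drop(crossprod(Xb, as.vector(dH))) * sign(par$W0)
      grads <- list(W0 = gW0, w1 = gW1, w2 = gW2, beta = gBeta, b = gB,
                    gamma = gGamma)
      stepN <- stepN + 1
      for (nm in names(par)) {
        if (!length(par[[nm]])) next
        adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * grads[[nm]]
        adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * grads[[nm]]^2
        mh <- adamM[[nm]] / (1 - b1^stepN)
        vh <- adamV[[nm]] / (1 - b2^stepN)
        par[[nm]] <- par[[nm]] - config$lr * mh / (sqrt(vh) + eps)
      }
    }
    lossTrace[ep] <- trainLoss()
    if (!is.finite(lossTrace[ep]))
      stop(sprintf(
        "training diverged at epoch %d (loss=%g); seed=%d, lr=%g",
        ep, lossTrace[ep], config$seed, config$lr))
  }
  valMetric <- NA_real_
  if (length(splits$val)) {
    fw <- scprsForward(par, X[splits$val, , , drop = FALSE], graph,
                       extra = if (nExtra) extra[splits$val, , drop = FALSE],
                       task = config$task, alpha = alpha)
    valMetric <- if (config$task == "binary")
      .auroc(fw$scores, labels[splits$val])
    else cor(fw$scores, labels[splits$val])
  }
  new("ScprsFit", params = par, config = config, lossTrace = lossTrace,
      valMetric = valMetric, splits = splits)
}

#' Predict from a fitted model
#'
#' @param fit a [ScprsFit-class].
#' @param X normalized feature array.
#' @param graph the [CellGraph-class] used in training.
#' @param extra optional extra feature matrix.
#' @return numeric score vector.
#' @export
scprsPredict <- function(fit, X, graph, extra = NULL) {
  scprsForward(fit@params, X, graph, extra = extra, task = fit@config$task,
               alpha = fit@config$alpha)$scores
}

#' Evaluate predictions
#'
#' Rank-based AUROC (mean-rank tie handling) and AUPRC (average precision)
#' for binary tasks; Pearson correlation for regression. Single-class binary
#' labels raise an explicit error.
#'
#' @param scores predicted scores.
#' @param labels observed labels/values.
#' @param task "binary" or "regression".
#' @return named list of metrics.
#' @export
evaluateScores <- function(scores, labels, task = "binary") {
  if (task == "binary")
    list(auroc = .auroc(scores, labels), auprc = .auprc(scores, labels))
  else list(pearson = cor(scores, labels))
}

#' Hyperparameter grid search
#'
#' Trains one model per configuration row on identical splits, selects the
#' configuration with the best validation metric (AUROC for binary, Pearson
#' r for regression; ties broken by row order) and reports held-out test
#' metrics for the winner.
#'
#' @param X,graph,labels,extra as in [scprsFit()].
#' @param grid data.frame whose columns override [scprsConfig()] fields
#'   (e.g. T, lambda1, lambda2, lambda3).
#' @param baseConfig configuration defaults for fields not in `grid`.
#' @param splits list from [splitData()].
#' @return list with `best` ([ScprsFit-class]), `bestIndex`, `valMetrics`,
#'   and `testMetrics` of the selected model.
#' @export
gridSearch <- function(X, graph, labels, grid, baseConfig = scprsConfig(),
                       splits, extra = NULL) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  fits <- vector("list", nrow(grid))
  valMetrics <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- baseConfig
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
    cfg$T <- as.integer(cfg$T)
    fits[[i]] <- scprsFit(X, graph, labels, cfg, extra = extra,
                          splits = splits)
    valMetrics[i] <- fits[[i]]@valMetric
  }
  bestIndex <- which.max(valMetrics)
  best <- fits[[bestIndex]]
  test <- NULL
  if (length(splits$test)) {
    sc <- scprsPredict(best, X[splits$test, , , drop = FALSE], graph,
                       extra = if (!is.null(extra))
                         extra[splits$test, , drop = FALSE])
    test <- evaluateScores(sc, labels[splits$test], baseConfig$task)
  }
  list(best = best, bestIndex = bestIndex, valMetrics = valMetrics,
       testMetrics = test)
}

#' Repeated cross-validated configuration selection
#'
#' k-fold cross-validation repeated `repeats` times: every sample appears in
#' exactly one validation fold per repeat; configurations are scored by the
#' validation metric averaged over folds x repeats, and the best
#' configuration is refit on the entire dataset.
#'
#' @param X,graph,labels,extra as in [scprsFit()].
#' @param grid data.frame of configuration overrides (one row per config).
#' @param baseConfig defaults for unlisted fields.
#' @param folds number of folds.
#' @param repeats number of repeats.
#' @param seed seed for fold assignment (fit seeds derive from it).
#' @return list with `bestConfig`, `bestIndex`, `meanMetrics` and
#'   `finalFit` trained on all samples.
#' @export
crossValidate <- function(X, graph, labels, grid,
                          baseConfig = scprsConfig(), folds = 5, repeats = 5,
                          seed = 1, extra = NULL) {
  n <- length(labels)
  if (n < folds) stop("need at least as many samples as folds")
  metrics <- matrix(NA_real_, nrow(grid), folds * repeats)
  old <- .Random.seed_save()
  set.seed(seed)
  foldPlans <- lapply(seq_len(repeats), function(r)
    sample(rep(seq_len(folds), length.out = n)))
  .Random.seed_restore(old)
  col <- 0
  for (r in seq_len(repeats)) {
    fold <- foldPlans[[r]]
    for (f in seq_len(folds)) {
      col <- col + 1
      splits <- list(train = which(fold != f), val = which(fold == f),
                     test = integer(0))
      for (i in seq_len(nrow(grid))) {
        cfg <- baseConfig
        for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
        cfg$T <- as.integer(cfg$T)
        cfg$seed <- seed + 1000 * r + f
        fit <- scprsFit(X, graph, labels, cfg, extra = extra,
                        splits = splits)
        metrics[i, col] <- fit@valMetric
      }
    }
  }
  meanMetrics <- rowMeans(metrics)
  bestIndex <- which.max(meanMetrics)
  cfg <- baseConfig
  for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][bestIndex]
  cfg$T <- as.integer(cfg$T)
  cfg$seed <- seed
  finalFit <- scprsFit(X, graph, labels, cfg, extra = extra, splits = NULL)
  list(bestConfig = cfg, bestIndex = bestIndex, meanMetrics = meanMetrics,
       finalFit = finalFit)
}
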