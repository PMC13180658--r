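#' LSI cell embedding
#'
#' Latent semantic indexing: term-frequency per cell scaled by the log
#' inverse document frequency per peak, followed by a truncated SVD. The
#' first component, which typically tracks sequencing depth, can be dropped.
#' Component signs are fixed (largest-magnitude loading positive) so the
#' embedding is deterministic.
#'
#' @param cpm a [CellPeakMatrix-class] (or any cells x features matrix).
#' @param nComponents number of components to return (after the optional
#'   first-component drop).
#' @param dropFirst drop the first (depth-correlated) component.
#' @return list with `embedding` (cells x nComponents), `d` (singular
#'   values used) and `method = "lsi"`.
#' @export
lsiEmbed <- function(cpm, nComponents = 15, dropFirst = TRUE) {
  x <- if (methods::is(cpm, "CellPeakMatrix")) cpm@counts else cpm
  x <- as.matrix(x)
  if (!nrow(x) || !ncol(x)) stop("empty matrix")
  nUse <- nComponents + as.integer(dropFirst)
  if (nUse >= min(dim(x)))
    stop(sprintf("nComponents (%d%s) must be < min(cells, peaks) = %d",
                 nComponents, if (dropFirst) " + dropped first" else "",
                 min(dim(x))))
  rs <- rowSums(x)
  rs[rs == 0] <- 1
  tf <- x / rs
  df <- colSums(x > 0)
  idf <- log(1 + nrow(x) / (1 + df))
  tfidf <- sweep(tf, 2, idf, `*`)
  sv <- svd(tfidf, nu = nUse, nv = nUse)
  # sign convention: largest |loading| of each right singular vector positive
  for (c_ in seq_len(nUse)) {
    m <- which.max(abs(sv$v[, c_]))
    if (sv$v[m, c_] < 0) { sv$v[, c_] <- -sv$v[, c_]; sv$u[, c_] <- -sv$u[, c_] }
  }
  emb <- sv$u %*% diag(sv$d[seq_len(nUse)], nUse)
  keep <- if (dropFirst) seq_len(nUse)[-1] else seq_len(nUse)
  emb <- emb[, keep, drop = FALSE]
  rownames(emb) <- rownames(x)
  colnames(emb) <- paste0("LSI", seq_len(ncol(emb)))
  list(embedding = emb, d = sv$d[keep], method = "lsi")
}

#' Directed k-nearest-neighbour graph
#'
#' Euclidean distances between cell embeddings; row i has a 1 in column j
#' iff cell j is among the k closest cells to cell i (self excluded). Ties
#' are broken by cell index, so duplicate points give a deterministic graph.
#'
#' @param embedding cells x components matrix (or the list from
#'   [lsiEmbed()]).
#' @param k neighbour count, must be < number of cells.
#' @return sparse directed adjacency matrix with exactly k ones per row.
#' @export
knnGraph <- function(embedding, k) {
  if (is.list(embedding)) embedding <- embedding$embedding
  m <- nrow(embedding)
  if (k >= m) stop("k must be smaller than the number of cells")
  d2 <- as.matrix(stats::dist(embedding))^2
  diag(d2) <- Inf
  idx <- integer(m * k)
  for (i in seq_len(m)) {
    nb <- order(d2[i, ], seq_len(m))[seq_len(k)]
    idx[((i - 1) * k + 1):(i * k)] <- nb
  }
  Matrix::sparseMatrix(i = rep(seq_len(m), each = k), j = idx, x = 1,
                       dims = c(m, m),
                       dimnames = list(rownames(embedding),
                                       rownames(embedding)))
}

#' Mutual kNN adjacency
#'
#' Keeps the edges where both directions are present: A = G o t(G)
#' (elementwise product of the directed kNN graph with its transpose). The
#' result is symmetric with zero diagonal; isolated cells are permitted.
#'
#' @param ghat directed adjacency from [knnGraph()].
#' @return binary symmetric sparse adjacency matrix.
#' @export
mutualKNN <- function(ghat) {
  A <- ghat * Matrix::t(ghat)
  methods::as(Matrix::drop0(A), "CsparseMatrix")
}

#' Symmetric normalized graph Laplacian
#'
#' L = I - D^(-1/2) A D^(-1/2) on non-isolated nodes; isolated nodes get a
#' zero row and column (including the diagonal), so they contribute nothing
#' to the quadratic penalty b' L b.
#'
#' @param A binary symmetric adjacency (zero diagonal).
#' @return sparse symmetric PSD matrix.
#' @export
normLaplacian <- function(A) {
  d <- Matrix::rowSums(A)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dn <- Matrix::Diagonal(x = inv)
  L <- Matrix::Diagonal(x = as.numeric(d > 0)) - Dn %*% A %*% Dn
  methods::as(Matrix::drop0(L), "CsparseMatrix")
}

#' Build the mutual-kNN cell graph
#'
#' Convenience wrapper: embedding (LSI unless an external one is supplied)
#' -> directed kNN graph -> mutual-kNN adjacency -> symmetric normalized
#' Laplacian, returned as a [CellGraph-class].
#'
#' @param cpm a [CellPeakMatrix-class]; ignored when `embedding` is given.
#' @param k neighbour count (25 or 50 in the model's hyperparameter grid).
#' @param embedding optional precomputed cells x components matrix (e.g.
#'   batch-corrected externally).
#' @param nComponents,dropFirst passed to [lsiEmbed()].
#' @return a [CellGraph-class].
#' @export
buildCellGraph <- function(cpm, k = 25, embedding = NULL, nComponents = 15,
                           dropFirst = TRUE) {
  if (is.null(embedding))
    embedding <- lsiEmbed(cpm, nComponents = nComponents,
                          dropFirst = dropFirst)$embedding
  ghat <- knnGraph(embedding, k)
  A <- mutualKNN(ghat)
  new("CellGraph", adjacency = A, laplacian = normLaplacian(A),
      degrees = Matrix::rowSums(A), k = as.integer(k))
}
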