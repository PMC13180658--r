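# internal helpers shared across modules

# chromosome names are normalized to the bare form ("chr1" -> "1") so that
# mixed naming between sumstats, genotypes and peaks cannot silently zero
# all overlaps
.normChrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

.complement <- function(alleles) chartr("ACGTacgt", "TGCAtgca", alleles)

.isAmbiguous <- function(ref, alt) {
  p <- paste0(toupper(ref), toupper(alt))
  p %in% c("AT", "TA", "CG", "GC")
}

# Hardy-Weinberg tests from genotype counts (nAA, nAa, naa).
# Default: Pearson chi-square with 1 df. midp = TRUE switches to the exact
# mid-p test (full enumeration of heterozygote counts given allele counts),
# matching PLINK's default behaviour.
.hweP <- function(n0, n1, n2, midp = FALSE) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  if (midp) return(.hweExactMidP(n0, n1, n2))
  p <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n0, n1, n2)
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  pchisq(stat, df = 1, lower.tail = FALSE)
}

.hweExactMidP <- function(n0, n1, n2) {
  # exact distribution of heterozygote count conditional on allele counts
  n <- n0 + n1 + n2
  nA <- 2 * n2 + n1                      # minor-ish allele count (either works)
  rare <- min(nA, 2 * n - nA)
  hetObs <- n1
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom1 <- (rare - h) / 2
    hom2 <- n - h - hom1
    lchoose(n, h) + lchoose(n - h, hom1) + h * log(2) -
      lchoose(2 * n, rare)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pObs <- pr[hets == hetObs]
  min(1, sum(pr[pr < pObs]) + sum(pr[pr == pObs]) - 0.5 * pObs)
}

# rank-based AUROC with tie handling via mean ranks (equivalent to the
# Mann-Whitney U statistic)
.auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# area under the precision-recall curve as average precision
# (sum over recall increments of the precision attained there)
.auprc <- function(scores, labels) {
  pos <- labels == 1
  if (!any(pos) || all(pos))
    stop("AUPRC undefined: labels contain a single class")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y == 1)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y == 1)
  dRec <- diff(c(0, rec))
  sum(prec * dRec)
}

.stopifnotScalarFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1)
    stop(sprintf("%s must be a single value in [0, 1]", name))
}
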