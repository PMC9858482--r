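# Independent brute-force oracles and small fixture builders. The oracles
# recompute every running-sum quantity from scratch at each position (O(n^2))
# and share no code with the package implementations.

# ssGSEA score of one sample by exhaustive accumulation over positions.
oracleSsgsea <- function(exprColumn, genes, alpha) {
  nm <- names(exprColumn)
  ord <- nm[order(-exprColumn, nm, method = "radix")]
  G <- length(ord)
  present <- intersect(genes, nm)
  W <- 0
  for (g in present) W <- W + (G - match(g, ord) + 1)^alpha
  total <- 0
  for (i in seq_len(G)) {
    pin <- 0; nmiss <- 0
    for (k in seq_len(i)) {
      if (ord[k] %in% present) {
        pin <- pin + (G - k + 1)^alpha / W
      } else {
        nmiss <- nmiss + 1
      }
    }
    total <- total + pin - nmiss / (G - length(present))
  }
  total
}

# SES by exhaustive enumeration of D(i) at every position.
oracleSes <- function(abundance, members, p) {
  nm <- names(abundance)
  ord <- nm[order(-abundance, nm, method = "radix")]
  inS <- ord %in% members
  NR <- sum(abs(abundance[ord[inS]])^p)
  Nnot <- sum(!inS)
  best <- 0; bestAbs <- -1
  for (i in seq_along(ord)) {
    fhit <- 0; fmiss <- 0
    for (k in seq_len(i)) {
      if (inS[k]) fhit <- fhit + abs(abundance[[ord[k]]])^p / NR
      else fmiss <- fmiss + 1 / Nnot
    }
    D <- fhit - fmiss
    if (abs(D) > bestAbs + 1e-15) { bestAbs <- abs(D); best <- D }
  }
  best
}

# Random expression matrix with unique ids.
randExpr <- function(nGenes, nSamples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(nGenes * nSamples, mean = 5, sd = 2), nGenes, nSamples,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("s%03d", seq_len(nSamples))))
}

# Tiny two-subtype labels over the columns of a matrix.
halfSubtypes <- function(m) {
  n <- ncol(m)
  stats::setNames(factor(rep(c("A", "B"), length.out = n)), colnames(m))
}

# Five-subtype sizes scaled to n, miniature cohort proportions.
scaledSizes <- function(n) {
  p <- c(Basal = 20, Her2 = 22, LumA = 68, LumB = 46, Normal = 14) / 170
  s <- round(p * n)
  s[s < 2] <- 2
  s[which.max(s)] <- s[which.max(s)] + (n - sum(s))
  s
}
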