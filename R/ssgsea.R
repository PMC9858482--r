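# Single-sample GSEA (ssGSEA) scoring engine.
#
# Per sample, genes are ranked by decreasing expression (ties broken by gene
# id, radix/C-locale order, so scores are fully deterministic). Walking down
# the ranking, the score accumulates the difference between the weighted
# in-set empirical CDF (weights = bottom-up rank^alpha of in-set genes) and
# the uniform out-of-set CDF; the enrichment score is the sum of the running
# difference over all positions (the classic ssGSEA integral).
#
# The batch path uses a closed form of that sum: with G genes, in-set
# positions p_k (1 = most expressed) and bottom-up ranks R_k = G - p_k + 1,
#   score = sum_k R_k^(alpha+1) / sum_k R_k^alpha
#           - [G(G+1)/2 - sum_k R_k] / (G - m).
# This makes gene-label permutation nulls cheap: the position matrix is
# computed once and only the in-set indices change per permutation.

# Position of each gene in each sample's descending-expression order.
.ssgseaPositions <- function(m) {
  G <- nrow(m)
  pos <- matrix(0L, G, ncol(m), dimnames = dimnames(m))
  rn <- rownames(m)
  for (j in seq_len(ncol(m))) {
    o <- order(-m[, j], rn, method = "radix")
    pos[o, j] <- seq_len(G)
  }
  pos
}

# Closed-form set scores for all samples, given the position matrix and the
# in-set row indices.
.ssgseaFromPositions <- function(pos, idx, alpha) {
  G <- nrow(pos)
  m <- length(idx)
  Rm <- G - pos[idx, , drop = FALSE] + 1
  Wa <- Rm^alpha
  colSums(Wa * Rm) / colSums(Wa) -
    (G * (G + 1) / 2 - colSums(Rm)) / (G - m)
}

#' ssGSEA enrichment score for one sample
#'
#' Explicit running-sum form of the single-sample enrichment score: genes are
#' ranked by decreasing expression in this sample (ties broken by gene id),
#' and the score is the sum over all ranking positions of the difference
#' between the weighted in-set empirical CDF and the uniform out-of-set CDF.
#'
#' @param exprColumn named numeric vector: one sample's expression over all
#'   genes (at least 2 genes).
#' @param genes character vector of set member gene ids.
#' @param alpha rank weighting exponent (>= 0).
#' @return numeric scalar enrichment score.
#' @examples
#' x <- setNames(c(6, 5, 4, 3, 2, 1), paste0("g", 1:6))
#' ssgseaScore(x, c("g1", "g2"), alpha = 0.25)
#' @export
ssgseaScore <- function(exprColumn, genes, alpha = 0.25) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (length(exprColumn) < 2L)
    stop("ranking is degenerate for a single-gene matrix")
  if (is.null(names(exprColumn))) stop("exprColumn must be named by gene")
  genes <- unique(genes)
  present <- genes[genes %in% names(exprColumn)]
  if (length(present) == 0L)
    stop("no gene of the set is present in the expression data")
  G <- length(exprColumn)
  if (length(present) >= G)
    stop("gene set covers the whole matrix; out-of-set CDF undefined")
  o <- order(-exprColumn, names(exprColumn), method = "radix")
  ranked <- names(exprColumn)[o]
  inSet <- ranked %in% present
  w <- (G - seq_len(G) + 1)^alpha   # bottom-up rank weight at each position
  stepHit <- ifelse(inSet, w, 0)
  stepHit <- stepHit / sum(stepHit)
  stepMiss <- ifelse(inSet, 0, 1 / (G - length(present)))
  sum(cumsum(stepHit - stepMiss))
}

.ssgseaMatrix <- function(m, geneSets, alpha, normalize) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (nrow(m) < 2L) stop("ranking is degenerate for a single-gene matrix")
  geneSets <- GeneSetList(geneSets)
  pos <- .ssgseaPositions(m)
  out <- matrix(NA_real_, length(geneSets), ncol(m),
                dimnames = list(names(geneSets), colnames(m)))
  dropped <- integer(0)
  for (i in seq_along(geneSets)) {
    nm <- names(geneSets)[i]
    idx <- match(unique(geneSets[[i]]), rownames(m))
    nMiss <- sum(is.na(idx))
    idx <- idx[!is.na(idx)]
    if (nMiss > 0L) dropped[nm] <- nMiss
    if (length(idx) == 0L)
      stop("set '", nm, "': no gene present in the expression matrix")
    if (length(idx) >= nrow(m))
      stop("set '", nm, "' covers the whole matrix; out-of-set CDF undefined")
    out[i, ] <- .ssgseaFromPositions(pos, idx, alpha)
  }
  if (length(dropped) > 0L)
    warning("genes absent from the matrix were dropped: ",
            paste(sprintf("%s (%d)", names(dropped), dropped), collapse = ", "))
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng == 0) stop("cannot normalize a constant score matrix")
    out <- out / rng
  }
  attr(out, "normalized") <- normalize
  out
}

#' @rdname ssgseaScores
#' @export
setMethod("ssgseaScores", "matrix",
  function(x, geneSets, alpha = 0.25, normalize = FALSE)
    .ssgseaMatrix(x, geneSets, alpha, normalize))

#' @rdname ssgseaScores
#' @export
setMethod("ssgseaScores", "SummarizedExperiment",
  function(x, geneSets, alpha = 0.25, normalize = FALSE)
    .ssgseaMatrix(assay(x, "exprs"), geneSets, alpha, normalize))
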