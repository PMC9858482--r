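# Cell-based subtype set enrichment analysis (SubSEA).
#
# For one cell, samples are ranked by decreasing infiltration abundance; the
# sample enrichment score (SES) is the signed maximum deviation of the
# weighted KS running sum
#   D(i) = F_hit(S, i) - F_miss(S, i),
#   F_hit(S, i)  = sum_{j in S, j <= i} |r_j|^p / N_R,
#   F_miss(S, i) = #{j not in S, j <= i} / N_NotS,
# with N_R = sum_{j in S} |r_j|^p. Significance comes from a gene-permutation
# null: gene labels of the expression matrix are shuffled (one global
# relabeling per permutation, shared by all cells), cell abundance and SES are
# recomputed, and the empirical p-value is the fraction of permuted SES values
# more extreme than the observed one in its own direction (M/N).

# SES for every subtype mask at once, given one cell's abundances.
# masks: samples x K logical matrix (same sample order as `a`).
.sesAllSubtypes <- function(a, masks, p, sampleNames) {
  o <- order(-a, sampleNames, method = "radix")
  w <- abs(a[o])^p
  mo <- masks[o, , drop = FALSE]
  n <- length(a)
  out <- numeric(ncol(masks))
  for (k in seq_len(ncol(masks))) {
    hit <- mo[, k]
    NR <- sum(w[hit])
    if (NR == 0)
      stop("weighted member mass N_R is zero; SES undefined for this subtype")
    steps <- numeric(n)
    steps[hit] <- w[hit] / NR
    steps[!hit] <- -1 / sum(!hit)
    D <- cumsum(steps)
    aD <- abs(D)
    # earliest position attaining the maximum deviation; the tolerance keeps
    # the tie-break stable under floating-point summation noise
    out[k] <- D[which(aD >= max(aD) - 1e-12)[1L]]
  }
  out
}

#' Sample enrichment score (SES)
#'
#' The weighted Kolmogorov-Smirnov statistic over samples ranked by
#' decreasing abundance: the value of the running difference between the
#' abundance-weighted member CDF and the uniform non-member CDF at the
#' position where its absolute value is maximal (signed; earliest such
#' position on ties). SES = 1 iff the members occupy exactly the top ranks,
#' -1 iff exactly the bottom ranks, and |SES| <= 1 always. Ties in abundance
#' are broken by sample id so the ranking is a deterministic total order.
#'
#' @param abundance named numeric vector: one cell's infiltration abundance
#'   for every sample.
#' @param members character vector of member sample ids, or logical mask
#'   aligned with \code{abundance}.
#' @param p abundance weighting exponent (default 1; \code{p = 0} reduces to
#'   the classic two-sample KS statistic on ranks, up to sign).
#' @return numeric scalar in [-1, 1].
#' @examples
#' r <- setNames(c(5, 4, 3, 2, 1), paste0("s", 1:5))
#' sampleEnrichmentScore(r, c("s1", "s3"))  # 2/3
#' @export
sampleEnrichmentScore <- function(abundance, members, p = 1) {
  if (is.null(names(abundance))) stop("abundance must be named by sample")
  if (is.logical(members)) {
    if (length(members) != length(abundance))
      stop("logical member mask must match abundance length")
    mask <- members
  } else {
    unknown <- setdiff(members, names(abundance))
    if (length(unknown) > 0L)
      stop("member sample(s) not in abundance vector: ",
           paste(unknown, collapse = ", "))
    mask <- names(abundance) %in% members
  }
  if (!any(mask) || all(mask))
    stop("membership must be a strict, non-empty subset of the samples")
  .sesAllSubtypes(abundance, matrix(mask, ncol = 1L), p, names(abundance))[1L]
}

#' Empirical permutation p-value for an observed SES
#'
#' For observed SES > 0, \code{M} counts permuted SES values strictly greater
#' than the observed one; for SES < 0, strictly smaller; \code{p = M/N}. An
#' observed SES of exactly 0 is treated as fully null-consistent
#' (\code{M = N}, p = 1). The optional add-one correction reports
#' \code{(M+1)/(N+1)} so that p never reaches exactly 0.
#'
#' @param observed observed SES.
#' @param null numeric vector of permuted SES values.
#' @param addOne apply the add-one correction (default \code{FALSE}, the
#'   literal M/N).
#' @return list with \code{p_value} and \code{n_extreme} (M).
#' @examples
#' sesPvalue(0.8, c(0.1, 0.9, 0.5, -0.2))  # M = 1, p = 0.25
#' @export
sesPvalue <- function(observed, null, addOne = FALSE) {
  if (length(null) == 0L) stop("null distribution is empty")
  M <- if (observed > 0) sum(null > observed)
       else if (observed < 0) sum(null < observed)
       else length(null)
  p <- if (addOne) (M + 1) / (length(null) + 1) else M / length(null)
  list(p_value = p, n_extreme = M)
}

#' SubSEA: subtype set enrichment analysis over TME cells
#'
#' Computes the observed SES for every (cell, subtype) pair, builds a
#' gene-permutation null by relabeling the genes of the expression matrix and
#' recomputing abundance and SES per permutation, and reports the empirical
#' p-value per pair. Cells with p-value below \code{sigAlpha} (strictly) are
#' flagged subtype-specific.
#'
#' The reported \code{p_value} is the directional tail probability M/N. As a
#' one-sided tail in the data-chosen direction it can be anti-conservative by
#' up to a factor of 2 in the far tail; \code{p_two_sided} (\code{min(1, 2p)})
#' is a valid two-sided bound for users who want strict type-I control at
#' stringent thresholds. \code{fdr_bh} is a BH adjustment of \code{p_value}
#' across the cells x subtypes family, provided as an extra column (the
#' specific call itself uses the raw threshold).
#'
#' @param x expression input: \linkS4class{TMECohort} (subtype labels taken
#'   from the container) or matrix/\linkS4class{SummarizedExperiment} plus
#'   \code{subtypeLabels}.
#' @param markers \linkS4class{GeneSetList} of per-cell marker sets.
#' @param subtypeLabels named factor (ignored when \code{x} is a
#'   \linkS4class{TMECohort}).
#' @param nPerm number of gene permutations (default 1000, the minimum
#'   resolution for the default \code{sigAlpha} of 0.001).
#' @param seed RNG seed for reproducible permutations.
#' @param weightExponent SES abundance weighting exponent p (default 1).
#' @param alpha ssGSEA rank weighting exponent for the abundance scorer.
#' @param sigAlpha subtype-specific call threshold (strict \code{p <}).
#' @param addOne use the add-one p-value correction.
#' @param perCellShuffle draw an independent gene relabeling per cell instead
#'   of one global relabeling shared by all cells.
#' @param keepNull attach the null SES matrix (permutations x pairs) as
#'   attribute \code{"null"}.
#' @param lineage optional lineage tags for the cells.
#' @param minMarkers minimum usable markers per cell.
#' @return data.frame with one row per (cell, subtype): \code{ses},
#'   \code{n_perm}, \code{n_extreme}, \code{p_value}, \code{p_two_sided},
#'   \code{fdr_bh}, \code{specific}, plus the observed
#'   \linkS4class{CellAbundance} as attribute \code{"abundance"}.
#' @seealso [sampleEnrichmentScore()], [sesPvalue()], [callSubtypeSpecific()]
#' @export
subsea <- function(x, markers, subtypeLabels = NULL, nPerm = 1000, seed = NULL,
                   weightExponent = 1, alpha = 0.25, sigAlpha = 0.001,
                   addOne = FALSE, perCellShuffle = FALSE, keepNull = FALSE,
                   lineage = NULL, minMarkers = 2L) {
  if (nPerm < 1L) stop("nPerm must be at least 1")
  if (sigAlpha < 1 / nPerm)
    warning("sigAlpha = ", sigAlpha, " is below the permutation resolution 1/",
            nPerm, "; no call can be significant except at p = 0")
  if (is(x, "TMECohort") && is.null(subtypeLabels)) subtypeLabels <- subtypes(x)
  if (is.null(subtypeLabels)) stop("subtype labels are required")
  m <- .exprInput(x)$values
  common <- intersect(colnames(m), names(subtypeLabels))
  if (length(common) < 2L) stop("need at least 2 annotated samples")
  m <- m[, common, drop = FALSE]
  st <- droplevels(factor(subtypeLabels[common]))
  if (nlevels(st) < 2L) stop("at least 2 subtypes required")
  masks <- vapply(levels(st), function(l) st == l,
                  logical(length(common)))
  rownames(masks) <- common

  markers <- GeneSetList(markers)
  usable <- vapply(as.list(markers),
                   function(g) sum(unique(g) %in% rownames(m)), integer(1L))
  bad <- names(markers)[usable < minMarkers]
  if (length(bad) > 0L) {
    warning("cell(s) with fewer than ", minMarkers, " usable markers dropped: ",
            paste(bad, collapse = ", "))
    if (length(bad) == length(markers)) stop("no cell has usable markers")
    markers <- markers[setdiff(names(markers), bad)]
  }
  cells <- names(markers)
  G <- nrow(m)
  pos <- .ssgseaPositions(m)
  idxList <- lapply(as.list(markers), function(g) {
    i <- match(unique(g), rownames(m)); i[!is.na(i)]
  })

  # observed abundance and SES
  obsAb <- matrix(NA_real_, length(cells), ncol(m),
                  dimnames = list(cells, colnames(m)))
  for (ci in seq_along(cells)) {
    a <- .ssgseaFromPositions(pos, idxList[[ci]], alpha)
    obsAb[ci, ] <- a - min(a)
  }
  K <- nlevels(st)
  obsSes <- matrix(NA_real_, length(cells), K,
                   dimnames = list(cells, levels(st)))
  for (ci in seq_along(cells))
    obsSes[ci, ] <- .sesAllSubtypes(obsAb[ci, ], masks, weightExponent, common)

  # gene-permutation null
  if (!is.null(seed)) set.seed(seed)
  nullSes <- array(NA_real_, dim = c(nPerm, length(cells), K))
  inv <- integer(G)
  for (b in seq_len(nPerm)) {
    if (!perCellShuffle) {
      perm <- sample.int(G)
      inv[perm] <- seq_len(G)
    }
    for (ci in seq_along(cells)) {
      if (perCellShuffle) {
        perm <- sample.int(G)
        inv[perm] <- seq_len(G)
      }
      idx <- inv[idxList[[ci]]]
      a <- tryCatch(.ssgseaFromPositions(pos, idx, alpha), error = function(e)
        stop("abundance scorer failed at permutation ", b, ": ",
             conditionMessage(e)))
      a <- a - min(a)
      nullSes[b, ci, ] <- .sesAllSubtypes(a, masks, weightExponent, common)
    }
  }

  grid <- expand.grid(cell = cells, subtype = levels(st),
                      stringsAsFactors = FALSE)
  pv <- vapply(seq_len(nrow(grid)), function(i) {
    ci <- match(grid$cell[i], cells); k <- match(grid$subtype[i], levels(st))
    pr <- sesPvalue(obsSes[ci, k], nullSes[, ci, k], addOne = addOne)
    c(pr$p_value, pr$n_extreme)
  }, numeric(2L))
  out <- data.frame(cell = grid$cell, subtype = grid$subtype,
                    ses = obsSes[cbind(match(grid$cell, cells),
                                       match(grid$subtype, levels(st)))],
                    n_perm = nPerm, n_extreme = as.integer(pv[2L, ]),
                    p_value = pv[1L, ],
                    p_two_sided = pmin(1, 2 * pv[1L, ]),
                    stringsAsFactors = FALSE)
  out$fdr_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$specific <- out$p_value < sigAlpha
  attr(out, "abundance") <- CellAbundance(obsAb, lineage)
  if (keepNull) attr(out, "null") <- nullSes
  out
}

#' Extract the subtype-specific (cell, subtype) calls
#'
#' Rows with p-value strictly below \code{alpha} (p exactly equal to the
#' threshold is NOT specific), sorted by subtype, then p, then decreasing
#' |SES|.
#'
#' @param results a [subsea()] result table.
#' @param alpha call threshold (default 0.001).
#' @return data.frame subset of \code{results}.
#' @export
callSubtypeSpecific <- function(results, alpha = 0.001) {
  out <- results[results$p_value < alpha, , drop = FALSE]
  out <- out[order(out$subtype, out$p_value, -abs(out$ses)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
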