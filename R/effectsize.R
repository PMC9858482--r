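# One-vs-rest subtype profiling: Cohen's d with the pooled-SD definition,
# Mann-Whitney U testing, Kruskal-Wallis, and BH-FDR over the whole
# feature x subtype family.

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference
#' \deqn{d = (M_1 - M_2) / SD_{pooled},\quad
#'       SD_{pooled} = \sqrt{(SS_1 + SS_2) / (df_1 + df_2)}}
#' where \eqn{SS_i} is the within-group sum of squared deviations and
#' \eqn{df_i = n_i - 1}. A zero pooled SD makes d undefined; the sentinel
#' \code{NA} is returned so downstream heatmaps stay finite.
#'
#' @param group1,group2 numeric vectors, each of length >= 2.
#' @return numeric scalar (or \code{NA} when the pooled SD is zero).
#' @examples
#' cohensD(c(2, 4), c(1, 3))  # 1/sqrt(2)
#' @export
cohensD <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  m1 <- mean(group1); m2 <- mean(group2)
  ss1 <- sum((group1 - m1)^2); ss2 <- sum((group2 - m2)^2)
  sdPooled <- sqrt((ss1 + ss2) / (n1 - 1 + n2 - 1))
  if (sdPooled == 0) return(NA_real_)
  (m1 - m2) / sdPooled
}

#' Interpretive label for an effect size
#'
#' Conventional bands: |d| below 0.2 is a small effect, between 0.5 and 0.8 a
#' medium effect, above 0.8 a large effect.
#'
#' @param d numeric vector of effect sizes.
#' @return character vector of labels (\code{NA} propagates).
#' @export
effectSizeLabel <- function(d) {
  a <- abs(d)
  out <- rep(NA_character_, length(d))
  out[!is.na(a) & a < 0.2] <- "small"
  out[!is.na(a) & a >= 0.2 & a < 0.5] <- "small-medium"
  out[!is.na(a) & a >= 0.5 & a <= 0.8] <- "medium"
  out[!is.na(a) & a > 0.8] <- "large"
  out
}

# Two-sided MWU p; exact for small tie-free samples, corrected normal
# approximation otherwise (stats::wilcox.test defaults). Identical constant
# groups get p = 1 by convention.
.mwuP <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' One-vs-rest effect-size profile over subtypes
#'
#' For every feature (row of \code{scores}) and every subtype, compares the
#' subtype's samples against all remaining samples: Cohen's d, two-sided
#' Mann-Whitney U p-value, and BH-FDR across the whole feature x subtype
#' family (one correction family per call, i.e. per heatmap).
#'
#' @param scores numeric matrix features x samples (e.g. from
#'   [ssgseaScores()]) or a \linkS4class{CellAbundance}.
#' @param subtypes named factor of subtype labels.
#' @param fdrThreshold significance flag threshold (default 0.05).
#' @return data.frame with one row per feature x subtype: \code{d},
#'   group sizes and means, pooled SD, \code{mwu_p}, \code{fdr},
#'   \code{significant}, \code{label}.
#' @export
oneVsRestProfile <- function(scores, subtypes, fdrThreshold = 0.05) {
  if (is(scores, "CellAbundance")) scores <- abundanceMatrix(scores)
  common <- intersect(colnames(scores), names(subtypes))
  if (length(common) == 0L) stop("no shared samples between scores and labels")
  scores <- scores[, common, drop = FALSE]
  st <- droplevels(factor(subtypes[common]))
  if (nlevels(st) < 2L) stop("at least 2 subtypes required")
  tab <- table(st)
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L) {
    warning("subtype(s) with fewer than 2 samples excluded: ",
            paste(small, collapse = ", "))
  }
  keepLevels <- setdiff(levels(st), small)
  grid <- expand.grid(feature = rownames(scores), subtype = keepLevels,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    v <- scores[grid$feature[i], ]
    inG <- st == grid$subtype[i]
    g1 <- v[inG]; g2 <- v[!inG]
    n1 <- length(g1); n2 <- length(g2)
    ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    sdP <- sqrt(ss / (n1 + n2 - 2))
    data.frame(feature = grid$feature[i], subtype = grid$subtype[i],
               d = if (sdP == 0) NA_real_ else (mean(g1) - mean(g2)) / sdP,
               n1 = n1, n2 = n2, m1 = mean(g1), m2 = mean(g2),
               sd_pooled = sdP, mwu_p = .mwuP(g1, g2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$mwu_p, method = "BH")
  out$significant <- !is.na(out$d) & out$fdr < fdrThreshold
  out$label <- effectSizeLabel(out$d)
  nSent <- sum(is.na(out$d))
  if (nSent > 0L)
    message(nSent, " feature x subtype cell(s) with zero pooled SD ",
            "(d sentinel NA, never flagged)")
  out
}

#' Star labels for p-value thresholds
#'
#' \code{ns} for p > 0.05, then \code{*} (<= 0.05), \code{**} (<= 0.01),
#' \code{***} (<= 0.001), \code{****} (<= 0.0001).
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @examples
#' pvalueStars(c(0.2, 0.03, 0.003))
#' @export
pvalueStars <- function(p) {
  out <- rep(NA_character_, length(p))
  out[!is.na(p)] <- "ns"
  out[!is.na(p) & p <= 0.05] <- "*"
  out[!is.na(p) & p <= 0.01] <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out[!is.na(p) & p <= 0.0001] <- "****"
  out
}

#' Overall and pairwise subtype tests for one feature
#'
#' One Kruskal-Wallis p-value across all groups plus all pairwise two-sided
#' Mann-Whitney U p-values, with star labels at the conventional thresholds.
#'
#' @param values numeric vector of a per-sample feature.
#' @param groups factor of group labels, aligned with \code{values}.
#' @return list with \code{kw_p}, \code{pairwise_p} (K x K symmetric matrix,
#'   \code{NA} diagonal) and \code{stars} (matching label matrix).
#' @export
groupTests <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("at least 2 groups required")
  if (any(table(groups) == 0L)) stop("empty group")
  kw <- stats::kruskal.test(values, groups)$p.value
  lv <- levels(groups)
  K <- length(lv)
  pm <- matrix(NA_real_, K, K, dimnames = list(lv, lv))
  for (i in seq_len(K - 1L)) {
    for (j in seq(i + 1L, K)) {
      p <- .mwuP(values[groups == lv[i]], values[groups == lv[j]])
      pm[i, j] <- pm[j, i] <- p
    }
  }
  stars <- matrix(pvalueStars(pm), K, K, dimnames = dimnames(pm))
  list(kw_p = kw, pairwise_p = pm, stars = stars)
}
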