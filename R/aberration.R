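# Subtype-specific genomic aberration: mutation binarization, frequency
# filtering, chi-square specificity with BH-FDR, and the analogous CNV
# amplification/deletion analyses. Chi-square tests are run without Yates
# continuity correction; tables with low expected counts are flagged, with an
# optional seeded Monte-Carlo p.

#' Binarize a somatic mutation table
#'
#' Collapses a MAF-like table to a gene x sample 0/1 matrix: entry (g, s) is 1
#' iff sample s carries at least one qualifying variant of gene g. Samples
#' without any qualifying variant get all-zero columns. Binarization is
#' idempotent by construction.
#'
#' @param mutations mutation table with canonical columns (see
#'   [readMutationTable()]) or a \linkS4class{TMECohort}.
#' @param samples sample universe (columns of the output). Defaults to the
#'   samples present in the table (or the cohort universe).
#' @param classes qualifying variant classes (default: the non-silent MAF
#'   vocabulary).
#' @return integer matrix, genes x samples, values in \{0, 1\}.
#' @export
binarizeMutations <- function(mutations, samples = NULL,
                              classes = .NON_SILENT) {
  if (is(mutations, "TMECohort")) {
    if (is.null(samples)) samples <- colnames(mutations)
    mutations <- mutationTable(mutations)
    if (is.null(mutations)) stop("cohort has no mutation layer")
  }
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  keep <- mutations$variant_classification %in% classes &
    mutations$sample_id %in% samples
  mut <- mutations[keep, , drop = FALSE]
  if (nrow(mut) == 0L) {
    warning("no qualifying variant; returning an all-zero matrix")
    return(matrix(0L, 0L, length(samples),
                  dimnames = list(character(0), samples)))
  }
  genes <- sort(unique(mut$gene_id))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(mut$gene_id, genes), match(mut$sample_id, samples))] <- 1L
  m
}

#' Filter genes by cohort-wide mutation frequency
#'
#' Keeps genes whose mutation rate across all samples is strictly greater
#' than \code{minRate} (a gene mutated in exactly 1\% of samples is dropped).
#'
#' @param matrix gene x sample 0/1 matrix from [binarizeMutations()].
#' @param minRate frequency threshold in (0, 1); default 0.01.
#' @return character vector of retained gene ids.
#' @export
filterByFrequency <- function(matrix, minRate = 0.01) {
  if (minRate <= 0 || minRate >= 1) stop("minRate must lie in (0, 1)")
  rates <- rowMeans(matrix > 0)
  rownames(matrix)[rates > minRate]
}

# Shared 2 x K specificity engine for a gene x sample 0/1 indicator matrix.
.specificityTest <- function(indicator, subtypeLabels, fdrThreshold,
                             monteCarlo = FALSE, B = 2000) {
  st <- droplevels(factor(subtypeLabels))
  names(st) <- names(subtypeLabels)
  common <- intersect(colnames(indicator), names(st))
  if (length(common) == 0L) stop("no shared samples with subtype annotation")
  ind <- indicator[, common, drop = FALSE]
  st <- droplevels(st[common])
  if (nlevels(st) < 2L) stop("at least 2 subtypes required")
  lv <- levels(st)
  sizes <- as.integer(table(st))
  rows <- list()
  for (g in rownames(ind)) {
    x <- ind[g, ]
    tot <- sum(x)
    if (tot == 0L || tot == length(x)) next   # degenerate table, excluded
    cnt <- vapply(lv, function(l) sum(x[st == l]), numeric(1L))
    tab <- rbind(mutated = cnt, wild = sizes - cnt)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE,
                                             simulate.p.value = monteCarlo,
                                             B = B))
    row <- data.frame(gene = g, t(cnt), t(cnt / sizes),
                      chi2 = unname(ct$statistic), p = ct$p.value,
                      low_expected = any(ct$expected < 5),
                      stringsAsFactors = FALSE)
    colnames(row)[2:(1 + length(lv))] <- paste0("n_", lv)
    colnames(row)[(2 + length(lv)):(1 + 2 * length(lv))] <- paste0("rate_", lv)
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0), chi2 = numeric(0), p = numeric(0),
                      fdr = numeric(0), specific = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$specific <- out$fdr < fdrThreshold
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtype-specific mutation test
#'
#' For every gene of the (pre-filtered) binary mutation matrix, tests the
#' 2 x K contingency of mutated/wild-type counts against the subtype
#' partition with a chi-square test (no continuity correction), applies
#' BH-FDR across genes, and flags genes with FDR strictly below the threshold
#' as subtype-specific. Genes mutated in no or in all samples are excluded as
#' degenerate.
#'
#' @param matrix gene x sample 0/1 matrix (e.g. [binarizeMutations()]
#'   restricted to [filterByFrequency()] genes).
#' @param subtypeLabels named factor of subtype labels.
#' @param fdrThreshold specificity threshold (default 0.01).
#' @param monteCarlo use a Monte-Carlo chi-square p (seed beforehand for
#'   reproducibility).
#' @param B Monte-Carlo replicates.
#' @return data.frame ordered by p: per-subtype mutated counts and rates,
#'   \code{chi2}, \code{p}, \code{fdr}, \code{low_expected}, \code{specific}.
#' @export
subtypeSpecificMutations <- function(matrix, subtypeLabels,
                                     fdrThreshold = 0.01, monteCarlo = FALSE,
                                     B = 2000) {
  .specificityTest(matrix, subtypeLabels, fdrThreshold, monteCarlo, B)
}

#' Subtype-specific CNV amplification / deletion tests
#'
#' Collapses GISTIC-style codes to amplification (code > 0) and deletion
#' (code < 0) indicators and runs two independent subtype-specificity
#' analyses, each BH-corrected across its own gene family.
#'
#' @param cnv gene x sample integer matrix with codes in \{-2,...,2\}, or a
#'   \linkS4class{TMECohort} carrying a CNV layer.
#' @param subtypeLabels named factor of subtype labels (taken from the cohort
#'   when \code{cnv} is a \linkS4class{TMECohort}).
#' @param fdrThreshold specificity threshold (default 0.01).
#' @param highLevelOnly restrict to high-level events (codes +/-2 only).
#' @param monteCarlo,B Monte-Carlo chi-square options (see
#'   [subtypeSpecificMutations()]).
#' @return list with elements \code{amp} and \code{del}, each a specificity
#'   table as in [subtypeSpecificMutations()].
#' @export
subtypeSpecificCnv <- function(cnv, subtypeLabels = NULL, fdrThreshold = 0.01,
                               highLevelOnly = FALSE, monteCarlo = FALSE,
                               B = 2000) {
  if (is(cnv, "TMECohort")) {
    if (is.null(subtypeLabels)) subtypeLabels <- subtypes(cnv)
    cnv <- cnvMatrix(cnv)
    if (is.null(cnv)) stop("cohort has no CNV layer")
  }
  if (!all(cnv %in% -2:2)) stop("CNV codes must lie in {-2, -1, 0, 1, 2}")
  thr <- if (highLevelOnly) 2L else 1L
  amp <- (cnv >= thr) * 1L
  del <- (cnv <= -thr) * 1L
  list(amp = .specificityTest(amp, subtypeLabels, fdrThreshold, monteCarlo, B),
       del = .specificityTest(del, subtypeLabels, fdrThreshold, monteCarlo, B))
}
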