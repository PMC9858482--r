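# Named per-sample TME feature scores: MHC class I score, T-cell-inflamed GEP,
# tumor mutation burden, ESTIMATE-style immune/stromal/purity, and the 8-set
# TME signature panel.

# MAF variant classes counted as non-silent (protein-affecting).
.NON_SILENT <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
                 "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
                 "Splice_Site", "Translation_Start_Site", "Nonstop_Mutation")

# Silent / non-coding classes recognised (and not counted).
.SILENT_CLASSES <- c("Silent", "3'UTR", "5'UTR", "Intron", "RNA", "IGR",
                     "3'Flank", "5'Flank", "Splice_Region")

#' Gene sets bundled with the package
#'
#' \describe{
#'   \item{mhc_core}{the 9-gene core MHC class I set (HLA-A, HLA-B, HLA-C,
#'     TAP1, TAP2, NLRC5, PSMB9, PSMB8, B2M).}
#'   \item{gep18}{the 18-gene T-cell-inflamed GEP inflammatory signature.}
#'   \item{tme_panel}{the 8 TME signature sets (two immune-related, two
#'     vascularization-related, one stromal, three metabolic); memberships are
#'     representative marker genes, pluggable via any user GMT.}
#'   \item{estimate_synthetic}{small synthetic stand-in immune/stromal sets for
#'     the ESTIMATE-style scores, intended for tests and demos.}
#'   \item{cells_demo}{curated ~10-cell demo marker collection with an
#'     immune/stromal lineage split.}
#' }
#'
#' @param name which bundled collection to load.
#' @return A \linkS4class{GeneSetList}.
#' @examples
#' length(bundledGeneSets("tme_panel"))
#' @export
bundledGeneSets <- function(name = c("mhc_core", "gep18", "tme_panel",
                                     "estimate_synthetic", "cells_demo")) {
  name <- match.arg(name)
  file <- c(mhc_core = "mhc_core.gmt", gep18 = "gep18.gmt",
            tme_panel = "tme_panel.gmt",
            estimate_synthetic = "estimate_sets_synthetic.gmt",
            cells_demo = "tme_cells_demo.gmt")[[name]]
  readGmt(system.file("extdata", file, package = "SubtypeTME", mustWork = TRUE))
}

#' MHC class I score
#'
#' Mean of log-transformed, median-centered expression of the core MHC class I
#' genes per patient: each core gene's FPKM values are \code{log2(x + 1)}
#' transformed, centered on that gene's median across all patients, and the
#' per-sample score is the average of the centered values over core genes.
#' Because of the median-centering the score is only meaningful relative to
#' the cohort it was computed in.
#'
#' @param x expression on FPKM scale: matrix (assumed FPKM),
#'   \linkS4class{SummarizedExperiment} or \linkS4class{TMECohort} with
#'   declared scale \code{"fpkm"}.
#' @param coreSet gene set to use; default the bundled 9-gene core set.
#' @param logTransform apply \code{log2(x+1)} before centering (set
#'   \code{FALSE} if the values are already on log scale).
#' @return named numeric vector of per-sample scores.
#' @export
mhcScore <- function(x, coreSet = NULL, logTransform = TRUE) {
  inp <- .exprInput(x)
  if (!is.null(inp$scale) && inp$scale != "fpkm" && logTransform)
    stop("declared scale is '", inp$scale, "'; the MHC score expects FPKM ",
         "input (or set logTransform = FALSE for pre-logged values)")
  m <- inp$values
  if (ncol(m) < 2L) stop("median-centering is degenerate with < 2 samples")
  if (is.null(coreSet)) coreSet <- bundledGeneSets("mhc_core")
  genes <- if (is(coreSet, "GeneSetList")) coreSet[[1L]] else coreSet
  present <- genes[genes %in% rownames(m)]
  if (length(present) == 0L) stop("no core MHC gene present in the matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " core gene(s) absent, dropped")
  v <- m[present, , drop = FALSE]
  if (logTransform) v <- log2(v + 1)
  centered <- v - apply(v, 1L, stats::median)
  colMeans(centered)
}

#' T-cell-inflamed GEP score
#'
#' Normalized ssGSEA enrichment score of the 18-gene T-cell-inflamed gene
#' expression profile, per sample.
#'
#' @param x expression input (matrix, \linkS4class{SummarizedExperiment} or
#'   \linkS4class{TMECohort}).
#' @param gepSet gene set; default the bundled 18-gene set.
#' @param alpha ssGSEA rank weighting exponent.
#' @return named numeric vector of per-sample GEP scores.
#' @export
gepScore <- function(x, gepSet = NULL, alpha = 0.25) {
  if (is.null(gepSet)) gepSet <- bundledGeneSets("gep18")
  gepSet <- GeneSetList(gepSet)
  sc <- ssgseaScores(.exprInput(x)$values, gepSet[1L], alpha = alpha,
                     normalize = TRUE)
  sc[1L, ]
}

#' Tumor mutation burden
#'
#' Number of non-silent somatic mutations per megabase of coding genome,
#' per sample.
#'
#' @param mutations mutation table with canonical columns (see
#'   [readMutationTable()]) or a \linkS4class{TMECohort}.
#' @param codingMb coding-area denominator in megabases (default 38, a
#'   conventional exome size).
#' @param samples sample universe; samples without any variant get TMB 0.
#'   Defaults to the samples present in the table (or the cohort universe).
#' @param nonSilentClasses variant classes counted as non-silent.
#' @param lenient if \code{TRUE}, unknown variant classifications are dropped
#'   with a message instead of raising an error.
#' @return named numeric vector of per-sample TMB values.
#' @export
tmbScore <- function(mutations, codingMb = 38, samples = NULL,
                     nonSilentClasses = .NON_SILENT, lenient = FALSE) {
  if (is(mutations, "TMECohort")) {
    if (is.null(samples)) samples <- colnames(mutations)
    mutations <- mutationTable(mutations)
    if (is.null(mutations)) stop("cohort has no mutation layer")
  }
  if (codingMb <= 0) stop("codingMb must be positive")
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  vc <- mutations$variant_classification
  known <- c(nonSilentClasses, .SILENT_CLASSES)
  unknown <- setdiff(unique(vc), known)
  if (length(unknown) > 0L) {
    if (!lenient)
      stop("unknown variant classification(s): ",
           paste(unknown, collapse = ", "))
    drop <- vc %in% unknown
    message("dropped ", sum(drop), " variant(s) with unknown classification")
    mutations <- mutations[!drop, , drop = FALSE]
    vc <- mutations$variant_classification
  }
  counts <- table(factor(mutations$sample_id[vc %in% nonSilentClasses],
                         levels = samples))
  stats::setNames(as.numeric(counts) / codingMb, samples)
}

# ESTIMATE purity transform constants (from the original ESTIMATE method).
.PURITY_A <- 0.6049872018
.PURITY_B <- 0.0001467884

#' ESTIMATE-style immune, stromal and purity scores
#'
#' Immune and stromal scores are ssGSEA enrichment scores of the respective
#' gene sets; the ESTIMATE score is their sum; tumor purity is
#' \code{cos(0.6049872018 + 0.0001467884 * estimate)}, clamped to [0, 1] and
#' flagged when the ESTIMATE score falls outside the range in which the
#' transform was calibrated (cosine argument in [0, pi/2]).
#'
#' @param x expression input.
#' @param immuneSet,stromalSet gene sets; defaults are the bundled synthetic
#'   stand-ins (supply the real immune/stromal signatures for real analyses).
#' @param alpha ssGSEA rank weighting exponent.
#' @return data.frame with columns \code{sample_id}, \code{immune_score},
#'   \code{stromal_score}, \code{estimate_score}, \code{tumor_purity},
#'   \code{purity_out_of_range}.
#' @export
estimateScores <- function(x, immuneSet = NULL, stromalSet = NULL,
                           alpha = 0.25) {
  if (is.null(immuneSet) || is.null(stromalSet)) {
    std <- bundledGeneSets("estimate_synthetic")
    if (is.null(immuneSet)) immuneSet <- std[["immune_signature"]]
    if (is.null(stromalSet)) stromalSet <- std[["stromal_signature"]]
    message("using bundled synthetic immune/stromal stand-in set(s)")
  }
  genes <- list(immune = if (is(immuneSet, "GeneSetList")) immuneSet[[1L]]
                         else immuneSet,
                stromal = if (is(stromalSet, "GeneSetList")) stromalSet[[1L]]
                          else stromalSet)
  sc <- ssgseaScores(.exprInput(x)$values, GeneSetList(genes), alpha = alpha,
                     normalize = FALSE)
  est <- sc["immune", ] + sc["stromal", ]
  arg <- .PURITY_A + .PURITY_B * est
  purity <- cos(arg)
  flagged <- arg < 0 | arg > pi / 2
  data.frame(sample_id = colnames(sc),
             immune_score = sc["immune", ],
             stromal_score = sc["stromal", ],
             estimate_score = est,
             tumor_purity = pmin(pmax(purity, 0), 1),
             purity_out_of_range = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' TME signature panel scores
#'
#' ssGSEA scores of the 8-set TME signature panel (cytolytic activity,
#' lymphocytes, hypoxia, lymphangiogenesis, stromal, glycolysis, lipid
#' metabolism, pentose phosphate pathway).
#'
#' @param x expression input.
#' @param panel a \linkS4class{GeneSetList}; default the bundled panel.
#' @param alpha ssGSEA rank weighting exponent.
#' @param normalize divide by the global score range (see [ssgseaScores()]).
#' @return numeric matrix, signature sets x samples.
#' @export
signaturePanel <- function(x, panel = NULL, alpha = 0.25, normalize = FALSE) {
  if (is.null(panel)) panel <- bundledGeneSets("tme_panel")
  ssgseaScores(.exprInput(x)$values, panel, alpha = alpha,
               normalize = normalize)
}
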