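#' Expression matrix of a container
#'
#' @param x a \linkS4class{TMECohort} or \linkS4class{SummarizedExperiment}.
#' @return numeric matrix, genes x samples.
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' Declared expression scale
#'
#' @param x a container carrying a declared scale (\code{"fpkm"} or
#'   \code{"log2p1"}).
#' @return character scalar.
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' Subtype labels of a cohort
#'
#' @param x a \linkS4class{TMECohort}.
#' @return named factor of subtype labels, one per sample.
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))

#' Survival records of a cohort
#'
#' @param x a \linkS4class{TMECohort}.
#' @return data.frame with columns \code{sample_id}, \code{time}, \code{event},
#'   restricted to samples with survival information.
#' @export
setGeneric("survivalRecords", function(x) standardGeneric("survivalRecords"))

#' Somatic mutation table of a cohort
#'
#' @param x a \linkS4class{TMECohort}.
#' @return data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{variant_classification}, or \code{NULL} when absent.
#' @export
setGeneric("mutationTable", function(x) standardGeneric("mutationTable"))

#' CNV code matrix of a cohort
#'
#' @param x a \linkS4class{TMECohort}.
#' @return integer matrix of GISTIC-style codes in \{-2,...,2\}, or \code{NULL}.
#' @export
setGeneric("cnvMatrix", function(x) standardGeneric("cnvMatrix"))

#' Per-layer sample coverage of a cohort
#'
#' @param x a \linkS4class{TMECohort}.
#' @return named list of per-layer covered sample counts.
#' @export
setGeneric("layerCoverage", function(x) standardGeneric("layerCoverage"))

#' log2(x + 1) transform of FPKM-scale expression
#'
#' Applies the standard \code{log2(value + 1)} transform used to bring
#' FPKM-normalised profiles onto a log scale before scoring.
#'
#' @param x matrix (all values >= 0) or \linkS4class{SummarizedExperiment} /
#'   \linkS4class{TMECohort} with declared scale \code{"fpkm"}.
#' @return object of the same shape on \code{log2p1} scale.
#' @examples
#' log2p1Transform(matrix(c(0, 1, 7, 3), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' @export
setGeneric("log2p1Transform", function(x) standardGeneric("log2p1Transform"))

#' Single-sample gene set enrichment scores (ssGSEA)
#'
#' @param x expression input: numeric matrix (genes x samples, with dimnames),
#'   \linkS4class{SummarizedExperiment} or \linkS4class{TMECohort}.
#' @param geneSets a \linkS4class{GeneSetList} (or named list of gene id
#'   vectors).
#' @param alpha rank weighting exponent (default 0.25, the usual ssGSEA
#'   convention).
#' @param normalize logical; if \code{TRUE} every score is divided by the
#'   global (max - min) of the whole score matrix, so the output range is 1.
#' @return numeric matrix of enrichment scores, sets x samples, with attribute
#'   \code{normalized}.
#' @export
setGeneric("ssgseaScores",
  function(x, geneSets, alpha = 0.25, normalize = FALSE)
    standardGeneric("ssgseaScores"))

#' Abundance matrix of a CellAbundance object
#'
#' @param x a \linkS4class{CellAbundance}.
#' @return numeric matrix, cells x samples.
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' Lineage tags of a CellAbundance object
#'
#' @param x a \linkS4class{CellAbundance}.
#' @return named character vector (\code{immune}/\code{stromal}/\code{other}).
#' @export
setGeneric("cellLineage", function(x) standardGeneric("cellLineage"))
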