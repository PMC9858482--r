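# Marker-set cell infiltration scoring with the cells x samples interface of
# reference estimators such as xCell. The estimator itself is pluggable:
# scores computed here are per-cell ssGSEA scores of the marker sets, shifted
# per cell so the cohort minimum is 0 (SubSEA weights samples by |r_j|^p, and
# nonnegative abundances make the weighting direction unambiguous). Output
# files from an external estimator can be loaded with readCellAbundance().

#' Marker-set cell infiltration abundance
#'
#' @param x expression input (matrix, \linkS4class{SummarizedExperiment} or
#'   \linkS4class{TMECohort}).
#' @param markers \linkS4class{GeneSetList} of per-cell marker sets.
#' @param lineage optional named character vector tagging each cell as
#'   \code{immune}/\code{stromal}/\code{other}.
#' @param alpha ssGSEA rank weighting exponent.
#' @param minMarkers cells with fewer usable (present) markers are dropped
#'   with a warning (default 2).
#' @return A \linkS4class{CellAbundance}; every cell's minimum over samples
#'   is exactly 0.
#' @export
cellAbundance <- function(x, markers, lineage = NULL, alpha = 0.25,
                          minMarkers = 2L) {
  m <- .exprInput(x)$values
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
  sc <- ssgseaScores(m, markers, alpha = alpha, normalize = FALSE)
  sc <- sc - apply(sc, 1L, min)
  attr(sc, "normalized") <- NULL
  CellAbundance(sc, lineage)
}

#' Load an externally computed cell abundance matrix
#'
#' Accepts a cells-as-rows TSV (e.g. xCell output). Lineage tags come from an
#' optional two-column sidecar TSV (\code{cell}, \code{lineage}); untagged
#' cells are \code{"other"}.
#'
#' @param path abundance TSV path.
#' @param cohortSamples optional character vector (or \linkS4class{TMECohort});
#'   when given, every sample in the file must belong to it.
#' @param lineagePath optional lineage sidecar TSV path.
#' @return A \linkS4class{CellAbundance}.
#' @export
readCellAbundance <- function(path, cohortSamples = NULL, lineagePath = NULL) {
  a <- .readTsvMatrix(path, "abundance")
  if (!is.null(cohortSamples)) {
    if (is(cohortSamples, "TMECohort")) cohortSamples <- colnames(cohortSamples)
    unknown <- setdiff(colnames(a), cohortSamples)
    if (length(unknown) > 0L)
      stop("abundance file contains sample(s) outside the cohort universe: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  lineage <- NULL
  if (!is.null(lineagePath)) {
    df <- utils::read.delim(lineagePath, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    lineage <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  }
  CellAbundance(a, lineage)
}

#' Write a cell abundance matrix (and lineage sidecar) to TSV
#'
#' @param x a \linkS4class{CellAbundance}.
#' @param path abundance TSV path.
#' @param lineagePath optional sidecar TSV path for the lineage tags.
#' @return \code{path}, invisibly.
#' @export
writeCellAbundance <- function(x, path, lineagePath = NULL) {
  .writeTsvMatrix(abundanceMatrix(x), path, idColumn = "cell")
  if (!is.null(lineagePath)) {
    utils::write.table(
      data.frame(cell = names(cellLineage(x)), lineage = cellLineage(x)),
      lineagePath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
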