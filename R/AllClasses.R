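#' @import methods
#' @importFrom S4Vectors metadata `metadata<-` DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay `assay<-` assayNames colData `colData<-`
NULL

#' Named collection of gene sets
#'
#' A light container for named, ordered gene lists as read from GMT files:
#' signature panels, marker sets, and score definitions. Set names are unique,
#' every set is non-empty, and genes do not repeat within a set.
#'
#' @slot sets named list of character vectors (gene identifiers).
#' @slot description character vector of per-set descriptions, parallel to
#'   \code{sets}.
#'
#' @seealso [readGmt()], [writeGmt()]
#' @export
setClass("GeneSetList",
  slots = c(sets = "list", description = "character"))

setValidity("GeneSetList", function(object) {
  s <- object@sets
  if (length(s) == 0L) return("collection must contain at least one set")
  nm <- names(s)
  if (is.null(nm) || any(!nzchar(nm))) return("all sets must be named")
  if (anyDuplicated(nm)) {
    return(paste0("duplicate set names: ",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  for (i in seq_along(s)) {
    g <- s[[i]]
    if (!is.character(g) || length(g) == 0L)
      return(paste0("set '", nm[i], "' is empty or not a character vector"))
    if (anyDuplicated(g))
      return(paste0("set '", nm[i], "' contains duplicated genes"))
  }
  if (length(object@description) != length(s))
    return("description must be parallel to sets")
  TRUE
})

#' Construct a GeneSetList
#'
#' @param sets named list of character vectors of gene ids.
#' @param description optional character vector of per-set descriptions;
#'   recycled empty strings by default.
#' @return A [GeneSetList-class] object.
#' @examples
#' gs <- GeneSetList(list(tcell = c("CD3D", "CD8A"), bcell = c("CD19", "MS4A1")))
#' names(gs)
#' gs[["tcell"]]
#' @export
GeneSetList <- function(sets, description = NULL) {
  if (is(sets, "GeneSetList")) return(sets)
  if (is.null(description)) description <- rep("", length(sets))
  new("GeneSetList", sets = sets, description = description)
}

#' @describeIn GeneSetList-class number of sets
#' @param x a \code{GeneSetList}
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))

#' @describeIn GeneSetList-class set names
#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

#' @describeIn GeneSetList-class extract one set (character vector of genes)
#' @param i index or set name
#' @export
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

#' @describeIn GeneSetList-class subset to several sets
#' @param j,...,drop ignored
#' @export
setMethod("[", "GeneSetList", function(x, i, j, ..., drop = FALSE) {
  idx <- if (is.character(i)) match(i, names(x@sets)) else i
  if (is.numeric(idx) && anyNA(idx))
    stop("unknown set name(s): ", paste(i[is.na(idx)], collapse = ", "))
  new("GeneSetList", sets = x@sets[idx], description = x@description[idx])
})

#' @describeIn GeneSetList-class gene sets as a plain named list
#' @export
setMethod("as.list", "GeneSetList", function(x) x@sets)

setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList with", length(object), "set(s)\n")
  n <- min(length(object), 5L)
  for (i in seq_len(n)) {
    g <- object@sets[[i]]
    cat("  ", names(object@sets)[i], " (", length(g), " genes): ",
        paste(utils::head(g, 4L), collapse = ", "),
        if (length(g) > 4L) ", ..." else "", "\n", sep = "")
  }
  if (length(object) > n) cat("  ...\n")
})

.EXPR_SCALES <- c("fpkm", "log2p1")

#' Multi-layer cohort container
#'
#' \code{TMECohort} extends \linkS4class{SummarizedExperiment}: the expression
#' matrix lives in assay \code{"exprs"}, the PAM50-style subtype label and
#' (optional) overall-survival time/event in \code{colData}, and the somatic
#' mutation table, CNV code matrix, declared expression scale and per-layer
#' coverage counts in \code{metadata}. All layers share the sample universe
#' fixed by [alignCohort()] (expression samples intersected with annotated
#' samples); mutation and CNV layers may cover only part of it.
#'
#' @seealso [alignCohort()], [exprMatrix()], [subtypes()], [survivalRecords()],
#'   [mutationTable()], [cnvMatrix()]
#' @export
setClass("TMECohort", contains = "SummarizedExperiment")

setValidity("TMECohort", function(object) {
  if (!"exprs" %in% assayNames(object)) return("assay 'exprs' is required")
  m <- assay(object, "exprs")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("expression matrix must have gene and sample names")
  if (anyDuplicated(rownames(m))) return("duplicate gene ids")
  if (anyDuplicated(colnames(m))) return("duplicate sample ids")
  if (!all(is.finite(m))) return("expression values must be finite")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% .EXPR_SCALES)
    return("metadata()$scale must be 'fpkm' or 'log2p1'")
  if (sc == "log2p1" && any(m < 0))
    return("log2p1-scaled values must be non-negative")
  cd <- colData(object)
  if (!"subtype" %in% colnames(cd)) return("colData column 'subtype' required")
  st <- cd$subtype
  if (!is.factor(st)) return("subtype must be a factor")
  tab <- table(droplevels(st))
  if (length(tab) < 2L) return("at least 2 subtypes required")
  if (any(tab < 2L))
    return(paste0("subtype(s) with fewer than 2 samples: ",
                  paste(names(tab)[tab < 2L], collapse = ", ")))
  if ("os_time" %in% colnames(cd)) {
    tt <- cd$os_time; ev <- cd$os_event
    ok <- !is.na(tt)
    if (any(tt[ok] <= 0)) return("survival times must be positive")
    if (!all(ev[!is.na(ev)] %in% c(0, 1))) return("event must be 0/1")
  }
  mut <- metadata(object)$mutations
  if (!is.null(mut)) {
    need <- c("sample_id", "gene_id", "variant_classification")
    if (!all(need %in% colnames(mut)))
      return("mutation table must have sample_id, gene_id, variant_classification")
    if (!all(mut$sample_id %in% colnames(m)))
      return("mutation table contains samples outside the cohort universe")
  }
  cnv <- metadata(object)$cnv
  if (!is.null(cnv)) {
    if (!all(cnv %in% -2:2)) return("CNV codes must lie in {-2,-1,0,1,2}")
    if (!all(colnames(cnv) %in% colnames(m)))
      return("CNV matrix contains samples outside the cohort universe")
  }
  TRUE
})

setMethod("show", "TMECohort", function(object) {
  m <- assay(object, "exprs")
  cat("TMECohort:", nrow(m), "genes x", ncol(m), "samples",
      sprintf("(scale: %s)\n", metadata(object)$scale))
  tab <- table(colData(object)$subtype)
  cat("  subtypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cov <- metadata(object)$coverage
  if (!is.null(cov))
    cat("  layer coverage:",
        paste(sprintf("%s=%d", names(cov), unlist(cov)), collapse = ", "), "\n")
})

#' Cell-infiltration abundance matrix
#'
#' Cells-by-samples infiltration scores \eqn{r_j} as produced by
#' [cellAbundance()] or loaded from an external estimator (e.g. xCell output)
#' via [readCellAbundance()]. Each cell carries a lineage tag
#' (\code{"immune"}, \code{"stromal"} or \code{"other"}).
#'
#' @slot abundance numeric matrix, cells as rows, samples as columns.
#' @slot lineage named character vector of lineage tags, one per cell.
#' @export
setClass("CellAbundance",
  slots = c(abundance = "matrix", lineage = "character"))

setValidity("CellAbundance", function(object) {
  a <- object@abundance
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("abundance matrix must have cell and sample names")
  if (anyDuplicated(rownames(a))) return("duplicate cell names")
  if (anyDuplicated(colnames(a))) return("duplicate sample ids")
  if (!all(is.finite(a))) return("abundance values must be finite")
  lin <- object@lineage
  if (length(lin) != nrow(a) || !identical(names(lin), rownames(a)))
    return("lineage must be named after the cells, in row order")
  if (!all(lin %in% c("immune", "stromal", "other")))
    return("lineage tags must be immune/stromal/other")
  TRUE
})

#' Construct a CellAbundance object
#'
#' @param abundance numeric matrix, cells x samples, with dimnames.
#' @param lineage optional named character vector of tags in
#'   \code{c("immune","stromal","other")}; defaults to \code{"other"}.
#' @return A [CellAbundance-class] object.
#' @export
CellAbundance <- function(abundance, lineage = NULL) {
  if (is.null(lineage)) {
    lineage <- stats::setNames(rep("other", nrow(abundance)), rownames(abundance))
  } else {
    lineage <- lineage[rownames(abundance)]
    names(lineage) <- rownames(abundance)
    lineage[is.na(lineage)] <- "other"
  }
  new("CellAbundance", abundance = abundance, lineage = lineage)
}

#' @describeIn CellAbundance-class dimensions (cells, samples)
#' @param x a \code{CellAbundance}
#' @export
setMethod("dim", "CellAbundance", function(x) dim(x@abundance))

setMethod("show", "CellAbundance", function(object) {
  cat("CellAbundance:", nrow(object@abundance), "cells x",
      ncol(object@abundance), "samples\n")
  cat("  lineage:", paste(sprintf("%s=%d", names(table(object@lineage)),
                                  table(object@lineage)), collapse = ", "), "\n")
})
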