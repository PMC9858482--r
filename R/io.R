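# Readers, writers and cohort assembly. TSV dialect throughout: tab-separated,
# genes as rows, first column = row ids (the common expression-matrix layout).

.readTsvMatrix <- function(path, what = "expression") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("'", path, "': expected id column plus data columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(what, " file '", path, "' has duplicated row id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  sm <- colnames(df)[-1L]
  if (anyDuplicated(sm)) {
    stop(what, " file '", path, "' has duplicated column id(s): ",
         paste(unique(sm[duplicated(sm)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L,
                                              as.numeric))) &
                   !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(what, " file '", path, "': non-numeric value at row '",
           ids[bad[1L, 1L]], "', column '", sm[bad[1L, 2L]], "'")
    }
    m <- apply(df[, -1L, drop = FALSE], 2L, as.numeric)
  }
  dimnames(m) <- list(ids, sm)
  m
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects tab-separated text with gene ids in the first column and sample ids
#' in the header. Duplicated gene or sample ids and non-numeric cells are hard
#' errors; missing values are rejected unless \code{imputeMissing = TRUE}, in
#' which case each gene's missing entries are replaced by that gene's median
#' (logged via a message).
#'
#' @param path file path.
#' @param scale declared scale of the values, \code{"log2p1"} or \code{"fpkm"}.
#'   The declaration travels with the matrix so that scale-sensitive scores
#'   (e.g. [mhcScore()]) can enforce their expected input.
#' @param samplesAsRows logical; set \code{TRUE} if the file stores samples as
#'   rows (the matrix is transposed on read).
#' @param imputeMissing logical; impute gene-wise medians instead of erroring
#'   on \code{NA}.
#' @return \linkS4class{SummarizedExperiment} with assay \code{"exprs"} and
#'   \code{metadata()$scale} set.
#' @seealso [writeExpression()], [log2p1Transform()], [alignCohort()]
#' @export
readExpression <- function(path, scale = c("log2p1", "fpkm"),
                           samplesAsRows = FALSE, imputeMissing = FALSE) {
  scale <- match.arg(scale)
  m <- .readTsvMatrix(path, "expression")
  if (samplesAsRows) m <- t(m)
  if (anyNA(m)) {
    if (!imputeMissing) {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", rownames(m)[bad[1L]], "', sample '",
           colnames(m)[bad[2L]], "' (set imputeMissing = TRUE to impute)")
    }
    nImp <- sum(is.na(m))
    for (i in which(rowSums(is.na(m)) > 0L)) {
      med <- stats::median(m[i, ], na.rm = TRUE)
      if (is.na(med)) stop("gene '", rownames(m)[i], "' is entirely missing")
      m[i, is.na(m[i, ])] <- med
    }
    message("imputed ", nImp, " missing value(s) with gene-wise medians")
  }
  if (!all(is.finite(m))) stop("expression values must be finite")
  if (scale == "log2p1" && any(m < 0))
    stop("negative values are inconsistent with declared scale 'log2p1'")
  SummarizedExperiment(assays = list(exprs = m),
                       metadata = list(scale = scale))
}

#' Write an expression matrix to TSV
#'
#' @param x matrix, \linkS4class{SummarizedExperiment} or
#'   \linkS4class{TMECohort}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
  m <- if (is.matrix(x)) x else exprMatrix(x)
  .writeTsvMatrix(m, path, idColumn = "gene_id")
}

.writeTsvMatrix <- function(m, path, idColumn = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname log2p1Transform
#' @export
setMethod("log2p1Transform", "matrix", function(x) {
  if (any(x < 0)) stop("log2p1Transform requires non-negative values")
  log2(x + 1)
})

#' @rdname log2p1Transform
#' @export
setMethod("log2p1Transform", "SummarizedExperiment", function(x) {
  sc <- metadata(x)$scale
  if (!identical(sc, "fpkm"))
    stop("declared scale is '", sc, "'; log2p1Transform expects 'fpkm'")
  m <- assay(x, "exprs")
  if (any(m < 0)) stop("log2p1Transform requires non-negative values")
  assay(x, "exprs") <- log2(m + 1)
  metadata(x)$scale <- "log2p1"
  x
})

#' Read / write gene sets in GMT format
#'
#' The Broad GMT dialect: one set per line,
#' \code{name <TAB> description <TAB> gene1 <TAB> gene2 ...}. Reading is
#' order-preserving and writing round-trips exactly.
#'
#' @param path file path.
#' @return \code{readGmt}: a \linkS4class{GeneSetList}.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("S\tdemo\tA\tB", f)
#' as.list(readGmt(f))
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("'", path, "' contains no gene sets")
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("'", path, "' line ", i, ": expected at least 3 tab-separated ",
           "fields (name, description, genes)")
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]
  }
  names(sets) <- nm
  GeneSetList(sets, desc)
}

#' @rdname readGmt
#' @param geneSets a \linkS4class{GeneSetList} (or named list) to write.
#' @return \code{writeGmt}: \code{path}, invisibly.
#' @export
writeGmt <- function(geneSets, path) {
  geneSets <- GeneSetList(geneSets)
  lines <- vapply(seq_along(geneSets), function(i) {
    paste(c(names(geneSets)[i], geneSets@description[i], geneSets[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample -> subtype annotation table
#'
#' Two-column TSV (\code{sample_id}, \code{subtype}) with a header line.
#'
#' @param path file path.
#' @return named factor of subtype labels.
#' @export
readSubtypeAnnotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected columns: sample_id, subtype")
  if (anyDuplicated(df[[1L]]))
    stop("duplicated sample id(s) in subtype annotation")
  stats::setNames(factor(df[[2L]]), as.character(df[[1L]]))
}

#' Read overall-survival records
#'
#' TSV with columns \code{sample_id}, \code{time}, \code{event}
#' (1 = death observed, 0 = censored). Times must be positive.
#'
#' @param path file path.
#' @return data.frame with columns \code{sample_id}, \code{time}, \code{event}.
#' @export
readSurvivalRecords <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample id(s)")
  df
}

#' Read a MAF-like somatic mutation table
#'
#' Requires at minimum the columns \code{Tumor_Sample_Barcode},
#' \code{Hugo_Symbol} and \code{Variant_Classification} (canonical
#' \code{sample_id}/\code{gene_id}/\code{variant_classification} names are
#' also accepted). A (sample, gene) pair may repeat when a sample carries
#' several variants of the same gene.
#'
#' @param path file path.
#' @return data.frame with canonical columns \code{sample_id}, \code{gene_id},
#'   \code{variant_classification}.
#' @export
readMutationTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  maf <- c(Tumor_Sample_Barcode = "sample_id", Hugo_Symbol = "gene_id",
           Variant_Classification = "variant_classification")
  for (nm in names(maf)) {
    if (nm %in% colnames(df)) colnames(df)[colnames(df) == nm] <- maf[[nm]]
  }
  need <- unname(maf)
  if (!all(need %in% colnames(df)))
    stop("mutation table must provide columns Tumor_Sample_Barcode, ",
         "Hugo_Symbol, Variant_Classification")
  df[, need]
}

#' Read a gene x sample CNV code matrix
#'
#' GISTIC-style integer codes \code{-2} (deep deletion) to \code{2}
#' (high-level amplification).
#'
#' @param path file path.
#' @return integer matrix, genes x samples.
#' @export
readCnvMatrix <- function(path) {
  m <- .readTsvMatrix(path, "CNV")
  if (!all(m %in% -2:2))
    stop("CNV codes must lie in {-2, -1, 0, 1, 2}")
  storage.mode(m) <- "integer"
  m
}

#' Assemble a multi-layer cohort on a common sample universe
#'
#' The sample universe is the intersection of expression samples and annotated
#' samples (in expression column order). Survival, mutation and CNV layers are
#' restricted to the universe; their per-layer coverage counts are recorded in
#' \code{metadata()$coverage}. Aligning an already aligned cohort changes
#' nothing (idempotence).
#'
#' @param expr \linkS4class{SummarizedExperiment} from [readExpression()], or a
#'   numeric matrix (then \code{scale} must be given).
#' @param subtypes named factor/character of subtype labels per sample.
#' @param survival optional data.frame (\code{sample_id}, \code{time},
#'   \code{event}).
#' @param mutations optional mutation table (see [readMutationTable()]).
#' @param cnv optional CNV code matrix.
#' @param scale declared expression scale when \code{expr} is a bare matrix.
#' @return A \linkS4class{TMECohort}.
#' @examples
#' m <- matrix(rnorm(20, 5), 4, 5,
#'   dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' st <- setNames(factor(c("A", "A", "B", "B")), paste0("s", 1:4))
#' co <- alignCohort(abs(m), subtypes = st, scale = "log2p1")
#' layerCoverage(co)
#' @export
alignCohort <- function(expr, subtypes, survival = NULL, mutations = NULL,
                        cnv = NULL, scale = NULL) {
  if (is.matrix(expr)) {
    if (is.null(scale)) stop("scale must be declared for a bare matrix")
    expr <- SummarizedExperiment(assays = list(exprs = expr),
                                 metadata = list(scale = match.arg(scale,
                                                                   .EXPR_SCALES)))
  }
  m <- assay(expr, "exprs")
  if (is(expr, "TMECohort") && missing(subtypes))
    subtypes <- subtypes(expr)
  st <- stats::setNames(factor(as.character(subtypes)), names(subtypes))
  universe <- intersect(colnames(m), names(st))
  if (length(universe) == 0L)
    stop("no samples shared between expression matrix and subtype annotation")
  m <- m[, universe, drop = FALSE]
  st <- droplevels(st[universe])
  cd <- DataFrame(subtype = st, row.names = universe)
  coverage <- list(expression = length(universe), subtype = length(universe))
  if (!is.null(survival)) {
    keep <- survival$sample_id %in% universe
    sv <- survival[keep, , drop = FALSE]
    coverage$survival <- nrow(sv)
    cd$os_time <- sv$time[match(universe, sv$sample_id)]
    cd$os_event <- sv$event[match(universe, sv$sample_id)]
  }
  md <- list(scale = metadata(expr)$scale)
  if (!is.null(mutations)) {
    keep <- mutations$sample_id %in% universe
    mut <- mutations[keep, , drop = FALSE]
    coverage$mutations <- length(unique(mut$sample_id))
    md$mutations <- mut
  }
  if (!is.null(cnv)) {
    shared <- intersect(colnames(cnv), universe)
    coverage$cnv <- length(shared)
    md$cnv <- cnv[, shared, drop = FALSE]
  }
  md$coverage <- coverage
  new("TMECohort",
      SummarizedExperiment(assays = list(exprs = m), colData = cd,
                           metadata = md))
}

## ---- accessors -------------------------------------------------------------

#' @rdname exprMatrix
#' @export
setMethod("exprMatrix", "SummarizedExperiment",
          function(x) assay(x, "exprs"))

#' @rdname exprScale
#' @export
setMethod("exprScale", "SummarizedExperiment",
          function(x) metadata(x)$scale)

#' @rdname subtypes
#' @export
setMethod("subtypes", "TMECohort", function(x)
  stats::setNames(colData(x)$subtype, colnames(x)))

#' @rdname survivalRecords
#' @export
setMethod("survivalRecords", "TMECohort", function(x) {
  cd <- colData(x)
  if (!"os_time" %in% colnames(cd)) return(NULL)
  keep <- !is.na(cd$os_time) & !is.na(cd$os_event)
  data.frame(sample_id = colnames(x)[keep], time = cd$os_time[keep],
             event = cd$os_event[keep], stringsAsFactors = FALSE)
})

#' @rdname mutationTable
#' @export
setMethod("mutationTable", "TMECohort", function(x) metadata(x)$mutations)

#' @rdname cnvMatrix
#' @export
setMethod("cnvMatrix", "TMECohort", function(x) metadata(x)$cnv)

#' @rdname layerCoverage
#' @export
setMethod("layerCoverage", "TMECohort", function(x) metadata(x)$coverage)

#' @rdname abundanceMatrix
#' @export
setMethod("abundanceMatrix", "CellAbundance", function(x) x@abundance)

#' @rdname cellLineage
#' @export
setMethod("cellLineage", "CellAbundance", function(x) x@lineage)

# Coerce any accepted expression input to a plain matrix (+ scale if known).
.exprInput <- function(x) {
  if (is.matrix(x)) return(list(values = x, scale = NULL))
  if (is(x, "SummarizedExperiment"))
    return(list(values = assay(x, "exprs"), scale = metadata(x)$scale))
  stop("expected a matrix, SummarizedExperiment or TMECohort")
}

#' Write a YAML run manifest
#'
#' Records inputs, parameters and seeds of an analysis run alongside its
#' outputs, for reproducibility.
#'
#' @param path output path (YAML).
#' @param ... named fields to record.
#' @return \code{path}, invisibly.
#' @export
writeRunManifest <- function(path, ...) {
  fields <- list(...)
  fields$r_version <- as.character(getRversion())
  fields$package_version <- as.character(utils::packageVersion("SubtypeTME"))
  fields$date <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  yaml::write_yaml(fields, path)
  invisible(path)
}
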