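# Synthetic cohort generator. Emulates the statistical structure every
# pipeline stage assumes — K unequal subtype groups, marker-gene blocks whose
# coexpression induces cell-abundance gradients concentrated in chosen
# subtypes, subtype-dependent mutation/CNV frequencies, and survival times
# whose hazard depends on the planted cell abundances — with full ground
# truth for recovery and calibration testing. Default subtype sizes are a
# 1/10-scale miniature of a large breast-cancer cohort's PAM50 composition.

.DEFAULT_SIZES <- c(Basal = 20L, Her2 = 22L, LumA = 68L, LumB = 46L,
                    Normal = 14L)

#' Configuration for a synthetic cohort
#'
#' @param nPerSubtype named integer vector of subtype sizes (default a
#'   1/10-scale five-subtype breast-cancer composition: Basal 20, Her2 22,
#'   LumA 68, LumB 46, Normal 14).
#' @param nGenes total number of genes (marker blocks are carved out of the
#'   front; default 2000).
#' @param cells data.frame with columns \code{name}, \code{n_markers},
#'   \code{lineage}; default 10 cells x 30 disjoint markers, 5 immune +
#'   5 stromal.
#' @param plantedSpecific data.frame with columns \code{cell}, \code{subtype},
#'   \code{delta} (mean shift of the cell's marker genes in that subtype's
#'   samples, in baseline-SD units, delta >= 0). \code{NULL} plants nothing.
#' @param mutationSpec numeric matrix genes x subtypes of per-sample mutation
#'   probabilities (rownames = gene ids, colnames = subtype names);
#'   \code{NULL} for no mutation layer.
#' @param cnvSpec list with matrices \code{amp} and \code{del} (genes x
#'   subtypes, per-sample event probabilities); \code{NULL} for no CNV layer.
#' @param survivalSpec list with \code{baselineHazard} (> 0),
#'   \code{coefficients} (named per cell log-hazard per SD of true abundance;
#'   default all 0) and \code{censoringRate} in [0, 1).
#' @param seed RNG seed; a fixed seed reproduces the cohort exactly.
#' @return validated config list (class \code{"tme_cohort_config"}).
#' @seealso [generateCohort()], [nullCohort()]
#' @export
cohortConfig <- function(nPerSubtype = .DEFAULT_SIZES, nGenes = 2000,
                         cells = NULL, plantedSpecific = NULL,
                         mutationSpec = NULL, cnvSpec = NULL,
                         survivalSpec = list(baselineHazard = 0.05,
                                             coefficients = NULL,
                                             censoringRate = 0.3),
                         seed = 1L) {
  if (is.null(names(nPerSubtype)))
    names(nPerSubtype) <- paste0("subtype_", seq_along(nPerSubtype))
  if (length(nPerSubtype) < 2L || any(nPerSubtype < 2L))
    stop("need >= 2 subtypes with >= 2 samples each")
  if (is.null(cells)) {
    cells <- data.frame(name = paste0("cell_", seq_len(10L)),
                        n_markers = 30L,
                        lineage = rep(c("immune", "stromal"), each = 5L),
                        stringsAsFactors = FALSE)
  }
  if (sum(cells$n_markers) > nGenes)
    stop("marker demand (", sum(cells$n_markers), ") exceeds nGenes (",
         nGenes, ")")
  if (!is.null(plantedSpecific)) {
    stopifnot(all(c("cell", "subtype", "delta") %in% colnames(plantedSpecific)))
    if (any(plantedSpecific$delta < 0)) stop("delta must be >= 0")
    if (!all(plantedSpecific$cell %in% cells$name))
      stop("planted cell(s) not in the cell list")
    if (!all(plantedSpecific$subtype %in% names(nPerSubtype)))
      stop("planted subtype(s) not in nPerSubtype")
  }
  if (!is.null(mutationSpec)) {
    if (!all(mutationSpec >= 0 & mutationSpec <= 1))
      stop("mutation probabilities must lie in [0, 1]")
    if (!identical(sort(colnames(mutationSpec)), sort(names(nPerSubtype))))
      stop("mutationSpec columns must match the subtype names")
  }
  if (!is.null(cnvSpec)) {
    stopifnot(all(c("amp", "del") %in% names(cnvSpec)))
    if (!all(cnvSpec$amp >= 0 & cnvSpec$amp <= 1) ||
        !all(cnvSpec$del >= 0 & cnvSpec$del <= 1) ||
        any(cnvSpec$amp + cnvSpec$del > 1))
      stop("CNV probabilities must lie in [0, 1] with amp + del <= 1")
  }
  if (is.null(survivalSpec$coefficients))
    survivalSpec$coefficients <- stats::setNames(numeric(nrow(cells)),
                                                 cells$name)
  if (is.null(survivalSpec$baselineHazard)) survivalSpec$baselineHazard <- 0.05
  if (is.null(survivalSpec$censoringRate)) survivalSpec$censoringRate <- 0.3
  if (survivalSpec$baselineHazard <= 0) stop("baselineHazard must be > 0")
  if (survivalSpec$censoringRate < 0 || survivalSpec$censoringRate >= 1)
    stop("censoringRate must lie in [0, 1)")
  structure(list(nPerSubtype = nPerSubtype, nGenes = as.integer(nGenes),
                 cells = cells, plantedSpecific = plantedSpecific,
                 mutationSpec = mutationSpec, cnvSpec = cnvSpec,
                 survivalSpec = survivalSpec, seed = as.integer(seed)),
            class = "tme_cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Expression is baseline Gaussian noise on the log scale (mean 0, SD 1),
#' shifted to be non-negative (declared scale \code{log2p1}; all downstream
#' scoring is rank-based, so the exact noise family is non-critical). For
#' every planted (cell, subtype, delta) triple, the cell's marker genes gain
#' a +delta mean shift in that subtype's samples. Mutations are per
#' gene x subtype Bernoulli draws; CNV codes are drawn as amplification
#' (+1/+2) or deletion (-1/-2) events per the spec probabilities. Survival
#' times are exponential with log-hazard equal to the configured coefficients
#' times the standardized true cell abundances (per-sample mean of marker
#' genes), with administrative censoring at the horizon hitting the target
#' censoring rate.
#'
#' @param config a [cohortConfig()].
#' @return list with elements \code{cohort} (\linkS4class{TMECohort}),
#'   \code{markers} (\linkS4class{GeneSetList}), \code{lineage} (named tags),
#'   and \code{truth} (planted pairs, planted mutation/CNV genes, true
#'   standardized abundance matrix, hazard coefficients, censoring horizon).
#' @examples
#' syn <- generateCohort(cohortConfig(
#'   nPerSubtype = c(A = 10, B = 12), nGenes = 300,
#'   cells = data.frame(name = c("c1", "c2"), n_markers = 10,
#'                      lineage = c("immune", "stromal")),
#'   seed = 7))
#' syn$cohort
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "tme_cohort_config"))
  set.seed(config$seed)
  sizes <- config$nPerSubtype
  n <- sum(sizes)
  sampleIds <- sprintf("S%04d", seq_len(n))
  st <- stats::setNames(factor(rep(names(sizes), times = sizes),
                               levels = names(sizes)), sampleIds)
  G <- config$nGenes
  geneIds <- sprintf("g%05d", seq_len(G))

  # disjoint marker blocks at the front of the gene list
  offsets <- cumsum(c(0L, config$cells$n_markers))
  markerSets <- lapply(seq_len(nrow(config$cells)), function(i)
    geneIds[(offsets[i] + 1L):offsets[i + 1L]])
  names(markerSets) <- config$cells$name
  markers <- GeneSetList(markerSets,
                         description = paste0("synthetic markers (",
                                              config$cells$lineage, ")"))
  lineage <- stats::setNames(config$cells$lineage, config$cells$name)

  logexpr <- matrix(stats::rnorm(G * n), G, n,
                    dimnames = list(geneIds, sampleIds))
  if (!is.null(config$plantedSpecific)) {
    for (i in seq_len(nrow(config$plantedSpecific))) {
      pl <- config$plantedSpecific[i, ]
      rows <- markerSets[[as.character(pl$cell)]]
      cols <- sampleIds[st == as.character(pl$subtype)]
      logexpr[rows, cols] <- logexpr[rows, cols] + pl$delta
    }
  }
  expr <- logexpr - min(logexpr)   # non-negative, log-scale values

  # true (noise-free-signal) abundance: mean marker expression, standardized
  z <- t(vapply(markerSets, function(g) {
    a <- colMeans(logexpr[g, , drop = FALSE])
    (a - mean(a)) / stats::sd(a)
  }, numeric(n)))

  # survival: exponential hazard on the true standardized abundances
  coef <- config$survivalSpec$coefficients[config$cells$name]
  coef[is.na(coef)] <- 0
  lp <- as.numeric(crossprod(z, coef))
  rate <- config$survivalSpec$baselineHazard * exp(lp)
  rawT <- stats::rexp(n, rate)
  cr <- config$survivalSpec$censoringRate
  horizon <- if (cr > 0) as.numeric(stats::quantile(rawT, 1 - cr)) else Inf
  event <- as.integer(rawT <= horizon)
  time <- pmin(rawT, horizon)
  survivalDf <- data.frame(sample_id = sampleIds, time = time, event = event,
                           stringsAsFactors = FALSE)

  mutations <- NULL
  plantedMutGenes <- character(0)
  if (!is.null(config$mutationSpec)) {
    ms <- config$mutationSpec
    prob <- ms[, as.character(st), drop = FALSE]   # genes x samples
    hits <- which(matrix(stats::runif(length(prob)), nrow(prob)) < prob,
                  arr.ind = TRUE)
    mutations <- data.frame(
      sample_id = sampleIds[hits[, 2L]],
      gene_id = rownames(ms)[hits[, 1L]],
      variant_classification = "Missense_Mutation",
      stringsAsFactors = FALSE)
    spread <- apply(ms, 1L, function(x) max(x) - min(x))
    plantedMutGenes <- rownames(ms)[spread > 0]
  }

  cnv <- NULL
  plantedCnv <- list(amp = character(0), del = character(0))
  if (!is.null(config$cnvSpec)) {
    pa <- config$cnvSpec$amp[, as.character(st), drop = FALSE]
    pd <- config$cnvSpec$del[, as.character(st), drop = FALSE]
    u <- matrix(stats::runif(length(pa)), nrow(pa))
    lvl <- matrix(sample(c(1L, 2L), length(pa), replace = TRUE), nrow(pa))
    cnv <- matrix(0L, nrow(pa), n,
                  dimnames = list(rownames(config$cnvSpec$amp), sampleIds))
    cnv[u < pa] <- lvl[u < pa]
    isDel <- u >= pa & u < pa + pd
    cnv[isDel] <- -lvl[isDel]
    plantedCnv$amp <- rownames(pa)[apply(pa, 1L, function(x)
      max(x) - min(x)) > 0]
    plantedCnv$del <- rownames(pd)[apply(pd, 1L, function(x)
      max(x) - min(x)) > 0]
  }

  se <- SummarizedExperiment(assays = list(exprs = expr),
                             metadata = list(scale = "log2p1"))
  cohort <- alignCohort(se, subtypes = st, survival = survivalDf,
                        mutations = mutations, cnv = cnv)
  list(cohort = cohort, markers = markers, lineage = lineage,
       truth = list(plantedPairs = config$plantedSpecific,
                    plantedMutationGenes = plantedMutGenes,
                    plantedCnvGenes = plantedCnv,
                    abundanceZ = z,
                    hazardCoefficients = coef,
                    censoringHorizon = horizon),
       config = config)
}

#' Null synthetic cohort (no planted structure)
#'
#' Convenience wrapper for calibration suites: a cohort with every effect
#' zeroed — no planted cell/subtype shifts, no mutation/CNV bias, zero hazard
#' coefficients — keeping the five-subtype composition scaled to \code{n}.
#'
#' @param n total number of samples (split across 5 subtypes in the default
#'   proportions).
#' @param nCells number of cells (disjoint marker blocks).
#' @param nMarkers markers per cell.
#' @param nGenes total genes.
#' @param seed RNG seed.
#' @return as [generateCohort()].
#' @export
nullCohort <- function(n = 150, nCells = 10, nMarkers = 30, nGenes = 1000,
                       seed = 1L) {
  props <- .DEFAULT_SIZES / sum(.DEFAULT_SIZES)
  sizes <- pmax(2L, round(props * n))
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] + (n - sum(sizes))
  cells <- data.frame(name = paste0("cell_", seq_len(nCells)),
                      n_markers = nMarkers,
                      lineage = rep_len(c("immune", "stromal"), nCells),
                      stringsAsFactors = FALSE)
  generateCohort(cohortConfig(nPerSubtype = sizes, nGenes = nGenes,
                              cells = cells, seed = seed))
}
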