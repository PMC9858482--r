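# Prognostic screening of subtype-specific cells: univariate Cox per
# (subtype, cell), maximally selected abundance cutpoint, Kaplan-Meier with
# log-rank. Cox ties use the Efron approximation (survival::coxph default).

#' Univariate Cox screening of cell abundance within subtypes
#'
#' For each requested (subtype, cell) pair, fits a univariate Cox
#' proportional-hazards model of overall survival on the continuous
#' infiltration abundance within that subtype's samples.
#'
#' @param abundance \linkS4class{CellAbundance} or cells x samples matrix.
#' @param survival data.frame with \code{sample_id}, \code{time},
#'   \code{event}.
#' @param subtypeLabels named factor of subtype labels, or \code{NULL} to
#'   screen the whole cohort as a single stratum (\code{"all"}).
#' @param cells which (cell, subtype) pairs to screen: a data.frame with
#'   columns \code{cell} and \code{subtype} (e.g. from
#'   [callSubtypeSpecific()]), a character vector of cells (screened in every
#'   subtype), or \code{NULL} for all cells in all subtypes.
#' @param pThreshold significance flag threshold (default 0.01).
#' @param minSamples minimum samples with survival per fit (default 10);
#'   pairs below it, without events, or with constant abundance are skipped
#'   with a warning.
#' @return data.frame ordered by p: \code{subtype}, \code{cell}, \code{n},
#'   \code{n_event}, \code{log_hr}, \code{hr}, \code{ci_low}, \code{ci_high},
#'   \code{cox_p}, \code{significant}.
#' @export
coxScreen <- function(abundance, survival, subtypeLabels = NULL, cells = NULL,
                      pThreshold = 0.01, minSamples = 10L) {
  if (is(abundance, "CellAbundance")) abundance <- abundanceMatrix(abundance)
  if (is.null(subtypeLabels))
    subtypeLabels <- stats::setNames(
      factor(rep("all", ncol(abundance))), colnames(abundance))
  st <- droplevels(factor(subtypeLabels))
  names(st) <- names(subtypeLabels)
  if (is.null(cells)) {
    cells <- expand.grid(cell = rownames(abundance), subtype = levels(st),
                         stringsAsFactors = FALSE)
  } else if (is.character(cells)) {
    cells <- expand.grid(cell = cells, subtype = levels(st),
                         stringsAsFactors = FALSE)
  }
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(cells))) {
    cl <- cells$cell[i]; sb <- cells$subtype[i]
    if (!cl %in% rownames(abundance)) {
      skipped <- c(skipped, sprintf("%s/%s (unknown cell)", sb, cl)); next
    }
    ids <- intersect(names(st)[st == sb],
                     intersect(colnames(abundance), survival$sample_id))
    sv <- survival[match(ids, survival$sample_id), , drop = FALSE]
    ab <- abundance[cl, ids]
    if (length(ids) < minSamples) {
      skipped <- c(skipped, sprintf("%s/%s (n=%d)", sb, cl, length(ids))); next
    }
    if (sum(sv$event) == 0L) {
      skipped <- c(skipped, sprintf("%s/%s (no events)", sb, cl)); next
    }
    if (stats::sd(ab) == 0) {
      skipped <- c(skipped, sprintf("%s/%s (constant abundance)", sb, cl)); next
    }
    fit <- survival::coxph(survival::Surv(sv$time, sv$event) ~ ab)
    sm <- summary(fit)
    rows[[length(rows) + 1L]] <- data.frame(
      subtype = sb, cell = cl, n = length(ids),
      n_event = sum(sv$event),
      log_hr = unname(stats::coef(fit)[1L]),
      hr = unname(sm$conf.int[1L, "exp(coef)"]),
      ci_low = unname(sm$conf.int[1L, "lower .95"]),
      ci_high = unname(sm$conf.int[1L, "upper .95"]),
      cox_p = unname(sm$coefficients[1L, "Pr(>|z|)"]),
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L)
    warning("skipped ", length(skipped), " pair(s): ",
            paste(utils::head(skipped, 5L), collapse = "; "),
            if (length(skipped) > 5L) "; ..." else "")
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$cox_p), , drop = FALSE]
  out$significant <- out$cox_p < pThreshold
  rownames(out) <- NULL
  out
}

# Standardized log-rank statistic of the split values > cutoff vs values <=
# cutoff (z signed so that positive means MORE deaths than expected in the
# high group).
.logrankZ <- function(high, time, event) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ high)
  z2 <- sd$chisq
  dObs <- sd$obs[2L] - sd$exp[2L]   # high group (TRUE sorts second)
  list(z = sign(dObs) * sqrt(z2), chisq = z2)
}

#' Maximally selected survival cutpoint
#'
#' Scans the observed abundance values whose induced high/low split keeps at
#' least \code{minprop} of the samples on each side, and picks the cutoff
#' maximizing the absolute standardized log-rank statistic (earliest value on
#' ties). The reported log-rank p-value is the naive p of the chosen split;
#' it is selection-biased (anti-conservative) and flagged as such. An
#' optional permutation adjustment recomputes the maximal statistic under
#' label permutation.
#'
#' Because candidates are induced splits of the empirical values, the chosen
#' grouping is invariant to strictly monotone transforms of the values.
#'
#' @param values named numeric vector (e.g. one cell's abundance).
#' @param survival data.frame with \code{sample_id}, \code{time},
#'   \code{event}.
#' @param minprop minimum proportion of samples on each side (default 0.1).
#' @param nPermAdjust permutations for the adjusted p (0 = skip).
#' @param seed RNG seed for the permutation adjustment.
#' @return list: \code{cutoff}, \code{n_high}, \code{n_low}, \code{statistic}
#'   (signed z of the high group), \code{logrank_p} (naive),
#'   \code{selection_biased = TRUE}, \code{direction} (which group has better
#'   survival), \code{adjusted_p} (\code{NA} unless requested).
#' @export
optimalCutoff <- function(values, survival, minprop = 0.1, nPermAdjust = 0,
                          seed = NULL) {
  ids <- intersect(names(values), survival$sample_id)
  if (length(ids) < 4L) stop("too few samples with survival data")
  v <- values[ids]
  sv <- survival[match(ids, survival$sample_id), , drop = FALSE]
  n <- length(v)

  scan <- function(vv) {
    cand <- sort(unique(vv))
    cand <- cand[-length(cand)]   # top value leaves an empty high group
    nLow <- vapply(cand, function(cc) sum(vv <= cc), integer(1L))
    keep <- nLow >= minprop * n & (n - nLow) >= minprop * n
    cand[keep]
  }
  cand <- scan(v)
  if (length(cand) == 0L)
    stop("no candidate cutoff satisfies minprop = ", minprop)
  zs <- vapply(cand, function(cc)
    .logrankZ(v > cc, sv$time, sv$event)$z, numeric(1L))
  best <- which.max(abs(zs))
  cutoff <- cand[best]
  high <- v > cutoff
  chisq <- zs[best]^2
  adjP <- NA_real_
  if (nPermAdjust > 0L) {
    if (!is.null(seed)) set.seed(seed)
    obsMax <- abs(zs[best])
    nullMax <- vapply(seq_len(nPermAdjust), function(b) {
      vp <- sample(v)
      cp <- scan(vp)
      max(abs(vapply(cp, function(cc)
        .logrankZ(vp > cc, sv$time, sv$event)$z, numeric(1L))))
    }, numeric(1L))
    adjP <- mean(nullMax >= obsMax)
  }
  list(cutoff = cutoff, n_high = sum(high), n_low = sum(!high),
       statistic = zs[best],
       logrank_p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       selection_biased = TRUE,
       direction = if (zs[best] > 0) "low" else "high",  # better survival
       adjusted_p = adjP)
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' @param groups named factor with exactly 2 levels (e.g. high/low
#'   infiltration), named by sample.
#' @param survival data.frame with \code{sample_id}, \code{time},
#'   \code{event}.
#' @return list: \code{fit} (a \code{survfit} object), \code{logrank_p},
#'   \code{table} (per-group n and events).
#' @export
kmLogrank <- function(groups, survival) {
  groups <- droplevels(factor(groups, exclude = NULL))
  if (nlevels(groups) != 2L) stop("exactly 2 groups required")
  if (any(table(groups) == 0L)) stop("each group needs at least 1 subject")
  ids <- intersect(names(groups), survival$sample_id)
  g <- groups[ids]
  sv <- survival[match(ids, survival$sample_id), , drop = FALSE]
  fit <- survival::survfit(survival::Surv(sv$time, sv$event) ~ g)
  sd <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ g)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(fit = fit, logrank_p = p,
       table = data.frame(group = levels(g),
                          n = as.integer(table(g)),
                          events = as.integer(tapply(sv$event, g, sum))))
}

#' Plot Kaplan-Meier curves with a log-rank p annotation
#'
#' @param km result of [kmLogrank()].
#' @param main plot title.
#' @param col two line colors.
#' @return invisibly, \code{km}.
#' @export
plotKM <- function(km, main = "", col = c("#D55E00", "#0072B2")) {
  graphics::plot(km$fit, col = col, lwd = 2, xlab = "Time",
                 ylab = "Survival probability", main = main)
  graphics::legend("topright", legend = km$table$group, col = col, lwd = 2,
                   bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", km$logrank_p), side = 3,
                  adj = 0, cex = 0.9)
  invisible(km)
}
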