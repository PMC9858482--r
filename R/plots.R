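# Basic figure helpers: effect-size heatmap with significance dots and the
# KM plot (see plotKM() in survival.R).

#' Heatmap of a one-vs-rest effect-size profile
#'
#' Features x subtypes heatmap of Cohen's d values, with a dot marking cells
#' significant at the profile's FDR flag. Requires the \pkg{pheatmap}
#' package.
#'
#' @param profile result of [oneVsRestProfile()].
#' @param main plot title.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return invisibly, the d-value matrix that was drawn.
#' @export
plotEffectSizeHeatmap <- function(profile, main = "one-vs-rest effect size",
                                  ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotEffectSizeHeatmap requires the 'pheatmap' package")
  feats <- unique(profile$feature)
  subs <- unique(profile$subtype)
  d <- matrix(NA_real_, length(feats), length(subs),
              dimnames = list(feats, subs))
  sig <- matrix("", length(feats), length(subs),
                dimnames = list(feats, subs))
  d[cbind(profile$feature, profile$subtype)] <- profile$d
  sig[cbind(profile$feature, profile$subtype)] <-
    ifelse(profile$significant, "*", "")
  drawn <- d
  drawn[is.na(drawn)] <- 0   # sentinel cells drawn neutral, never marked
  pheatmap::pheatmap(drawn, cluster_rows = FALSE, cluster_cols = FALSE,
                     display_numbers = sig, main = main, ...)
  invisible(d)
}
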