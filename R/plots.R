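# ggplot2 visualizations.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline geom_step geom_abline geom_ribbon labs scale_x_log10
#'   scale_y_log10 theme_bw annotation_logticks
#' @export
ggplot2::autoplot

#' Plot a fitted dose-response curve
#'
#' Group means, the fitted mean curve, and the benchmark-response band around
#' the control mean; the BMD (and bounds, when supplied) are drawn as vertical
#' lines.
#'
#' @param object A `drc_fit`.
#' @param bmd,bmdl,bmdu Optional benchmark dose and bounds to annotate.
#' @param bmr_factor Benchmark response factor used for the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drc_fit <- function(object, bmd = NULL, bmdl = NULL, bmdu = NULL,
                             bmr_factor = .default_bmr_factor, ...) {
  gs <- object$group_stats
  pts <- tibble(dose = gs$doses, mean = gs$means)
  grid <- tibble(dose = seq(0, max(gs$doses), length.out = 200))
  grid$mu <- predict(object, grid$dose)
  mu0 <- predict(object, 0)
  bmr <- bmr_factor * object$sigma
  p <- ggplot(pts, aes(x = .data$dose, y = .data$mean)) +
    geom_line(data = grid, aes(y = .data$mu), color = "steelblue") +
    geom_point(size = 2) +
    geom_hline(yintercept = c(mu0 - bmr, mu0 + bmr), linetype = "dotted") +
    labs(x = "dose", y = "mean response (log2)",
         title = paste0(object$model, " fit")) +
    theme_bw()
  if (!is.null(bmd) && is.finite(bmd)) {
    p <- p + geom_vline(xintercept = bmd, color = "firebrick")
  }
  for (b in c(bmdl, bmdu)) {
    if (!is.null(b) && is.finite(b)) {
      p <- p + geom_vline(xintercept = b, color = "firebrick",
                          linetype = "dashed")
    }
  }
  p
}

#' Accumulation plot of gene-set medians
#'
#' Cumulative count of enriched gene sets ordered by their median BMD and by
#' their median BMDL — the standard visualization of gene-set potency.
#'
#' @param enrichments Tibble from [enrich_gene_sets()].
#' @param enriched_only Restrict to enriched sets (default TRUE).
#' @return A ggplot object.
#' @export
plot_accumulation <- function(enrichments, enriched_only = TRUE) {
  acc <- accumulation_table(enrichments, enriched_only = enriched_only)
  if (nrow(acc) == 0) abort("nothing to plot: no sets with a median BMD")
  long <- dplyr::bind_rows(
    tibble(value = sort(acc$median_bmd), rank = seq_len(nrow(acc)),
           statistic = "median BMD"),
    tibble(value = sort(acc$median_bmdl), rank = seq_len(nrow(acc)),
           statistic = "median BMDL")
  )
  ggplot(long, aes(x = .data$value, y = .data$rank,
                   color = .data$statistic)) +
    geom_step() +
    scale_x_log10() +
    labs(x = "dose", y = "cumulative gene sets", color = NULL) +
    theme_bw()
}

#' Scatter plot of transcriptomic vs. apical PODs
#'
#' log10-log10 scatter with the identity line and the 10-fold agreement band.
#'
#' @param comparisons Tibble of [fold_difference()] rows.
#' @return A ggplot object.
#' @export
plot_pod_concordance <- function(comparisons) {
  stopifnot(nrow(comparisons) >= 1)
  ggplot(comparisons, aes(x = .data$apod, y = .data$tpod)) +
    geom_abline(slope = 1, intercept = 0) +
    geom_abline(slope = 1, intercept = c(-1, 1), linetype = "dashed") +
    geom_point(aes(color = .data$chemical), size = 2) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "apical POD", y = "transcriptomic POD") +
    theme_bw()
}
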