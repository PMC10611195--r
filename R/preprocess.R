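# Count filtering, CPM/log2 normalization, batch adjustment and the
# ANOVA/fold-change prefilter.

#' Remove low-count genes
#'
#' Drops gene features whose median count across all samples is at or below
#' `min_median` (default 8), the noise-reduction rule applied before
#' normalization. Gene order is preserved.
#'
#' @param experiment A [dr_experiment()].
#' @param min_median Median-count threshold; genes with median `<= min_median`
#'   are removed.
#' @return The experiment with offending genes removed.
#' @export
filter_low_counts <- function(experiment, min_median = 8) {
  stopifnot(inherits(experiment, "dr_experiment"))
  med <- apply(experiment$counts, 1, median)
  keep <- med > min_median
  if (!any(keep)) {
    abort("no genes survive the low-count filter")
  }
  experiment$counts <- experiment$counts[keep, , drop = FALSE]
  experiment
}

#' Normalize counts to log2(CPM + 1)
#'
#' Library-size normalization to counts per million mapped reads followed by a
#' log2 transform with a pseudocount of 1:
#' `value = log2(count / colsum * 1e6 + 1)`.
#'
#' @param experiment A [dr_experiment()].
#' @return A numeric matrix (genes x samples) of log2(CPM+1) values with
#'   attribute `batch_adjusted = FALSE`.
#' @export
normalize_log2 <- function(experiment) {
  stopifnot(inherits(experiment, "dr_experiment"))
  libsize <- colSums(experiment$counts)
  if (any(libsize == 0)) {
    abort(paste0("zero library size in sample(s): ",
                 paste(colnames(experiment$counts)[libsize == 0],
                       collapse = ", ")))
  }
  cpm <- sweep(experiment$counts, 2, libsize, `/`) * 1e6
  out <- log2(cpm + 1)
  attr(out, "batch_adjusted") <- FALSE
  out
}

#' Remove additive batch effects
#'
#' Per gene, fits the additive linear model `value ~ dose_group + batch` by
#' least squares and subtracts the fitted batch effects (reference batch =
#' first label in lexicographic order). With a single batch (or no labels) the
#' matrix is returned unchanged.
#'
#' @param matrix Numeric matrix (genes x samples) of log2 expression values.
#' @param batch Per-sample batch labels (length = ncol).
#' @param doses Per-sample doses; dose is treated as a categorical group here.
#' @return The adjusted matrix with attribute `batch_adjusted = TRUE` (or the
#'   input when there is nothing to adjust).
#' @details Errors when batch is confounded with dose, i.e. some dose group
#'   lies entirely within one batch: the batch effect is then not separable
#'   from the dose effect, and the offending groups are reported.
#' @export
adjust_batch <- function(matrix, batch, doses) {
  if (is.null(batch)) return(matrix)
  batch <- as.character(batch)
  if (length(batch) != ncol(matrix) || length(doses) != ncol(matrix)) {
    abort("`batch` and `doses` must align with the columns of `matrix`")
  }
  if (length(unique(batch)) < 2) {
    attr(matrix, "batch_adjusted") <- FALSE
    return(matrix)
  }
  if (any(table(batch) < 2)) {
    abort("every batch needs at least two samples")
  }
  tab <- table(doses, batch)
  confounded <- rownames(tab)[rowSums(tab > 0) == 1]
  if (length(confounded) > 0) {
    abort(paste0(
      "batch is confounded with dose; dose group(s) entirely within one ",
      "batch: ", paste(confounded, collapse = ", ")
    ))
  }
  dose_f <- factor(doses)
  batch_f <- factor(batch, levels = sort(unique(batch)))
  X <- stats::model.matrix(~ dose_f + batch_f)
  qrX <- qr(X)
  # coefficients for all genes at once: solve X B = t(matrix)
  B <- qr.coef(qrX, t(matrix))
  batch_cols <- grep("^batch_f", colnames(X))
  fitted_batch <- X[, batch_cols, drop = FALSE] %*%
    B[batch_cols, , drop = FALSE]
  out <- matrix - t(fitted_batch)
  attr(out, "batch_adjusted") <- TRUE
  out
}

#' ANOVA / fold-change prefilter for dose-responsive genes
#'
#' Per gene, a one-way fixed-effects ANOVA across dose groups plus a maximum
#' absolute fold-change gate. Significance is judged on the
#' Benjamini-Hochberg-adjusted p-value when `fdr_mode = TRUE` (the dietary
#' rodent design) and on the raw p-value otherwise (the aquatic larva design).
#' The fold change of a dose group is `2^|mean_group - mean_control|` computed
#' on the log2 matrix; a gene passes when it is significant and its maximum
#' fold change is at least `min_fc` (boundary inclusive).
#'
#' @param matrix Numeric matrix (genes x samples) of log2 expression values.
#' @param doses Per-sample doses (categorical grouping; the control group is
#'   dose 0).
#' @param fdr_mode Logical; adjust p-values before thresholding?
#' @param alpha Significance level (default 0.05).
#' @param min_fc Fold-change threshold on the linear scale (default 2).
#' @return A tibble with one row per gene: `gene_id`, `f_stat`, `p_value`,
#'   `fdr_p`, `max_fc`, `pass`, and the `fdr_mode` used.
#' @details Genes with zero within-group variance in every group get `p = 0`
#'   if any group means differ and `p = 1` otherwise (an explicit convention
#'   for degenerate rows).
#' @export
prefilter_anova <- function(matrix, doses, fdr_mode, alpha = 0.05,
                            min_fc = 2) {
  if (ncol(matrix) != length(doses)) {
    abort("`doses` must align with the columns of `matrix`")
  }
  groups <- factor(doses)
  k <- nlevels(groups)
  if (k < 2) abort("need at least two dose groups")
  n_g <- as.vector(table(groups))
  if (any(n_g < 2)) abort("every dose group needs at least two samples")
  n <- ncol(matrix)

  # group means for all genes at once
  G <- stats::model.matrix(~ 0 + groups)
  means <- matrix %*% G %*% diag(1 / n_g)
  colnames(means) <- levels(groups)
  grand <- rowMeans(matrix)
  ssb <- as.vector((means - grand)^2 %*% n_g)
  sst <- rowSums((matrix - grand)^2)
  ssw <- pmax(sst - ssb, 0)

  df1 <- k - 1
  df2 <- n - k
  f_stat <- (ssb / df1) / (ssw / df2)
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  # degenerate rows: no within-group variance anywhere
  zero_w <- ssw <= .Machine$double.eps * pmax(sst, 1)
  p[zero_w & ssb > 0] <- 0
  p[zero_w & ssb <= 0] <- 1
  f_stat[zero_w & ssb > 0] <- Inf
  f_stat[zero_w & ssb <= 0] <- 0
  fdr_p <- p.adjust(p, method = "BH")

  ctrl <- which(levels(groups) == "0")
  if (length(ctrl) == 0) ctrl <- 1L  # lowest dose as reference
  lfc <- abs(means[, -ctrl, drop = FALSE] - means[, ctrl])
  max_fc <- 2^apply(lfc, 1, max)

  sig <- if (fdr_mode) fdr_p < alpha else p < alpha
  tibble(
    gene_id = rownames(matrix),
    f_stat = unname(f_stat),
    p_value = unname(p),
    fdr_p = unname(fdr_p),
    max_fc = unname(max_fc),
    pass = unname(sig & max_fc >= min_fc),
    fdr_mode = fdr_mode
  )
}
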