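#' Construct a dose-response expression experiment
#'
#' Bundles a genes-by-samples count matrix with per-sample dose metadata.
#' This is the raw input of the TPOD workflow: counts straight from
#' quantification, one dose (or concentration) per sample, and an optional
#' batch label used for linear-model batch adjustment.
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns. Row and column names are required (gene and sample ids).
#' @param samples Data frame with one row per column of `counts`, containing
#'   at least `sample_id` and `dose`. An optional `batch` column carries
#'   blocking labels. Extra columns are kept.
#' @param dose_units Unit label for the dose axis, e.g. `"mg/Kg-bw/day"`
#'   (dietary studies) or `"mg/L"` (aquatic exposures).
#'
#' @return A `dr_experiment` object: a list with elements `counts`,
#'   `samples` (a tibble, ordered to match the columns of `counts`) and
#'   `dose_units`.
#'
#' @details At least one sample must be at dose 0 (the control group);
#'   downstream fold changes and benchmark doses are defined relative to it.
#'
#' @examples
#' counts <- matrix(rpois(20, 50), nrow = 4,
#'                  dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' samples <- data.frame(sample_id = paste0("s", 1:5), dose = c(0, 0, 1, 1, 2))
#' dr_experiment(counts, samples, "mg/L")
#' @export
dr_experiment <- function(counts, samples, dose_units = "mg/Kg-bw/day") {
  if (!is.matrix(counts)) {
    abort("`counts` must be a matrix (genes x samples).")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene row names and sample column names.")
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort("`counts` must be non-negative and free of missing values.")
  }
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "dose") %in% names(samples))) {
    abort("`samples` must contain columns `sample_id` and `dose`.")
  }
  missing_meta <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0(
      "Samples present in `counts` but absent from `samples`: ",
      paste(missing_meta, collapse = ", ")
    ))
  }
  orphan_meta <- setdiff(samples$sample_id, colnames(counts))
  if (length(orphan_meta) > 0) {
    abort(paste0(
      "Samples present in `samples` but absent from `counts`: ",
      paste(orphan_meta, collapse = ", ")
    ))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (anyNA(samples$dose) || any(samples$dose < 0)) {
    abort("Every sample needs a non-negative `dose`.")
  }
  if (!any(samples$dose == 0)) {
    abort("At least one sample must be at dose 0 (control).")
  }
  structure(
    list(counts = counts, samples = samples, dose_units = dose_units),
    class = "dr_experiment"
  )
}

#' @export
print.dr_experiment <- function(x, ...) {
  doses <- sort(unique(x$samples$dose))
  cat("<dr_experiment> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  dose levels (", x$dose_units, "): ",
      paste(signif(doses, 4), collapse = ", "), "\n", sep = "")
  if (!is.null(x$samples[["batch"]])) {
    cat("  batches: ", paste(sort(unique(as.character(x$samples[["batch"]]))),
                             collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.dr_experiment <- function(x) dim(x$counts)

#' Doses aligned with the columns of an experiment or matrix
#' @param experiment A `dr_experiment`.
#' @return Numeric vector of per-sample doses.
#' @export
sample_doses <- function(experiment) {
  stopifnot(inherits(experiment, "dr_experiment"))
  experiment$samples$dose
}
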