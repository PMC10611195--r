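# End-to-end pipeline: filter -> normalize -> (batch) -> prefilter ->
# model/BMD/bounds -> gene filters -> enrichment -> TPOD.

#' Pipeline configuration
#'
#' @param mode `"mouse_like"` (FDR-adjusted prefilter p-values and batch
#'   adjustment when labels exist — the dietary rodent design) or
#'   `"minnow_like"` (raw prefilter p-values, never batch-adjusted — the
#'   aquatic larva design).
#' @param alpha Prefilter and enrichment significance level.
#' @param min_fc Prefilter fold-change threshold (linear scale).
#' @param bmr_factor Benchmark response in residual SDs.
#' @param confidence One-sided confidence level of the BMD bounds.
#' @param ratio_cutoff BMDU:BMDL exclusion threshold.
#' @param hill_k_fraction Hill flag threshold as a fraction of the lowest
#'   positive dose.
#' @param min_overlap Minimum responsive-gene overlap for enrichment.
#' @param universe_mode Universe for Fisher's test: `"filtered"` (all genes
#'   surviving the low-count filter — the tested transcriptome) or
#'   `"annotated"` (genes appearing in any gene set, intersected with the
#'   filtered genes).
#' @return A `tpod_config` list.
#' @export
tpod_config <- function(mode = c("mouse_like", "minnow_like"),
                        alpha = 0.05, min_fc = 2,
                        bmr_factor = .default_bmr_factor,
                        confidence = 0.95, ratio_cutoff = 40,
                        hill_k_fraction = 1 / 3, min_overlap = 3,
                        universe_mode = c("filtered", "annotated")) {
  mode <- match.arg(mode)
  universe_mode <- match.arg(universe_mode)
  stopifnot(alpha > 0, min_fc > 0, bmr_factor > 0, confidence > 0,
            confidence < 1, ratio_cutoff > 0, hill_k_fraction > 0)
  structure(
    list(mode = mode, fdr_mode = mode == "mouse_like", alpha = alpha,
         min_fc = min_fc, bmr_factor = bmr_factor, confidence = confidence,
         ratio_cutoff = ratio_cutoff, hill_k_fraction = hill_k_fraction,
         min_overlap = min_overlap, universe_mode = universe_mode),
    class = "tpod_config"
  )
}

#' Run the full transcriptomic-POD pipeline
#'
#' Executes every stage on a raw experiment: low-count filter, log2(CPM+1)
#' normalization, batch adjustment (mouse-like mode with batch labels only),
#' ANOVA/fold-change prefilter, nine-model BMD fitting with profile bounds,
#' gene-level exclusion filters, Fisher gene-set enrichment, and TPOD
#' derivation. All stages are deterministic: identical inputs and config give
#' identical outputs.
#'
#' @param experiment A [dr_experiment()].
#' @param gene_sets Named list of gene sets ([read_gmt()]).
#' @param config A [tpod_config()].
#' @param chemical,assay Labels carried into the TPOD result.
#' @param out_dir Optional directory; when given, every intermediate table is
#'   written as CSV together with a `manifest.json` recording the config, its
#'   hash and the package version.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `tpod_result`: `status` (`"ok"`,
#'   `"no_responsive_genes"` or `"no_enriched_sets"`), `tpod` (one-row
#'   tibble), `prefilter`, `gene_bmds`, `enrichment`, `accumulation`,
#'   `n_genes` (per-stage gene counts), and `config`.
#' @export
run_tpod_pipeline <- function(experiment, gene_sets, config = tpod_config(),
                              chemical = NA_character_,
                              assay = NA_character_, out_dir = NULL,
                              quiet = FALSE) {
  stopifnot(inherits(experiment, "dr_experiment"),
            inherits(config, "tpod_config"))
  say <- function(...) if (!quiet) inform(paste0(...))

  n0 <- nrow(experiment$counts)
  filtered <- filter_low_counts(experiment)
  say("low-count filter: ", nrow(filtered$counts), "/", n0, " genes kept")

  mat <- normalize_log2(filtered)
  doses <- sample_doses(filtered)
  batch <- filtered$samples[["batch"]]
  if (config$mode == "mouse_like" && !is.null(batch) &&
      length(unique(batch)) > 1) {
    mat <- adjust_batch(mat, batch, doses)
    say("batch adjustment: ", length(unique(batch)), " batches removed")
  }

  pre <- prefilter_anova(mat, doses, fdr_mode = config$fdr_mode,
                         alpha = config$alpha, min_fc = config$min_fc)
  candidates <- pre$gene_id[pre$pass]
  say("prefilter (", if (config$fdr_mode) "FDR" else "raw p", " < ",
      config$alpha, ", maxFC >= ", config$min_fc, "): ", length(candidates),
      " candidate genes")

  universe <- switch(config$universe_mode,
    filtered = rownames(mat),
    annotated = intersect(rownames(mat), unique(unlist(gene_sets)))
  )

  empty_tpod <- function(status) {
    out <- list(
      status = status,
      tpod = derive_tpod(tibble(set_id = character(), overlap = integer(),
                                p_value = numeric(), enriched = logical(),
                                median_bmd = numeric(),
                                median_bmdl = numeric(),
                                median_bmdu = numeric()),
                         chemical = chemical, assay = assay),
      prefilter = pre,
      gene_bmds = tibble(),
      enrichment = tibble(),
      accumulation = tibble(),
      n_genes = c(input = n0, filtered = nrow(mat),
                  candidates = length(candidates), modeled = 0L,
                  retained = 0L),
      config = config
    )
    class(out) <- "tpod_result"
    out
  }

  if (length(candidates) == 0) {
    say("no responsive genes; stopping")
    res <- empty_tpod("no_responsive_genes")
    if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
    return(res)
  }

  gene_bmds <- fit_gene_bmds(mat, doses, genes = candidates,
                             bmr_factor = config$bmr_factor,
                             confidence = config$confidence,
                             hill_k_fraction = config$hill_k_fraction)
  max_dose <- max(doses)
  gene_bmds <- filter_bmd_results(gene_bmds, max_dose,
                                  ratio_cutoff = config$ratio_cutoff)
  n_kept <- sum(!gene_bmds$excluded)
  say("BMD modeling: ", n_kept, "/", nrow(gene_bmds),
      " genes pass the BMD filters")

  enr <- enrich_gene_sets(gene_sets, gene_bmds, universe,
                          alpha = config$alpha,
                          min_overlap = config$min_overlap)
  say("enrichment: ", sum(enr$enriched), "/", nrow(enr), " sets enriched")

  tpod <- derive_tpod(enr, chemical = chemical, assay = assay)
  status <- if (tpod$n_enriched_sets == 0) "no_enriched_sets" else "ok"
  out <- list(
    status = status, tpod = tpod, prefilter = pre, gene_bmds = gene_bmds,
    enrichment = enr, accumulation = accumulation_table(enr),
    n_genes = c(input = n0, filtered = nrow(mat),
                candidates = length(candidates), modeled = nrow(gene_bmds),
                retained = n_kept),
    config = config
  )
  class(out) <- "tpod_result"
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

.write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(res$config))
  stamp <- function(df) {
    if (nrow(df) > 0) df$config_hash <- cfg_hash else df$config_hash <- character(0)
    df
  }
  readr::write_csv(stamp(res$prefilter), file.path(out_dir, "prefilter.csv"))
  readr::write_csv(stamp(res$gene_bmds), file.path(out_dir, "gene_bmds.csv"))
  readr::write_csv(stamp(res$enrichment), file.path(out_dir, "enrichment.csv"))
  readr::write_csv(stamp(res$accumulation),
                   file.path(out_dir, "accumulation.csv"))
  readr::write_csv(stamp(res$tpod), file.path(out_dir, "tpod.csv"))
  manifest <- list(
    package = "tpodr",
    version = as.character(utils::packageVersion("tpodr")),
    status = res$status,
    config = unclass(res$config),
    config_hash = cfg_hash,
    n_genes = as.list(res$n_genes)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.tpod_result <- function(x, ...) {
  cat("<tpod_result> status: ", x$status, "\n", sep = "")
  cat("  genes: ", paste(names(x$n_genes), x$n_genes, sep = "=",
                         collapse = ", "), "\n", sep = "")
  if (x$status == "ok") {
    cat("  most sensitive enriched set: ", x$tpod$set_id, "\n", sep = "")
    cat("  gene-set BMD = ", signif(x$tpod$geneset_bmd, 4),
        ", TPOD (median BMDL) = ", signif(x$tpod$tpod, 4),
        ", BMDU = ", signif(x$tpod$geneset_bmdu, 4), "\n", sep = "")
  }
  invisible(x)
}
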