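# Gene-set enrichment by Fisher's exact test and TPOD derivation.

#' Two-tailed Fisher exact p-value for a 2x2 enrichment table
#'
#' Hypergeometric null: the two-tailed p is the sum of the probabilities of
#' all tables (with the same margins) whose probability does not exceed that
#' of the observed table. A relative tolerance of 1e-7 guards against ties
#' lost to floating point, matching common practice.
#'
#' @param overlap Responsive genes inside the set.
#' @param set_size Genes of the set present in the universe.
#' @param n_responsive Responsive genes in the universe.
#' @param n_universe Universe size.
#' @return The two-tailed p-value.
#' @export
fisher_exact_two_tailed <- function(overlap, set_size, n_responsive,
                                    n_universe) {
  if (set_size > n_universe || n_responsive > n_universe ||
      overlap > min(set_size, n_responsive) ||
      overlap < max(0, set_size + n_responsive - n_universe)) {
    abort("inconsistent 2x2 table")
  }
  support <- max(0, n_responsive + set_size - n_universe):
    min(n_responsive, set_size)
  probs <- dhyper(support, set_size, n_universe - set_size, n_responsive)
  p_obs <- dhyper(overlap, set_size, n_universe - set_size, n_responsive)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Gene-set enrichment of dose-responsive genes
#'
#' For each gene set, builds the 2x2 table {in set vs. not} x {responsive vs.
#' not} over the tested universe and computes the two-tailed Fisher exact
#' p-value. A set is called enriched when p < `alpha` and at least
#' `min_overlap` responsive genes fall in it. Per-set medians of the gene
#' BMD/BMDL/BMDU are computed over the overlapping, non-excluded genes (each
#' column's median taken independently).
#'
#' @param gene_sets Named list of member gene-id vectors (e.g. [read_gmt()]).
#' @param gene_results Filtered gene-level results ([filter_bmd_results()]);
#'   rows with `excluded = FALSE` define the responsive genes.
#' @param universe Character vector of all tested gene ids (typically the
#'   genes surviving the low-count filter).
#' @param alpha Enrichment significance level (default 0.05).
#' @param min_overlap Minimum responsive-gene overlap (default 3).
#' @return A tibble with one row per set: `set_id`, `overlap`, `set_size`
#'   (within the universe), `n_responsive`, `n_universe`, `p_value`,
#'   `enriched`, `median_bmd`, `median_bmdl`, `median_bmdu`. Sets with no
#'   member in the universe are skipped (recorded in attribute
#'   `"skipped_sets"`).
#' @export
enrich_gene_sets <- function(gene_sets, gene_results, universe, alpha = 0.05,
                             min_overlap = 3) {
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  responsive <- gene_results$gene_id[!gene_results$excluded]
  bad <- setdiff(responsive, universe)
  if (length(bad) > 0) {
    abort(paste0("responsive genes missing from the universe: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  n_universe <- length(universe)
  n_responsive <- length(responsive)
  kept <- gene_results[!gene_results$excluded, c("gene_id", "bmd", "bmdl",
                                                 "bmdu")]

  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(unique(gene_sets[[id]]), universe)
    if (length(members) == 0) return(NULL)
    hits <- intersect(members, responsive)
    p <- fisher_exact_two_tailed(length(hits), length(members), n_responsive,
                                 n_universe)
    sub <- kept[kept$gene_id %in% hits, ]
    tibble(
      set_id = id, overlap = length(hits), set_size = length(members),
      n_responsive = n_responsive, n_universe = n_universe,
      p_value = p,
      enriched = p < alpha && length(hits) >= min_overlap,
      median_bmd = if (nrow(sub) > 0) median(sub$bmd) else NA_real_,
      median_bmdl = if (nrow(sub) > 0) median(sub$bmdl) else NA_real_,
      median_bmdu = if (nrow(sub) > 0) median(sub$bmdu) else NA_real_
    )
  })
  skipped <- names(gene_sets)[vapply(rows, is.null, logical(1))]
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_sets") <- skipped
  out
}

#' Transcriptomic point of departure from enriched gene sets
#'
#' The most sensitive enriched set is the one with the lowest median BMD (ties
#' broken by lower median BMDL, then smaller p, then lexicographic set id).
#' Its median BMD is the gene-set (transcriptomic) BMD; its median BMDL is the
#' TPOD.
#'
#' @param enrichments Tibble from [enrich_gene_sets()].
#' @param chemical,assay Labels carried into the result.
#' @return One-row tibble: `chemical`, `assay`, `set_id`, `geneset_bmd`,
#'   `tpod` (median BMDL), `geneset_bmdu`, `n_enriched_sets`. With no enriched
#'   set, the labels are kept, the numbers are `NA` and `n_enriched_sets` is
#'   0 (no fabricated fallback).
#' @export
derive_tpod <- function(enrichments, chemical = NA_character_,
                        assay = NA_character_) {
  enr <- enrichments[isTRUE_vec(enrichments$enriched) &
                       !is.na(enrichments$median_bmd), ]
  if (nrow(enr) == 0) {
    return(tibble(
      chemical = chemical, assay = assay, set_id = NA_character_,
      geneset_bmd = NA_real_, tpod = NA_real_, geneset_bmdu = NA_real_,
      n_enriched_sets = 0L
    ))
  }
  ord <- order(enr$median_bmd, enr$median_bmdl, enr$p_value, enr$set_id)
  win <- enr[ord[1], ]
  tibble(
    chemical = chemical, assay = assay, set_id = win$set_id,
    geneset_bmd = win$median_bmd, tpod = win$median_bmdl,
    geneset_bmdu = win$median_bmdu, n_enriched_sets = nrow(enr)
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Accumulation table of gene-set medians
#'
#' Orders enriched-set medians ascending — the data behind accumulation plots
#' of gene-set potency. Ranks by median BMD and by median BMDL are reported
#' separately (the two orders can differ when per-gene uncertainty varies).
#'
#' @param enrichments Tibble from [enrich_gene_sets()]; rows without a median
#'   BMD are dropped.
#' @param enriched_only Restrict to enriched sets (default TRUE).
#' @return Tibble sorted by `median_bmd` with columns `set_id`, `median_bmd`,
#'   `median_bmdl`, `rank_bmd`, `rank_bmdl`.
#' @export
accumulation_table <- function(enrichments, enriched_only = TRUE) {
  df <- enrichments[!is.na(enrichments$median_bmd), ]
  if (enriched_only) df <- df[isTRUE_vec(df$enriched), ]
  if (nrow(df) == 0) {
    return(tibble(set_id = character(), median_bmd = numeric(),
                  median_bmdl = numeric(), rank_bmd = integer(),
                  rank_bmdl = integer()))
  }
  df <- df[order(df$median_bmd, df$set_id), ]
  df$rank_bmd <- seq_len(nrow(df))
  df$rank_bmdl <- rank(df$median_bmdl, ties.method = "first")
  df[, c("set_id", "median_bmd", "median_bmdl", "rank_bmd", "rank_bmdl")]
}
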