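# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dose-response model fit
#'
#' @param x A `drc_fit` from [fit_drc()].
#' @param ... Unused.
#' @return Tibble with one row per mean parameter (`term`, `estimate`).
#' @export
tidy.drc_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' One-row model summary of a dose-response fit
#'
#' @param x A `drc_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `sigma`, `logLik`, `AIC`, `gof_p`,
#'   `hill_k_flag`, `converged`, `nobs`.
#' @export
glance.drc_fit <- function(x, ...) {
  tibble(
    model = x$model, sigma = x$sigma, logLik = x$loglik, AIC = x$aic,
    gof_p = x$gof_p, hill_k_flag = x$hill_k_flag, converged = x$converged,
    nobs = x$group_stats$n
  )
}

#' Tidy a pipeline result
#'
#' @param x A `tpod_result` from [run_tpod_pipeline()].
#' @param ... Unused.
#' @return The per-gene BMD table with exclusion flags.
#' @export
tidy.tpod_result <- function(x, ...) x$gene_bmds

#' One-row summary of a pipeline run
#'
#' @param x A `tpod_result`.
#' @param ... Unused.
#' @return Tibble with the headline TPOD quantities and stage gene counts.
#' @export
glance.tpod_result <- function(x, ...) {
  dplyr::bind_cols(
    x$tpod,
    tibble(status = x$status,
           n_input = unname(x$n_genes["input"]),
           n_filtered = unname(x$n_genes["filtered"]),
           n_candidates = unname(x$n_genes["candidates"]),
           n_retained = unname(x$n_genes["retained"]))
  )
}
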