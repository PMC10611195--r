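# Constant-variance maximum-likelihood fitting on group sufficient statistics.
#
# With Gaussian errors and a variance shared across dose groups, the
# log-likelihood depends on the data only through group means, group sizes and
# the pooled within-group sum of squares:
#   SSE(theta) = SSW + sum_g n_g * (ybar_g - mu(d_g; theta))^2
#   loglik     = -n/2 * (log(2*pi*SSE/n) + 1)   at the MLE sigma^2 = SSE/n
# Fitting on the (few) group means instead of all samples makes the multistart
# search and the profile-likelihood bounds cheap.

.group_stats <- function(doses, responses) {
  if (anyNA(responses) || any(!is.finite(responses))) {
    abort("responses must be finite")
  }
  ud <- sort(unique(doses))
  idx <- match(doses, ud)
  n_g <- tabulate(idx, length(ud))
  means <- vapply(seq_along(ud), function(i) mean(responses[idx == i]),
                  numeric(1))
  ssw <- sum(vapply(seq_along(ud), function(i) {
    y <- responses[idx == i]
    sum((y - means[i])^2)
  }, numeric(1)))
  list(doses = ud, n_g = n_g, means = means, ssw = ssw, n = length(responses))
}

.loglik_from_sse <- function(sse, n) {
  sse <- max(sse, 1e-300)
  -n / 2 * (log(2 * pi * sse / n) + 1)
}

# rss between group means and model means (SSW excluded)
.rss_between <- function(mean_fn, theta, gs) {
  mu <- mean_fn(gs$doses, theta)
  if (any(!is.finite(mu))) return(Inf)
  sum(gs$n_g * (gs$means - mu)^2)
}

.fit_poly_ls <- function(gs, degree) {
  basis <- outer(gs$doses, 0:degree, `^`)
  cf <- .wls(basis, gs$means, gs$n_g)
  unname(cf)
}

.fit_nonlinear <- function(model, gs) {
  def <- .model_defs[[model]]
  dm <- max(gs$doses)
  bnd <- def$bounds(dm)
  starts <- .model_starts(model, gs)
  obj <- function(th) .rss_between(def$mean, th, gs)
  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    st <- pmin(pmax(starts[i, ], bnd$lower), bnd$upper)
    res <- tryCatch(
      nlminb(st, obj, lower = bnd$lower, upper = bnd$upper,
             control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    n_used <- n_used + 1L
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) {
    return(list(theta = rep(NA_real_, length(def$par_names)),
                rss = NA_real_, converged = FALSE, n_starts = n_used))
  }
  list(theta = best$par, rss = best$objective, converged = TRUE,
       n_starts = n_used)
}

#' Fit one continuous dose-response model
#'
#' Fits a single model from the nine-model suite by maximum likelihood under
#' Gaussian errors with constant variance (equivalently, least squares with
#' the variance MLE `sigma^2 = SSE/n`). Linear and polynomial models are
#' solved in closed form; the nonlinear models use a deterministic multistart
#' grid derived from data quantiles (no random numbers), so refits are
#' bit-reproducible.
#'
#' @param model Model id; see [tpodr_models()].
#' @param doses Numeric vector of non-negative doses, at least two distinct
#'   values, one of them typically 0.
#' @param responses Numeric response vector (same length), e.g. log2 CPM.
#' @return A `drc_fit` object with elements `model`, `coef` (named vector),
#'   `sigma` (residual SD, MLE), `loglik`, `aic`, `gof_p` (likelihood-ratio
#'   goodness-of-fit p against the saturated group-means model; `NA` when the
#'   model has as many mean parameters as there are dose groups),
#'   `hill_k_flag`, `converged`, and `n_multistarts_used`.
#'
#' @details AIC counts the residual-variance parameter:
#'   `AIC = 2*(p_mean + 1) - 2*loglik`. The Hill `k` flag marks fits whose
#'   half-maximal dose falls below one third of the lowest positive dose, an
#'   unsupported low-dose plateau.
#'
#' @param hill_k_fraction Hill flag threshold, as a fraction of the lowest
#'   positive dose (default 1/3).
#' @examples
#' d <- rep(c(0, 1, 2, 4), each = 3)
#' y <- 5 + 0.8 * d + rnorm(length(d), sd = 0.2)
#' fit_drc("linear", d, y)
#' @export
fit_drc <- function(model, doses, responses, hill_k_fraction = 1 / 3) {
  model <- match.arg(model, .tpodr_models)
  if (length(doses) != length(responses)) {
    abort("`doses` and `responses` must have equal length.")
  }
  if (length(unique(doses)) < 2) {
    abort("need at least two distinct doses")
  }
  gs <- .group_stats(doses, responses)
  def <- .model_defs[[model]]

  if (!is.null(def$degree)) {
    theta <- .fit_poly_ls(gs, def$degree)
    rss <- .rss_between(def$mean, theta, gs)
    res <- list(theta = theta, rss = rss, converged = TRUE, n_starts = 1L)
  } else {
    res <- .fit_nonlinear(model, gs)
  }

  npar <- length(def$par_names)
  if (!res$converged) {
    fit <- list(model = model, coef = setNames(res$theta, def$par_names),
                sigma = NA_real_, loglik = NA_real_, aic = NA_real_,
                gof_p = NA_real_, hill_k_flag = FALSE, converged = FALSE,
                n_multistarts_used = res$n_starts, group_stats = gs)
    return(structure(fit, class = "drc_fit"))
  }

  sse <- gs$ssw + res$rss
  n <- gs$n
  sigma <- sqrt(max(sse, 1e-300) / n)
  ll <- .loglik_from_sse(sse, n)
  aic <- 2 * (npar + 1) - 2 * ll
  df_gof <- length(gs$doses) - npar
  gof_p <- if (df_gof > 0) {
    ll_sat <- .loglik_from_sse(gs$ssw, n)
    pchisq(2 * (ll_sat - ll), df = df_gof, lower.tail = FALSE)
  } else NA_real_

  hill_k_flag <- FALSE
  if (model == "hill") {
    lowest_pos <- min(gs$doses[gs$doses > 0])
    hill_k_flag <- is.finite(res$theta[3]) &&
      res$theta[3] < lowest_pos * hill_k_fraction
  }

  fit <- list(
    model = model, coef = setNames(res$theta, def$par_names),
    sigma = sigma, loglik = ll, aic = aic, gof_p = gof_p,
    hill_k_flag = hill_k_flag, converged = TRUE,
    n_multistarts_used = res$n_starts, group_stats = gs
  )
  structure(fit, class = "drc_fit")
}

#' @export
print.drc_fit <- function(x, ...) {
  cat("<drc_fit> ", x$model, if (!x$converged) " (not converged)", "\n",
      sep = "")
  if (x$converged) {
    cat("  coef: ", paste(names(x$coef), signif(x$coef, 5), sep = "=",
                          collapse = ", "), "\n", sep = "")
    cat("  sigma=", signif(x$sigma, 5), "  loglik=", signif(x$loglik, 6),
        "  AIC=", signif(x$aic, 6), "\n", sep = "")
  }
  invisible(x)
}

#' @export
predict.drc_fit <- function(object, doses, ...) {
  .model_defs[[object$model]]$mean(doses, unname(object$coef))
}

#' Fit the full nine-model suite to one gene
#'
#' @inheritParams fit_drc
#' @param models Subset of model ids to fit (default: all nine).
#' @return Named list of `drc_fit` objects.
#' @export
fit_drc_suite <- function(doses, responses, models = tpodr_models(),
                          hill_k_fraction = 1 / 3) {
  models <- match.arg(models, .tpodr_models, several.ok = TRUE)
  setNames(lapply(models, fit_drc, doses = doses, responses = responses,
                  hill_k_fraction = hill_k_fraction),
           models)
}

#' Select the best model from a suite of fits
#'
#' Implements the BMDExpress-style selection cascade: within the polynomial
#' family (linear, poly2, poly3) the model is promoted to the next order only
#' when the nested likelihood-ratio chi-square test rejects at p < 0.05; the
#' resulting family champion then competes with the exponential, Hill and
#' power fits on lowest AIC. If the AIC winner is a Hill fit whose `k` falls
#' below one third of the lowest positive dose, it is set aside and the
#' next-lowest-AIC unflagged model with goodness-of-fit p > 0.05 is returned
#' instead; when no such model exists the gene has no selection.
#'
#' @param fits List of `drc_fit` objects (e.g. from [fit_drc_suite()]).
#' @param nested_alpha Promotion threshold for the nested polynomial test.
#' @return The selected `drc_fit`, or `NULL` when nothing converged or every
#'   candidate is disqualified. The returned fit carries attribute
#'   `"selection_note"` (`"aic"` or `"hill_flag_fallback"`).
#' @export
select_best_model <- function(fits, nested_alpha = 0.05) {
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(fits) == 0) return(NULL)
  ids <- vapply(fits, `[[`, character(1), "model")
  names(fits) <- ids

  # polynomial family champion by nested LR chi-square; df = difference in
  # mean-parameter count between candidate and current champion
  champion <- NULL
  for (m in c("linear", "poly2", "poly3")) {
    cand <- fits[[m]]
    if (is.null(cand)) next
    if (is.null(champion)) { champion <- cand; next }
    lr <- 2 * (cand$loglik - champion$loglik)
    df <- length(cand$coef) - length(champion$coef)
    p <- pchisq(max(lr, 0), df = df, lower.tail = FALSE)
    if (p < nested_alpha) champion <- cand
  }

  pool <- fits[setdiff(ids, c("linear", "poly2", "poly3"))]
  if (!is.null(champion)) pool <- c(pool, list(champion))
  if (length(pool) == 0) return(NULL)

  aics <- vapply(pool, `[[`, numeric(1), "aic")
  ord <- order(aics)
  winner <- pool[[ord[1]]]
  if (!winner$hill_k_flag) {
    attr(winner, "selection_note") <- "aic"
    return(winner)
  }
  # flagged Hill won on AIC: fall back to the next-best unflagged model with
  # an acceptable goodness of fit (p > 0.05; NA = saturated-df, accepted)
  for (i in ord[-1]) {
    cand <- pool[[i]]
    if (cand$hill_k_flag) next
    if (is.na(cand$gof_p) || cand$gof_p > 0.05) {
      attr(cand, "selection_note") <- "hill_flag_fallback"
      return(cand)
    }
  }
  NULL
}
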