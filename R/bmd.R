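# Benchmark-dose inversion and profile-likelihood confidence bounds.

#' Benchmark dose of a fitted model
#'
#' Inverts the fitted mean curve at the benchmark response
#' `BMR = bmr_factor * sigma_hat`: the BMD is the smallest dose at which the
#' mean response departs from the control mean by the BMR. The crossing is
#' located by bracketing on a log-spaced dose grid over `(0, 10 * max_dose]`
#' followed by root refinement to a relative tolerance of 1e-8; crossings
#' beyond the tested dose range are deliberately found here and rejected later
#' by [filter_bmd_results()], so that the "BMD above highest dose" exclusion
#' reason can be recorded.
#'
#' @param fit A converged `drc_fit`.
#' @param max_dose Highest tested dose (defaults to the highest dose in the
#'   fit); the search extends to 10 times this value.
#' @param bmr_factor Benchmark response in residual standard deviations
#'   (default 1.349, a ~10% tail shift under normality).
#' @return A list with `bmd` (numeric or `NA` when the curve never reaches the
#'   BMR within the search range) and `direction` (+1 if the response at the
#'   BMD is above the control mean, -1 below, `NA` when no BMD).
#' @examples
#' d <- rep(c(0, 1, 2, 4), each = 5)
#' y <- 2 + 1.349 * d + rnorm(length(d), sd = 0.01)
#' fit <- fit_drc("linear", d, y)
#' compute_bmd(fit)  # close to sigma_hat / 1 since slope ~ 1.349
#' @export
compute_bmd <- function(fit, max_dose = NULL, bmr_factor = .default_bmr_factor) {
  stopifnot(inherits(fit, "drc_fit"))
  if (!isTRUE(fit$converged)) abort("fit did not converge; no BMD")
  if (!is.finite(fit$sigma) || fit$sigma <= 0) {
    abort("residual SD must be positive to define the benchmark response")
  }
  max_dose <- max_dose %||% max(fit$group_stats$doses)
  target <- bmr_factor * fit$sigma
  mu <- function(d) predict(fit, d)
  mu0 <- mu(0)
  g <- function(d) abs(mu(d) - mu0) - target

  d_hi <- 10 * max_dose
  grid <- exp(seq(log(max_dose * 1e-8), log(d_hi), length.out = 400))
  vals <- g(grid)
  hit <- which(vals >= 0)
  if (length(hit) == 0) {
    return(list(bmd = NA_real_, direction = NA_real_))
  }
  i <- hit[1]
  if (i == 1) {
    # curve exceeds the BMR from (numerically) zero dose upwards
    bmd <- grid[1]
  } else {
    root <- uniroot(g, lower = grid[i - 1], upper = grid[i],
                    tol = max_dose * 1e-12)
    bmd <- root$root
    # polish to relative tolerance 1e-8
    bmd <- uniroot(g, lower = bmd * (1 - 1e-6), upper = min(bmd * (1 + 1e-6), d_hi),
                   tol = bmd * 1e-10, extendInt = "yes")$root
  }
  list(bmd = bmd, direction = as.numeric(sign(mu(bmd) - mu0)))
}

# Profile log-likelihood at a pinned BMD value b.
#
# The BMR constraint |mu(b) - mu(0)| = bmr_factor * sigma ties sigma to the
# mean parameters, so the constrained likelihood is maximized over the mean
# parameters only with sigma substituted by |mu(b) - mu(0)| / bmr_factor:
#   ll(theta) = -n/2*log(2*pi*sigma_c^2) - SSE(theta) / (2*sigma_c^2)
.profile_ll <- function(fit, b, bmr_factor) {
  def <- .model_defs[[fit$model]]
  gs <- fit$group_stats
  dm <- max(gs$doses)
  bnd <- if (!is.null(def$bounds)) def$bounds(dm) else
    list(lower = rep(-Inf, length(def$par_names)),
         upper = rep(Inf, length(def$par_names)))
  n <- gs$n

  negll <- function(th) {
    mu_b <- def$mean(b, th)
    mu_0 <- def$mean(0, th)
    if (!is.finite(mu_b) || !is.finite(mu_0)) return(Inf)
    sig <- abs(mu_b - mu_0) / bmr_factor
    if (sig <= 0) return(Inf)
    rss <- .rss_between(def$mean, th, gs)
    if (!is.finite(rss)) return(Inf)
    sse <- gs$ssw + rss
    n / 2 * log(2 * pi * sig^2) + sse / (2 * sig^2)
  }

  th_hat <- unname(fit$coef)
  step <- 0.25 * pmax(abs(th_hat), 1e-3)
  starts <- rbind(th_hat, th_hat + step, th_hat - step)
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- pmin(pmax(starts[i, ], bnd$lower), bnd$upper)
    res <- tryCatch(
      nlminb(st, negll, lower = bnd$lower, upper = bnd$upper,
             control = list(iter.max = 300, eval.max = 600)),
      error = function(e) NULL
    )
    if (!is.null(res) && is.finite(res$objective) && res$objective < best) {
      best <- res$objective
    }
  }
  -best
}

#' Profile-likelihood confidence bounds on a BMD
#'
#' One-sided 95% profile-likelihood limits in the BMDS tradition: the BMDL
#' (BMDU) is the smallest (largest) pinned BMD whose constrained maximum
#' log-likelihood stays within `qchisq(2*confidence - 1, 1) / 2` (about 1.3528
#' at 95%) of the unconstrained maximum. The BMD is made an explicit parameter
#' by substituting the benchmark-response constraint into the likelihood, and
#' each bound is located by monotone bisection.
#'
#' @param fit A converged `drc_fit`.
#' @param bmd The benchmark dose from [compute_bmd()].
#' @param confidence One-sided confidence level for each bound (default 0.95).
#' @param bmr_factor Benchmark response factor used for `bmd`.
#' @param max_dose Highest tested dose; the BMDU search is capped at 100 times
#'   this value (an upper bound that cannot be located below the cap is
#'   reported `NA` and excludes the gene downstream).
#' @return List with `bmdl` and `bmdu` (either may be `NA`).
#' @export
compute_bmd_bounds <- function(fit, bmd, confidence = 0.95,
                               bmr_factor = .default_bmr_factor,
                               max_dose = NULL) {
  stopifnot(inherits(fit, "drc_fit"))
  if (!is.finite(bmd) || bmd <= 0) abort("`bmd` must be a positive number")
  max_dose <- max_dose %||% max(fit$group_stats$doses)
  drop <- qchisq(2 * confidence - 1, df = 1) / 2
  ll_max <- fit$loglik
  crit <- ll_max - drop
  f <- function(b) .profile_ll(fit, b, bmr_factor) - crit

  bisect <- function(lo, hi, f_lo, f_hi) {
    # f(lo) and f(hi) have opposite signs; keep the root bracketed
    for (i in 1:60) {
      mid <- sqrt(lo * hi)
      fm <- f(mid)
      if (!is.finite(fm)) fm <- -Inf
      if ((fm > 0) == (f_lo > 0)) { lo <- mid; f_lo <- fm }
      else { hi <- mid; f_hi <- fm }
      if (hi / lo < 1 + 1e-4) break
    }
    sqrt(lo * hi)
  }

  # lower bound: walk down from the BMD until the profile drops below the cut
  bmdl <- NA_real_
  lo <- bmd; f_lo <- NA
  found <- FALSE
  b <- bmd
  for (i in 1:40) {
    b <- b / 2
    fb <- f(b)
    if (!is.finite(fb)) fb <- -Inf
    if (fb < 0) { found <- TRUE; lo <- b; f_lo <- fb; break }
  }
  if (found) {
    bmdl <- bisect(lo, min(2 * lo, bmd), f_lo, f(min(2 * lo, bmd)))
    if (bmdl > bmd) bmdl <- bmd
  }

  # upper bound: walk up, capped at 100 * max_dose
  bmdu <- NA_real_
  cap <- 100 * max_dose
  found <- FALSE
  b <- bmd
  while (b < cap) {
    b <- min(b * 2, cap)
    fb <- f(b)
    if (!is.finite(fb)) fb <- -Inf
    if (fb < 0) { found <- TRUE; break }
    if (b >= cap) break
  }
  if (found) {
    bmdu <- bisect(b / 2, b, f(b / 2), fb)
    if (bmdu < bmd) bmdu <- bmd
  }

  list(bmdl = bmdl, bmdu = bmdu)
}

#' Gene-level benchmark-dose modeling
#'
#' Runs the full per-gene modeling stage on a normalized expression matrix:
#' fits the nine-model suite, applies the selection cascade
#' ([select_best_model()]), inverts the winner at the benchmark response
#' ([compute_bmd()]) and profiles the confidence bounds
#' ([compute_bmd_bounds()]).
#'
#' @param matrix Numeric matrix of responses (genes x samples), typically the
#'   log2(CPM+1) values of prefiltered genes.
#' @param doses Per-sample doses aligned with the columns.
#' @param genes Optional subset of row names to model (default: all rows).
#' @param bmr_factor,confidence See [compute_bmd()] and
#'   [compute_bmd_bounds()].
#' @param hill_k_fraction Hill flag threshold (see [fit_drc()]).
#' @param models Model ids to include (default: the full suite).
#' @return A tibble with one row per gene: `gene_id`, `model`, `params`
#'   (JSON-formatted named coefficients), `bmd`, `bmdl`, `bmdu`, `direction`,
#'   `gof_p`, `selection_note`. Genes where no model can be selected carry
#'   `model = NA`.
#' @export
fit_gene_bmds <- function(matrix, doses, genes = NULL,
                          bmr_factor = .default_bmr_factor,
                          confidence = 0.95, hill_k_fraction = 1 / 3,
                          models = tpodr_models()) {
  if (ncol(matrix) != length(doses)) {
    abort("`doses` must align with the columns of `matrix`")
  }
  genes <- genes %||% rownames(matrix)
  max_dose <- max(doses)
  rows <- lapply(genes, function(g) {
    y <- matrix[g, ]
    fits <- fit_drc_suite(doses, y, models = models,
                          hill_k_fraction = hill_k_fraction)
    sel <- select_best_model(fits)
    if (is.null(sel)) {
      return(tibble(
        gene_id = g, model = NA_character_, params = NA_character_,
        bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
        direction = NA_real_, gof_p = NA_real_,
        selection_note = "no_converged_model"
      ))
    }
    bd <- compute_bmd(sel, max_dose = max_dose, bmr_factor = bmr_factor)
    if (is.na(bd$bmd)) {
      bounds <- list(bmdl = NA_real_, bmdu = NA_real_)
    } else {
      bounds <- compute_bmd_bounds(sel, bd$bmd, confidence = confidence,
                                   bmr_factor = bmr_factor,
                                   max_dose = max_dose)
    }
    tibble(
      gene_id = g, model = sel$model,
      params = as.character(jsonlite::toJSON(as.list(sel$coef),
                                             auto_unbox = TRUE, digits = NA)),
      bmd = bd$bmd, bmdl = bounds$bmdl, bmdu = bounds$bmdu,
      direction = bd$direction, gof_p = sel$gof_p,
      selection_note = attr(sel, "selection_note") %||% "aic"
    )
  })
  dplyr::bind_rows(rows)
}

#' Apply the gene-level exclusion filters
#'
#' Marks genes to be dropped before gene-set aggregation: a gene is excluded
#' when its BMD exceeds the highest tested dose (strict), its BMDU:BMDL ratio
#' exceeds `ratio_cutoff` (strict; a ratio of exactly 40 is retained), no
#' model could be selected, or any of BMD/BMDL/BMDU is undefined.
#'
#' @param results Tibble from [fit_gene_bmds()].
#' @param max_dose Highest tested dose.
#' @param ratio_cutoff BMDU:BMDL exclusion threshold (default 40).
#' @return The input tibble with logical `excluded` and character `reason`
#'   (`"none"`, `"no_converged_model"`, `"no_bmd_in_range"`,
#'   `"bmd_above_max_dose"`, `"bmdu_bmdl_ratio"`).
#' @export
filter_bmd_results <- function(results, max_dose, ratio_cutoff = 40) {
  stopifnot(is.data.frame(results))
  reason <- rep("none", nrow(results))
  no_model <- is.na(results$model)
  reason[no_model] <- "no_converged_model"
  undef <- !no_model &
    (is.na(results$bmd) | is.na(results$bmdl) | is.na(results$bmdu))
  reason[undef] <- "no_bmd_in_range"
  above <- reason == "none" & results$bmd > max_dose
  reason[above] <- "bmd_above_max_dose"
  wide <- reason == "none" & results$bmdu / results$bmdl > ratio_cutoff
  reason[wide] <- "bmdu_bmdl_ratio"
  results$excluded <- reason != "none"
  results$reason <- reason
  as_tibble(results)
}
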