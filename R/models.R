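# Continuous dose-response model suite.
#
# Nine models in the EPA BMDS continuous tradition, constant variance on the
# (log2) response scale. Parameterizations:
#   linear  mu = b0 + b1*d
#   poly2   mu = b0 + b1*d + b2*d^2
#   poly3   mu = b0 + b1*d + b2*d^2 + b3*d^3
#   power   mu = g + beta*d^delta,                 delta in [1, 18]
#   hill    mu = g + v*d^n / (k^n + d^n),          n in (0, 18], k > 0
#   exp2    mu = a*exp(u*d),                        a > 0 (u = s*b, sign free)
#   exp3    mu = a*exp(u*d^c),                      a > 0, c in [1, 18]
#   exp4    mu = a*(c - (c-1)*exp(-b*d)),           a > 0, b > 0, c > 0
#   exp5    mu = a*(c - (c-1)*exp(-(b*d)^g)),       g in [1, 18]
# exp2/exp3 absorb the BMDS adverse-direction sign s and rate b into a single
# signed rate u (u = s*b^c), which keeps the parameter space smooth; the
# reported coefficients are the signed forms. exp4/exp5 encode direction in
# c (> 1 rises towards asymptote a*c, < 1 falls).

.exp_safe <- function(x) exp(pmin(x, 700))

# stable d^n / (k^n + d^n)
.hill_frac <- function(d, k, n) {
  out <- numeric(length(d))
  pos <- d > 0
  out[pos] <- 1 / (1 + (k / d[pos])^n)
  out
}

.model_defs <- list(
  linear = list(
    par_names = c("b0", "b1"),
    mean = function(d, th) th[1] + th[2] * d,
    degree = 1L
  ),
  poly2 = list(
    par_names = c("b0", "b1", "b2"),
    mean = function(d, th) th[1] + th[2] * d + th[3] * d^2,
    degree = 2L
  ),
  poly3 = list(
    par_names = c("b0", "b1", "b2", "b3"),
    mean = function(d, th) th[1] + th[2] * d + th[3] * d^2 + th[4] * d^3,
    degree = 3L
  ),
  power = list(
    par_names = c("g", "beta", "delta"),
    mean = function(d, th) th[1] + th[2] * ifelse(d > 0, d^th[3], 0),
    bounds = function(dm) list(lower = c(-Inf, -Inf, 1),
                               upper = c(Inf, Inf, 18))
  ),
  hill = list(
    par_names = c("g", "v", "k", "n"),
    mean = function(d, th) th[1] + th[2] * .hill_frac(d, th[3], th[4]),
    bounds = function(dm) list(lower = c(-Inf, -Inf, dm * 1e-6, 1e-2),
                               upper = c(Inf, Inf, dm * 1e4, 18))
  ),
  exp2 = list(
    par_names = c("a", "u"),
    mean = function(d, th) th[1] * .exp_safe(th[2] * d),
    bounds = function(dm) list(lower = c(1e-8, -1e4 / dm),
                               upper = c(Inf, 1e4 / dm))
  ),
  exp3 = list(
    par_names = c("a", "u", "c"),
    mean = function(d, th) th[1] * .exp_safe(th[2] * ifelse(d > 0, d^th[3], 0)),
    bounds = function(dm) list(lower = c(1e-8, -Inf, 1),
                               upper = c(Inf, Inf, 18))
  ),
  exp4 = list(
    par_names = c("a", "b", "c"),
    mean = function(d, th) th[1] * (th[3] - (th[3] - 1) * .exp_safe(-th[2] * d)),
    bounds = function(dm) list(lower = c(1e-8, 1e-6 / dm, 1e-4),
                               upper = c(Inf, 1e6 / dm, 1e4))
  ),
  exp5 = list(
    par_names = c("a", "b", "c", "g"),
    mean = function(d, th) {
      th[1] * (th[3] - (th[3] - 1) * .exp_safe(-(ifelse(d > 0, th[2] * d, 0))^th[4]))
    },
    bounds = function(dm) list(lower = c(1e-8, 1e-6 / dm, 1e-4, 1),
                               upper = c(Inf, 1e6 / dm, 1e4, 18))
  )
)

#' Mean response of a dose-response model
#'
#' Evaluates the mean function of one of the nine supported continuous models
#' at the given doses.
#'
#' @param model Model id, one of `tpodr_models()`.
#' @param doses Numeric vector of non-negative doses.
#' @param theta Named or positional numeric parameter vector in the model's
#'   parameterization (see [fit_drc()]).
#' @return Numeric vector of mean responses.
#' @export
drc_mean <- function(model, doses, theta) {
  def <- .model_defs[[match.arg(model, .tpodr_models)]]
  def$mean(doses, unname(theta))
}

#' Supported dose-response model identifiers
#' @return Character vector of the nine model ids.
#' @export
tpodr_models <- function() .tpodr_models

# --- deterministic multistart grids ---------------------------------------
# All starts are functions of data quantiles only (no RNG), so fits are
# reproducible and dose-scale equivariant.

# weighted LS on a fixed basis: returns coefficients (used to seed the
# location/scale parameters once the shape parameters are pinned)
.wls <- function(basis, ybar, w) {
  fit <- tryCatch(stats::lm.wfit(x = basis, y = ybar, w = w),
                  error = function(e) NULL)
  if (is.null(fit)) return(rep(0, ncol(basis)))
  cf <- fit$coefficients
  cf[!is.finite(cf)] <- 0
  cf
}

.model_starts <- function(model, gs) {
  d <- gs$doses; ybar <- gs$means; w <- gs$n_g
  dm <- max(d)
  dpos <- d[d > 0]
  dmid <- stats::median(dpos)
  y0 <- ybar[which.min(d)]
  ym <- ybar[which.max(d)]
  delta <- ym - y0
  s0 <- if (delta >= 0) 1 else -1
  eps <- 1e-6
  a0 <- max(y0, eps)

  switch(model,
    power = {
      deltas <- c(1, 1.5, 2, 3, 4, 6, 8, 12)
      t(vapply(deltas, function(dl) {
        cf <- .wls(cbind(1, ifelse(d > 0, d^dl, 0)), ybar, w)
        c(cf[1], cf[2], dl)
      }, numeric(3)))
    },
    hill = {
      ks <- stats::quantile(dpos, c(0.25, 0.5, 0.75, 1), names = FALSE)
      grid <- expand.grid(k = ks, n = c(1, 4))
      t(mapply(function(k, n) {
        cf <- .wls(cbind(1, .hill_frac(d, k, n)), ybar, w)
        c(cf[1], cf[2], k, n)
      }, grid$k, grid$n))
    },
    exp2 = {
      uh <- if (y0 > 0 && ym > 0 && ym != y0) log(ym / y0) / dm else s0 * 0.1 / dm
      us <- c(uh, uh / 3, 3 * uh, -uh, uh / 10, -uh / 10, 1e-3 / dm, -1e-3 / dm)
      cbind(a0, us)
    },
    exp3 = {
      base_u <- if (y0 > 0 && ym > 0 && ym != y0) log(ym / y0) else s0 * 0.1
      grid <- expand.grid(c = c(1, 2, 4), f = c(1, 0.3))
      st <- t(mapply(function(cc, f) c(a0, f * base_u / dm^cc, cc),
                     grid$c, grid$f))
      rbind(st, c(a0, -base_u / dm, 1), c(a0, -base_u / dm^2, 2))
    },
    exp4 = {
      ch <- min(max(ym / max(y0, eps), 0.01), 100)
      grid <- expand.grid(b = c(1 / dm, 3 / dm, 1 / dmid, 0.3 / dm),
                          c = c(ch, 1 + 2 * (ch - 1)))
      cbind(a0, grid$b, pmin(pmax(grid$c, 2e-4), 1e3))
    },
    exp5 = {
      ch <- min(max(ym / max(y0, eps), 0.01), 100)
      grid <- expand.grid(b = c(1 / dm, 1 / dmid), g = c(1, 2),
                          c = c(ch, 1 + 2 * (ch - 1)))
      cbind(a0, grid$b, pmin(pmax(grid$c, 2e-4), 1e3), grid$g)
    },
    abort(paste0("no multistart grid for model ", model))
  )
}
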