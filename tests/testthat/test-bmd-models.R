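# helper: fabricate a minimal converged drc_fit for selection-cascade tests
fake_fit <- function(model, loglik, npar, gof_p = 0.5, hill_k_flag = FALSE) {
  structure(list(model = model, coef = setNames(rep(1, npar),
                                                paste0("p", seq_len(npar))),
                 sigma = 1, loglik = loglik, aic = 2 * (npar + 1) - 2 * loglik,
                 gof_p = gof_p, hill_k_flag = hill_k_flag, converged = TRUE,
                 n_multistarts_used = 1L,
                 group_stats = list(doses = c(0, 1, 2, 4, 8))),
            class = "drc_fit")
}

test_that("linear fit recovers collinear data exactly", {
  d <- rep(c(0, 1, 2, 4), each = 3)
  y <- 1 + 2 * d
  f <- fit_drc("linear", d, y)
  expect_equal(unname(f$coef), c(1, 2), tolerance = 1e-10)
  expect_lt(f$sigma, 1e-7)
})

test_that("power at its exponent floor nests linear (never worse likelihood)", {
  set.seed(4)
  for (i in 1:5) {
    d <- rep(c(0, 1.5, 3.75, 7.5, 15), each = 4)
    y <- 5 + 0.3 * d + rnorm(length(d), sd = 0.4)
    lin <- fit_drc("linear", d, y)
    pow <- fit_drc("power", d, y)
    expect_gte(pow$loglik, lin$loglik - 1e-6)
  }
})

test_that("noiseless hill data are refit to 1e-4 relative accuracy", {
  d <- c(0, 0.25, 0.5, 1, 2, 4)
  y <- 6 + 2 * d^2 / (1 + d^2)     # gamma=6, v=2, k=1, n=2
  f <- fit_drc("hill", d, y)
  expect_equal(unname(f$coef), c(6, 2, 1, 2), tolerance = 1e-4)
})

test_that("BMD closed forms: linear slope 1.349 with sigma 1 gives BMD 1", {
  # group means exactly on the line, within-group SSE = n so sigma_hat = 1
  d <- rep(c(0, 1, 2, 4), each = 2)
  y <- 1.349 * d + rep(c(1, -1), 4)
  f <- fit_drc("linear", d, y)
  expect_equal(unname(f$coef), c(0, 1.349), tolerance = 1e-10)
  expect_equal(f$sigma, 1, tolerance = 1e-10)
  bd <- compute_bmd(f)
  expect_equal(bd$bmd, 1, tolerance = 1e-6)
  expect_equal(bd$direction, 1)
})

test_that("hill BMD matches its closed-form inversion to 1e-6", {
  set.seed(6)
  d <- rep(c(0, 0.25, 0.5, 1, 2, 4), each = 6)
  y <- 6 + 2 * d^2 / (1 + d^2) + rnorm(length(d), sd = 0.15)
  f <- fit_drc("hill", d, y)
  bd <- compute_bmd(f)
  g <- f$coef
  r <- 1.349 * f$sigma / abs(g["v"])
  closed <- unname(g["k"] * (r / (1 - r))^(1 / g["n"]))
  expect_equal(bd$bmd, closed, tolerance = 1e-6)
})

test_that("negating responses flips direction but preserves the BMD", {
  set.seed(7)
  d <- rep(c(0, 1, 2, 4, 8), each = 5)
  y <- 3 + 0.5 * d + rnorm(length(d), sd = 0.3)
  for (model in c("linear", "hill", "power")) {
    f_up <- fit_drc(model, d, y)
    f_dn <- fit_drc(model, d, -y)
    b_up <- compute_bmd(f_up)
    b_dn <- compute_bmd(f_dn)
    expect_equal(b_up$bmd, b_dn$bmd, tolerance = 1e-5,
                 label = paste(model, "BMD symmetric under negation"))
    expect_equal(b_dn$direction, -b_up$direction)
  }
})

test_that("selection: a single converged candidate is returned unchanged", {
  f <- fake_fit("exp2", loglik = -10, npar = 2)
  sel <- select_best_model(list(f))
  expect_identical(sel$model, "exp2")
  expect_identical(attr(sel, "selection_note"), "aic")
  expect_null(select_best_model(list()))
})

test_that("strong quadratic truth promotes poly2 via the nested chi-square", {
  set.seed(8)
  d <- rep(c(0, 1, 2, 4, 8), each = 6)
  y <- 5 + 0.05 * d + 0.12 * d^2 + rnorm(length(d), sd = 0.3)
  fits <- fit_drc_suite(d, y, models = c("linear", "poly2", "poly3"))
  sel <- select_best_model(fits)
  expect_identical(sel$model, "poly2")

  # oracle: likelihood-ratio statistic from two explicit OLS fits
  n <- length(y)
  sse1 <- sum(stats::resid(stats::lm(y ~ d))^2)
  sse2 <- sum(stats::resid(stats::lm(y ~ d + I(d^2)))^2)
  lr <- n * log(sse1 / sse2)
  expect_lt(pchisq(lr, df = 1, lower.tail = FALSE), 0.05)
  expect_equal(2 * (fits$poly2$loglik - fits$linear$loglik), lr,
               tolerance = 1e-6)
})

test_that("flagged hill winner falls back to next AIC model with GOF p > 0.05", {
  hill <- fake_fit("hill", loglik = 1, npar = 4, hill_k_flag = TRUE)   # AIC 8
  bad <- fake_fit("power", loglik = -0.5, npar = 3, gof_p = 0.01)      # AIC 9
  good <- fake_fit("exp2", loglik = -2, npar = 2, gof_p = 0.4)         # AIC 10
  expect_lt(hill$aic, min(good$aic, bad$aic))
  sel <- select_best_model(list(hill = hill, exp2 = good, power = bad))
  expect_identical(sel$model, "exp2")  # power skipped: GOF p below 0.05
  expect_identical(attr(sel, "selection_note"), "hill_flag_fallback")

  # no acceptable fallback -> explicit no-selection
  sel2 <- select_best_model(list(hill = hill, power = bad))
  expect_null(sel2)
})

test_that("profile bounds bracket the BMD and tighten with sample size", {
  set.seed(9)
  d <- rep(c(0, 1, 2, 4, 8), each = 7)
  y <- 2 + 0.6 * d + rnorm(length(d), sd = 0.5)
  f <- fit_drc("linear", d, y)
  bd <- compute_bmd(f)
  bb <- compute_bmd_bounds(f, bd$bmd)
  expect_true(bb$bmdl <= bd$bmd && bd$bmd <= bb$bmdu)

  # large-sample consistency: n = 2000/group, tiny sigma -> ratio near 1
  d2 <- rep(c(0, 1, 2, 4, 8), each = 2000)
  set.seed(10)
  y2 <- 2 + 0.6 * d2 + rnorm(length(d2), sd = 0.05)
  f2 <- fit_drc("linear", d2, y2)
  bd2 <- compute_bmd(f2)
  bb2 <- compute_bmd_bounds(f2, bd2$bmd)
  expect_lt(bb2$bmdu / bb2$bmdl, 1.05)
})

test_that("linear profile BMDL matches the dense grid-search oracle within 1%", {
  set.seed(12)
  d <- rep(c(0, 1, 2, 4), each = 5)
  y <- 1 + 0.9 * d + rnorm(length(d), sd = 0.6)
  f <- fit_drc("linear", d, y)
  bd <- compute_bmd(f)
  bb <- compute_bmd_bounds(f, bd$bmd)
  oracle <- linear_profile_bmdl_oracle(d, y)
  expect_equal(bb$bmdl, oracle, tolerance = 0.01)
})

test_that("gene filters follow the strict boundary semantics", {
  res <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    model = c("linear", "linear", "linear", "linear", NA, "hill"),
    params = NA_character_,
    bmd = c(10, 10.1, 5, 5, NA, 5),
    bmdl = c(1, 1, 0.1, 0.1 - 1e-9, NA, NA),
    bmdu = c(2, 2, 4, 4.1, NA, 6),
    direction = 1, gof_p = 0.5, selection_note = "aic"
  )
  out <- filter_bmd_results(res, max_dose = 10, ratio_cutoff = 40)
  expect_false(out$excluded[1])                         # BMD = max dose: kept
  expect_equal(out$reason[2], "bmd_above_max_dose")     # 1.01 * max: dropped
  expect_false(out$excluded[3])                         # ratio exactly 40: kept
  expect_equal(out$reason[4], "bmdu_bmdl_ratio")        # ratio > 40: dropped
  expect_equal(out$reason[5], "no_converged_model")
  expect_equal(out$reason[6], "no_bmd_in_range")        # missing BMDL
})

test_that("BMD/BMDL/BMDU are dose-scale equivariant", {
  set.seed(13)
  d <- rep(c(0, 1, 2, 4, 8), each = 6)
  y_hill <- 4 + 2.5 * d / (2 + d) + rnorm(length(d), sd = 0.25)
  cc <- 3.7
  for (model in c("linear", "poly2", "power", "hill", "exp2", "exp4", "exp5")) {
    f1 <- fit_drc(model, d, y_hill)
    f2 <- fit_drc(model, cc * d, y_hill)
    b1 <- compute_bmd(f1)
    b2 <- compute_bmd(f2)
    expect_equal(b2$bmd, cc * b1$bmd, tolerance = 5e-3,
                 label = paste(model, "BMD scales with dose units"))
  }
  f1 <- fit_drc("linear", d, y_hill)
  b1 <- compute_bmd(f1)
  bb1 <- compute_bmd_bounds(f1, b1$bmd)
  f2 <- fit_drc("linear", cc * d, y_hill)
  b2 <- compute_bmd(f2)
  bb2 <- compute_bmd_bounds(f2, b2$bmd)
  expect_equal(bb2$bmdl, cc * bb1$bmdl, tolerance = 1e-3)
  expect_equal(bb2$bmdu, cc * bb1$bmdu, tolerance = 1e-3)
})

test_that("location-family BMDs are invariant to a constant response shift", {
  set.seed(14)
  d <- rep(c(0, 1, 2, 4, 8), each = 6)
  y <- 1 + 1.2 * d / (2 + d) + rnorm(length(d), sd = 0.2)
  for (model in c("linear", "poly2", "poly3", "hill", "power")) {
    b1 <- compute_bmd(fit_drc(model, d, y))
    b2 <- compute_bmd(fit_drc(model, d, y + 50))
    expect_equal(b1$bmd, b2$bmd, tolerance = 1e-4,
                 label = paste(model, "BMD shift-invariant"))
  }
})

test_that("AIC ordering is invariant to rescaling the response units", {
  set.seed(15)
  d <- rep(c(0, 1.5, 3.75, 7.5, 15), each = 7)
  y <- 5 + 1.5 * d / (3 + d) + rnorm(length(d), sd = 0.3)
  f1 <- fit_drc_suite(d, y)
  f2 <- fit_drc_suite(d, 2.5 * y)
  aic1 <- vapply(f1, `[[`, numeric(1), "aic")
  aic2 <- vapply(f2, `[[`, numeric(1), "aic")
  expect_identical(names(sort(aic1)), names(sort(aic2)))
})
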