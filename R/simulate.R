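# Synthetic dose-series experiments with known per-gene ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a minority of genes follow known dose-response curve shapes on the log2 CPM
# scale, noise is Gaussian on that scale with a constant SD of log2(1 + cv)
# (the constant-variance assumption of the modeling stage), counts arise by
# scaling 2^x to a lognormal per-sample library size and rounding, and batch
# effects are additive gene-wise log2 shifts shared within balanced blocks.

# size-safe sample (sample() treats a scalar x as 1:x)
.sample_vec <- function(x, size) x[sample.int(length(x), size)]

.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generator
#'
#' @param design `"mouse_like"` (control + 4 dietary dose levels, n = 7 per
#'   group, two blocking batches) or `"minnow_like"` (control + 10
#'   half-log-spaced water concentrations, n = 8 per group, no batches).
#'   The design picks the defaults below; every field can be overridden.
#' @param n_genes Number of gene features.
#' @param dose_levels Ascending doses; the first must be 0 (control).
#' @param dose_units Unit label for the dose axis.
#' @param n_per_group Samples per dose group (scalar, or one value per level
#'   to emulate dropout).
#' @param frac_responsive Fraction of genes given a real dose response.
#' @param true_model_mix Named weights over `linear`, `hill`, `exp5`, `power`
#'   giving the curve-shape mixture of responsive genes (normalized to 1).
#' @param effect_size_range Range of the absolute response change at the top
#'   dose, in log2 units.
#' @param cv Coefficient of variation of counts; noise on the log2 scale has
#'   SD `log2(1 + cv)`, constant across dose.
#' @param baseline_log2cpm_range Range of baseline expression (log2 CPM);
#'   baselines are then shifted by a common constant so true CPM sums to 1e6.
#' @param library_size_mean Mean per-sample library size (counts).
#' @param n_batches Number of blocking batches (0 or 1 = no batch structure).
#' @param batch_shift_sd SD of the per-gene additive batch shifts (log2).
#' @param n_gene_sets,set_size_range Gene-set annotation to generate.
#' @param n_enriched_sets How many sets are seeded with responsive genes so
#'   that enrichment is detectable; the remainder are drawn uniformly.
#' @param enriched_set_frac Fraction of an enriched set's members drawn from
#'   the responsive genes.
#' @param seed Integer seed; identical configs reproduce identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(design = c("mouse_like", "minnow_like"),
                              n_genes = 2000,
                              dose_levels = NULL,
                              dose_units = NULL,
                              n_per_group = NULL,
                              frac_responsive = 0.1,
                              true_model_mix = c(linear = 0.4, hill = 0.25,
                                                 exp5 = 0.2, power = 0.15),
                              effect_size_range = c(1, 3),
                              cv = 0.25,
                              baseline_log2cpm_range = c(3, 10),
                              library_size_mean = 3e6,
                              n_batches = NULL,
                              batch_shift_sd = NULL,
                              n_gene_sets = 50,
                              set_size_range = c(10, 40),
                              n_enriched_sets = 5,
                              enriched_set_frac = 0.6,
                              seed = 1L) {
  design <- match.arg(design)
  if (design == "mouse_like") {
    dose_levels <- dose_levels %||% c(0, 1.5, 3.75, 7.5, 15)
    dose_units <- dose_units %||% "mg/Kg-bw/day"
    n_per_group <- n_per_group %||% 7L
    n_batches <- n_batches %||% 2L
    batch_shift_sd <- batch_shift_sd %||% 0.3
  } else {
    dose_levels <- dose_levels %||% c(0, 0.00021 * 3.1623^(0:9))
    dose_units <- dose_units %||% "mg/L"
    n_per_group <- n_per_group %||% 8L
    n_batches <- n_batches %||% 0L
    batch_shift_sd <- batch_shift_sd %||% 0
  }
  cfg <- list(
    design = design, n_genes = as.integer(n_genes),
    dose_levels = dose_levels, dose_units = dose_units,
    n_per_group = as.integer(n_per_group),
    frac_responsive = frac_responsive,
    true_model_mix = true_model_mix,
    effect_size_range = effect_size_range, cv = cv,
    baseline_log2cpm_range = baseline_log2cpm_range,
    library_size_mean = library_size_mean,
    n_batches = as.integer(n_batches), batch_shift_sd = batch_shift_sd,
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    n_enriched_sets = as.integer(n_enriched_sets),
    enriched_set_frac = enriched_set_frac,
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  d <- cfg$dose_levels
  if (length(d) < 2) abort("need at least 2 dose levels")
  if (d[1] != 0) abort("the first dose level must be 0 (control)")
  if (any(diff(d) <= 0)) abort("dose_levels must be strictly ascending")
  if (any(cfg$n_per_group < 2)) abort("n_per_group must be at least 2")
  if (!(length(cfg$n_per_group) %in% c(1L, length(d)))) {
    abort("n_per_group must be scalar or one value per dose level")
  }
  if (cfg$frac_responsive < 0 || cfg$frac_responsive > 1) {
    abort("frac_responsive must lie in [0, 1]")
  }
  if (cfg$frac_responsive > 0 && cfg$frac_responsive * cfg$n_genes < 1) {
    abort("frac_responsive * n_genes must be >= 1 when responsive genes are requested")
  }
  mix <- cfg$true_model_mix
  if (is.null(names(mix)) ||
      !all(names(mix) %in% c("linear", "hill", "exp5", "power"))) {
    abort("true_model_mix must be named over linear/hill/exp5/power")
  }
  if (any(mix < 0) || sum(mix) <= 0) abort("true_model_mix weights invalid")
  if (cfg$cv <= 0) abort("cv must be positive")
  invisible(cfg)
}

# deviation-from-baseline curve f(d) with f(0) = 0 and f(dmax) = effect
.truth_curve <- function(model, effect, dose_levels) {
  dmax <- max(dose_levels)
  dpos_min <- min(dose_levels[dose_levels > 0])
  switch(model,
    linear = {
      b <- effect / dmax
      list(f = function(d) b * d, params = list(b = b))
    },
    power = {
      delta <- runif(1, 1, 3)
      list(f = function(d) effect * (d / dmax)^delta,
           params = list(beta = effect / dmax^delta, delta = delta))
    },
    hill = {
      n <- sample(1:4, 1)
      k <- runif(1, dpos_min, dmax / 2)
      v <- effect * (k^n + dmax^n) / dmax^n
      list(f = function(d) v * .hill_frac(d, k, n),
           params = list(v = v, k = k, n = n))
    },
    exp5 = {
      g <- runif(1, 1, 2)
      b <- 1 / (runif(1, 0.2, 0.8) * dmax)
      A <- effect / (1 - exp(-(b * dmax)^g))
      list(f = function(d) A * (1 - exp(-(ifelse(d > 0, b * d, 0))^g)),
           params = list(A = A, b = b, g = g))
    }
  )
}

# analytic BMD of the noiseless deviation curve at target = bmr_factor * sigma
.truth_bmd <- function(model, params, target) {
  with(params, switch(model,
    linear = target / b,
    power = (target / beta)^(1 / delta),
    hill = {
      r <- target / v
      if (r >= 1) NA_real_ else k * (r / (1 - r))^(1 / n)
    },
    exp5 = {
      r <- target / A
      if (r >= 1) NA_real_ else (-log(1 - r))^(1 / g) / b
    }
  ))
}

#' Generate a synthetic dose-response experiment with known truth
#'
#' @param config A [simulation_config()].
#' @return A list with
#'   * `experiment`: a [dr_experiment()] of simulated counts;
#'   * `truth`: a tibble (one row per gene) with `gene_id`, `responsive`,
#'     `model`, `direction`, `effect`, `true_bmd` (analytic BMD of the
#'     noiseless curve at the 1.349-SD benchmark response, using the
#'     configured noise SD; `NA` for non-responsive genes), `params` (JSON),
#'     `true_curve` (JSON array of mean log2 CPM at each dose level), and
#'     `gene_sets` (semicolon-joined ids of sets containing the gene);
#'   * `gene_sets`: named list of member gene-id vectors.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .validate_sim_config(config)
  .with_seed(config$seed, {
    n_genes <- config$n_genes
    doses <- config$dose_levels
    n_levels <- length(doses)
    npg <- if (length(config$n_per_group) == 1) {
      rep(config$n_per_group, n_levels)
    } else config$n_per_group
    sample_dose <- rep(doses, times = npg)
    n_samples <- length(sample_dose)
    sample_id <- sprintf("s%03d_d%02d", seq_len(n_samples),
                         rep(seq_len(n_levels), times = npg) - 1L)
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    sigma <- log2(1 + config$cv)
    target <- .default_bmr_factor * sigma

    # baselines, shifted so the expected realized total CPM is 1e6: the
    # lognormal log2-scale noise inflates the count pool by the Jensen factor
    # E[2^eps] = exp((sigma*ln2)^2 / 2), which must be budgeted for so that
    # the recorded truth curve really is the mean realized log2 CPM
    baseline <- runif(n_genes, config$baseline_log2cpm_range[1],
                      config$baseline_log2cpm_range[2])
    jensen <- exp((sigma * log(2))^2 / 2)
    baseline <- baseline + log2(1e6 / (sum(2^baseline) * jensen))

    n_resp <- round(config$frac_responsive * n_genes)
    resp_idx <- if (n_resp > 0) sort(sample.int(n_genes, n_resp)) else integer(0)
    responsive <- seq_len(n_genes) %in% resp_idx
    mix <- config$true_model_mix / sum(config$true_model_mix)
    model <- rep(NA_character_, n_genes)
    direction <- rep(NA_real_, n_genes)
    effect <- rep(NA_real_, n_genes)
    true_bmd <- rep(NA_real_, n_genes)
    params_json <- rep(NA_character_, n_genes)
    curve_mat <- matrix(rep(baseline, n_levels), nrow = n_genes)

    if (n_resp > 0) {
      model[resp_idx] <- sample(names(mix), n_resp, replace = TRUE,
                                prob = mix)
      direction[resp_idx] <- sample(c(-1, 1), n_resp, replace = TRUE)
      effect[resp_idx] <- runif(n_resp, config$effect_size_range[1],
                                config$effect_size_range[2])
      for (i in resp_idx) {
        tc <- .truth_curve(model[i], effect[i], doses)
        true_bmd[i] <- .truth_bmd(model[i], tc$params, target)
        params_json[i] <- as.character(
          jsonlite::toJSON(tc$params, auto_unbox = TRUE, digits = NA))
        curve_mat[i, ] <- baseline[i] + direction[i] * tc$f(doses)
      }
    }

    # balanced batch blocks: within each dose group, round-robin assignment
    if (config$n_batches >= 2) {
      batch <- unlist(lapply(npg, function(m) {
        rep(paste0("batch", seq_len(config$n_batches)), length.out = m)
      }))
      shift <- matrix(0, n_genes, config$n_batches)
      shift[, -1] <- rnorm(n_genes * (config$n_batches - 1),
                           sd = config$batch_shift_sd)
      batch_idx <- as.integer(factor(batch,
                                     levels = paste0("batch",
                                                     seq_len(config$n_batches))))
    } else {
      batch <- NULL
      shift <- matrix(0, n_genes, 1)
      batch_idx <- rep(1L, n_samples)
    }

    level_idx <- rep(seq_len(n_levels), times = npg)
    x <- curve_mat[, level_idx, drop = FALSE] +
      shift[, batch_idx, drop = FALSE] +
      matrix(rnorm(n_genes * n_samples, sd = sigma), n_genes, n_samples)
    libsize <- rlnorm(n_samples,
                      meanlog = log(config$library_size_mean) - 0.5 * 0.2^2,
                      sdlog = 0.2)
    counts <- round(sweep(2^x, 2, libsize / 1e6, `*`))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(gene_id, sample_id)

    samples <- tibble(sample_id = sample_id, dose = sample_dose)
    if (!is.null(batch)) samples$batch <- batch
    experiment <- dr_experiment(counts, samples, config$dose_units)

    # gene sets: the first n_enriched_sets are seeded with responsive genes
    sizes <- config$set_size_range[1] - 1L +
      sample.int(config$set_size_range[2] - config$set_size_range[1] + 1L,
                 config$n_gene_sets, replace = TRUE)
    gene_sets <- vector("list", config$n_gene_sets)
    names(gene_sets) <- sprintf("SET%04d", seq_len(config$n_gene_sets))
    n_seeded <- min(config$n_enriched_sets, config$n_gene_sets)
    for (s in seq_len(config$n_gene_sets)) {
      size <- min(sizes[s], n_genes)
      if (s <= n_seeded && n_resp > 0) {
        n_from_resp <- min(round(config$enriched_set_frac * size), n_resp)
        members <- c(.sample_vec(gene_id[resp_idx], n_from_resp),
                     .sample_vec(gene_id[-resp_idx],
                                 min(size - n_from_resp, n_genes - n_resp)))
      } else {
        members <- .sample_vec(gene_id, size)
      }
      gene_sets[[s]] <- sort(unique(members))
    }
    membership <- vapply(gene_id, function(g) {
      paste(names(gene_sets)[vapply(gene_sets, function(m) g %in% m,
                                    logical(1))], collapse = ";")
    }, character(1))

    truth <- tibble(
      gene_id = gene_id, responsive = responsive, model = model,
      direction = direction, effect = effect, true_bmd = true_bmd,
      params = params_json,
      true_curve = vapply(seq_len(n_genes), function(i) {
        as.character(jsonlite::toJSON(curve_mat[i, ], digits = NA))
      }, character(1)),
      gene_sets = unname(membership)
    )
    list(experiment = experiment, truth = truth, gene_sets = gene_sets)
  })
}

#' Write a synthetic experiment to disk as plain-text fixtures
#'
#' Emits `counts.tsv` (genes x samples), `samples.csv`, `gene_sets.gmt` and
#' `truth.csv` into `dir`. The files round-trip losslessly through
#' [read_experiment()] and [read_gmt()].
#'
#' @param sim Output of [generate_experiment()].
#' @param dir Target directory (created if missing).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(sim, dir, overwrite = FALSE) {
  stopifnot(is.list(sim), inherits(sim$experiment, "dr_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.csv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.csv")
  )
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0 && !overwrite) {
    abort(paste0("refusing to overwrite existing file(s): ",
                 paste(basename(existing), collapse = ", "),
                 " (set overwrite = TRUE)"))
  }
  write_counts(sim$experiment, paths[["counts"]])
  readr::write_csv(sim$experiment$samples, paths[["samples"]])
  write_gmt(sim$gene_sets, paths[["gmt"]])
  readr::write_csv(sim$truth, paths[["truth"]])
  invisible(paths)
}
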