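# TPOD vs. apical POD concordance: fold differences, 10-fold band,
# potency ranking, dose-unit conversion.

# half-up rounding to one decimal for display values (round() is half-even)
.round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Fold difference between a transcriptomic and an apical POD
#'
#' The absolute fold difference is `max(tpod, apod) / min(tpod, apod)` (always
#' >= 1); `direction` records which POD is more sensitive (smaller), and
#' `within_10fold` whether the two agree within a factor of 10 (boundary
#' inclusive).
#'
#' @param tpod,apod Positive PODs in the same units.
#' @param chemical Optional chemical label.
#' @param tpod_units,apod_units Unit labels; a mismatch is an error (no
#'   cross-media conversion is attempted).
#' @return One-row tibble: `chemical`, `tpod`, `apod`, `fold` (unrounded),
#'   `fold_display` (one decimal, half-up), `direction`
#'   (`tpod_more_sensitive`, `apod_more_sensitive` or `equal`),
#'   `within_10fold`.
#' @examples
#' fold_difference(0.093, 0.01)  # 9.3-fold, apical POD more sensitive
#' @export
fold_difference <- function(tpod, apod, chemical = NA_character_,
                            tpod_units = NULL, apod_units = NULL) {
  if (!is.null(tpod_units) && !is.null(apod_units) &&
      tpod_units != apod_units) {
    abort(paste0("unit mismatch: TPOD in ", tpod_units, ", APOD in ",
                 apod_units))
  }
  if (!is.finite(tpod) || !is.finite(apod) || tpod <= 0 || apod <= 0) {
    abort("both PODs must be positive")
  }
  fold <- max(tpod, apod) / min(tpod, apod)
  direction <- if (tpod < apod) "tpod_more_sensitive"
    else if (apod < tpod) "apod_more_sensitive"
    else "equal"
  tibble(
    chemical = chemical, tpod = tpod, apod = apod,
    fold = fold, fold_display = .round1_half_up(fold),
    direction = direction, within_10fold = fold <= 10
  )
}

#' Most sensitive apical POD for a chemical
#'
#' Selects the record with the minimal value among a chemical's apical PODs;
#' "less than" qualifiers are compared at their printed bound; ties are broken
#' by species name (alphabetical).
#'
#' @param records APOD tibble ([read_apod()]).
#' @param chemical Chemical to look up.
#' @param units Optionally restrict to one unit system (e.g. `"mg/L"` for the
#'   fish assay class vs. `"mg/Kg-bw/day"` for mammals).
#' @return One-row tibble, or a zero-row tibble when no record matches.
#' @export
most_sensitive_apod <- function(records, chemical, units = NULL) {
  df <- records[records$chemical == chemical, ]
  if (!is.null(units)) df <- df[df$units == units, ]
  if (nrow(df) == 0) return(df)
  df <- df[order(df$value, df$species), ]
  df[1, ]
}

#' Concordance summary of TPOD-to-APOD fold differences
#'
#' @param comparisons Tibble of [fold_difference()] rows (optionally several
#'   per chemical).
#' @return One row per chemical: `n`, `mean_fold` (arithmetic mean of absolute
#'   folds), `sd_fold` (sample SD, n-1 denominator; reported as 0 with
#'   `n = 1`), `frac_within_10fold`.
#' @export
concordance_summary <- function(comparisons) {
  stopifnot(nrow(comparisons) >= 1)
  comparisons |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fold = mean(.data$fold),
      sd_fold = if (dplyr::n() > 1) sd(.data$fold) else 0,
      frac_within_10fold = mean(.data$within_10fold),
      .groups = "drop"
    )
}

#' Convert a dietary concentration (ppm) to an intake dose
#'
#' Linear conversion `intake = ppm * factor`, with the per-ppm factor
#' typically calibrated from one printed (ppm, intake) pair as `intake / ppm`.
#'
#' @param ppm Dietary concentration(s), ppm.
#' @param factor Intake per ppm (mg/Kg-bw/day per ppm).
#' @return Intake dose(s) in mg/Kg-bw/day.
#' @examples
#' ppm_to_intake(c(10, 25, 50, 100), factor = 0.15)
#' @export
ppm_to_intake <- function(ppm, factor) {
  if (any(ppm < 0)) abort("ppm must be non-negative")
  if (factor <= 0) abort("factor must be positive")
  ppm * factor
}

#' Rank chemicals by transcriptomic potency
#'
#' Ascending TPOD order = descending potency (a smaller point of departure
#' means a more potent chemical).
#'
#' @param tpods Named numeric vector (chemical -> TPOD) or a tibble with
#'   columns `chemical` and `tpod`.
#' @return Tibble sorted by ascending TPOD with `rank` and a `tied` flag.
#' @export
potency_ranking <- function(tpods) {
  if (is.data.frame(tpods)) {
    df <- tibble(chemical = tpods$chemical, tpod = tpods$tpod)
  } else {
    if (is.null(names(tpods))) abort("tpods must be named by chemical")
    df <- tibble(chemical = names(tpods), tpod = unname(tpods))
  }
  if (anyNA(df$tpod)) abort("TPODs must be defined for ranking")
  df <- df[order(df$tpod, df$chemical), ]
  df$rank <- seq_len(nrow(df))
  df$tied <- duplicated(df$tpod) | duplicated(df$tpod, fromLast = TRUE)
  df
}
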