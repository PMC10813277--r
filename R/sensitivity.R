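#' Single-factor stress sweep over one design variable
#'
#' Evaluates the five grid levels of one variable with all other variables
#' held at the baseline placement, and summarizes the sweep: extrema, the
#' relative stress range 100 * (max - min) / max, and a monotonicity flag
#' (strictly one-directional across all five levels, else `"none"`).
#'
#' @param emulator An `fea_emulator` (or any object with an
#'   [evaluate_stress()]-compatible contract).
#' @param variable Name of the design variable to sweep.
#' @param baseline Baseline placement (default [baseline_config()]).
#' @return A one-row tibble: `variable`, `grid` and `stress_MPa`
#'   (list-columns of 5 values), `min_MPa`, `max_MPa`, `relative_range_pct`
#'   (unrounded), `monotone_flag`.
#' @export
single_factor_sweep <- function(emulator, variable,
                                baseline = baseline_config()) {
  assert_emulator(emulator)
  space <- emulator$space
  if (!variable %in% space$name) {
    stop("unknown variable '", variable, "'; design variables are: ",
         paste(space$name, collapse = ", "), call. = FALSE)
  }
  baseline <- validate_config(baseline, space)
  grid <- space$levels[[match(variable, space$name)]]
  sweep <- baseline[rep(1, length(grid)), , drop = FALSE]
  sweep[[variable]] <- grid
  stress <- evaluate_stress(sweep, emulator)
  summarize_sweep(variable, grid, stress)
}

summarize_sweep <- function(variable, grid, stress) {
  d <- diff(stress)
  flag <- if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else "none"
  tibble::tibble(
    variable = variable,
    grid = list(grid),
    stress_MPa = list(stress),
    min_MPa = min(stress),
    max_MPa = max(stress),
    relative_range_pct = relative_range(stress, rounded = FALSE),
    monotone_flag = flag
  )
}

#' Relative stress range of a sweep
#'
#' The influence statistic used to rank design variables: the difference
#' between the largest and smallest stress over the sweep, as a percentage
#' of the largest — `100 * (max - min) / max`. Scale-invariant: multiplying
#' all stresses by a positive constant leaves it unchanged.
#'
#' @param stress_values Positive stress values over the sweep.
#' @param rounded Round to one decimal for reporting (default TRUE)?
#' @return The percentage in \[0, 100).
#' @examples
#' relative_range(c(14.98, 14.87, 13.81, 13.28, 10.49))  # 30.0
#' @export
relative_range <- function(stress_values, rounded = TRUE) {
  if (max(stress_values) <= 0) {
    stop("relative range requires a positive maximum stress", call. = FALSE)
  }
  pct <- 100 * (max(stress_values) - min(stress_values)) / max(stress_values)
  if (rounded) round(pct, 1) else pct
}

#' Rank design-variable influence from single-factor sweeps
#'
#' Variables without a clear trend (non-monotone across the five grid
#' points) are excluded from the ranking — cortical thickness shows two
#' offsetting effects (stress spreading vs. shrinking cancellous support)
#' and is the canonical exclusion. The remaining variables are ranked by
#' descending relative stress range; ties are broken alphabetically and
#' flagged. Note that single-factor ranges carry some error from the
#' differing scales of the input variables.
#'
#' @param sweeps A tibble of sweep rows (from [single_factor_sweep()] or
#'   [sensitivity_report()]'s `sweeps`).
#' @return An `implant_sensitivity` list: `sweeps`, `ranking` (tibble with
#'   `variable`, `relative_range_pct`, `tie`), `excluded` (tibble with
#'   `variable`, `reason`).
#' @export
rank_influence <- function(sweeps) {
  stopifnot(is.data.frame(sweeps),
            all(c("variable", "relative_range_pct", "monotone_flag") %in%
                  names(sweeps)))
  excluded <- sweeps[sweeps$monotone_flag == "none", c("variable"), drop = FALSE]
  excluded$reason <- "no clear trend"
  ranked <- sweeps[sweeps$monotone_flag != "none", , drop = FALSE]
  ranked <- ranked[order(-ranked$relative_range_pct, ranked$variable), ,
                   drop = FALSE]
  tie <- duplicated(ranked$relative_range_pct) |
    duplicated(ranked$relative_range_pct, fromLast = TRUE)
  ranking <- tibble::tibble(variable = ranked$variable,
                            relative_range_pct = ranked$relative_range_pct,
                            tie = tie)
  structure(list(sweeps = tibble::as_tibble(sweeps),
                 ranking = ranking,
                 excluded = tibble::as_tibble(excluded)),
            class = "implant_sensitivity")
}

#' Full sensitivity analysis on an emulator
#'
#' Runs all six single-factor sweeps at the baseline placement and ranks
#' the variables by influence on cortical stress.
#'
#' @inheritParams single_factor_sweep
#' @return An `implant_sensitivity` (see [rank_influence()]).
#' @examples
#' rep <- sensitivity_report(anchored_emulator())
#' rep$ranking
#' @export
sensitivity_report <- function(emulator, baseline = baseline_config()) {
  assert_emulator(emulator)
  sweeps <- dplyr::bind_rows(lapply(emulator$space$name, function(v) {
    single_factor_sweep(emulator, v, baseline)
  }))
  rank_influence(sweeps)
}

#' @export
print.implant_sensitivity <- function(x, ...) {
  cat("<implant_sensitivity>\n  influence ranking (relative stress range):\n")
  for (i in seq_len(nrow(x$ranking))) {
    cat(sprintf("   %d. %s (%.1f%%)%s\n", i, x$ranking$variable[i],
                x$ranking$relative_range_pct[i],
                if (x$ranking$tie[i]) " [tie]" else ""))
  }
  if (nrow(x$excluded)) {
    cat("  excluded:", paste(x$excluded$variable, "-", x$excluded$reason,
                             collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy sensitivity sweeps: one row per variable and grid level
#' @param x An `implant_sensitivity`.
#' @param ... Unused.
#' @return A long tibble: `variable`, `level`, `stress_MPa`,
#'   `relative_range_pct`, `monotone_flag`.
#' @export
tidy.implant_sensitivity <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(x$sweeps, "variable", "grid", "stress_MPa",
                  "relative_range_pct", "monotone_flag"),
    cols = c("grid", "stress_MPa")
  ) |>
    dplyr::rename(level = "grid")
}
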