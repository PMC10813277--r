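#' Stress-response emulator anchored to published single-factor FEA sweeps
#'
#' Builds a deterministic response function standing in for a full 3-D
#' finite-element solve. It is anchored exactly to the published
#' single-factor sweeps of cortical von Mises stress: for each of the six
#' design variables, the five grid levels and the stress observed when that
#' variable alone moves off the baseline placement. The joint response is
#' composed multiplicatively in ratios to the shared 13.81 MPa baseline,
#'
#'   sigma(x) = region_scale * sigma0 * prod_i f_i(x_i) / sigma0,
#'
#' where f_i is the piecewise-linear interpolant through variable i's anchor
#' table. By construction every single-factor sweep (all other variables at
#' baseline) reproduces the published table exactly; joint variation is a
#' modelling choice — the simplest composition that preserves all six
#' anchors. No extrapolation is allowed beyond the grid ranges.
#'
#' Two companion output channels make a full three-channel simulation result
#' available for pipeline testing; both are synthetic (no published values
#' exist for them): implant stress is a fixed ratio of cortical stress, and
#' deformation is `deformation_compliance * cortical stress / E_cancellous`.
#'
#' @param space The design space the anchors refer to (default six-variable
#'   space; the anchor grids must match its levels).
#' @param region_scale Named positive multipliers per tooth region
#'   (default 1 for all three regions; the published sweeps used a single
#'   geometry).
#' @param noise_cv Default coefficient of variation for [sample_noisy()];
#'   0 means deterministic.
#' @param implant_stress_ratio Synthetic implant-to-cortical stress ratio.
#' @param deformation_compliance Synthetic compliance scaling for the
#'   deformation channel (mm * GPa / MPa).
#' @param anchors Optional override of the anchor tables: a tibble with
#'   columns `variable`, `level`, `stress_MPa`. Grids must match the space
#'   levels and all tables must agree at the baseline (13.81 MPa).
#' @return An object of class `fea_emulator`.
#' @examples
#' emu <- anchored_emulator()
#' evaluate_stress(baseline_config(), emu)  # 13.81
#' @export
anchored_emulator <- function(space = design_space("anterior"),
                              region_scale = c(anterior = 1, premolar = 1, posterior = 1),
                              noise_cv = 0,
                              implant_stress_ratio = 2.0,
                              deformation_compliance = 0.01,
                              anchors = NULL) {
  assert_space(space)
  if (is.null(anchors)) anchors <- default_anchor_tables()
  anchors <- tibble::as_tibble(anchors)
  stopifnot(all(c("variable", "level", "stress_MPa") %in% names(anchors)))
  if (any(region_scale <= 0)) stop("region_scale values must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (implant_stress_ratio <= 0 || deformation_compliance <= 0) {
    stop("output scalings must be positive", call. = FALSE)
  }

  baseline <- baseline_config(space_region(space))
  baseline_stress <- 13.81
  for (nm in space$name) {
    tab <- anchors[anchors$variable == nm, ]
    lv <- space$levels[[match(nm, space$name)]]
    if (nrow(tab) != length(lv) || !isTRUE(all.equal(sort(tab$level), lv))) {
      stop("anchor grid for '", nm, "' does not match the space levels",
           call. = FALSE)
    }
    b <- tab$stress_MPa[match(baseline[[nm]], tab$level)]
    if (!isTRUE(all.equal(b, baseline_stress))) {
      stop("anchor table for '", nm, "' disagrees at the baseline level (",
           b, " != ", baseline_stress, " MPa)", call. = FALSE)
    }
  }

  structure(
    list(space = space,
         anchors = anchors[order(match(anchors$variable, space$name), anchors$level), ],
         baseline = baseline,
         baseline_stress_MPa = baseline_stress,
         region_scale = region_scale,
         noise_cv = noise_cv,
         implant_stress_ratio = implant_stress_ratio,
         deformation_compliance = deformation_compliance,
         material_props = tibble::tibble(
           material = c("implant", "cortical", "cancellous"),
           youngs_modulus_GPa = c(105, 13, 7),
           poisson_ratio = c(0.37, 0.3, 0.3)
         )),
    class = "fea_emulator"
  )
}

# Published cortical von Mises stress for each single-factor sweep, all other
# variables held at the baseline placement. The t_c sweep is genuinely
# non-monotone (two offsetting effects) and is kept as printed.
default_anchor_tables <- function() {
  tibble::tibble(
    variable = rep(c("length", "diameter", "cancellous_modulus",
                     "front_rear_angle", "left_right_angle",
                     "cortical_thickness"), each = 5L),
    level = c(8.5, 10, 11.5, 13, 15,
              3.0, 3.5, 4.0, 4.5, 5.0,
              0.5, 2.0, 4.5, 7.0, 9.5,
              0, 2.5, 5, 7.5, 10,
              0, 2.5, 5, 7.5, 10,
              1.5, 1.75, 2.0, 2.25, 2.5),
    stress_MPa = c(14.98, 14.87, 13.81, 13.28, 10.49,
                   20.08, 16.14, 13.81, 9.91, 8.46,
                   44.53, 22.50, 15.74, 13.81, 12.51,
                   13.81, 13.86, 14.87, 19.94, 24.03,
                   13.81, 15.04, 15.30, 18.81, 23.83,
                   13.81, 9.26, 17.22, 10.04, 11.58)
  )
}

#' @export
print.fea_emulator <- function(x, ...) {
  cat("<fea_emulator> anchored stress-response emulator\n")
  cat("  baseline cortical stress:", x$baseline_stress_MPa, "MPa\n")
  cat("  region:", space_region(x$space),
      "| noise_cv:", x$noise_cv, "\n")
  invisible(x)
}

assert_emulator <- function(emu) {
  if (!inherits(emu, "fea_emulator")) {
    stop("expected an `fea_emulator` (see anchored_emulator())", call. = FALSE)
  }
  invisible(emu)
}

#' Cortical von Mises stress for one or more placements
#'
#' Evaluates the anchored emulator: single-factor ratio interpolants
#' composed multiplicatively around the 13.81 MPa baseline. Exact at every
#' anchor grid point; rejects out-of-range inputs (no extrapolation).
#'
#' @param data A data frame of placements (one row each), or a single
#'   config as returned by [validate_config()].
#' @param emulator An `fea_emulator`.
#' @return Numeric vector of cortical stress in MPa, one per row.
#' @export
evaluate_stress <- function(data, emulator) {
  assert_emulator(emulator)
  design <- validate_design(data, emulator$space)
  stress <- rep(emulator$baseline_stress_MPa, nrow(design))
  for (nm in emulator$space$name) {
    tab <- emulator$anchors[emulator$anchors$variable == nm, ]
    f <- stats::approx(tab$level, tab$stress_MPa, xout = design[[nm]],
                       method = "linear", rule = 1)$y
    stress <- stress * f / emulator$baseline_stress_MPa
  }
  scale <- emulator$region_scale[design$region]
  if (anyNA(scale)) scale[is.na(scale)] <- 1
  unname(stress * as.numeric(scale))
}

#' Full three-channel simulation result for one or more placements
#'
#' Cortical stress from [evaluate_stress()]; implant stress and deformation
#' from the emulator's documented synthetic scalings (no published joint
#' tables exist for those channels).
#'
#' @inheritParams evaluate_stress
#' @return A tibble: the design columns plus `cortical_stress_MPa`,
#'   `implant_stress_MPa` and `deformation_mm`.
#' @export
evaluate_outputs <- function(data, emulator) {
  assert_emulator(emulator)
  design <- validate_design(data, emulator$space)
  cortical <- evaluate_stress(design, emulator)
  design$cortical_stress_MPa <- cortical
  design$implant_stress_MPa <- emulator$implant_stress_ratio * cortical
  design$deformation_mm <-
    emulator$deformation_compliance * cortical / design$cancellous_modulus
  design
}

#' Noisy emulator draw
#'
#' Multiplies each response channel by an independent lognormal factor with
#' unit median and coefficient of variation `noise_cv`, emulating run-to-run
#' solver scatter while preserving positivity. Deterministic for a fixed
#' `(emulator, data, seed)` triple.
#'
#' @inheritParams evaluate_outputs
#' @param seed Integer RNG seed.
#' @param noise_cv Coefficient of variation; defaults to the emulator's own.
#' @return As [evaluate_outputs()].
#' @export
sample_noisy <- function(data, emulator, seed, noise_cv = NULL) {
  assert_emulator(emulator)
  if (is.null(noise_cv)) noise_cv <- emulator$noise_cv
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  out <- evaluate_outputs(data, emulator)
  if (noise_cv == 0) return(out)
  sdlog <- sqrt(log(1 + noise_cv^2))
  channels <- c("cortical_stress_MPa", "implant_stress_MPa", "deformation_mm")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (ch in channels) {
    out[[ch]] <- out[[ch]] * stats::rlnorm(nrow(out), meanlog = 0, sdlog = sdlog)
  }
  out
}

#' Run a design of experiments through the emulator
#'
#' Evaluates every row of a design matrix, preserving row order, and returns
#' the response table that the surrogate-fitting functions consume.
#'
#' @param design An `implant_design` or any data frame of valid placements.
#' @param emulator An `fea_emulator`.
#' @param noise_cv Optional noise level; 0 (default) is deterministic.
#' @param seed RNG seed, used only when `noise_cv > 0`.
#' @return A response tibble: design columns, `region`, and the three
#'   response channels.
#' @examples
#' doe <- taguchi_l25(design_space("anterior"))
#' responses <- run_doe(doe, anchored_emulator())
#' @export
run_doe <- function(design, emulator, noise_cv = 0, seed = 1L) {
  if (noise_cv > 0) {
    sample_noisy(design, emulator, seed = seed, noise_cv = noise_cv)
  } else {
    evaluate_outputs(design, emulator)
  }
}

#' Read / write a response table as CSV
#'
#' Plain UTF-8 CSV with "." decimal separator; columns are the six design
#' variables, `region`, and the three response channels.
#'
#' @param data A response tibble (see [run_doe()]).
#' @param path File path.
#' @return `read_response_table()` returns the tibble; the writer returns
#'   `data` invisibly.
#' @export
write_response_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
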