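#' Build the default six-variable implant placement design space
#'
#' The placement of a dental implant is parameterised by six controllable
#' variables: implant length and diameter, the Young's modulus of the
#' patient's cancellous (inner, porous) bone, the front-rear and left-right
#' placement angles, and the thickness of the cortical (outer, dense) bone.
#' Each variable takes five grid levels spanning its clinically used range;
#' a fixed 100 N masticatory load is applied at the abutment.
#'
#' @param region Tooth region the space applies to: `"anterior"`,
#'   `"premolar"` or `"posterior"`. The region is a categorical tag carried
#'   through designs and fitted surrogates (one surrogate per region); it
#'   does not change the variable grids.
#' @return A tibble of class `implant_space` with one row per design
#'   variable and columns `name`, `unit`, `levels` (list-column of the five
#'   grid values), `lower` and `upper`. Attributes `region` and `load_N`
#'   carry the tooth region and applied load.
#' @examples
#' space <- design_space("anterior")
#' space$levels[[which(space$name == "cancellous_modulus")]]
#' @export
design_space <- function(region = c("anterior", "premolar", "posterior")) {
  if (length(region) != 1L || !is.character(region) ||
      !region %in% c("anterior", "premolar", "posterior")) {
    stop("unknown region ", if (is.character(region)) paste0("'", region[1], "' "),
         "- valid regions are: anterior, premolar, posterior", call. = FALSE)
  }
  vars <- tibble::tibble(
    name = c("length", "diameter", "cancellous_modulus",
             "front_rear_angle", "left_right_angle", "cortical_thickness"),
    unit = c("mm", "mm", "GPa", "degrees", "degrees", "mm"),
    levels = list(
      c(8.5, 10, 11.5, 13, 15),
      c(3.0, 3.5, 4.0, 4.5, 5.0),
      c(0.5, 2.0, 4.5, 7.0, 9.5),
      c(0, 2.5, 5, 7.5, 10),
      c(0, 2.5, 5, 7.5, 10),
      c(1.5, 1.75, 2.0, 2.25, 2.5)
    )
  )
  vars$lower <- vapply(vars$levels, min, numeric(1))
  vars$upper <- vapply(vars$levels, max, numeric(1))
  new_implant_space(vars, region = region, load_N = 100)
}

new_implant_space <- function(vars, region, load_N) {
  stopifnot(is.data.frame(vars),
            all(c("name", "unit", "levels", "lower", "upper") %in% names(vars)))
  if (anyDuplicated(vars$name)) {
    stop("design variable names must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(vars))) {
    lv <- vars$levels[[i]]
    if (any(diff(lv) <= 0)) {
      stop("levels of '", vars$name[i], "' must be strictly increasing",
           call. = FALSE)
    }
  }
  structure(tibble::as_tibble(vars),
            region = region, load_N = load_N,
            class = c("implant_space", class(tibble::tibble())))
}

space_region <- function(space) attr(space, "region", exact = TRUE)

assert_space <- function(space) {
  if (!inherits(space, "implant_space")) {
    stop("expected an `implant_space` (see design_space())", call. = FALSE)
  }
  invisible(space)
}

#' Taguchi L25(5^6) orthogonal-array design
#'
#' Generates the 25-run orthogonal array over six five-level factors used to
#' reduce the full 5^6 factorial to 25 simulation cases. The array is built
#' from the canonical two-generator construction over GF(5): with row index
#' pairs (a, b) running over 0..4 in row-major order, the six columns are
#' a, b, a+b, a+2b, a+3b and a+4b (mod 5), mapped to the sorted grid levels.
#' Every level of every factor occurs exactly five times, and every ordered
#' pair of levels of every factor pair occurs exactly once, so main effects
#' are estimated free of two-factor aliasing.
#'
#' @param space An `implant_space` with exactly six variables of five levels
#'   each (see [design_space()]).
#' @return A tibble of class `implant_design` with 25 rows, one column per
#'   design variable plus `region`; attribute `design_kind = "l25"`. The
#'   output is deterministic: two calls on the same space are identical.
#' @examples
#' doe <- taguchi_l25(design_space("anterior"))
#' table(doe$length)
#' @export
taguchi_l25 <- function(space) {
  assert_space(space)
  if (nrow(space) != 6L) {
    stop("L25 requires exactly 6 variables; space has ", nrow(space),
         call. = FALSE)
  }
  for (i in seq_len(nrow(space))) {
    if (length(space$levels[[i]]) != 5L) {
      stop("L25 requires 5 levels per variable; '", space$name[i],
           "' has ", length(space$levels[[i]]), call. = FALSE)
    }
  }
  ab <- expand.grid(b = 0:4, a = 0:4)[, c("a", "b")]  # row-major in a
  idx <- cbind(ab$a,
               ab$b,
               (ab$a + ab$b) %% 5,
               (ab$a + 2 * ab$b) %% 5,
               (ab$a + 3 * ab$b) %% 5,
               (ab$a + 4 * ab$b) %% 5)
  cols <- lapply(seq_len(6L), function(j) space$levels[[j]][idx[, j] + 1L])
  names(cols) <- space$name
  out <- tibble::as_tibble(cols)
  out$region <- space_region(space)
  structure(out, design_kind = "l25",
            class = c("implant_design", class(tibble::tibble())))
}

#' Full-factorial design over the grid levels
#'
#' Cartesian product of all grid levels in deterministic lexicographic order
#' (the last variable varies fastest). For the default six-variable,
#' five-level space this is 5^6 = 15,625 runs per tooth region.
#'
#' @inheritParams taguchi_l25
#' @return A tibble of class `implant_design` with `prod(level counts)` rows;
#'   attribute `design_kind = "full_factorial"`.
#' @export
full_factorial <- function(space) {
  assert_space(space)
  grids <- rev(stats::setNames(space$levels, space$name))
  out <- tibble::as_tibble(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  out <- out[, space$name, drop = FALSE]
  out$region <- space_region(space)
  structure(out, design_kind = "full_factorial",
            class = c("implant_design", class(tibble::tibble())))
}

#' Validate a candidate placement configuration
#'
#' Checks one placement (one value per design variable) against the design
#' space: the keys must match the variable names exactly and every value
#' must lie within its variable's range. Off-grid values inside the range
#' are allowed — interpolation queries between grid levels are a normal use.
#'
#' @param config A named list, named numeric vector, or one-row data frame
#'   with one value per design variable.
#' @param space An `implant_space`.
#' @return A one-row tibble with the variables in space order plus `region`.
#' @examples
#' validate_config(baseline_config(), design_space("anterior"))
#' @export
validate_config <- function(config, space) {
  assert_space(space)
  if (is.data.frame(config)) {
    if (nrow(config) != 1L) stop("config must be a single placement", call. = FALSE)
    config <- as.list(config[, setdiff(names(config), "region"), drop = FALSE])
  }
  config <- as.list(config)
  missing <- setdiff(space$name, names(config))
  extra <- setdiff(names(config), space$name)
  if (length(missing)) {
    stop("config is missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra)) {
    stop("config has unknown key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(space$name, function(nm) as.numeric(config[[nm]]), numeric(1))
  for (i in seq_along(vals)) {
    if (!is.finite(vals[i]) || vals[i] < space$lower[i] || vals[i] > space$upper[i]) {
      stop(space$name[i], " ", vals[i], " outside [", space$lower[i], ", ",
           space$upper[i], "]", call. = FALSE)
    }
  }
  out <- tibble::as_tibble(as.list(vals))
  out$region <- space_region(space)
  out
}

#' Baseline placement configuration
#'
#' The reference placement used throughout the single-factor analyses:
#' length 11.5 mm, diameter 4.0 mm, cancellous modulus 7.0 GPa, both
#' placement angles 0 degrees, cortical thickness 1.5 mm.
#'
#' @param region Tooth region tag for the returned configuration.
#' @return A one-row tibble with the six variables plus `region`.
#' @export
baseline_config <- function(region = "anterior") {
  validate_config(
    list(length = 11.5, diameter = 4.0, cancellous_modulus = 7.0,
         front_rear_angle = 0, left_right_angle = 0, cortical_thickness = 1.5),
    design_space(region)
  )
}

#' Validate every row of a design against the space
#'
#' @param design A data frame of placements (columns = variable names,
#'   optionally `region`).
#' @param space An `implant_space`.
#' @return The design as a tibble with columns in space order plus `region`;
#'   errors name the first offending row.
#' @export
validate_design <- function(design, space) {
  assert_space(space)
  stopifnot(is.data.frame(design))
  missing <- setdiff(space$name, names(design))
  if (length(missing)) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(space))) {
    v <- design[[space$name[i]]]
    bad <- which(!is.finite(v) | v < space$lower[i] | v > space$upper[i])
    if (length(bad)) {
      stop("row ", bad[1], ": ", space$name[i], " ", v[bad[1]],
           " outside [", space$lower[i], ", ", space$upper[i], "]",
           call. = FALSE)
    }
  }
  out <- tibble::as_tibble(design)
  if (is.null(out$region)) out$region <- space_region(space)
  out[, c(space$name, "region"), drop = FALSE]
}
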