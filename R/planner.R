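#' Assess candidate implant placements against the stress safety threshold
#'
#' The real-time planning layer: predicts cortical von Mises stress for each
#' candidate placement with a fitted surrogate (or the anchored emulator)
#' and classifies it `green` (safe) when the stress is strictly under the
#' threshold — 40 MPa by default — and `red` otherwise. A predicted stress
#' of exactly the threshold is red ("under 40 MPa" is read strictly).
#' Prediction through a fitted polynomial is a constant-time formula
#' evaluation: no simulation occurs at query time.
#'
#' @param candidates A data frame of one or more placements (a single config
#'   or a whole design matrix). Row order is preserved.
#' @param model An `implant_rom` or an `fea_emulator`.
#' @param threshold_MPa Positive safety threshold in MPa (default 40).
#' @param bands Optional multi-band gradation: a named numeric vector of
#'   increasing upper bounds, e.g. `c(safe = 20, caution = 40, danger = Inf)`.
#'   The default two-band rule is `status`-only; bands add a `band` column.
#' @return A tibble of class `implant_assessment`: the candidate columns plus
#'   `cortical_stress_MPa` (and companion channels when the predictor is the
#'   emulator), `status` (`"green"`/`"red"`), `extrapolation_flag`,
#'   `threshold_MPa` and `model_id`; attribute `summary` holds green/red
#'   counts.
#' @examples
#' assess_placement(baseline_config(), anchored_emulator())
#' @export
assess_placement <- function(candidates, model, threshold_MPa = 40,
                             bands = NULL) {
  stopifnot(is.data.frame(candidates))
  if (threshold_MPa <= 0) stop("threshold_MPa must be > 0", call. = FALSE)
  if (inherits(model, "fea_emulator")) {
    out <- evaluate_outputs(candidates, model)
    stress <- out$cortical_stress_MPa
    extrap <- rep(FALSE, nrow(out))
    model_id <- "fea_emulator"
  } else if (inherits(model, "implant_rom")) {
    pred <- predict(model, candidates)
    stress <- as.numeric(pred)
    extrap <- attr(pred, "extrapolated")
    out <- tibble::as_tibble(candidates)
    out$cortical_stress_MPa <- stress
    model_id <- paste0("implant_rom:", model$response, ":", model$region)
  } else {
    stop("model must be an `implant_rom` or an `fea_emulator`", call. = FALSE)
  }
  out$status <- ifelse(stress < threshold_MPa, "green", "red")
  out$extrapolation_flag <- extrap
  out$threshold_MPa <- threshold_MPa
  out$model_id <- model_id
  if (!is.null(bands)) {
    if (is.unsorted(bands, strictly = TRUE)) {
      stop("bands must be strictly increasing upper bounds", call. = FALSE)
    }
    out$band <- names(bands)[pmax(1L, findInterval(stress, bands,
                                                   left.open = FALSE) + 1L)]
  }
  structure(out,
            summary = c(green = sum(out$status == "green"),
                        red = sum(out$status == "red")),
            class = c("implant_assessment", class(tibble::tibble())))
}

#' @rdname assess_placement
#' @details `batch_assess()` is the fault-tolerant batch variant: a row that
#'   fails validation is reported as a warning carrying its row index and
#'   returned with `status = NA`, while all remaining rows are still
#'   assessed.
#' @export
batch_assess <- function(candidates, model, threshold_MPa = 40, bands = NULL) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) {
    out <- assess_placement(candidates, model, threshold_MPa = threshold_MPa,
                            bands = bands)
    return(out)
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    tryCatch(
      assess_placement(candidates[i, , drop = FALSE], model,
                       threshold_MPa = threshold_MPa, bands = bands),
      error = function(e) {
        msg <- sub("^row \\d+: ", "", conditionMessage(e))
        warning("row ", i, ": ", msg, call. = FALSE)
        bad <- tibble::as_tibble(candidates[i, , drop = FALSE])
        bad$cortical_stress_MPa <- NA_real_
        bad$status <- NA_character_
        bad$extrapolation_flag <- NA
        bad$threshold_MPa <- threshold_MPa
        bad$model_id <- NA_character_
        bad
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            summary = c(green = sum(out$status == "green", na.rm = TRUE),
                        red = sum(out$status == "red", na.rm = TRUE)),
            class = c("implant_assessment", class(tibble::tibble())))
}

#' Green/red counts of an assessment
#' @param x An `implant_assessment`.
#' @param ... Unused.
#' @return A tibble with `n`, `green`, `red`, `threshold_MPa`.
#' @export
glance.implant_assessment <- function(x, ...) {
  s <- attr(x, "summary", exact = TRUE)
  tibble::tibble(n = nrow(x), green = unname(s["green"]),
                 red = unname(s["red"]),
                 threshold_MPa = x$threshold_MPa[1] %||% NA_real_)
}
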