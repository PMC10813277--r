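#' Save / load a fitted surrogate as JSON
#'
#' The model file is a versioned JSON document holding the term exponent
#' vectors, coefficients, normalization map, quality report and provenance —
#' everything needed to predict, so a loaded model reproduces the original's
#' predictions exactly.
#'
#' @param model An `implant_rom`.
#' @param path File path for the JSON document.
#' @return `save_rom()` returns `path` invisibly; `load_rom()` returns the
#'   reconstructed `implant_rom`.
#' @export
save_rom <- function(model, path) {
  stopifnot(inherits(model, "implant_rom"))
  var_names <- model$normalization$name
  doc <- list(
    version = "1.0",
    region = model$region,
    response = model$response,
    variables = var_names,
    terms = lapply(seq_len(nrow(model$terms)), function(i) {
      as.integer(unlist(model$terms[i, paste0("e_", var_names)]))
    }),
    coefficients = unname(model$coefficients),
    normalization = list(center = model$normalization$center,
                         halfwidth = model$normalization$halfwidth),
    quality = model$quality[c("cod", "cop", "cv_scheme", "n")],
    provenance = model$provenance[setdiff(names(model$provenance), "settings")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_rom
#' @export
load_rom <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("unreadable model file: ",
                                           conditionMessage(e), call. = FALSE))
  required <- c("version", "region", "response", "variables", "terms",
                "coefficients", "normalization")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop("model file schema violation; missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(doc$version, "1.0")) {
    stop("unknown model file version: ", doc$version, call. = FALSE)
  }
  var_names <- unlist(doc$variables)
  expo <- do.call(rbind, lapply(doc$terms, function(t) as.integer(unlist(t))))
  if (is.null(expo) || ncol(expo) != length(var_names) ||
      nrow(expo) != length(doc$coefficients)) {
    stop("model file schema violation: terms/coefficients mismatch",
         call. = FALSE)
  }
  colnames(expo) <- paste0("e_", var_names)
  terms <- tibble::as_tibble(expo)
  terms$order <- rowSums(expo)
  terms$term <- term_labels(expo, var_names)
  terms <- terms[, c("term", paste0("e_", var_names), "order")]
  normalization <- tibble::tibble(
    name = var_names,
    center = unlist(doc$normalization$center),
    halfwidth = unlist(doc$normalization$halfwidth)
  )
  quality <- if (!is.null(doc$quality)) {
    list(cod = doc$quality$cod %||% NA_real_,
         cop = doc$quality$cop %||% NA_real_,
         cv_scheme = doc$quality$cv_scheme %||% "none",
         n = doc$quality$n %||% NA_integer_)
  } else list(cod = NA_real_, cop = NA_real_, cv_scheme = "none", n = NA_integer_)
  structure(
    list(region = doc$region, response = doc$response, terms = terms,
         coefficients = stats::setNames(as.numeric(unlist(doc$coefficients)),
                                        terms$term),
         normalization = normalization, quality = quality,
         provenance = c(doc$provenance, list(loaded_version = doc$version))),
    class = "implant_rom"
  )
}
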