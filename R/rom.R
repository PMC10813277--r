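#' Polynomial basis terms over the design variables
#'
#' Enumerates monomial basis terms (exponent vectors) up to a maximum total
#' order, deterministically ordered by total order then lexicographically on
#' the exponents. The intercept (all-zero exponents) is always first. With
#' interactions and `max_order = 2` over six variables the basis has
#' 1 + 6 + 6 + 15 = 28 terms.
#'
#' @param max_order Maximum total order (>= 1; default 2).
#' @param interactions Include cross terms (exponents on more than one
#'   variable)? Pure powers are always included.
#' @param var_names Design-variable names (default: the six-variable space).
#' @return A tibble with one row per term: `term` (label), one exponent
#'   column per variable (`e_<name>`), and `order`.
#' @export
polynomial_basis <- function(max_order = 2, interactions = TRUE,
                             var_names = design_space("anterior")$name) {
  stopifnot(max_order >= 1)
  p <- length(var_names)
  grids <- rep(list(0:max_order), p)
  expo <- as.matrix(expand.grid(rev(grids)))[, p:1, drop = FALSE]
  ord <- rowSums(expo)
  keep <- ord <= max_order
  if (!interactions) keep <- keep & (rowSums(expo > 0) <= 1)
  expo <- expo[keep, , drop = FALSE]
  ord <- ord[keep]
  # canonical order: total order, then lexicographic with earlier variables
  # more significant (so linear terms follow the variable order)
  o <- do.call(order, c(list(ord), lapply(seq_len(p), function(j) -expo[, j])))
  expo <- expo[o, , drop = FALSE]
  colnames(expo) <- paste0("e_", var_names)
  out <- tibble::as_tibble(expo)
  out$order <- ord[o]
  out$term <- term_labels(expo, var_names)
  out[, c("term", paste0("e_", var_names), "order")]
}

term_labels <- function(expo, var_names) {
  apply(expo, 1, function(e) {
    if (all(e == 0)) return("(Intercept)")
    parts <- mapply(function(nm, k) {
      if (k == 0) "" else if (k == 1) nm else paste0(nm, "^", k)
    }, var_names, e)
    paste(parts[parts != ""], collapse = ":")
  })
}

# Affine map of each raw variable onto [-1, 1] over the design-space range.
# Raw polynomial bases over variables spanning three orders of magnitude
# (0.5 GPa vs 15 mm) are numerically ill-conditioned without it.
normalization_from_space <- function(space) {
  tibble::tibble(name = space$name,
                 center = (space$lower + space$upper) / 2,
                 halfwidth = (space$upper - space$lower) / 2)
}

normalize_design <- function(design, normalization) {
  out <- lapply(seq_len(nrow(normalization)), function(i) {
    (design[[normalization$name[i]]] - normalization$center[i]) /
      normalization$halfwidth[i]
  })
  m <- do.call(cbind, out)
  colnames(m) <- normalization$name
  m
}

# Model matrix for a term set on normalized variables.
basis_matrix <- function(xnorm, terms) {
  expo <- as.matrix(terms[, paste0("e_", colnames(xnorm)), drop = FALSE])
  m <- matrix(1, nrow(xnorm), nrow(terms))
  for (j in seq_len(nrow(terms))) {
    e <- expo[j, ]
    for (i in which(e > 0)) m[, j] <- m[, j] * xnorm[, i]^e[i]
  }
  colnames(m) <- terms$term
  m
}

#' Fit a polynomial surrogate by ordinary least squares
#'
#' The "1-D CAE solver": a closed-form polynomial in the six normalized
#' placement variables, fitted to a response table by OLS. Variables are
#' mapped onto \[-1, 1\] over the design-space range before basis expansion.
#' The returned model carries its normalization, a quality report
#' (in-sample CoD; cross-validated CoP via [rom_quality()] on demand), and
#' provenance.
#'
#' @param data Response tibble (design columns + response channels), e.g.
#'   from [run_doe()].
#' @param response Response column name (default cortical stress).
#' @param terms Basis term tibble from [polynomial_basis()]; default full
#'   order-2 basis with interactions.
#' @param space Design space defining the normalization (default matches
#'   `data`'s region if possible).
#' @param cv Compute a cross-validated CoP for the quality report
#'   (LOO for n <= 30, else 5-fold)? Default TRUE.
#' @param seed Seed for the k-fold partition (LOO is deterministic anyway).
#' @return An object of class `implant_rom`.
#' @examples
#' doe <- run_doe(taguchi_l25(design_space("anterior")), anchored_emulator())
#' fit <- fit_polynomial(doe, terms = polynomial_basis(2, interactions = FALSE))
#' glance(fit)
#' @export
fit_polynomial <- function(data, response = "cortical_stress_MPa",
                           terms = polynomial_basis(),
                           space = design_space(data$region[1] %||% "anterior"),
                           cv = TRUE, seed = 1L) {
  assert_space(space)
  stopifnot(is.data.frame(data), response %in% names(data))
  y <- data[[response]]
  if (any(!is.finite(y))) stop("response contains non-finite values", call. = FALSE)
  if (nrow(data) < nrow(terms)) {
    stop("n (", nrow(data), ") < number of terms (", nrow(terms), ")",
         call. = FALSE)
  }
  normalization <- normalization_from_space(space)
  xnorm <- normalize_design(data, normalization)
  X <- basis_matrix(xnorm, terms)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient basis; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  model <- structure(
    list(region = data$region[1] %||% space_region(space),
         response = response,
         terms = terms,
         coefficients = stats::setNames(as.numeric(beta), terms$term),
         normalization = normalization,
         quality = list(cod = as.numeric(cod(y, fitted, form = "explained")),
                        cop = NA_real_, cv_scheme = "none", n = nrow(data)),
         provenance = list(design_kind = attr(data, "design_kind") %||% "custom",
                           n = nrow(data), seed = seed,
                           version = "1.0")),
    class = "implant_rom"
  )
  if (cv) {
    q <- rom_quality(model, data, seed = seed)
    model$quality <- list(cod = model$quality$cod, cop = q$cop,
                          cv_scheme = q$cv_scheme, n = q$n,
                          flags = q$flags)
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated quality of a fitted polynomial surrogate
#'
#' Refits the model's term set on each fold complement and scores held-out
#' predictions with the coefficient of prognosis ([cop_cv()]). Folds too
#' small for the full term set fall back to the largest admissible nested
#' basis (terms in canonical order), recorded in the report flags.
#'
#' @param model An `implant_rom`.
#' @param data The response tibble to cross-validate on.
#' @param scheme,k,seed Passed to [cop_cv()].
#' @return A `quality_report`.
#' @export
rom_quality <- function(model, data, scheme = NULL, k = 5, seed = 1L) {
  truncated <- FALSE
  fit_fun <- function(train) {
    terms <- model$terms
    if (nrow(train) < nrow(terms)) {
      terms <- terms[seq_len(nrow(train)), , drop = FALSE]
      truncated <<- TRUE
    }
    fit_polynomial(train, response = model$response, terms = terms,
                   space = space_from_normalization(model), cv = FALSE)
  }
  rep <- cop_cv(data, model$response, fit_fun, scheme = scheme, k = k, seed = seed)
  if (truncated) rep$flags <- c(rep$flags, "fold_basis_truncated")
  rep
}

# Reconstruct an implant_space carrying the model's normalization ranges so
# refits normalize identically to the original fit.
space_from_normalization <- function(model) {
  base <- design_space(if (model$region %in% c("anterior", "premolar", "posterior"))
    model$region else "anterior")
  nm <- model$normalization
  base$lower <- nm$center - nm$halfwidth
  base$upper <- nm$center + nm$halfwidth
  base
}

#' Predict from a fitted polynomial surrogate
#'
#' Evaluates the closed-form polynomial at one or more placements: a pure,
#' effectively instantaneous formula evaluation — no simulation happens at
#' query time. Placements outside the training normalization range are
#' predicted anyway but flagged as extrapolation.
#'
#' @param object An `implant_rom`.
#' @param newdata Data frame of placements.
#' @param ... Unused.
#' @return Numeric predictions with attribute `extrapolated` (logical, one
#'   per row).
#' @export
predict.implant_rom <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  xnorm <- normalize_design(newdata, object$normalization)
  extrap <- apply(abs(xnorm) > 1 + 1e-8, 1, any)
  if (any(extrap)) {
    warning("prediction outside the training range for ", sum(extrap),
            " placement(s); flagged as extrapolation", call. = FALSE)
  }
  X <- basis_matrix(xnorm, object$terms)
  structure(drop(X %*% object$coefficients), extrapolated = unname(extrap))
}

#' @export
print.implant_rom <- function(x, ...) {
  cat("<implant_rom>", x$response, "|", x$region, "region\n")
  cat("  ", length(x$coefficients), "terms, n =", x$quality$n,
      "| CoD =", round(x$quality$cod, 4))
  if (!is.na(x$quality$cop)) cat(" | CoP =", round(x$quality$cop, 4))
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted surrogate: one row per basis term
#' @param x An `implant_rom`.
#' @param ... Unused.
#' @return A tibble with `term`, the exponent columns and `estimate`.
#' @export
tidy.implant_rom <- function(x, ...) {
  out <- x$terms
  out$estimate <- unname(x$coefficients)
  out
}

#' One-row model summary
#' @param x An `implant_rom`.
#' @param ... Unused.
#' @return A tibble with `region`, `response`, `n_terms`, `n`, `cod`,
#'   `cop` and `cv_scheme`.
#' @export
glance.implant_rom <- function(x, ...) {
  tibble::tibble(region = x$region, response = x$response,
                 n_terms = length(x$coefficients), n = x$quality$n,
                 cod = x$quality$cod, cop = x$quality$cop,
                 cv_scheme = x$quality$cv_scheme)
}
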