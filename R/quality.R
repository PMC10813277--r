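#' Coefficient of determination (CoD)
#'
#' In-sample approximation quality of a regression surrogate: the relative
#' amount of response variation explained by the approximation. For
#' predictions from ordinary least squares with an intercept the
#' explained-variance form
#'   CoD = sum((yhat - mean(y))^2) / sum((y - mean(y))^2)
#' is used; it coincides with 1 - SS_res/SS_tot there. For arbitrary
#' predictors the residual form 1 - SS_res/SS_tot is computed and clamped
#' to \[0, 1\]; the form actually used and whether clamping occurred are
#' recorded as attributes `form` and `clamped`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @param form `"explained"` (OLS-with-intercept variance ratio) or
#'   `"residual"` (clamped 1 - SS_res/SS_tot, valid for any predictor).
#' @return The CoD in \[0, 1\] with attributes `form` and `clamped`.
#' @export
cod <- function(observed, predicted, form = c("explained", "residual")) {
  form <- match.arg(form)
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("degenerate response: zero total variance", call. = FALSE)
  if (form == "explained") {
    value <- sum((predicted - mean(observed))^2) / ss_tot
  } else {
    value <- 1 - sum((observed - predicted)^2) / ss_tot
  }
  clamped <- value < 0 || value > 1
  value <- min(max(value, 0), 1)
  structure(value, form = form, clamped = clamped)
}

#' Cross-validation fold assignments
#'
#' @param n Number of observations (>= 2).
#' @param scheme `"loo"` (leave-one-out: n singleton folds) or `"kfold"`.
#' @param k Number of folds for `"kfold"`; fold sizes differ by at most 1.
#' @param seed Integer seed controlling the k-fold permutation; LOO ignores
#'   it. Deterministic given the seed.
#' @return Integer vector of fold ids, one per observation.
#' @export
make_folds <- function(n, scheme = c("loo", "kfold"), k = 5, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 2)
  if (scheme == "loo") return(seq_len(n))
  if (k > n) stop("k (", k, ") exceeds n (", n, ")", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- rep_len(seq_len(k), n)[sample.int(n)]
  fold
}

#' Coefficient of prognosis (CoP) by cross-validation
#'
#' Predictive (as opposed to descriptive) quality of a surrogate: the data
#' are partitioned into folds; for each fold the surrogate is refit on the
#' complement and used to predict the held-out rows; the CoP is the squared
#' Pearson correlation between all pooled held-out observations and their
#' predictions, clamped to \[0, 1\]. Pooling a single correlation over all
#' out-of-sample pairs keeps the statistic well defined for singleton folds
#' (leave-one-out), which per-fold correlations cannot handle. If the pooled
#' predictions are constant the correlation is degenerate and the CoP is 0
#' by convention.
#'
#' @param data A response tibble (design columns plus response channels).
#' @param response Name of the response column.
#' @param fit_fun A function `(train_data) -> model` where the model has a
#'   `predict(model, newdata)` method returning numeric predictions. Any
#'   fit-then-predict surrogate satisfies the contract.
#' @param scheme,k,seed Passed to [make_folds()]. The default scheme is LOO
#'   for n <= 30, else 5-fold.
#' @return A `quality_report` list: `cop`, `cod` (full-data fit, residual
#'   form), `n`, `cv_scheme`, `fold_assignments`, `response`, `flags`.
#' @export
cop_cv <- function(data, response, fit_fun,
                   scheme = NULL, k = 5, seed = 1L) {
  stopifnot(is.data.frame(data), response %in% names(data))
  n <- nrow(data)
  if (is.null(scheme)) scheme <- if (n <= 30) "loo" else "kfold"
  folds <- make_folds(n, scheme, k = k, seed = seed)
  y <- data[[response]]
  yhat <- rep(NA_real_, n)
  flags <- character(0)
  for (f in unique(folds)) {
    hold <- folds == f
    model <- fit_fun(data[!hold, , drop = FALSE])
    yhat[hold] <- as.numeric(stats::predict(model, data[hold, , drop = FALSE]))
  }
  if (stats::sd(yhat) == 0 || stats::sd(y) == 0) {
    cop <- 0
    flags <- c(flags, "degenerate_correlation")
  } else {
    cop <- min(max(stats::cor(y, yhat)^2, 0), 1)
  }
  full_model <- fit_fun(data)
  full_pred <- as.numeric(stats::predict(full_model, data))
  cod_full <- cod(y, full_pred, form = "residual")
  structure(
    list(cop = cop,
         cod = as.numeric(cod_full),
         n = n,
         cv_scheme = if (scheme == "kfold") paste0("kfold(", k, ")") else scheme,
         fold_assignments = folds,
         response = response,
         flags = c(flags, if (attr(cod_full, "clamped")) "cod_clamped")),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>", x$response, "\n")
  cat(sprintf("  CoP = %.4f (%s, n = %d) | CoD = %.4f\n",
              x$cop, x$cv_scheme, x$n, x$cod))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
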