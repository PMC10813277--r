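#' Settings for genetic-algorithm basis-subset selection
#'
#' Hyperparameters of the GA used by [gars_select()]. Defaults are standard
#' small-GA settings sized so a full run on a 25-point design completes in
#' seconds: tournament selection (size 2), uniform crossover, bit-flip
#' mutation at rate 1/chromosome-length, two elites carried over unchanged.
#'
#' @param population Population size (>= 4).
#' @param generations Number of generations.
#' @param crossover_prob Uniform-crossover probability per mating pair.
#' @param mutation_prob Per-bit flip probability; `NULL` means
#'   1/chromosome-length.
#' @param elitism Number of elites (< population).
#' @param fitness Cross-validation scheme used for the CoP fitness:
#'   `"cop_loo"` or `"cop_kfold"`.
#' @param k Folds when `fitness = "cop_kfold"`.
#' @param seed Integer seed; identical settings and seed give identical
#'   selections.
#' @param candidate_max_order Maximum order of the candidate basis.
#' @return A `gars_settings` list.
#' @export
gars_settings <- function(population = 40, generations = 60,
                          crossover_prob = 0.9, mutation_prob = NULL,
                          elitism = 2, fitness = c("cop_loo", "cop_kfold"),
                          k = 5, seed = 1L, candidate_max_order = 2) {
  fitness <- match.arg(fitness)
  stopifnot(population >= 4, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            is.null(mutation_prob) || (mutation_prob >= 0 && mutation_prob <= 1),
            elitism >= 0, elitism < population)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism = as.integer(elitism),
                 fitness = fitness, k = k, seed = as.integer(seed),
                 candidate_max_order = candidate_max_order),
            class = "gars_settings")
}

# Exact leave-one-out predictions for an OLS fit via the hat-matrix identity
# yhat(-i) = y_i - e_i / (1 - h_ii). One QR per term set instead of n refits;
# identical to the brute-force refit loop (tested against it).
loo_predictions_ols <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NULL)
  beta <- qr.coef(qrX, y)
  e <- y - drop(X %*% beta)
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  if (any(h >= 1 - 1e-10)) return(NULL)  # a point its own sole support
  y - e / (1 - h)
}

# CoP of the OLS fit restricted to one term subset (intercept always in).
gars_fitness <- function(chrom, X_all, y, settings, fold_ids) {
  cols <- c(1L, which(chrom) + 1L)
  n <- length(y)
  if (length(cols) >= n) return(-1)  # oversized subset: penalized, never fit
  X <- X_all[, cols, drop = FALSE]
  if (settings$fitness == "cop_loo") {
    yhat <- loo_predictions_ols(X, y)
    if (is.null(yhat)) return(-1)
  } else {
    yhat <- rep(NA_real_, n)
    for (f in unique(fold_ids)) {
      hold <- fold_ids == f
      if (sum(!hold) < length(cols)) return(-1)
      qrX <- qr(X[!hold, , drop = FALSE])
      if (qrX$rank < length(cols)) return(-1)
      beta <- qr.coef(qrX, y[!hold])
      yhat[hold] <- drop(X[hold, , drop = FALSE] %*% beta)
    }
  }
  if (stats::sd(yhat) == 0) return(0)
  min(max(stats::cor(y, yhat)^2, 0), 1)
}

# TRUE if chromosome a beats b under the deterministic ordering:
# higher fitness, then fewer terms (parsimony), then lexicographically
# smaller bit string.
gars_better <- function(fa, a, fb, b) {
  if (fa != fb) return(fa > fb)
  if (sum(a) != sum(b)) return(sum(a) < sum(b))
  d <- which(a != b)
  if (!length(d)) return(FALSE)
  !a[d[1]]  # 0 before 1 lexicographically
}

#' Genetic-algorithm selection of a robust polynomial term subset
#'
#' Searches over subsets of a candidate polynomial basis for the subset
#' whose OLS fit maximizes the cross-validated coefficient of prognosis —
#' i.e. it optimizes predictive rather than in-sample quality, guarding
#' against the overfitting a full interaction basis invites on a 25-run
#' design. Chromosomes are inclusion bit-strings over the non-intercept
#' candidate terms (the intercept is always included); fitness is the CoP
#' of the restricted OLS fit; selection is by binary tournament, with
#' uniform crossover, bit-flip mutation and elitism. Oversized subsets
#' (more terms than training rows) are penalized, never fitted. Ties are
#' broken toward fewer terms, then the lexicographically smallest
#' chromosome, so the search is deterministic given the seed.
#'
#' @param data Response tibble (e.g. from [run_doe()]).
#' @param response Response column name.
#' @param settings A [gars_settings()] object.
#' @param space Design space for normalization.
#' @param candidate_terms Candidate basis; default the full
#'   order-`candidate_max_order` basis with interactions.
#' @return An `implant_rom` refit on all data with the selected terms; its
#'   `provenance` records the GA settings, seed and best fitness.
#' @examples
#' doe <- run_doe(taguchi_l25(design_space("anterior")), anchored_emulator())
#' fit <- gars_select(doe, settings = gars_settings(population = 12, generations = 8))
#' @export
gars_select <- function(data, response = "cortical_stress_MPa",
                        settings = gars_settings(),
                        space = design_space(data$region[1] %||% "anterior"),
                        candidate_terms = NULL) {
  assert_space(space)
  stopifnot(is.data.frame(data), response %in% names(data))
  if (is.null(candidate_terms)) {
    candidate_terms <- polynomial_basis(settings$candidate_max_order,
                                        interactions = TRUE,
                                        var_names = space$name)
  }
  if (candidate_terms$order[1] != 0) {
    stop("candidate basis must include the intercept", call. = FALSE)
  }
  y <- data[[response]]
  n <- length(y)
  if (n < 2) stop("need at least 2 rows", call. = FALSE)
  normalization <- normalization_from_space(space)
  X_all <- basis_matrix(normalize_design(data, normalization), candidate_terms)
  L <- nrow(candidate_terms) - 1L  # chromosome length (non-intercept terms)
  pmut <- settings$mutation_prob %||% (1 / L)
  fold_ids <- if (settings$fitness == "cop_kfold") {
    make_folds(n, "kfold", k = settings$k, seed = settings$seed)
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(settings$seed)

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(chrom) {
    key <- rawToChar(as.raw(45L + chrom))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- gars_fitness(chrom, X_all, y, settings, fold_ids)
    cache[[key]] <- f
    f
  }

  # Initial population: random inclusion at rate 0.3, plus the linear-only
  # chromosome as a sensible seed individual.
  pop <- lapply(seq_len(settings$population), function(i) {
    stats::runif(L) < 0.3
  })
  linear_only <- candidate_terms$order[-1] == 1
  pop[[1]] <- linear_only
  fit <- vapply(pop, fitness_of, numeric(1))

  best_chrom <- NULL
  best_fit <- -Inf
  update_best <- function(chrom, f) {
    if (is.null(best_chrom) || gars_better(f, chrom, best_fit, best_chrom)) {
      best_chrom <<- chrom
      best_fit <<- f
    }
  }
  for (i in seq_along(pop)) update_best(pop[[i]], fit[i])

  for (gen in seq_len(settings$generations)) {
    ord <- order(-fit, vapply(pop, sum, numeric(1)))
    elites <- pop[ord[seq_len(settings$elitism)]]
    children <- elites
    while (length(children) < settings$population) {
      pick <- function() {
        ij <- sample.int(settings$population, 2)
        if (gars_better(fit[ij[1]], pop[[ij[1]]], fit[ij[2]], pop[[ij[2]]]))
          pop[[ij[1]]] else pop[[ij[2]]]
      }
      p1 <- pick(); p2 <- pick()
      if (stats::runif(1) < settings$crossover_prob) {
        mask <- stats::runif(L) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        flip <- stats::runif(L) < pmut
        child <- xor(child, flip)
        children[[length(children) + 1L]] <- child
        if (length(children) >= settings$population) break
      }
    }
    pop <- children
    fit <- vapply(pop, fitness_of, numeric(1))
    for (i in seq_along(pop)) update_best(pop[[i]], fit[i])
  }

  selected <- candidate_terms[c(TRUE, best_chrom), , drop = FALSE]
  model <- fit_polynomial(data, response = response, terms = selected,
                          space = space, cv = FALSE, seed = settings$seed)
  model$quality <- list(
    cod = model$quality$cod,
    cop = max(best_fit, 0),
    cv_scheme = if (settings$fitness == "cop_loo") "loo"
                else paste0("kfold(", settings$k, ")"),
    n = n, flags = character(0)
  )
  model$provenance <- c(model$provenance,
                        list(method = "gars",
                             settings = unclass(settings),
                             best_fitness = best_fit,
                             candidate_terms = nrow(candidate_terms)))
  model
}
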