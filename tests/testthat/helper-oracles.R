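# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force enumeration, explicit normal
# equations, refit loops.

# Published single-factor cortical stress sweeps (grid level -> MPa),
# transcribed independently of the package's anchor tables.
published_sweeps <- list(
  length = list(grid = c(8.5, 10, 11.5, 13, 15),
                stress = c(14.98, 14.87, 13.81, 13.28, 10.49)),
  diameter = list(grid = c(3.0, 3.5, 4.0, 4.5, 5.0),
                  stress = c(20.08, 16.14, 13.81, 9.91, 8.46)),
  cancellous_modulus = list(grid = c(0.5, 2.0, 4.5, 7.0, 9.5),
                            stress = c(44.53, 22.50, 15.74, 13.81, 12.51)),
  front_rear_angle = list(grid = c(0, 2.5, 5, 7.5, 10),
                          stress = c(13.81, 13.86, 14.87, 19.94, 24.03)),
  left_right_angle = list(grid = c(0, 2.5, 5, 7.5, 10),
                          stress = c(13.81, 15.04, 15.30, 18.81, 23.83)),
  cortical_thickness = list(grid = c(1.5, 1.75, 2.0, 2.25, 2.5),
                            stress = c(13.81, 9.26, 17.22, 10.04, 11.58))
)

# Normal-equations OLS solve: beta = (X'X)^-1 X'y.
oracle_ols <- function(X, y) solve(crossprod(X), crossprod(X, y))

# Brute-force leave-one-out predictions by literal refitting.
oracle_loo <- function(X, y) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    b <- oracle_ols(X[-i, , drop = FALSE], y[-i])
    drop(X[i, , drop = FALSE] %*% b)
  }, numeric(1))
}

# Uniformly random in-range design of n placements, seeded.
random_design <- function(n, seed, region = "anterior") {
  space <- design_space(region)
  set.seed(seed)
  d <- tibble::as_tibble(lapply(stats::setNames(seq_len(nrow(space)), space$name),
                                function(i) stats::runif(n, space$lower[i],
                                                         space$upper[i])))
  d$region <- region
  d
}

# A sparse polynomial ground truth on the normalized variables:
# y = 10 + 4*length~ - 3*cancellous_modulus~ + 2*length~*diameter~
sparse_truth <- function(design) {
  space <- design_space("anterior")
  center <- (space$lower + space$upper) / 2
  half <- (space$upper - space$lower) / 2
  nz <- function(nm) {
    i <- match(nm, space$name)
    (design[[nm]] - center[i]) / half[i]
  }
  10 + 4 * nz("length") - 3 * nz("cancellous_modulus") +
    2 * nz("length") * nz("diameter")
}

sparse_truth_terms <- c("length", "cancellous_modulus", "length:diameter")

# Exhaustive-subset oracle: evaluate every subset of the non-intercept
# candidate terms with the same LOO-CoP fitness and the same deterministic
# tie-break (higher fitness, then fewer terms, then lexicographically
# smallest chromosome).
exhaustive_best_subset <- function(data, response, candidate_terms) {
  space <- design_space("anterior")
  center <- (space$lower + space$upper) / 2
  half <- (space$upper - space$lower) / 2
  xn <- sapply(seq_len(6), function(i)
    (data[[space$name[i]]] - center[i]) / half[i])
  colnames(xn) <- space$name
  expo <- as.matrix(candidate_terms[, paste0("e_", space$name)])
  X_all <- sapply(seq_len(nrow(expo)), function(j) {
    v <- rep(1, nrow(data))
    for (i in which(expo[j, ] > 0)) v <- v * xn[, i]^expo[j, i]
    v
  })
  y <- data[[response]]
  L <- nrow(candidate_terms) - 1L
  best <- NULL
  for (code in 0:(2^L - 1)) {
    chrom <- as.logical(bitwAnd(code, 2^(0:(L - 1))) > 0)
    cols <- c(1L, which(chrom) + 1L)
    if (length(cols) >= length(y)) next
    X <- X_all[, cols, drop = FALSE]
    yhat <- tryCatch(oracle_loo(X, y), error = function(e) NULL)
    if (is.null(yhat)) next
    f <- if (stats::sd(yhat) == 0) 0 else min(max(stats::cor(y, yhat)^2, 0), 1)
    cand <- list(chrom = chrom, fitness = f)
    if (is.null(best)) { best <- cand; next }
    better <- if (f != best$fitness) f > best$fitness
      else if (sum(chrom) != sum(best$chrom)) sum(chrom) < sum(best$chrom)
      else {
        d <- which(chrom != best$chrom)
        length(d) > 0 && !chrom[d[1]]
      }
    if (isTRUE(better)) best <- cand
  }
  best
}
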