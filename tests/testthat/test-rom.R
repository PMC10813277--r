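test_that("basis enumeration has the expected sizes and canonical order", {
  b2 <- polynomial_basis(2, interactions = TRUE)
  expect_equal(nrow(b2), 28)  # 1 + 6 linear + 6 squares + 15 cross
  expect_equal(nrow(polynomial_basis(1)), 7)
  expect_equal(nrow(polynomial_basis(2, interactions = FALSE)), 13)
  expect_identical(b2$term[1], "(Intercept)")
  expect_true(all(diff(b2$order) >= 0))
  expect_identical(polynomial_basis(2), polynomial_basis(2))
})

test_that("a noise-free linear response is recovered exactly", {
  d <- random_design(20, seed = 8)
  space <- design_space("anterior")
  xnorm <- (d$length - (8.5 + 15) / 2) / ((15 - 8.5) / 2)
  d$y <- 2 + 3 * xnorm
  fit <- fit_polynomial(d, response = "y", terms = polynomial_basis(1),
                        cv = FALSE)
  est <- coef <- fit$coefficients
  expect_equal(unname(est["(Intercept)"]), 2, tolerance = 1e-10)
  expect_equal(unname(est["length"]), 3, tolerance = 1e-10)
  expect_equal(unname(est[setdiff(names(est), c("(Intercept)", "length"))]),
               rep(0, 5), tolerance = 1e-8)
  expect_equal(fit$quality$cod, 1, tolerance = 1e-12)
  # grid predictions match the generating function exactly
  doe <- taguchi_l25(space)
  pred <- predict(fit, doe)
  expect_equal(as.numeric(pred),
               2 + 3 * (doe$length - 11.75) / 3.25, tolerance = 1e-10)
})

test_that("OLS coefficients equal the normal-equations oracle on a toy quadratic", {
  d <- random_design(9, seed = 12)
  d$y <- sparse_truth(d) + c(0.3, -0.2, 0.1, 0, -0.1, 0.2, -0.3, 0.15, -0.05)
  terms <- polynomial_basis(2, interactions = FALSE)[1:5, ]
  fit <- fit_polynomial(d, response = "y", terms = terms, cv = FALSE)
  # oracle: build the same normalized design matrix by hand, solve X'X b = X'y
  space <- design_space("anterior")
  xn <- sapply(seq_len(6), function(i)
    (d[[space$name[i]]] - (space$lower[i] + space$upper[i]) / 2) /
      ((space$upper[i] - space$lower[i]) / 2))
  X <- cbind(1, xn[, 1], xn[, 2], xn[, 3], xn[, 4])
  expect_equal(unname(fit$coefficients), drop(oracle_ols(X, d$y)),
               tolerance = 1e-9)
})

test_that("perturbing any fitted coefficient increases the residual sum of squares", {
  d <- random_design(15, seed = 13)
  d$y <- sparse_truth(d) + rnorm(15, sd = 0.4)
  fit <- fit_polynomial(d, response = "y", terms = polynomial_basis(1),
                        cv = FALSE)
  rss <- function(coefs) {
    m <- fit
    m$coefficients <- coefs
    sum((d$y - as.numeric(predict(m, d)))^2)
  }
  base_rss <- rss(fit$coefficients)
  for (j in seq_along(fit$coefficients)) {
    for (delta in c(-0.05, 0.05)) {
      perturbed <- fit$coefficients
      perturbed[j] <- perturbed[j] + delta
      expect_gt(rss(perturbed), base_rss)
    }
  }
})

test_that("degenerate fits are rejected informatively", {
  d <- random_design(10, seed = 14)
  d$y <- sparse_truth(d)
  expect_error(fit_polynomial(d, response = "y", terms = polynomial_basis(2)),
               "< number of terms")
  d$length <- 11.5  # constant column makes its basis term collinear
  expect_error(fit_polynomial(d, response = "y", terms = polynomial_basis(1)),
               "collinear")
})

test_that("an intercept-only model predicts its constant everywhere", {
  d <- random_design(5, seed = 15)
  d$y <- rep(13.81, 5) + rnorm(5, sd = 1)
  fit <- fit_polynomial(d, response = "y", terms = polynomial_basis(1)[1, ],
                        cv = FALSE)
  pred <- predict(fit, random_design(7, seed = 16))
  expect_equal(as.numeric(pred), rep(mean(d$y), 7), tolerance = 1e-10)
})

test_that("fit-then-predict on L25 emulator data round-trips near the baseline anchor", {
  # the emulator's log response is additive with degree <= 4 per variable,
  # so the order-4 pure-power basis (25 terms on 25 runs) represents it
  # exactly and the round trip through fit + predict recovers the anchor
  res <- run_doe(taguchi_l25(design_space("anterior")), anchored_emulator())
  res$log_stress <- log(res$cortical_stress_MPa)
  fit <- fit_polynomial(res, response = "log_stress",
                        terms = polynomial_basis(4, interactions = FALSE),
                        cv = FALSE)
  pred <- exp(as.numeric(predict(fit, baseline_config())))
  expect_lt(abs(pred - 13.81) / 13.81, 0.10)
  expect_equal(pred, 13.81, tolerance = 1e-8)
})

test_that("in-sample CoD grows under basis nesting on emulator data", {
  d <- random_design(80, seed = 17)
  res <- run_doe(d, anchored_emulator())
  cods <- vapply(list(polynomial_basis(1),
                      polynomial_basis(2, interactions = FALSE),
                      polynomial_basis(2, interactions = TRUE)),
                 function(tt) fit_polynomial(res, terms = tt, cv = FALSE)$quality$cod,
                 numeric(1))
  expect_true(all(diff(cods) >= -1e-12))
  expect_gt(cods[3], 0.8)
})

test_that("predictions outside the training range are flagged, not refused", {
  d <- random_design(20, seed = 18)
  d$y <- sparse_truth(d)
  fit <- fit_polynomial(d, response = "y", terms = polynomial_basis(1),
                        cv = FALSE)
  # shrink the normalization so the baseline lies outside it
  fit$normalization$halfwidth <- fit$normalization$halfwidth / 10
  expect_warning(pred <- predict(fit, baseline_config()), "extrapolation")
  expect_true(attr(pred, "extrapolated"))
})

test_that("normalization absorbs affine changes of raw units", {
  d <- random_design(30, seed = 19)
  d$y <- sparse_truth(d) + rnorm(30, sd = 0.2)
  fit <- fit_polynomial(d, response = "y", terms = polynomial_basis(2, FALSE),
                        cv = FALSE)
  # express length in centimetres: rescale data and normalization together
  d_cm <- d
  d_cm$length <- d$length / 10
  fit_cm <- fit
  fit_cm$normalization$center[1] <- fit$normalization$center[1] / 10
  fit_cm$normalization$halfwidth[1] <- fit$normalization$halfwidth[1] / 10
  q <- random_design(5, seed = 20)
  q_cm <- q
  q_cm$length <- q$length / 10
  expect_equal(as.numeric(predict(fit, q)),
               as.numeric(predict(fit_cm, q_cm)), tolerance = 1e-10)
})

test_that("models round-trip through JSON with identical predictions", {
  res <- run_doe(taguchi_l25(design_space("anterior")), anchored_emulator())
  fit <- fit_polynomial(res, terms = polynomial_basis(2, interactions = FALSE),
                        cv = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  save_rom(fit, path)
  back <- load_rom(path)
  doe <- taguchi_l25(design_space("anterior"))
  expect_equal(as.numeric(predict(back, doe)), as.numeric(predict(fit, doe)),
               tolerance = 1e-12)
  expect_identical(back$provenance$loaded_version, "1.0")

  # truncated document -> schema error
  txt <- readLines(path)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 40), bad)
  expect_error(load_rom(bad), "unreadable|schema")
  # missing field -> schema error
  doc <- jsonlite::read_json(path)
  doc$coefficients <- NULL
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad2, auto_unbox = TRUE)
  expect_error(load_rom(bad2), "missing field")
})

test_that("tidy and glance summarize a fitted model", {
  res <- run_doe(taguchi_l25(design_space("anterior")), anchored_emulator())
  fit <- fit_polynomial(res, terms = polynomial_basis(1), cv = TRUE)
  td <- tidy(fit)
  expect_equal(nrow(td), 7)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 25)
  expect_true(gl$cod >= 0 && gl$cod <= 1)
  expect_true(gl$cop >= 0 && gl$cop <= 1)
})
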