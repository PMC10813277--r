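test_that("every single-factor sweep reproduces the published table exactly", {
  emu <- anchored_emulator()
  base <- baseline_config()
  for (nm in names(published_sweeps)) {
    tab <- published_sweeps[[nm]]
    sweep <- base[rep(1, 5), ]
    sweep[[nm]] <- tab$grid
    expect_equal(evaluate_stress(sweep, emu), tab$stress,
                 tolerance = 1e-12, label = nm)
  }
})

test_that("all anchor tables agree at the 13.81 MPa baseline", {
  emu <- anchored_emulator()
  expect_equal(evaluate_stress(baseline_config(), emu), 13.81)
  base <- baseline_config()
  for (nm in emu$space$name) {
    tab <- emu$anchors[emu$anchors$variable == nm, ]
    expect_equal(tab$stress_MPa[match(base[[nm]], tab$level)], 13.81,
                 label = nm)
  }
  # an anchor override violating baseline consistency is rejected
  bad <- implantrom:::default_anchor_tables()
  bad$stress_MPa[bad$variable == "length" & bad$level == 11.5] <- 14
  expect_error(anchored_emulator(anchors = bad), "baseline")
  # as is a grid inconsistent with the space levels
  shifted <- implantrom:::default_anchor_tables()
  shifted$level[shifted$variable == "length"] <- c(8, 10, 11.5, 13, 15)
  expect_error(anchored_emulator(anchors = shifted), "grid")
})

test_that("joint variation composes multiplicatively in ratios to baseline", {
  emu <- anchored_emulator()
  cfg <- baseline_config()
  cfg$length <- 15
  cfg$cancellous_modulus <- 0.5
  expect_equal(evaluate_stress(cfg, emu), 10.49 * 44.53 / 13.81,
               tolerance = 1e-12)
  # three factors off baseline
  cfg$front_rear_angle <- 10
  expect_equal(evaluate_stress(cfg, emu),
               13.81 * (10.49 / 13.81) * (44.53 / 13.81) * (24.03 / 13.81),
               tolerance = 1e-12)
})

test_that("sweeps are monotone where the published trends are, and bracketed between grid points", {
  emu <- anchored_emulator()
  base <- baseline_config()
  trends <- c(length = -1, diameter = -1, cancellous_modulus = -1,
              front_rear_angle = 1, left_right_angle = 1)
  for (nm in names(trends)) {
    grid <- published_sweeps[[nm]]$grid
    fine <- seq(min(grid), max(grid), length.out = 41)
    sweep <- base[rep(1, length(fine)), ]
    sweep[[nm]] <- fine
    s <- evaluate_stress(sweep, emu)
    expect_true(all(trends[nm] * diff(s) >= -1e-12), label = nm)
  }
  # interpolated values lie within the bracketing anchor values
  for (nm in names(published_sweeps)) {
    tab <- published_sweeps[[nm]]
    mid <- (tab$grid[-5] + tab$grid[-1]) / 2
    sweep <- base[rep(1, 4), ]
    sweep[[nm]] <- mid
    s <- evaluate_stress(sweep, emu)
    lo <- pmin(tab$stress[-5], tab$stress[-1])
    hi <- pmax(tab$stress[-5], tab$stress[-1])
    expect_true(all(s >= lo - 1e-12 & s <= hi + 1e-12), label = nm)
  }
})

test_that("out-of-range placements are rejected rather than extrapolated", {
  emu <- anchored_emulator()
  cfg <- baseline_config()
  cfg$diameter <- 5.5
  expect_error(evaluate_stress(cfg, emu), "diameter 5.5 outside")
})

test_that("companion channels follow the documented synthetic scalings", {
  emu <- anchored_emulator(implant_stress_ratio = 2.0,
                           deformation_compliance = 0.03)
  out <- evaluate_outputs(baseline_config(), emu)
  expect_equal(out$implant_stress_MPa, 2 * 13.81)
  expect_equal(out$deformation_mm, 0.03 * 13.81 / 7.0)
  # ratio invariance across arbitrary configs
  d <- random_design(10, seed = 11)
  outs <- evaluate_outputs(d, emu)
  expect_equal(outs$implant_stress_MPa / outs$cortical_stress_MPa,
               rep(2, 10))
  expect_true(all(outs$cortical_stress_MPa > 0 & outs$deformation_mm > 0))
})

test_that("noisy sampling is seeded, degenerate at zero noise, and has the lognormal mean", {
  emu <- anchored_emulator()
  d <- random_design(5, seed = 2)
  expect_equal(sample_noisy(d, emu, seed = 9, noise_cv = 0),
               evaluate_outputs(d, emu))
  a <- sample_noisy(d, emu, seed = 9, noise_cv = 0.1)
  b <- sample_noisy(d, emu, seed = 9, noise_cv = 0.1)
  expect_identical(a, b)
  c2 <- sample_noisy(d, emu, seed = 10, noise_cv = 0.1)
  expect_false(identical(a$cortical_stress_MPa, c2$cortical_stress_MPa))

  # Monte-Carlo moment check: unit-median lognormal with CV s has mean
  # exp(sdlog^2/2); 10,000 draws at the baseline
  base <- baseline_config()[rep(1, 10000), ]
  draws <- sample_noisy(base, emu, seed = 123, noise_cv = 0.05)
  expected_mean <- 13.81 * exp(log(1 + 0.05^2) / 2)
  expect_equal(mean(draws$cortical_stress_MPa), expected_mean,
               tolerance = 0.01)
})

test_that("run_doe preserves row order and round-trips through CSV", {
  emu <- anchored_emulator()
  doe <- taguchi_l25(design_space("anterior"))
  res <- run_doe(doe, emu)
  expect_equal(nrow(res), 25)
  rev_doe <- doe[25:1, ]
  rev_res <- run_doe(rev_doe, emu)
  expect_equal(rev_res$cortical_stress_MPa, rev(res$cortical_stress_MPa))

  path <- withr::local_tempfile(fileext = ".csv")
  write_response_table(res, path)
  back <- read_response_table(path)
  expect_equal(as.data.frame(back), as.data.frame(res), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a single-row baseline design yields the 13.81 MPa anchor", {
  res <- run_doe(baseline_config(), anchored_emulator())
  expect_equal(res$cortical_stress_MPa, 13.81)
})
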