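test_that("identical seeds give bit-identical traces", {
  cfg <- quick_config(mutant_species(), duration = 0.3, seed = 42)
  t1 <- simulate_trace(cfg)
  t2 <- simulate_trace(cfg)
  expect_identical(t1$counts_G, t2$counts_G)
  expect_identical(t1$counts_R, t2$counts_R)
  t3 <- simulate_trace(quick_config(mutant_species(), duration = 0.3, seed = 43))
  expect_false(identical(t3$counts_R, t1$counts_R))
})

test_that("degenerate configurations are rejected", {
  cfg <- quick_config(list())
  expect_error(simulate_trace(cfg), "degenerate")
})

test_that("pure background gives the configured rate and no correlation", {
  cfg <- simulation_config(
    species = list(), volume = default_volume(),
    background_G = 1000, background_R = 1000,
    duration = 2, base_bin = 1e-4, time_step = 1e-4,
    box_factor = 5, seed = 5
  )
  tr <- simulate_trace(cfg)
  # Poisson SE of the rate is sqrt(R/T)
  se <- sqrt(1000 / 2)
  expect_lt(abs(mean_count_rate(tr, "G") - 1000), 3 * se)
  expect_lt(abs(mean_count_rate(tr, "R") - 1000), 3 * se)
  cv <- correlate_multitau(tr, "GG", max_lag = 0.05)
  ok <- is.finite(cv$G_err) & cv$G_err > 0
  expect_true(all(abs(cv$G[ok]) < 5 * cv$G_err[ok]))
})

test_that("mean count rate matches the analytic box average", {
  cfg <- quick_config(mutant_species(), duration = 2, seed = 77)
  tr <- simulate_trace(cfg)
  expected <- expected_count_rate(cfg, "R")
  rel_err <- abs(mean_count_rate(tr, "R") - expected) / expected
  expect_lt(rel_err, 3 * rate_rel_se(cfg))
  expect_equal(mean_count_rate(tr, "G"), 0) # no green label on this species
})

test_that("mean rate arithmetic is exact on constructed traces", {
  tr <- intensity_trace(
    counts_G = rep(3, 1000), counts_R = rep(0, 1000),
    bin_width = 1e-5
  )
  expect_equal(mean_count_rate(tr, "G"), 3e5)
  expect_equal(mean_count_rate(tr, "R"), 0)
})

test_that("a quasi-immobile species decorrelates negligibly", {
  sp <- species_spec("frozen",
    D = 1e-3, concentration = 2,
    brightness_G = 2e4
  )
  cfg <- quick_config(sp, duration = 2, base_bin = 1e-3, seed = 9)
  tr <- simulate_trace(cfg)
  cv <- correlate_multitau(tr, "GG", max_lag = 0.05)
  # tau_D = omega_xy^2 / (4D) = 15.6 s >> max lag; closed-form ratio ~ 0.999
  tau_D <- 0.25^2 / (4 * 1e-3)
  model_ratio <- model_3d_diffusion(max(cv$lags), 1, tau_D, 5) /
    model_3d_diffusion(min(cv$lags), 1, tau_D, 5)
  emp_ratio <- mean(tail(cv$G, 3)) / mean(head(cv$G, 3))
  expect_gt(model_ratio, 0.99)
  expect_lt(abs(emp_ratio - model_ratio), 0.1)
})

test_that("photobleaching decays the intensity as configured", {
  sp <- species_spec("bleachy",
    D = 10.6, concentration = 40,
    brightness_G = 5000, bleach_rate = 1 / 20
  )
  cfg <- quick_config(sp, duration = 10, base_bin = 1e-3, seed = 21)
  tr <- simulate_trace(cfg)
  # analytic expectation integrates the decay over the acquisition
  expected <- expected_count_rate(cfg, "G")
  expect_lt(
    abs(mean_count_rate(tr, "G") - expected) / expected,
    4 * rate_rel_se(cfg)
  )
  # first fifth vs last fifth should show the decay e^{-8/20} ~ 0.67
  n <- tr$n_bins
  head_rate <- sum(tr$counts_G[1:(n / 5)])
  tail_rate <- sum(tr$counts_G[(4 * n / 5):n])
  expect_lt(tail_rate / head_rate, 0.85)
})

test_that("traces survive a round trip through the text format", {
  cfg <- quick_config(mutant_species(), duration = 0.2, seed = 3)
  tr <- simulate_trace(cfg)
  tr$metadata$condition <- "control"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_identical(back$counts_G, tr$counts_G)
  expect_identical(back$counts_R, tr$counts_R)
  expect_equal(back$bin_width, tr$bin_width)
  expect_equal(back$metadata$condition, "control")
})
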