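test_that("the diffusion model evaluates to its landmark values", {
  expect_equal(model_3d_diffusion(0, N = 4, tau_D = 1e-3, kappa = 5), 0.25)
  expect_equal(
    model_3d_diffusion(0, N = 4, tau_D = 1e-3, kappa = 5, offset = 0.01),
    0.26
  )
  # 2D limit: half amplitude exactly at tau_D
  expect_equal(
    model_3d_diffusion(1e-3, N = 1, tau_D = 1e-3, kappa = 1e9),
    0.5,
    tolerance = 1e-9
  )
  # kappa = 5: (1/2) / sqrt(1 + 1/25)
  expect_equal(
    model_3d_diffusion(1e-3, N = 1, tau_D = 1e-3, kappa = 5),
    0.5 / sqrt(1.04)
  )
  expect_equal(0.5 / sqrt(1.04), 0.490290, tolerance = 1e-6)
})

test_that("the model decreases monotonically in lag when offset is zero", {
  tau <- 10^seq(-5, 0, length.out = 200)
  for (kappa in c(2, 5, 10)) {
    g <- model_3d_diffusion(tau, N = 3, tau_D = 8e-4, kappa = kappa)
    expect_true(all(diff(g) < 0))
  }
})

make_model_curve <- function(N, tau_D, kappa, offset = 0, err = 1e-4) {
  lags <- 2e-5 * 2^seq(0, 15, by = 0.25)
  correlation_curve(
    lags = lags,
    G = model_3d_diffusion(lags, N, tau_D, kappa, offset),
    G_err = rep(err, length(lags)),
    pair = "GG", duration = 10, bin_width = 2e-6
  )
}

test_that("fitting a noiseless model curve returns the exact parameters", {
  cv <- make_model_curve(N = 5, tau_D = 1e-3, kappa = 5)
  fit <- fit_curve(cv, kappa = 5)
  expect_true(fit$converged)
  expect_equal(fit$N, 5, tolerance = 1e-6)
  expect_equal(fit$tau_D, 1e-3, tolerance = 1e-6)
  expect_equal(fit$offset, 0, tolerance = 1e-7)
})

test_that("fit(model(theta)) = theta over random parameters in bounds", {
  set.seed(99)
  for (i in 1:12) {
    N <- 10^stats::runif(1, -0.5, 2)
    tau_D <- 10^stats::runif(1, -3.5, -2)
    off <- stats::runif(1, -0.002, 0.002)
    cv <- make_model_curve(N, tau_D, kappa = 5, offset = off)
    fit <- fit_curve(cv, kappa = 5)
    expect_true(fit$converged)
    expect_equal(fit$N, N, tolerance = 1e-4)
    expect_equal(fit$tau_D, tau_D, tolerance = 1e-4)
  }
})

test_that("degenerate curves are reported, never silently defaulted", {
  lags <- 2e-5 * 2^seq(0, 15, by = 0.25)
  flat <- correlation_curve(
    lags = lags, G = rep(0, length(lags)),
    G_err = rep(1e-4, length(lags)), pair = "GR",
    duration = 10, bin_width = 2e-6
  )
  fit <- fit_curve(flat, kappa = 5)
  expect_false(fit$converged)
  expect_true(is.na(fit$N))
  negative <- correlation_curve(
    lags = lags, G = rep(-0.01, length(lags)),
    G_err = rep(1e-4, length(lags)), pair = "GR",
    duration = 10, bin_width = 2e-6
  )
  expect_false(fit_curve(negative, kappa = 5)$converged)
})

test_that("fits demand an informative lag range", {
  short <- correlation_curve(
    lags = (1:10) * 1e-4, G = rep(0.1, 10),
    pair = "GG", duration = 1, bin_width = 1e-5
  )
  expect_error(fit_curve(short, kappa = 5), "decades")
})

test_that("simulated diffusion times are recovered through the fit", {
  # D = 17.3 um^2/s at omega_xy = 0.25 um: tau_D = 0.903 ms
  cfg <- quick_config(wildtype_species(), duration = 4, seed = 123)
  tr <- simulate_trace(cfg)
  fit <- fit_curve(correlate_multitau(tr, "GG"), kappa = 5)
  expect_true(fit$converged)
  tau_true <- 0.25^2 / (4 * 17.3)
  expect_lt(abs(fit$tau_D - tau_true) / tau_true, 0.15)
})

test_that("the cross-correlation read-out is null for independent species", {
  cfg <- quick_config(
    list(wildtype_species(), mutant_species()),
    duration = 4, seed = 321
  )
  tr <- simulate_trace(cfg)
  gr <- crosscorr_amplitude(correlate_multitau(tr, "GR"))
  expect_false(isTRUE(gr$significant))
  expect_lt(abs(gr$G0), 3 * gr$se)
})
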