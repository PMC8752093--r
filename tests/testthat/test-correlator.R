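test_that("direct correlator reproduces the closed form for a cosine", {
  a <- 100
  b <- 20
  f <- 10
  tr <- cosine_trace(a = a, b = b, freq = f, bin = 1e-3, n = 10000)
  cv <- correlate_direct(tr, "GG", max_lag = 0.2)
  expected <- b^2 / (2 * a^2) * cos(2 * pi * f * cv$lags)
  # finite-length edge effects are O(lag / duration)
  expect_lt(max(abs(cv$G - expected)), 0.02 * b^2 / (2 * a^2))
})

test_that("a constant trace has zero correlation at all lags", {
  tr <- intensity_trace(rep(7, 5000), rep(7, 5000), bin_width = 1e-4)
  cv <- correlate_direct(tr, "GG", max_lag = 0.02)
  expect_true(all(abs(cv$G) < 1e-12))
})

test_that("independent Poisson channels give a flat zero cross-correlation", {
  set.seed(8)
  tr <- intensity_trace(rpois(40000, 5), rpois(40000, 5), bin_width = 1e-4)
  cv <- correlate_multitau(tr, "GR", max_lag = 0.1)
  ok <- is.finite(cv$G_err) & cv$G_err > 0
  expect_true(mean(abs(cv$G[ok]) < 3 * cv$G_err[ok]) > 0.9)
  expect_lt(abs(mean(cv$G)), 3 * sd(cv$G) / sqrt(length(cv$G)))
})

test_that("multi-tau equals the direct estimator on level-0 lags", {
  cfg <- quick_config(mutant_species(), duration = 2, seed = 31)
  tr <- simulate_trace(cfg)
  mt <- correlate_multitau(tr, "RR", m_per_octave = 16, max_lag = 0.1)
  dr <- correlate_direct(tr, "RR", max_lag = 16 * tr$bin_width)
  shared <- match(round(dr$lags / tr$bin_width), round(mt$lags / tr$bin_width))
  expect_true(all(!is.na(shared)))
  expect_equal(mt$G[shared], dr$G, tolerance = 1e-12)
})

test_that("rebinned multi-tau levels agree with direct within the block error", {
  # rebinning by 2^l averages the fine-grained correlation over a triangular
  # window of that width, so that window average of the direct estimator is
  # the exact expectation of the multi-tau value at the deeper levels
  cfg <- quick_config(mutant_species(), duration = 2, seed = 31)
  tr <- simulate_trace(cfg)
  bw <- tr$bin_width
  mt <- correlate_multitau(tr, "RR", m_per_octave = 16, max_lag = 0.02)
  dr <- correlate_direct(tr, "RR", max_lag = 0.021)
  tri_avg <- function(lag_bins, mult) {
    offs <- (-(mult - 1)):(mult - 1)
    w <- mult - abs(offs)
    ks <- lag_bins + offs
    ok <- ks >= 1 & ks <= length(dr$G)
    sum(w[ok] * dr$G[ks[ok]]) / sum(w[ok])
  }
  deep <- which(mt$lags > 16 * bw)
  expect_gt(length(deep), 20)
  z <- vapply(deep, function(i) {
    mult <- 2^max(0, ceiling(log2(mt$lags[i] / bw / 16)))
    ta <- tri_avg(round(mt$lags[i] / bw), mult)
    (mt$G[i] - ta) / max(mt$G_err[i], 1e-4)
  }, numeric(1))
  expect_true(all(abs(z) < 3))
})

test_that("halving the base bin leaves the correlation estimate stable", {
  sp <- mutant_species()
  cfg_fine <- quick_config(sp, duration = 2, base_bin = 1e-5, seed = 55)
  cfg_coarse <- quick_config(sp, duration = 2, base_bin = 2e-5, seed = 55)
  fine <- correlate_multitau(simulate_trace(cfg_fine), "RR", max_lag = 0.05)
  coarse <- correlate_multitau(simulate_trace(cfg_coarse), "RR", max_lag = 0.05)
  shared <- intersect(round(fine$lags, 10), round(coarse$lags, 10))
  expect_gt(length(shared), 10)
  i_f <- match(shared, round(fine$lags, 10))
  i_c <- match(shared, round(coarse$lags, 10))
  err <- pmax(fine$G_err[i_f], coarse$G_err[i_c], 1e-4)
  agree <- abs(fine$G[i_f] - coarse$G[i_c]) < 4 * err
  expect_true(mean(agree, na.rm = TRUE) > 0.9)
})

test_that("single-species amplitude tracks the occupancy law", {
  # one trace: fitted 1/G(0) close to c * N_A * V_eff (tight ensemble
  # version lives with the acceptance suite)
  cfg <- quick_config(mutant_species(), duration = 4, seed = 12)
  tr <- simulate_trace(cfg)
  cv <- correlate_multitau(tr, "RR")
  fit <- fit_curve(cv, kappa = 5)
  expect_true(fit$converged)
  n_true <- 75 * 0.602214076 * default_volume()$V_eff
  expect_lt(abs(fit$N - n_true) / n_true, 0.25)
})

test_that("lag-grid contracts hold and bad requests fail", {
  cfg <- quick_config(mutant_species(), duration = 0.5, seed = 2)
  tr <- simulate_trace(cfg)
  cv <- correlate_multitau(tr, "RR", max_lag = 0.02)
  expect_true(all(diff(cv$lags) > 0))
  expect_gte(min(cv$lags), tr$bin_width)
  expect_true(all(is.finite(cv$G)))
  expect_error(correlate_direct(tr, "RR", max_lag = 0.3), "half")
  expect_error(correlate_multitau(tr, "RR", max_lag = 0.5), "half")
})

test_that("curves survive a round trip through the text format", {
  cfg <- quick_config(mutant_species(), duration = 0.5, seed = 2)
  cv <- correlate_multitau(simulate_trace(cfg), "RR", max_lag = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curve(cv, path)
  back <- read_curve(path)
  expect_equal(back$lags, cv$lags)
  expect_equal(back$G, cv$G)
  expect_equal(back$pair, "RR")
})
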