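test_that("tail-current normalization divides by the global maximum", {
  gv <- normalize_gv(c(-40, 0, 40), c(1, 2, 4))
  expect_equal(gv$g_norm, c(0.25, 0.5, 1))
  expect_equal(normalize_gv(c(0, 40), c(3, 3))$g_norm, c(1, 1))
  # interior maximum still sets the scale
  expect_equal(normalize_gv(c(0, 40, 80), c(1, 4, 2))$g_norm,
               c(0.25, 1, 0.5))
})

test_that("noise-free Boltzmann data are recovered exactly", {
  gv <- make_gv_dataset(100, 20, seq(-100, 300, by = 20), noise_sd = 0)
  fit <- fit_boltzmann(gv, mc_draws = 0)
  expect_equal(fit$v_half, 100, tolerance = 1e-6)
  expect_equal(fit$slope_b, 20, tolerance = 1e-6)
  # midpoint identity: fitted curve at fitted V1/2 is half of gmax
  expect_equal(boltzmann(fit$v_half, fit$v_half, fit$slope_b, fit$g_max),
               fit$g_max / 2)
  # free-amplitude variant also recovers the truth on saturated data
  fit2 <- fit_boltzmann(gv, fix_gmax = FALSE, mc_draws = 0)
  expect_equal(c(fit2$v_half, fit2$slope_b, fit2$g_max), c(100, 20, 1),
               tolerance = 1e-6)
})

test_that("a transition outside the voltage range is flagged", {
  gv <- make_gv_dataset(500, 10, seq(-100, 100, by = 20), noise_sd = 0)
  fit <- suppressWarnings(fit_boltzmann(gv, mc_draws = 0))
  expect_false(fit$converged)
})

test_that("GV shifts propagate standard errors in quadrature", {
  gv <- make_gv_dataset(100, 20, seq(-50, 250, 20), noise_sd = 0.05,
                        n_reps = 4, seed = 2)
  fa <- fit_boltzmann(gv, mc_draws = 100, seed = 1)
  expect_equal(delta_v_half(fa, fa)$delta_v_half, 0)
  fb <- fa; fb$v_half <- fa$v_half - 20; fb$se_v_half <- 2
  fa2 <- fa; fa2$se_v_half <- 2
  d <- delta_v_half(fa2, fb)
  expect_equal(d$delta_v_half, 20)
  expect_equal(d$se, sqrt(8))
  expect_equal(delta_v_half(fb, fa2)$delta_v_half, -20)  # antisymmetry
})

test_that("noise-free Hill data are recovered exactly with n fixed at 1", {
  dr <- make_dose_response(2.5, -60, c(0.1, 0.5, 1, 2.5, 10, 50, 300),
                           noise_sd = 0)
  fit <- fit_hill(dr, mc_draws = 0)
  expect_equal(fit$ec50, 2.5, tolerance = 1e-6)
  expect_equal(fit$max_response, -60, tolerance = 1e-6)
  expect_equal(fit$hill_n, 1)
  # fitted curve at EC50 is half-maximal
  expect_equal(hill(fit$ec50, fit$ec50, fit$max_response), fit$max_response / 2)
  # freed Hill coefficient recovers a steeper generator
  dr2 <- make_dose_response(2.5, 1, c(0.1, 0.5, 1, 2.5, 10, 50, 300),
                            hill_n = 2, noise_sd = 0)
  fit2 <- fit_hill(dr2, fix_n = FALSE, mc_draws = 0)
  expect_equal(fit2$hill_n, 2, tolerance = 1e-4)
  expect_equal(fit2$ec50, 2.5, tolerance = 1e-4)
})

test_that("Monte-Carlo SEs scale with the input noise level", {
  a <- bk_reference_designs()$activation
  ses <- vapply(c(1, 2, 4), function(ns) {
    dr <- make_dose_response(a$ec50, a$max_response, a$concentrations,
                             noise_sd = ns, n_reps = a$n_reps, seed = 5)
    fit_hill(dr, mc_draws = 150, seed = 7)$se_ec50
  }, numeric(1))
  expect_true(all(diff(ses) > 0))
  # doubling the noise roughly doubles the SE
  expect_equal(ses[3] / ses[1], 4, tolerance = 0.5)
})

test_that("NPo integration is exact on constant traces and linear", {
  expect_equal(estimate_npo(rep(27.3, 1000), 27.3, 1e-3)$npo, 1)
  expect_equal(estimate_npo(rep(0, 1000), 27.3, 1e-3)$npo, 0)
  set.seed(4)
  x <- abs(rnorm(2000)) * 10
  n1 <- estimate_npo(x, 5, 1e-3)$npo
  n2 <- estimate_npo(3 * x, 5, 1e-3)$npo
  expect_equal(n2, 3 * n1)
  # resampling a constant trace at finer intervals changes nothing
  expect_equal(estimate_npo(rep(13.65, 10000), 27.3, 1e-4)$npo, 0.5)
  expect_error(estimate_npo(x, 0, 1e-3), "unitary")
})

test_that("channel count arithmetic inverts the macroscopic current", {
  cc <- estimate_channel_count(2730, gamma = 273, v = 100, e_k = 0,
                               p_open = 1)
  expect_equal(cc$N, 100)
  expect_equal(cc$N_raw, 100)
  expect_equal(estimate_channel_count(5460, 273, 100, 0, 1)$N_raw, 200)
  # partial open probability scales the estimate up
  expect_equal(estimate_channel_count(2730, 273, 100, 0, 0.5)$N_raw, 200)
  expect_error(estimate_channel_count(100, 273, 100, 0, 0), "p_open")
  expect_error(estimate_channel_count(100, 273, 0, 0, 1), "E_K")
})

test_that("fractional inhibition is 1 - I_treated / I_control", {
  expect_equal(fractional_inhibition(c(10, 20), c(10, 20)), c(0, 0))
  expect_equal(fractional_inhibition(10, 0), 1)
  expect_equal(fractional_inhibition(10, 5), 0.5)
  expect_error(fractional_inhibition(c(1, 2), 1), "matched")
})

test_that("ephys tables round-trip through CSV", {
  gv <- make_gv_dataset(120, 18, seq(-40, 280, 40), noise_sd = 0.05,
                        n_reps = 3, seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ephys_csv(gv, f)
  back <- read_gv_csv(f)
  expect_equal(back$g_norm, gv$g_norm)
  expect_equal(back$sem, gv$sem)
  dr <- make_dose_response(1.1, 1, c(0.1, 1, 10), noise_sd = 0.02, seed = 6)
  write_ephys_csv(dr, f)
  expect_equal(read_dose_csv(f)$theta, dr$theta)
})
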