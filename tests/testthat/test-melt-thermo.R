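wt <- two_state_params(dH = -45.69, Tm_K = 349.55)

test_that("free energy and fraction folded obey the two-state closed forms", {
  expect_equal(dG_at(310.15, wt), -5.15, tolerance = 2e-3)
  expect_equal(dG_at(wt$Tm_K, wt), 0)
  u <- two_state_params(-50.73, 313.05)
  expect_equal(dG_at(310.15, u), -0.47, tolerance = 2e-3)
  expect_equal(fraction_folded(wt$Tm_K, wt), 0.5)
  expect_equal(fraction_folded(310.15, wt), 0.99976, tolerance = 1e-4)
  expect_gt(fraction_folded(10, wt), 1 - 1e-12)  # T -> 0 limit
  # strictly decreasing in T for dH < 0
  Ts <- seq(280, 380, by = 0.5)
  expect_true(all(diff(fraction_folded(Ts, wt)) < 0))
})

test_that("simulated curves are deterministic and inflect at Tm", {
  c1 <- simulate_melting_curve(wt, noise_sd = 0.002, seed = 9)
  c2 <- simulate_melting_curve(wt, noise_sd = 0.002, seed = 9)
  expect_identical(c1$signal, c2$signal)
  c3 <- simulate_melting_curve(wt, noise_sd = 0.002, seed = 10)
  expect_false(identical(c1$signal, c3$signal))
  # flat baselines a_f=1, a_u=0: curve equals f(T); derivative extremum at Tm
  fl <- list(a_f = 1, b_f = 0, a_u = 0, b_u = 0)
  dense <- simulate_melting_curve(wt, baselines = fl,
                                  T_grid_C = seq(40, 95, by = 0.05))
  expect_equal(dense$signal,
               fraction_folded(celsius_to_kelvin(dense$temperature_C), wt))
  dAdT <- diff(dense$signal) / diff(dense$temperature_C)
  mid <- (dense$temperature_C[-1] + dense$temperature_C[-nrow(dense)]) / 2
  expect_lt(abs(mid[which.max(abs(dAdT))] - kelvin_to_celsius(wt$Tm_K)), 0.5)
  expect_error(simulate_melting_curve(wt, T_grid_C = numeric(0)),
               class = "quadstall_bad_curve")
})

test_that("noiseless fits recover the published melting temperatures", {
  fit_wt <- fit_two_state(simulate_melting_curve(wt))
  expect_equal(kelvin_to_celsius(fit_wt$params$Tm_K), 76.4, tolerance = 0.1)
  g <- two_state_params(-45.89, 355.55)   # dS = -129.07 cal/mol/K
  fit_g <- fit_two_state(simulate_melting_curve(g))
  expect_equal(kelvin_to_celsius(fit_g$params$Tm_K), 82.4, tolerance = 0.1)
  # self-consistency to <= 0.1%
  expect_equal(fit_wt$params$dH, wt$dH, tolerance = 1e-3)
  expect_equal(fit_wt$params$Tm_K, wt$Tm_K, tolerance = 1e-3)
})

test_that("noiseless parameter recovery holds across the parameter space", {
  set.seed(2024)
  for (i in 1:50) {
    p <- two_state_params(stats::runif(1, -80, -20),
                          celsius_to_kelvin(stats::runif(1, 35, 90)))
    fit <- fit_two_state(simulate_melting_curve(p))
    expect_equal(fit$params$dG37, p$dG37, tolerance = 0.01)
  }
})

test_that("mean recovered stability stays within 0.2 kcal/mol under noise", {
  dg <- vapply(1:20, function(s) {
    cv <- simulate_melting_curve(wt, noise_sd = 0.002, seed = 1000 + s)
    fit_two_state(cv)$params$dG37
  }, 0)
  expect_lt(abs(mean(dg) - wt$dG37), 0.2)
})

test_that("replicate aggregation gives zero SD on identical replicates", {
  curves <- lapply(1:5, function(r)
    simulate_melting_curve(wt, replicate = paste0("r", r)))
  fit <- fit_two_state(curves)
  expect_equal(nrow(fit$replicates), 5)
  expect_equal(unname(fit$summary$sd[["dG37"]]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$summary$sd[["Tm_C"]]), 0, tolerance = 1e-6)
})

test_that("monotone transition-free curves raise a no-transition error", {
  Tc <- seq(20, 95, by = 0.5)
  set.seed(5)
  flat <- melting_curve(Tc, 0.2 - 2e-4 * Tc + stats::rnorm(length(Tc), 0, 0.002))
  expect_error(fit_two_state(flat), class = "quadstall_no_transition")
})

test_that("normalisation inverts the forward model", {
  cv <- simulate_melting_curve(wt)
  fit <- fit_two_state(cv)
  theta <- normalize_curve(cv, fit)
  f <- fraction_folded(celsius_to_kelvin(cv$temperature_C), wt)
  expect_equal(theta$signal, f, tolerance = 1e-4)
  expect_equal(theta$signal[1], 1, tolerance = 1e-3)     # coldest point folded
  i_tm <- which.min(abs(cv$temperature_C - kelvin_to_celsius(wt$Tm_K)))
  expect_equal(theta$signal[i_tm], 0.5, tolerance = 0.02)  # nearest grid point
  degen <- fit
  degen$baselines <- list(a_f = 1, b_f = 0, a_u = 1, b_u = 0)
  expect_error(normalize_curve(cv, degen), class = "quadstall_bad_curve")
})

test_that("melting CSV round-trips replicates and metadata", {
  tmp <- tempfile(fileext = ".csv")
  curves <- lapply(1:3, function(r)
    simulate_melting_curve(wt, noise_sd = 0.002, seed = r,
                           replicate = paste0("r", r)))
  write_melting_csv(curves, tmp)
  back <- read_melting_csv(tmp)
  expect_length(back, 3)
  expect_equal(back$r2$signal, curves[[2]]$signal, tolerance = 1e-12)
  expect_equal(attr(back$r1, "wavelength_nm"), 295)
})
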