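base_model <- stall_model(k0 = 0.03, alpha = 0.6, phi = 1, k_fast = 1)
table1_dG <- c(wild_type = -5.15, C_mutant = -4.77, G_mutant = -5.86,
               U_mutant = -0.47, A_mutant = 0)

test_that("escape rate anchors at k0 and scales exponentially in stability", {
  expect_equal(escape_rate(0, base_model), base_model$k0)
  m0 <- stall_model(k0 = 0.03, alpha = 0, phi = 1)
  expect_equal(escape_rate(-5.15, m0), 0.03)
  # closed-form ratio between two stabilities
  r <- escape_rate(-5.86, base_model) / escape_rate(-4.77, base_model)
  expect_equal(r, exp(0.6 * (-5.86 + 4.77) / (1.9872e-3 * 310.15)),
               tolerance = 1e-12)
  expect_error(escape_rate(1, base_model))
  expect_error(stall_model(k0 = 0.2, k_fast = 1), class = "quadstall_bad_model")
})

test_that("time courses conserve mass and respect limiting behaviours", {
  for (dg in table1_dG) {
    tc <- simulate_timecourse(base_model, dg, seq(0, 600, by = 10))
    expect_lt(max(abs(tc$H + tc$I + tc$F - 1)), 1e-9)
    expect_true(all(tc$H >= 0 & tc$I >= -1e-12 & tc$F >= -1e-12))
  }
  # phi = 0: no stalled intermediate, full-length only
  tc_a <- simulate_timecourse(base_model, 0, phi = 0)
  expect_equal(tc_a$I, rep(0, 6))
  expect_equal(tc_a$F[6], 1, tolerance = 1e-10)
  # very stable quadruplex: I plateaus near phi, F stays near 1 - phi
  slow <- stall_model(k0 = 1e-6, alpha = 0, phi = 0.7)
  tc_s <- simulate_timecourse(slow, -5, c(0, 60, 600))
  expect_equal(tc_s$I[3], 0.7, tolerance = 5e-3)
  expect_equal(tc_s$F[3], 0.3, tolerance = 5e-3)
  # intermediate rate: I rises then decays while F accumulates
  mid <- simulate_timecourse(base_model, -0.47, phi = 0.5)
  expect_gt(mid$I[2], 0.1)            # visible transient at 20 s
  expect_lt(mid$I[6], 0.05)           # gone by 600 s
  expect_true(all(diff(mid$F) > 0))
})

test_that("full-length yield decreases with quadruplex stability at fixed time", {
  dgs <- c(-0.5, -2, -4, -6)
  F120 <- vapply(dgs, function(dg)
    simulate_timecourse(base_model, dg, c(0, 120))$F[2], 0)
  I120 <- vapply(dgs, function(dg)
    simulate_timecourse(base_model, dg, c(0, 120))$I[2], 0)
  expect_true(all(diff(F120) < 0))   # more stable -> less full-length
  expect_true(all(diff(I120) > 0))   # more stable -> more stalled product
})

test_that("noiseless escape fits recover the generating model to <= 1%", {
  phis <- c(1, 1, 1, 0.5, 0)
  tcs <- lapply(seq_along(table1_dG), function(i)
    list(name = names(table1_dG)[i], dG37 = unname(table1_dG[i]),
         tc = simulate_timecourse(base_model, table1_dG[i], phi = phis[i])))
  fit <- fit_escape(tcs)
  expect_equal(fit$k0, 0.03, tolerance = 0.01)
  expect_equal(fit$alpha, 0.6, tolerance = 0.01)
  expect_equal(unname(fit$phi[1:4]), phis[1:4], tolerance = 0.01)
  expect_error(fit_escape(tcs[1]), class = "quadstall_bad_input")
  short <- list(list(dG37 = 0, tc = simulate_timecourse(base_model, 0, c(0, 20))),
                list(dG37 = -1, tc = simulate_timecourse(base_model, -1, c(0, 20))))
  expect_error(fit_escape(short), class = "quadstall_bad_input")
})

test_that("stability-independent data yield an alpha interval covering zero", {
  m0 <- stall_model(k0 = 0.02, alpha = 0, phi = 1)
  set.seed(77)
  tcs <- lapply(c(-5.15, -4.77, -0.47), function(dg) {
    tc <- simulate_timecourse(m0, dg)
    tc$I <- pmax(tc$I + stats::rnorm(6, 0, 0.02), 0)
    tc$F <- pmax(tc$F + stats::rnorm(6, 0, 0.02), 0)
    list(dG37 = dg, tc = tc)
  })
  fit <- fit_escape(tcs)
  expect_true(fit$ci_alpha[1] <= 0 && fit$ci_alpha[2] >= 0)
})

test_that("alpha is recovered within 15% median error at 5% band noise", {
  phis <- c(1, 1, 1, 0.5)
  dgs <- c(-5.15, -4.77, -5.86, -0.47)
  errs <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    tcs <- lapply(seq_along(dgs), function(i) {
      tc <- simulate_timecourse(base_model, dgs[i], phi = phis[i])
      for (b in c("I", "F"))
        tc[[b]] <- tc[[b]] * stats::rlnorm(6, 0, 0.05)
      list(dG37 = dgs[i], tc = tc)
    })
    abs(fit_escape(tcs)$alpha - 0.6) / 0.6
  }, 0)
  expect_lte(stats::median(errs), 0.15)
})

test_that("stall CSV round-trips and renormalises band fractions", {
  recs <- lapply(c(-5.15, 0), function(dg)
    list(name = paste0("v", dg), dG37 = dg,
         tc = simulate_timecourse(base_model, dg)))
  tmp <- tempfile(fileext = ".csv")
  write_stall_csv(recs, tmp)
  back <- read_stall_csv(tmp)
  expect_length(back, 2)
  i <- which(vapply(back, function(r) r$dG37 == -5.15, TRUE))
  expect_equal(back[[i]]$tc$I, recs[[1]]$tc$I, tolerance = 1e-6)
})
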