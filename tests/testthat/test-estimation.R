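test_that("observed-release containers validate and round-trip through CSV", {
  obs <- observed_release(c(1, 7, 28), c(15, 40, 70), sd = c(2, 2, 2))
  path <- tempfile(fileext = ".csv")
  write_observed_csv(obs, path)
  back <- read_observed_release(path)
  expect_equal(back$times, obs$times)
  expect_equal(back$q_obs, obs$q_obs)
  expect_equal(back$sd, obs$sd)

  expect_error(observed_release(c(7, 1), c(10, 20)), "increasing")
  expect_error(observed_release(c(1, 7), c(10, 120)), "\\[0, 100\\]")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_observed_release(bad), "time_days")
})

test_that("the SSE objective is zero at truth and additive in squared residuals", {
  geom <- baseline_geometry()
  ctx <- estimation_context(geom, n_core = 40)
  truth <- bev_params()
  syn <- generate_observations(truth, geom, schedule = c(1, 7, 28),
                               noise_sd = 0, n_core = 40)
  frag <- c(burst = truth$burst, d_core = truth$d_core)
  # not exactly zero: context rebuilds d_shell as ratio * d_core, and the
  # one-ulp difference is amplified to the integrator tolerance level
  expect_lt(sse_objective(frag, syn, ctx), 1e-6)

  # shift the observations by (1, 2) points -> SSE = 1 + 4 = 5
  shifted <- observed_release(syn$times[1:2], syn$q_true[1:2] + c(1, 2))
  expect_equal(sse_objective(frag, shifted, ctx), 5, tolerance = 1e-8)

  # out-of-bounds parameters return a signalled penalty
  expect_warning(pen <- sse_objective(c(burst = 50, d_core = truth$d_core),
                                      syn, ctx), "outside bounds")
  expect_gt(pen, 1e7)
})

test_that("multi-start fitting recovers the generating parameters without noise", {
  geom <- baseline_geometry()
  ctx <- estimation_context(geom, n_core = 40)
  truth <- bev_params()
  syn <- generate_observations(truth, geom, noise_sd = 0, n_core = 40)
  fit <- multistart_fit(syn, ctx, n_starts = 6, seed = 42)

  expect_lt(abs(fit$best_params[["burst"]] - 10) / 10, 0.01)
  expect_lt(abs(fit$best_params[["d_core"]] - 2.6e-15) / 2.6e-15, 0.01)
  # bookkeeping invariants
  ok <- fit$starts$converged & is.finite(fit$starts$sse)
  expect_equal(fit$best_sse, min(fit$starts$sse[ok]))
  expect_true(all(fit$starts$sse[fit$accepted] <= 1.05 * fit$best_sse))
  # bounds respected by every converged start
  b <- default_fit_bounds()
  expect_true(all(fit$starts$burst[ok] >= b$burst[1] - 1e-12))
  expect_true(all(fit$starts$burst[ok] <= b$burst[2] + 1e-12))
  expect_true(all(fit$starts$d_core[ok] >= b$d_core[1] * (1 - 1e-9)))
  expect_true(all(fit$starts$d_core[ok] <= b$d_core[2] * (1 + 1e-9)))
})

test_that("fits on noisy data stay near truth and agree across starts", {
  geom <- baseline_geometry()
  ctx <- estimation_context(geom, n_core = 40)
  truth <- bev_params()
  syn <- generate_observations(truth, geom, noise_sd = 2, seed = 99, n_core = 40)
  fit <- multistart_fit(syn, ctx, n_starts = 8, seed = 7)
  # regime-dependent identifiability: burst within +/-2 points, d_core
  # within +/-30% for 2%-noise data
  expect_lt(abs(fit$average_params[["burst"]] - 10), 2)
  expect_lt(abs(fit$average_params[["d_core"]] - 2.6e-15) / 2.6e-15, 0.30)
  # the core-limited problem is insensitive to the initial guess: every
  # converged start lands within 5% of the minimum error
  ok <- fit$starts$converged
  expect_true(all(fit$starts$sse[ok] <= 1.05 * fit$best_sse))
  # the reported best error equals the objective at the best parameters
  expect_equal(sse_objective(fit$best_params, syn, ctx), fit$best_sse,
               tolerance = 1e-6)
})

test_that("LHS initial guesses honour the sampling box and seeding", {
  geom <- baseline_geometry()
  ctx <- estimation_context(geom, n_core = 40)
  syn <- generate_observations(bev_params(), geom, schedule = c(1, 7, 28, 84),
                               noise_sd = 0, n_core = 40)
  f1 <- multistart_fit(syn, ctx, n_starts = 5, seed = 3)
  f2 <- multistart_fit(syn, ctx, n_starts = 5, seed = 3)
  expect_identical(f1$starts$burst0, f2$starts$burst0)
  expect_true(all(f1$starts$burst0 >= 0.1 & f1$starts$burst0 <= 20))
  expect_true(all(f1$starts$d_core0 >= 1e-15 & f1$starts$d_core0 <= 1e-13))
})
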