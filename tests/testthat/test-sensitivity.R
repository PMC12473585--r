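# Cheap analytic model functions exercise the estimator algebra; one PDE
# regime checks the physics. p = (burst, d_core, d_shell, kappa).

test_that("local normalised sensitivity is exact for scale-free models", {
  baseline <- transport_params(1e-14, 1e-14, kappa = 1, burst = 10)
  # f = c * kappa exactly -> normalised sensitivity 1 for kappa, 0 elsewhere
  fn <- function(p) 7.3 * p$kappa
  s <- local_normalized_sensitivity(fn, baseline)
  expect_equal(s[["kappa"]], 1)
  expect_equal(unname(s[c("burst", "d_core", "d_shell")]), rep(0, 3))
  # zero baseline output is rejected
  expect_error(local_normalized_sensitivity(function(p) 0, baseline),
               "zero or non-finite")
})

test_that("local sensitivity ranks core diffusivity and burst in the core-limited regime", {
  fn <- release_model_fn(baseline_geometry(), target_time = 28, n_core = 50)
  s <- abs(local_normalized_sensitivity(fn, regime_params("core-limited")))
  expect_gt(s[["d_core"]], 10 * s[["d_shell"]])
  expect_gt(s[["burst"]], 10 * s[["kappa"]])
  expect_gt(s[["d_core"]], s[["burst"]] / 3) # comparable magnitudes dominate
})

test_that("Morris screening flags inert and linear parameters", {
  baseline <- transport_params(1e-14, 1e-14, kappa = 1, burst = 10)
  # model ignoring kappa -> mu_star ~ 0 for kappa
  fn_ignore <- function(p) p$burst + 1e14 * p$d_core
  m <- morris_screening(fn_ignore, baseline, seed = 11)
  expect_equal(m$mu_star[["kappa"]], 0)
  expect_gt(m$mu_star[["burst"]], 0)
  # additive linear model -> elementary effects constant, sigma ~ 0
  expect_true(all(m$sigma < 1e-9))
  # reproducible under a fixed seed
  m2 <- morris_screening(fn_ignore, baseline, seed = 11)
  expect_identical(m$elementary_effects, m2$elementary_effects)
  expect_error(morris_screening(fn_ignore, baseline, rel_bound = 0),
               "degenerate")
})

test_that("Sobol indices recover the analytic additive decomposition", {
  baseline <- transport_params(1e-14, 1e-14, kappa = 1, burst = 10)
  # f = burst/10 + kappa: both terms have sd 0.01 -> S1 = S2 = 0.5
  fn <- function(p) p$burst / 10 + p$kappa
  s <- sobol_indices(fn, baseline, n_base_samples = 1024, seed = 5)
  expect_equal(s$first[["burst"]], 0.5, tolerance = 0.06)
  expect_equal(s$first[["kappa"]], 0.5, tolerance = 0.06)
  # totals approximately equal firsts (no interactions)
  expect_equal(unname(s$total[c("burst", "kappa")]),
               unname(s$first[c("burst", "kappa")]), tolerance = 0.06)
  # ignored parameters have vanishing indices
  expect_lt(abs(s$first[["d_shell"]]), 0.02)
  expect_lt(s$total[["d_shell"]], 0.02)
  # sum rule for an additive response
  expect_gt(sum(s$first), 0.9)
  expect_lt(sum(s$first), 1.05)
})

test_that("Sobol analysis flags a degenerate (constant) output", {
  baseline <- transport_params(1e-14, 1e-14, kappa = 1, burst = 10)
  s <- sobol_indices(function(p) 42, baseline, n_base_samples = 128, seed = 1)
  expect_true(s$degenerate)
  expect_true(all(is.na(s$first)))
})

test_that("truncated-normal sampling respects the 1% bounds", {
  baseline <- transport_params(1e-14, 2e-14, kappa = 1, burst = 10)
  seen <- list()
  fn <- function(p) {
    seen[[length(seen) + 1L]] <<- c(p$burst, p$d_core, p$d_shell, p$kappa)
    p$burst
  }
  invisible(sobol_indices(fn, baseline, n_base_samples = 128, seed = 2))
  all_p <- do.call(rbind, seen)
  base <- c(10, 1e-14, 2e-14, 1)
  for (j in 1:4) {
    expect_gte(min(all_p[, j]), 0.99 * base[j] - 1e-12)
    expect_lte(max(all_p[, j]), 1.01 * base[j] + 1e-12)
  }
})
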