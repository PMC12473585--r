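test_that("a single-cell sweep reproduces a direct simulation", {
  grid <- design_grid(core_multipliers = 1, shell_multipliers = 1)
  metrics <- sweep_design(grid, bev_params(), bev_dose(),
                          horizon = 120, n_core = 50)
  sim <- simulate_release(horizon = 120, n_core = 50)
  dur <- duration_above_rate_threshold(sim$rates, 2)
  expect_equal(metrics$t_rate_threshold[1, 1], dur$duration)
  expect_equal(metrics$q_at_horizon[1, 1], sim$release$q[121])
  expect_equal(metrics$band_enter[1, 1], dur$band_interval[["upper"]])
})

test_that("time to the release threshold grows with both layer sizes", {
  grid <- design_grid(core_multipliers = c(0.5, 0.7, 0.9),
                      shell_multipliers = c(1, 5))
  metrics <- sweep_design(grid, bev_params(), bev_dose(),
                          horizon = 360, n_core = 50)
  tq <- metrics$t_q_threshold
  expect_true(all(is.finite(tq)))
  expect_true(all(apply(tq, 2, diff) > 0))  # larger core -> later
  expect_true(all(tq[, 2] > tq[, 1]))       # thicker shell -> later
})

test_that("the threshold intersection is located by interpolation", {
  grid <- design_grid(core_multipliers = c(0.5, 0.6, 0.7, 0.8),
                      shell_multipliers = 1)
  metrics <- sweep_design(grid, bev_params(), bev_dose(),
                          horizon = 180, n_core = 50)
  hit <- find_threshold_intersection(metrics, 1)
  expect_false(hit$degenerate)
  expect_true(hit$core_multiplier >= 0.5 && hit$core_multiplier <= 0.8)
  # at the intersection both metrics should be close
  expect_error(find_threshold_intersection(metrics, 3), "not present")
})

test_that("degenerate and bracketing-failure cases are reported, not guessed", {
  # fabricate a metrics object with identical surfaces
  grid <- design_grid(core_multipliers = c(1, 1.5), shell_multipliers = 1)
  m <- matrix(c(50, 80), 2, 1, dimnames = list(c("1", "1.5"), "1"))
  fake <- structure(list(t_q_threshold = m, t_rate_threshold = m,
                         grid = grid),
                    class = "cs_design_metrics")
  hit <- find_threshold_intersection(fake, 1)
  expect_true(hit$degenerate)
  expect_equal(hit$core_multiplier, 1)

  # no sign change -> NULL with the difference profile returned
  fake2 <- fake
  fake2$t_rate_threshold <- m + 10
  miss <- find_threshold_intersection(fake2, 1)
  expect_null(miss$core_multiplier)
  expect_equal(unname(miss$difference), c(-10, -10))
})

test_that("maximum-duration search breaks ties toward the larger payload", {
  grid <- design_grid(core_multipliers = c(1, 1.5, 2), shell_multipliers = 1)
  m <- matrix(c(100, 120, 120), 3, 1,
              dimnames = list(c("1", "1.5", "2"), "1"))
  fake <- structure(list(t_rate_threshold = m, t_q_threshold = m, grid = grid),
                    class = "cs_design_metrics")
  best <- find_max_duration_config(fake, 1)
  expect_equal(best$core_multiplier, 2)
  expect_true(best$boundary)

  # monotone decreasing column -> boundary flag at the smallest multiplier
  m2 <- matrix(c(120, 110, 100), 3, 1,
               dimnames = list(c("1", "1.5", "2"), "1"))
  fake2 <- structure(list(t_rate_threshold = m2, t_q_threshold = m2, grid = grid),
                     class = "cs_design_metrics")
  best2 <- find_max_duration_config(fake2, 1)
  expect_equal(best2$core_multiplier, 1)
  expect_true(best2$boundary)
})

test_that("sweep matrices export to labelled CSV files", {
  grid <- design_grid(core_multipliers = c(0.5, 1), shell_multipliers = 1)
  metrics <- sweep_design(grid, bev_params(), bev_dose(),
                          horizon = 60, n_core = 40)
  dir <- tempfile()
  paths <- write_design_csv(metrics, dir)
  expect_true(all(file.exists(paths)))
  df <- read.csv(paths[["t_rate_threshold"]], check.names = FALSE)
  expect_named(df, c("core_multiplier", "shell_1"))
  expect_equal(df$core_multiplier, c(0.5, 1))
})
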