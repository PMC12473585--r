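# Shared fixtures: the bevacizumab case study (average fitted parameters)
# and small helpers used across the suite.

baseline_geometry <- function() geometry(5.10, 1.25)

bev_params <- function() transport_params(2.6e-15, 2.6e-12, kappa = 1, burst = 10)

bev_dose <- function() dose_spec(1030, drug = "bevacizumab")

# Solve + summarise one configuration: cumulative release and daily rate.
simulate_release <- function(geom = baseline_geometry(), params = bev_params(),
                             horizon = 180, n_core = 100L, dt = 1,
                             dose = bev_dose()) {
  settings <- solver_settings(save_times = seq(0, horizon, by = dt))
  prof <- solve_concentration(geom, params, settings = settings, n_core = n_core)
  rel <- cumulative_release(prof)
  list(profile = prof, release = rel, rates = release_rate(rel, dose, dt = dt))
}

# A fabricated release curve for metric unit tests (no solve needed).
fake_release <- function(times, q, burst = q[1]) {
  structure(list(times = times, q = q, burst = burst), class = "cs_release")
}

fake_rate <- function(times, rate, dt = 1) {
  structure(list(times = times, rate = rate, dt = dt), class = "cs_rate")
}
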