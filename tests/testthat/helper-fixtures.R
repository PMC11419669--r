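# Shared fixtures, built once per test run. Everything is generated in
# code; the cache avoids re-simulating the same movie across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small quiet configuration: no wound, no bait, low noise.
tiny_cfg <- function(...) {
  px <- 123.26 / 512
  defaults <- list(frame_count = 16, image_size = 96,
                   field_size = 96 * px, baseline_rate_intercept = 12,
                   baseline_rate_slope = 0, drift_sigma = 0,
                   bleach_rate = 0, noise_read = 0.01,
                   noise_photon = 0.002)
  over <- list(...)
  do.call(sim_config, utils::modifyList(defaults, over))
}

tiny_sim <- function() {
  fixture("tiny_sim", function() simulate_epithelium(tiny_cfg(), seed = 42))
}

# One programmed division at the field centre with horizontal axis.
one_division_sim <- function(theta = 0) {
  fixture(paste0("one_div_", round(theta, 3)), function() {
    cfg <- tiny_cfg(baseline_rate_intercept = 0, noise_read = 0,
                    noise_photon = 0)
    sched <- data.frame(frame = 6L, x_px = 48, y_px = 48,
                        theta_rad = theta)
    simulate_epithelium(cfg, seed = 7, schedule = sched)
  })
}

# A wounded simulation with a closing wound.
wounded_sim <- function() {
  fixture("wounded_sim", function() {
    cfg <- tiny_cfg(frame_count = 20, wound_radius = 6,
                    wound_closure_time = 20, debris_count = 3,
                    immune_count = 2)
    simulate_epithelium(cfg, seed = 9)
  })
}

expect_angle_close <- function(a, b, tol_deg) {
  expect_lte(nematic_diff_deg(a, b), tol_deg)
}
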