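test_that("division schedule follows the programmed Poisson intensity", {
  # zero intensity -> no events
  cfg0 <- tiny_cfg(baseline_rate_intercept = 0, baseline_rate_slope = 0)
  expect_equal(nrow(sample_division_schedule(cfg0, seed = 1)), 0)

  # constant rate: mean count over seeds within 3 standard errors of the
  # integral of the programmed intensity
  cfg <- tiny_cfg(baseline_rate_intercept = 20, baseline_rate_slope = 0)
  lambda <- 20 / 1e4 / 10 * cfg$frame_interval *
    cfg$field_size^2 * cfg$frame_count
  counts <- vapply(1:20, function(s) {
    nrow(sample_division_schedule(cfg, seed = s))
  }, numeric(1))
  se <- sqrt(lambda / 20)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("division suppression zone near the wound is empty before the burst", {
  px <- 123.26 / 512
  cfg <- sim_config(frame_count = 50, image_size = 256,
                    field_size = 256 * px,
                    baseline_rate_intercept = 40, baseline_rate_slope = 0,
                    wound_radius = 8, wound_closure_time = 40,
                    suppression_radius = 20, suppression_until = 70,
                    suppression_factor = 0, burst_amplitude = 1)
  ev <- do.call(rbind, lapply(1:5, function(s) {
    sample_division_schedule(cfg, seed = s)
  }))
  expect_gt(nrow(ev), 20)
  t_min <- (ev$frame - 1) * cfg$frame_interval
  cx <- cfg$field_size / 2
  rw <- vapply(t_min, function(tm) {
    cfg$wound_radius * max(0, 1 - tm / cfg$wound_closure_time)
  }, numeric(1))
  d_edge <- sqrt((ev$x_px * px - cx)^2 + (ev$y_px * px - cx)^2) - rw
  in_zone <- d_edge < cfg$suppression_radius & t_min < cfg$suppression_until
  expect_equal(sum(in_zone), 0)
})

test_that("simulation is bit-identical given (config, seed)", {
  a <- simulate_epithelium(tiny_cfg(), seed = 5)
  b <- simulate_epithelium(tiny_cfg(), seed = 5)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$divisions, b$truth$divisions)
  expect_identical(a$truth$cell_label_movie, b$truth$cell_label_movie)
})

test_that("a division renders as metaphase condensation then two separating nuclei", {
  sim <- one_division_sim(theta = 0)
  d <- sim$truth$divisions
  expect_equal(nrow(d), 1)
  t_div <- d$frame[1]
  # one frame after t + 2 min: two local maxima separated along x
  fr <- movie_frame(sim$movie, t_div + 1, "nuclear")
  y0 <- round(d$y_px[1]); x0 <- round(d$x_px[1])
  prof <- fr[y0, (x0 - 10):(x0 + 10)]
  peaks <- which(diff(sign(diff(prof))) == -2) + 1
  expect_gte(length(peaks), 2)
  # metaphase frame is brighter at the centre than an ordinary nucleus frame
  expect_gt(movie_frame(sim$movie, t_div, "nuclear")[y0, x0],
            movie_frame(sim$movie, 1, "nuclear")[y0, x0])
})

test_that("photobleaching decays mean intensity at the programmed rate", {
  cfg <- tiny_cfg(baseline_rate_intercept = 0, bleach_rate = 0.01,
                  noise_read = 0, noise_photon = 0)
  sim <- simulate_epithelium(cfg, seed = 3)
  m <- apply(sim$movie$data[, , 2, ], 3, mean)
  fit <- lm(log(m) ~ seq_along(m))
  expect_equal(unname(coef(fit)[2]), log(1 - 0.01), tolerance = 0.02)
})

test_that("default configuration reproduces the target imaging regime", {
  cfg <- sim_config()
  expect_equal(cfg$frame_count, 93)
  expect_equal(cfg$image_size, 512)
  expect_equal(cfg$field_size, 123.26)
  expect_equal(cfg$frame_interval, 2)
  expect_equal(cfg$pixel_size, 123.26 / 512)
  sim <- simulate_epithelium(cfg, seed = 1)
  expect_equal(dim(sim$movie$data), c(512, 512, 2, 93))
})

test_that("config validation rejects impossible geometries", {
  expect_error(sim_config(wound_radius = 70), "wound_radius")
  expect_error(sim_config(frame_count = 0))
  expect_error(sim_config(anaphase_duration = -1))
})

test_that("wound radius shrinks monotonically to zero by closure time", {
  sim <- wounded_sim()
  areas <- apply(sim$truth$wound_mask_movie, 3, sum)
  radii <- sqrt(areas / pi)
  expect_true(all(diff(radii) <= 1e-9))
  closure_frame <- ceiling(20 / 2) + 1  # wound_closure_time / frame_interval
  expect_equal(sum(areas[closure_frame:length(areas)]), 0)
  expect_gt(areas[1], 0)
})

test_that("ground-truth divisions lie in tissue with theta in [0, pi)", {
  sim <- wounded_sim()
  d <- sim$truth$divisions
  expect_true(all(d$theta_rad >= 0 & d$theta_rad < pi))
  for (k in seq_len(nrow(d))) {
    xi <- min(max(round(d$x_px[k]), 1), 96)
    yi <- min(max(round(d$y_px[k]), 1), 96)
    expect_true(sim$truth$tissue_mask_movie[yi, xi, d$frame[k]])
  }
  # labels are dense positive integers per frame
  lab <- sim$truth$cell_label_movie[, , 1]
  u <- sort(unique(as.vector(lab[lab > 0])))
  expect_true(all(diff(u) >= 1))
})

test_that("rendered z-stacks are sharp on the focal surface", {
  sim <- one_division_sim()
  small <- calibrated_movie(sim$movie$data[, , , 6, drop = FALSE],
                            sim$movie$pixel_size,
                            sim$movie$frame_interval)
  zs <- render_zstack(small, focal_surface = c(3, 0, 0), z_slices = 5)
  expect_equal(dim(zs), c(96, 96, 2, 5, 1))
  expect_equal(attr(zs, "z_step"), 0.75)
  # flat surface at slice 3: that slice is the unblurred image
  expect_equal(zs[, , 2, 3, 1], small$data[, , 2, 1])
  # slices away from the surface are strictly smoother
  v <- vapply(1:5, function(z) var(as.vector(zs[, , 2, z, 1])), numeric(1))
  expect_gt(v[3], v[1])
  expect_gt(v[3], v[5])
  expect_error(render_zstack(small, z_slices = 2), "z_slices")
})
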