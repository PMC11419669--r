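test_that("a static circular wound yields a radial distance geometry", {
  masks <- array(FALSE, c(100, 100, 3))
  for (t in 1:3) masks[, , t] <- mitoscope:::disc_mask(100, 100, 50, 50, 15)
  wt <- wound_track(masks * 1L, pixel_size = 1)
  expect_equal(wt$centres$x_px, rep(50, 3), tolerance = 0.01)
  expect_equal(wt$centres$y_px, rep(50, 3), tolerance = 0.01)
  expect_true(is.na(wt$closure_frame))
  d <- wound_distance(wt, 1)
  expect_equal(d[50, 50], 0)
  expect_equal(d[50, 90], 90 - 50 - 15, tolerance = 1.5)
  expect_true(all(d >= 0))
})

test_that("wound closure frame matches the programmed closure", {
  sim <- wounded_sim()  # closure at 20 min = frame 11
  wt <- wound_track(sim$truth$wound_mask_movie * 1L, movie = sim$movie,
                    pixel_size = sim$movie$pixel_size)
  expect_equal(wt$closure_frame, 11, tolerance = 1)
})

test_that("the wound-site point advects with the supplied flow", {
  flow <- data.frame(dx = rep(1, 9), dy = rep(0, 9))
  wt <- wound_track(flow = flow, frames = 10, image_size = c(64, 64),
                    pixel_size = 1)
  expect_equal(wt$centres$x_px, 32.5 + 0:9)
  expect_equal(wt$centres$y_px, rep(32.5, 10))
})

test_that("banded densities follow the count / observed-area definition", {
  # virtual wound fixed at the centre of a fully observed field
  px <- 1
  flow <- data.frame(dx = rep(0, 4), dy = rep(0, 4))
  wt <- wound_track(flow = flow, frames = 5, image_size = c(201, 201),
                    pixel_size = px)
  tissue <- array(1L, c(201, 201, 5))
  # one division at 25 um from the centre -> band (20, 30], one time bin
  ev <- data.frame(frame = 3L, x_px = 101 + 25, y_px = 101)
  bd <- band_division_density(ev, wt, tissue, frame_interval = 2,
                              band_width = 10, time_bin = 10)
  row <- bd[bd$band_r_inner_um == 20 & bd$t_bin_min == 0, ]
  expect_equal(row$count, 1)
  expect_equal(row$area_um2, pi * (30^2 - 20^2), tolerance = 0.02)
  expect_equal(row$density, 1 / (500 * pi), tolerance = 0.02)
  # total counts conserved across bands
  expect_equal(sum(bd$count), 1)

  # an annulus half outside the field: halved area, doubled density
  wt_edge <- wound_track(flow = flow, frames = 5,
                         image_size = c(201, 201), pixel_size = px)
  wt_edge$centres$x_px[] <- 1
  wt_edge$centres$y_px[] <- 101
  ev2 <- data.frame(frame = 3L, x_px = 1 + 25, y_px = 101)
  bd2 <- band_division_density(ev2, wt_edge, tissue, frame_interval = 2)
  row2 <- bd2[bd2$band_r_inner_um == 20 & bd2$t_bin_min == 0, ]
  expect_equal(row2$area_um2, pi * (30^2 - 20^2) / 2, tolerance = 0.03)
  expect_equal(row2$density, 2 / (500 * pi), tolerance = 0.03)
})

test_that("zero-area bins are flagged undefined rather than zero", {
  flow <- data.frame(dx = 0, dy = 0)
  wt <- wound_track(flow = flow, frames = 2, image_size = c(41, 41),
                    pixel_size = 1)
  tissue <- array(1L, c(41, 41, 2))
  ev <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric())
  bd <- band_division_density(ev, wt, tissue, frame_interval = 2,
                              r_max = 100)
  far <- bd[bd$band_r_inner_um == 90, ]
  expect_true(all(is.na(far$density)))
  expect_true(all(far$count == 0))
})

test_that("the unwounded baseline is an exact least-squares line", {
  d <- data.frame(t_min = c(0, 10, 20, 30),
                  density = 0.002 - 1e-5 * c(0, 10, 20, 30))
  fit <- unwounded_baseline(d)
  expect_equal(fit$intercept, 0.002, tolerance = 1e-12)
  expect_equal(fit$slope, -1e-5, tolerance = 1e-12)
  expect_equal(sum(residuals(fit$fit)^2), 0, tolerance = 1e-20)

  flat <- data.frame(t_min = c(0, 10, 20), density = rep(0.01, 3))
  expect_equal(unwounded_baseline(flat)$slope, 0, tolerance = 1e-12)
  expect_error(unwounded_baseline(flat[1, ]), "at least 2")
})

test_that("density change heatmap is zero when wounded equals baseline", {
  base <- structure(list(intercept = 0.01, slope = -1e-5),
                    class = "baseline_fit")
  bd <- expand.grid(band_r_inner_um = c(0, 10), t_bin_min = c(0, 10))
  bd$count <- 1L
  bd$area_um2 <- 100
  bd$density <- 0.01 - 1e-5 * bd$t_bin_min
  hm <- density_change_heatmap(bd, base)
  expect_true(all(abs(hm) < 1e-12))
  bd$density[2] <- NA
  hm2 <- density_change_heatmap(bd, base)
  expect_true(is.na(hm2[2, 1]))
})

test_that("orientation to wound separates radial from tangential divisions", {
  flow <- data.frame(dx = rep(0, 4), dy = rep(0, 4))
  wt <- wound_track(flow = flow, frames = 5, image_size = c(101, 101),
                    pixel_size = 1)
  # division east of centre dividing along x (radially) and along y
  ev <- data.frame(frame = c(2L, 2L, 2L), x_px = c(81, 81, 51),
                   y_px = c(51, 51, 51),
                   theta_rad = c(0, pi / 2, 0.3))
  out <- orientation_to_wound(ev, wt)
  expect_equal(out$wound_angle_deg[1], 0, tolerance = 1e-6)
  expect_equal(out$wound_angle_deg[2], 90, tolerance = 1e-6)
  expect_true(is.na(out$wound_angle_deg[3]))  # event at the wound centre

  # isotropic axes average to the unbiased 45-degree reference
  set.seed(5)
  n <- 400
  evr <- data.frame(frame = 2L, x_px = runif(n, 60, 100),
                    y_px = runif(n, 1, 101),
                    theta_rad = runif(n, 0, pi))
  outr <- orientation_to_wound(evr, wt)
  expect_equal(mean(outr$wound_angle_deg), 45,
               tolerance = 3 * 26 / sqrt(n) / 45)
})
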