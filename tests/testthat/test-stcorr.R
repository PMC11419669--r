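test_that("division matrix bookkeeping matches the default geometry", {
  empty <- data.frame(frame = integer(), x_px = numeric(),
                      y_px = numeric())
  dm <- division_matrix(empty)
  expect_equal(dm$N, 1368464L)
  expect_equal(dim(dm$M), c(124, 124, 89))
  expect_equal(dm$N_d, 0)

  one <- data.frame(frame = 10L, x_px = 256, y_px = 256)
  dm1 <- division_matrix(one)
  expect_equal(dm1$N_d, 1)
  expect_equal(dm1$N_d / dm1$N, 1 / 1368464)

  # two events in the same 1-um bin collapse (OR)
  two <- data.frame(frame = c(10L, 10L), x_px = c(256, 256.5),
                    y_px = c(256, 256))
  expect_equal(division_matrix(two)$N_d, 1)
})

test_that("annular densities equal the triple-loop oracle on a 10x10x10 matrix", {
  set.seed(4)
  ev <- data.frame(frame = sample(2:11, 12, TRUE),
                   x_px = runif(12, 0, 10 / (123.26 / 512)),
                   y_px = runif(12, 0, 10 / (123.26 / 512)))
  dm <- division_matrix(ev, field_size_um = 10, usable_frames = 10)
  expect_equal(dim(dm$M), c(10, 10, 10))
  for (el in list(c(1, 1, 1), c(5, 5, 5), c(10, 10, 10), c(3, 8, 2))) {
    for (t in c(0, 10, 20)) {
      for (r in c(0, 5, 10)) {
        got <- annular_density(dm, el, t, r, delta_t = 10, delta_r = 5)
        want <- oracle_mi(dm, el[1], el[2], el[3], t, r, 10, 5)
        expect_equal(got, want, info = sprintf("el=%s t=%d r=%d",
                                               paste(el, collapse = ","),
                                               t, r))
      }
    }
  }
})

test_that("a single offset division lands in exactly one annular bin", {
  px <- 123.26 / 512
  # element at matrix index (50, 50, 30) = movie frame 31; the division sits
  # 15 um away at movie frame 29, i.e. a 4-min backward lag
  ev <- data.frame(frame = 29L, x_px = 64.5 / px, y_px = 49.5 / px)
  dm <- division_matrix(ev, field_size_um = 100, usable_frames = 60)
  el <- c(50, 50, 30)
  hits <- outer(c(10, 20, 30), c(10, 20), Vectorize(function(r, t) {
    v <- annular_density(dm, el, t, r)
    !is.na(v) && v > 0
  }))
  expect_equal(sum(hits), 1)
  expect_true(hits[2, 1])  # r in (10, 20], lag 4 min in [0, 10)
})

test_that("field-corner shells are denominator-corrected by about 4x", {
  ev <- data.frame(frame = 5L, x_px = 10, y_px = 10)
  dm <- division_matrix(ev, field_size_um = 100, usable_frames = 20)
  offs <- mitoscope:::annulus_offsets(20, 10)[[1]]
  # brute voxel counts of the clipped shell at the corner vs the interior
  count_at <- function(ix, iy) {
    xs <- ix + offs[, 1]; ys <- iy + offs[, 2]
    sum(xs >= 1 & xs <= 100 & ys >= 1 & ys <= 100)
  }
  expect_equal(count_at(1, 1) / count_at(50, 50), 0.25, tolerance = 0.05)
})

test_that("density correlation vanishes for homogeneous Poisson events", {
  px <- 123.26 / 512
  set.seed(11)
  n <- 150
  ev <- data.frame(frame = sample(2:60, n, TRUE),
                   x_px = runif(n, 0, 80 / px), y_px = runif(n, 0, 80 / px))
  dm <- division_matrix(ev, field_size_um = 80, usable_frames = 60)
  dc <- density_correlation(dm, t_bins = c(10, 20, 30),
                            r_bins = c(10, 20, 30), n_subset = 400,
                            seed = 3)
  # the natural scale of the correlation is the element density N_d / N
  scale <- dm$N_d / dm$N
  expect_true(all(abs(dc$values) < 5 * scale, na.rm = TRUE))
})

test_that("clustered events correlate positively near the origin", {
  cfg <- sim_config()  # full 123.26-um, 93-frame geometry
  ev <- sample_clustered_schedule(cfg, n_clusters = 20,
                                  events_per_cluster = 8,
                                  cluster_radius = 15,
                                  cluster_lifetime = 20, seed = 8)
  dm <- division_matrix(ev)
  dc <- density_correlation(dm, t_bins = c(10, 20, 40, 60),
                            r_bins = c(10, 20, 40, 60), n_subset = 400,
                            seed = 5)
  near <- dc$values["10", "10"]
  far <- dc$values["60", "60"]
  expect_gt(near, 0)
  expect_gt(near, 5 * abs(far))
})

test_that("subset sampling agrees with full enumeration", {
  set.seed(2)
  ev <- data.frame(frame = sample(2:11, 10, TRUE),
                   x_px = runif(10, 0, 20 / (123.26 / 512)),
                   y_px = runif(10, 0, 20 / (123.26 / 512)))
  dm <- division_matrix(ev, field_size_um = 20, usable_frames = 10)
  exact <- density_correlation(dm, t_bins = c(10, 20), r_bins = c(10, 20),
                               n_subset = dm$N + 1, seed = 1)
  sampled <- density_correlation(dm, t_bins = c(10, 20),
                                 r_bins = c(10, 20), n_subset = 300,
                                 seed = 2)
  # population sd from the exact enumeration, finite-population corrected
  se <- sqrt(exact$mi_var / 300) *
    sqrt((dm$N - 300) / (dm$N - 1))
  dev <- abs(sampled$mean_density - exact$mean_density)
  expect_true(all(dev <= 3 * se + 1e-12, na.rm = TRUE))
})

test_that("orientation correlation hits the nematic anchors", {
  px <- 123.26 / 512
  aligned <- data.frame(frame = c(2, 3, 4, 5),
                        x_px = c(10, 30, 50, 70) / px,
                        y_px = rep(10 / px, 4),
                        theta_rad = rep(0.7, 4))
  oc <- orientation_correlation(aligned, t_bins = c(0, 10),
                                r_bins = c(10, 20, 30))
  expect_true(all(oc$values[!is.na(oc$values)] == 1))

  ortho <- data.frame(frame = c(2, 2), x_px = c(10, 20) / px,
                      y_px = c(10, 10) / px, theta_rad = c(0, pi / 2))
  oc2 <- orientation_correlation(ortho, t_bins = c(0),
                                 r_bins = c(10))
  expect_equal(oc2$values["10", "0"], -1)

  # uniform random orientations decorrelate
  set.seed(9)
  n <- 120
  ev <- data.frame(frame = sample(2:40, n, TRUE),
                   x_px = runif(n, 0, 400), y_px = runif(n, 0, 400),
                   theta_rad = runif(n, 0, pi))
  oc3 <- orientation_correlation(ev, t_bins = c(20, 40, 60),
                                 r_bins = c(20, 40, 60))
  ok <- !is.na(oc3$values)
  bound <- 3.5 / sqrt(oc3$pairs[ok])
  expect_true(all(abs(oc3$values[ok]) <= bound))

  # global rotation invariance
  ev_rot <- transform(ev, theta_rad = (theta_rad + 1.1) %% pi)
  oc4 <- orientation_correlation(ev_rot, t_bins = c(20, 40, 60),
                                 r_bins = c(20, 40, 60))
  expect_equal(oc3$values, oc4$values, tolerance = 1e-10)

  expect_error(orientation_correlation(aligned[1, , drop = FALSE]),
               "at least 2")
})
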