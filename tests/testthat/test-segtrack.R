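make_two_basin_map <- function() {
  m <- matrix(1, 40, 40)
  m[mitoscope:::disc_mask(40, 40, 12, 20, 8)] <- 0
  m[mitoscope:::disc_mask(40, 40, 30, 20, 8)] <- 0
  as.matrix(EBImage::gblur(m, 1)) -> m
  (m - min(m)) / (max(m) - min(m))
}

test_that("watershed separates basins and labels densely", {
  lab <- watershed_segment(make_two_basin_map(), h = 0.1)
  ids <- sort(unique(lab[lab > 0]))
  expect_equal(ids, c(1L, 2L))
  # uniform map: a single region
  lab_u <- watershed_segment(matrix(0.5, 20, 20))
  expect_lte(length(unique(lab_u[lab_u > 0])), 1)
})

test_that("segmenting a rendered boundary map recovers the cell count", {
  sim <- tiny_sim()
  lab_true <- sim$truth$cell_label_movie[, , 1]
  bmap <- movie_frame(sim$movie, 1, "junction")
  bmap <- pmin(bmap / max(bmap), 1)
  lab <- watershed_segment(bmap, h = 0.2)
  n_true <- length(unique(as.vector(lab_true)))
  n_got <- max(lab)
  expect_lt(abs(n_got - n_true) / n_true, 0.05)
})

test_that("static labels track through all frames with fixed centroids", {
  lab <- matrix(0L, 30, 30)
  lab[5:12, 5:12] <- 1L
  lab[18:25, 18:25] <- 2L
  mov <- array(rep(lab, 6), c(30, 30, 6))
  tr <- track_cells(mov)
  expect_equal(length(unique(tr$track_id)), 2)
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    expect_equal(sub$frame, 1:6)
    expect_equal(diff(range(sub$x_px)), 0)
    expect_equal(diff(range(sub$area_px)), 0)
  }
  # label conservation: each (frame, label) belongs to exactly one track
  expect_false(any(duplicated(tr[, c("frame", "label")])))
  expect_false(any(duplicated(tr[, c("frame", "track_id")])))
})

test_that("tracks survive a steady 2 px/frame drift", {
  mov <- array(0L, c(40, 40, 8))
  for (t in 1:8) {
    m <- matrix(0L, 40, 40)
    m[(5:14) + 2 * (t - 1), 10:19] <- 1L
    mov[, , t] <- m
  }
  tr <- track_cells(mov)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 8)
  expect_equal(diff(tr$y_px), rep(2, 7))
})

test_that("a division splits one track into two daughters", {
  sim <- one_division_sim(theta = 0)
  lab_mov <- sim$truth$cell_label_movie
  tr <- track_cells(lab_mov)
  d <- sim$truth$divisions
  t_div <- d$frame[1]
  # daughters: tracks born within two frames after the division near it
  births <- do.call(rbind, lapply(split(tr, tr$track_id), function(x) {
    x[which.min(x$frame), ]
  }))
  near_birth <- births[births$frame > t_div & births$frame <= t_div + 2 &
                         sqrt((births$x_px - d$x_px)^2 +
                                (births$y_px - d$y_px)^2) < 20, ]
  expect_gte(nrow(near_birth), 1)
  # the parent cell's track does not extend past the division by much
  parent <- tr[tr$frame == t_div &
                 sqrt((tr$x_px - d$x_px)^2 + (tr$y_px - d$y_px)^2) < 6, ]
  expect_equal(nrow(parent), 1)
})

test_that("track filtering applies the jump rules exactly", {
  good <- data.frame(track_id = 1L, frame = 1:5, label = 1L,
                     x_px = 10, y_px = 10, area_px = c(50, 52, 51, 53, 52),
                     q0 = 0.01)
  jumpy <- data.frame(track_id = 2L, frame = 1:5, label = 2L,
                      x_px = 20, y_px = 20,
                      area_px = c(50, 50, 100, 50, 50), q0 = 0.01)
  shapey <- data.frame(track_id = 3L, frame = 1:5, label = 3L,
                       x_px = 30, y_px = 30, area_px = 50,
                       q0 = c(0.01, 0.01, 0.09, 0.01, 0.01))
  short <- data.frame(track_id = 4L, frame = 1L, label = 4L,
                      x_px = 5, y_px = 5, area_px = 40, q0 = 0.01)
  all_tr <- rbind(good, jumpy, shapey, short)
  kept <- filter_tracks(all_tr, max_area_jump = 0.3, max_shape_jump = 0.03,
                        min_length = 2)
  expect_equal(unique(kept$track_id), 1L)

  # brute-force rule scan agrees on randomised tracks
  set.seed(3)
  rnd <- do.call(rbind, lapply(1:12, function(id) {
    n <- sample(2:6, 1)
    data.frame(track_id = id, frame = 1:n, label = id,
               x_px = 0, y_px = 0,
               area_px = sample(40:80, n, TRUE),
               q0 = runif(n, 0, 0.05))
  }))
  kept2 <- filter_tracks(rnd, 0.3, 0.03, 2)
  oracle <- vapply(split(rnd, rnd$track_id), function(tr) {
    ok <- TRUE
    for (i in seq_len(nrow(tr) - 1)) {
      if (abs(tr$area_px[i + 1] - tr$area_px[i]) / tr$area_px[i] > 0.3) {
        ok <- FALSE
      }
      if (abs(tr$q0[i + 1] - tr$q0[i]) > 0.03) ok <- FALSE
    }
    ok
  }, logical(1))
  expect_setequal(unique(kept2$track_id),
                  as.integer(names(oracle)[oracle]))
})

test_that("daughter pairs report the post-division axis and shuffle", {
  # two daughters separating along the division axis: shuffle ~ 0
  theta <- 0.6
  tr <- do.call(rbind, lapply(1:2, function(k) {
    sgn <- if (k == 1) 1 else -1
    data.frame(track_id = k, frame = 6:20, label = k,
               x_px = 50 + sgn * cos(theta) * (1:15),
               y_px = 50 + sgn * sin(theta) * (1:15),
               area_px = 50, q0 = 0.01)
  }))
  ev <- data.frame(frame = 5L, x_px = 50, y_px = 50, theta_rad = theta)
  dp <- daughter_shuffling(ev, tr, frame_interval = 2, lag = 20)
  expect_true(dp$usable)
  expect_lt(dp$shuffle_shift, 1)
  expect_angle_close(dp$theta_post, theta, 1)

  # lag beyond the movie end: unusable
  dp2 <- daughter_shuffling(ev, tr, frame_interval = 2, lag = 60)
  expect_false(dp2$usable)
  expect_true(is.na(dp2$shuffle_shift))

  # a programmed 30-degree post-division rotation is recovered
  rot <- 30 * pi / 180
  tr3 <- do.call(rbind, lapply(1:2, function(k) {
    sgn <- if (k == 1) 1 else -1
    ang <- theta + rot * pmin((1:15) * 2 / 20, 1)
    data.frame(track_id = k, frame = 6:20, label = k,
               x_px = 50 + sgn * cos(ang) * 6,
               y_px = 50 + sgn * sin(ang) * 6,
               area_px = 50, q0 = 0.01)
  }))
  dp3 <- daughter_shuffling(ev, tr3, frame_interval = 2, lag = 20)
  expect_equal(dp3$shuffle_shift, 30, tolerance = 0.05)
})
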