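test_that("clip bookkeeping matches the sliding-window rule", {
  expect_equal(nrow(extract_clips(93)), 89)
  expect_equal(nrow(extract_clips(93, width = 3)), 89)
  expect_equal(sum(vapply(rep(93, 11), function(T) {
    nrow(extract_clips(T))
  }, numeric(1))), 979)
  expect_equal(nrow(extract_clips(5)), 1)
  expect_error(extract_clips(4), "at least 5")
  clips <- extract_clips(20)
  expect_false(any(duplicated(clips$label_frame)))
  expect_equal(clips$label_frame, clips$start_frame + 1L)
  expect_equal(extract_clips(20, width = 3)$label_frame,
               extract_clips(20, width = 3)$start_frame)
})

test_that("input encodings have the documented shapes and colour structure", {
  sim <- one_division_sim(theta = 0)
  t_div <- sim$truth$divisions$frame[1]
  x0 <- round(sim$truth$divisions$x_px[1])
  y0 <- round(sim$truth$divisions$y_px[1])
  clip <- list(start_frame = t_div - 1L)
  enc <- encode_input(sim$movie, clip, "mc10")
  expect_equal(dim(enc), c(96, 96, 10))
  expect_true(all(enc >= 0 & enc <= 1))

  # 3-frame RGB of a static nucleus is grey (R = G = B)
  rgb_static <- encode_input(sim$movie, list(start_frame = 1L), "rgb3")
  off <- y0 + 20  # a non-dividing neighbourhood
  expect_equal(rgb_static[, off, 1], rgb_static[, off, 2], tolerance = 0.15)

  # 3-frame RGB around the division: red centrally (metaphase only in R),
  # green/blue flanking as the nuclei separate outwards
  rgb_div <- encode_input(sim$movie, list(start_frame = t_div), "rgb3")
  expect_gt(rgb_div[y0, x0, 1], rgb_div[y0, x0, 3])
  sep <- round(6 / sim$movie$pixel_size / 2)  # final separation / 2
  expect_gt(rgb_div[y0, x0 + sep, 3], rgb_div[y0, x0 + sep, 1])

  junk_free <- calibrated_movie(sim$movie$data[, , 2, , drop = FALSE],
                                channels = c(nuclear = 1))
  expect_error(encode_input(junk_free, clip, "mc10"), "junction")
})

test_that("division masks are unions of discs at label-frame events", {
  clip <- list(label_frame = 5L)
  ev0 <- data.frame(frame = 3L, x_px = 50, y_px = 50)
  expect_equal(sum(division_mask(ev0, clip, c(100, 100))), 0)

  ev1 <- data.frame(frame = 5L, x_px = 50, y_px = 60)
  m1 <- division_mask(ev1, clip, c(100, 100), radius_px = 10)
  expect_equal(sum(m1), pi * 10^2, tolerance = 0.02)
  expect_equal(max(m1), 1)

  # overlapping discs stay binary
  ev2 <- data.frame(frame = c(5L, 5L), x_px = c(50, 56), y_px = c(50, 50))
  m2 <- division_mask(ev2, clip, c(100, 100))
  expect_true(all(m2 %in% c(0, 1)))
  expect_lt(sum(m2), 2 * pi * 100)

  ev3 <- data.frame(frame = 5L, x_px = -2, y_px = 50)
  expect_warning(m3 <- division_mask(ev3, clip, c(100, 100)), "clipped")
  expect_lt(sum(m3), pi * 100 / 2 + 30)
})

test_that("orientation targets are correctly sized and oriented ellipses", {
  m0 <- orientation_target(0)
  expect_equal(dim(m0), c(120, 120))
  expect_equal(sum(m0), pi * 50 * 15, tolerance = 0.02)
  # wider than tall
  cols_extent <- range(which(colSums(m0) > 0))
  rows_extent <- range(which(rowSums(m0) > 0))
  expect_gt(diff(cols_extent), diff(rows_extent))
  # 90 degrees is the transpose
  expect_equal(unclass(orientation_target(pi / 2)), t(unclass(m0)))
  expect_error(orientation_target(pi), "theta")
})

test_that("boundary targets mark 3-px-wide interfaces after 2x upscaling", {
  uniform <- matrix(1L, 30, 30)
  expect_equal(sum(boundary_target(uniform)), 0)

  half <- cbind(matrix(1L, 30, 15), matrix(2L, 30, 15))
  bt <- boundary_target(half)
  expect_equal(dim(bt), c(60, 60))
  widths <- rowSums(bt)
  expect_true(all(widths[2:59] == 3))

  sim <- tiny_sim()
  lab <- sim$truth$cell_label_movie[, , 1]
  bt2 <- boundary_target(lab)
  up <- kronecker(lab, matrix(1L, 2, 2))
  n <- nrow(up)
  edge_len <- sum(up[, -1] != up[, -n]) + sum(up[-1, ] != up[-n, ])
  expect_equal(sum(bt2), 3 * edge_len, tolerance = 0.2)
})

test_that("augmentation is seed-deterministic and geometry-consistent", {
  sim <- one_division_sim()
  clip <- list(start_frame = 5L, label_frame = 6L)
  x <- encode_input(sim$movie, clip, "mc10")
  y <- unclass(division_mask(sim$truth$divisions, clip, c(96, 96)))
  a1 <- augment(x, y, seed = 31)
  a2 <- augment(x, y, seed = 31)
  expect_identical(a1$input, a2$input)
  expect_identical(a1$target, a2$target)

  # geometric transform commutes with mask construction
  for (seed in c(2, 3, 8, 15)) {
    p <- augment_params(seed)
    tm <- apply_geometric(y, p)
    ev <- sim$truth$divisions
    pt <- transform_points(ev$x_px, ev$y_px, p, c(96, 96))
    ev2 <- data.frame(frame = ev$frame, x_px = pt$x, y_px = pt$y)
    m2 <- division_mask(ev2, clip, c(96, 96))
    expect_equal(tm, m2, ignore_attr = TRUE)
  }

  # pure horizontal flip maps x to width + 1 - x
  p <- list(k90 = 0L, hflip = TRUE, vflip = FALSE)
  pt <- transform_points(10, 20, p, c(96, 96))
  expect_equal(pt$x, 96 + 1 - 10)
  expect_equal(pt$y, 20)
})

test_that("rotating an orientation target shifts the recovered angle", {
  y <- unclass(orientation_target(pi / 6))
  p <- list(k90 = 1L, hflip = FALSE, vflip = FALSE)
  rot <- apply_geometric(y, p)
  th <- theta_from_q(q_tensor(rot, 0.5))
  expect_angle_close(th, pi / 6 + pi / 2, 1)
})
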