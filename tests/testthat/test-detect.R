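test_that("LoG detection finds disc centres to sub-pixel accuracy", {
  empty <- matrix(0, 120, 120)
  expect_equal(nrow(log_detect(empty)), 0)

  frame <- matrix(0, 256, 256)
  frame[mitoscope:::disc_mask(256, 256, 200, 150, 10)] <- 1
  cand <- log_detect(frame, scale_px = 10, threshold = 0.1)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$x_px - 200)^2 + (cand$y_px - 150)^2), 2)

  frame2 <- frame
  frame2[mitoscope:::disc_mask(256, 256, 160, 150, 10)] <- 1
  cand2 <- log_detect(frame2, scale_px = 10, threshold = 0.1)
  expect_equal(nrow(cand2), 2)
})

test_that("temporal suppression keeps the brightest of linked detections", {
  cand <- data.frame(frame = c(10L, 11L, 12L), x_px = c(50, 50.5, 50),
                     y_px = c(60, 60, 60.5),
                     response = c(0.4, 0.9, 0.5))
  ev <- temporal_nms(cand)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 11L)
  expect_equal(ev$response, 0.9)

  apart <- data.frame(frame = c(5L, 5L), x_px = c(10, 110),
                      y_px = c(10, 10), response = c(0.5, 0.6))
  expect_equal(nrow(temporal_nms(apart)), 2)

  # transitive chain a-b-c groups even though a-c exceeds the radius
  chain <- data.frame(frame = c(1L, 2L, 3L), x_px = c(0, 8, 16),
                      y_px = c(0, 0, 0), response = c(0.2, 0.3, 0.8))
  ev_ch <- temporal_nms(chain, link_radius_px = 10)
  expect_equal(nrow(ev_ch), 1)
  expect_equal(ev_ch$x_px, 16)
})

# brute-force transitive grouping oracle
oracle_groups <- function(cand, radius, gap) {
  n <- nrow(cand)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- abs(cand$frame[i] - cand$frame[j]) <= gap &&
        (cand$x_px[i] - cand$x_px[j])^2 +
          (cand$y_px[i] - cand$y_px[j])^2 <= radius^2
    }
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(reach[i, ])] <- cid
    }
  }
  vapply(split(seq_len(n), comp),
         function(g) g[which.max(cand$response[g])], integer(1))
}

test_that("suppression equals the brute-force grouping oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:18, 1)
    cand <- data.frame(frame = sort(sample(1:6, n, TRUE)),
                       x_px = runif(n, 0, 60), y_px = runif(n, 0, 60),
                       response = runif(n))
    ev <- temporal_nms(cand, link_radius_px = 12, frame_gap = 1)
    keep <- sort(oracle_groups(cand, 12, 1))
    expect_equal(nrow(ev), length(keep))
    expect_setequal(ev$response, cand$response[keep])
    expect_lte(nrow(ev), n)
    # no two surviving events are within the suppression neighbourhood
    if (nrow(ev) > 1) {
      for (i in 1:(nrow(ev) - 1)) {
        for (j in (i + 1):nrow(ev)) {
          close_t <- abs(ev$frame[i] - ev$frame[j]) <= 1
          close_s <- (ev$x_px[i] - ev$x_px[j])^2 +
            (ev$y_px[i] - ev$y_px[j])^2 <= 12^2
          expect_false(close_t && close_s)
        }
      }
    }
  }
})

test_that("response-movie detection is idempotent and sorted", {
  resp <- array(0, c(96, 96, 6))
  tmp1 <- matrix(0, 96, 96)
  tmp1[mitoscope:::disc_mask(96, 96, 30, 40, 10)] <- 0.9
  resp[, , 1] <- tmp1
  tmp <- matrix(0, 96, 96)
  tmp[mitoscope:::disc_mask(96, 96, 70, 20, 10)] <- 0.8
  resp[, , 4] <- tmp
  rm_obj <- structure(list(response = resp, label_frames = 2:7,
                           pixel_size = 0.24, frame_interval = 2),
                      class = "response_movie")
  ev1 <- detect_divisions_from_response(rm_obj, threshold = 0.1)
  ev2 <- detect_divisions_from_response(rm_obj, threshold = 0.1)
  expect_identical(ev1, ev2)
  expect_equal(nrow(ev1), 2)
  expect_equal(ev1$frame, sort(ev1$frame))
})
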