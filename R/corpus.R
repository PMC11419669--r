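# Desk-scale training corpora: synthetic movies turned into paired
# (input, target) samples for the detection and orientation models.

#' Default desk-scale simulation configuration for model training
#'
#' A 128 x 128 px field (30.8 um at the standard calibration) imaged for
#' 26 frames, with the division rate raised so each short movie carries a
#' handful of divisions, and (for odd seeds) a small wound with motile
#' debris and immune-cell bait so the detector learns to reject the same
#' false-positive sources it will meet at evaluation time.
#'
#' @param image_size field side in pixels.
#' @param frame_count frames per movie.
#' @param wounded include a wound plus bait.
#' @return A [sim_config()].
#' @export
desk_train_config <- function(image_size = 128, frame_count = 26,
                              wounded = FALSE) {
  px <- 123.26 / 512
  sim_config(frame_count = frame_count, image_size = image_size,
             field_size = image_size * px,
             baseline_rate_intercept = 10, baseline_rate_slope = -0.01,
             wound_radius = if (wounded) 6 else 0,
             wound_closure_time = 30,
             suppression_radius = 8, suppression_until = 20,
             burst_amplitude = 1,
             debris_count = if (wounded) 4 else 0,
             immune_count = if (wounded) 2 else 1,
             drift_sigma = 0.3)
}

#' Build detection training samples from a simulated movie
#'
#' One sample per clip window whose label frame carries at least one
#' division (capped at `max_positive`), plus `negatives` windows without
#' divisions: inputs are the 10-channel encoding, targets the
#' division-circle mask.
#'
#' @param sim output of [simulate_epithelium()].
#' @param max_positive cap on division windows per movie.
#' @param negatives number of division-free windows per movie.
#' @param radius_px division-circle radius.
#' @param seed seed for window selection.
#' @return List of samples, each `list(x, y)`.
#' @export
detection_samples <- function(sim, max_positive = 3, negatives = 1,
                              radius_px = 10, seed = 1L) {
  clips <- extract_clips(sim$movie, width = 5)
  div <- sim$truth$divisions
  has_div <- clips$label_frame %in% div$frame
  with_seed(seed, {
    pos <- which(has_div)
    if (length(pos) > max_positive) pos <- sort(sample(pos, max_positive))
    neg <- which(!has_div)
    if (length(neg) > negatives) neg <- sort(sample(neg, negatives))
    lapply(c(pos, neg), function(k) {
      clip <- clips[k, ]
      list(x = encode_input(sim$movie, clip, "mc10"),
           y = unclass(division_mask(div, clip, dim(sim$movie$data)[1:2],
                                     radius_px)))
    })
  })
}

#' Build orientation training samples from a simulated movie
#'
#' One sample per ground-truth division: the 120 x 120 ten-channel crop
#' around the division paired with the oriented oval target.
#'
#' @param sim output of [simulate_epithelium()].
#' @param max_per_movie cap on divisions used per movie.
#' @param seed selection seed.
#' @return List of samples, each `list(x, y, theta)`.
#' @export
orientation_samples <- function(sim, max_per_movie = Inf, seed = 1L) {
  div <- sim$truth$divisions
  TT <- n_frames(sim$movie)
  div <- div[div$frame >= 2 & div$frame <= TT - 3, , drop = FALSE]
  if (nrow(div) == 0) return(list())
  with_seed(seed, {
    if (nrow(div) > max_per_movie) {
      div <- div[sort(sample(nrow(div), max_per_movie)), , drop = FALSE]
    }
    lapply(seq_len(nrow(div)), function(k) {
      list(x = crop_division(sim$movie, div[k, ]),
           y = unclass(orientation_target(div$theta_rad[k])),
           theta = div$theta_rad[k])
    })
  })
}

#' Restrict ground-truth divisions to the detectable frame range
#'
#' Divisions at the first movie frame and in the last frames have no
#' valid clip window (label frames span 2 .. T-3) and cannot be detected
#' by construction; evaluation excludes them.
#'
#' @param divisions ground-truth events data frame.
#' @param n_frames movie frame count.
#' @return Filtered data frame.
#' @export
detectable_divisions <- function(divisions, n_frames) {
  divisions[divisions$frame >= 2 & divisions$frame <= n_frames - 3, ,
            drop = FALSE]
}

#' Calibrate the detection threshold on validation movies
#'
#' Sweeps the LoG peak threshold over `thresholds` and returns the value
#' maximising the event-matching Dice score on the given movies.
#'
#' @param model trained detection model.
#' @param sims list of [simulate_epithelium()] outputs (validation split).
#' @param thresholds candidate thresholds.
#' @return List with `threshold` and the per-threshold `dice` table.
#' @export
calibrate_threshold <- function(model, sims,
                                thresholds = seq(0.05, 0.6, by = 0.05)) {
  resp <- lapply(sims, function(s) predict_movie(model, s$movie))
  dice <- vapply(thresholds, function(th) {
    tot <- c(0, 0, 0)
    for (i in seq_along(sims)) {
      ev <- detect_divisions_from_response(resp[[i]], threshold = th)
      truth <- detectable_divisions(sims[[i]]$truth$divisions,
                                    n_frames(sims[[i]]$movie))
      mm <- match_divisions(ev, truth)
      tot <- tot + c(mm$Tp, mm$Fp, mm$Fn)
    }
    if (sum(tot) == 0) 0 else 2 * tot[1] / (2 * tot[1] + tot[2] + tot[3])
  }, numeric(1))
  list(threshold = thresholds[which.max(dice)],
       dice = data.frame(threshold = thresholds, dice = dice))
}

#' Simulate a desk-scale corpus of training movies
#'
#' Simulates `n` movies under [desk_train_config()] (alternating unwounded
#' and wounded) with seeds derived from `seed`.
#'
#' @param n number of movies.
#' @param seed base seed.
#' @param image_size,frame_count forwarded to [desk_train_config()].
#' @return List of [simulate_epithelium()] outputs.
#' @export
simulate_corpus <- function(n, seed = 1L, image_size = 128,
                            frame_count = 26) {
  movie_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    cfg <- desk_train_config(image_size, frame_count,
                             wounded = i %% 2 == 1)
    simulate_epithelium(cfg, seed = movie_seeds[i])
  })
}
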