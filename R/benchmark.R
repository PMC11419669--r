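# Desk-scale end-to-end benchmarks: train the detection and orientation
# models on a synthetic corpus and measure event-matching Dice, the
# orientation error against ground truth, recovery of the programmed
# wound burst/suppression, and correlation-function behaviour. These are
# the package's reference experiments; both the test suite and the
# acceptance script run them.

#' Train and evaluate the desk-scale division detector
#'
#' Simulates a corpus of `n_movies` short movies (train/validation/test
#' split 30/5/5 at the default size), trains the 10-channel detection
#' model, calibrates the LoG threshold on the validation movies, and
#' reports event-matching Dice on the held-out test movies.
#'
#' @param seed master seed for the corpus, initialisation and training.
#' @param n_movies corpus size (default 40).
#' @param epochs training epochs (default 12).
#' @param base_width network width (default 16).
#' @return List: `model`, `threshold`, `dice` (test), `counts`
#'   (Tp/Fp/Fn), `history`, `val_dice`, and the test simulations.
#' @export
desk_detection_benchmark <- function(seed = 1L, n_movies = 40,
                                     epochs = 14, base_width = 16) {
  sims <- simulate_corpus(n_movies, seed = seed)
  n_test <- max(1L, round(n_movies / 8))
  n_val <- max(1L, round(n_movies / 8))
  idx_test <- seq(n_movies - n_test + 1L, n_movies)
  idx_val <- seq(n_movies - n_test - n_val + 1L, n_movies - n_test)
  idx_train <- setdiff(seq_len(n_movies), c(idx_val, idx_test))
  train_s <- unlist(lapply(idx_train, function(i) {
    detection_samples(sims[[i]], seed = seed + i)
  }), recursive = FALSE)
  val_s <- unlist(lapply(idx_val, function(i) {
    detection_samples(sims[[i]], seed = seed + i)
  }), recursive = FALSE)
  model <- build_model(net_config(10, base_width, 3), seed = seed)
  fit <- train_divnet(model, train_s, val_s,
                      train_config(epochs = epochs, batch_size = 4,
                                   learning_rate = 1e-3, seed = seed))
  cal <- calibrate_threshold(fit$model, sims[idx_val])
  tot <- c(Tp = 0L, Fp = 0L, Fn = 0L)
  for (s in sims[idx_test]) {
    ev <- detect_divisions(fit$model, s$movie, threshold = cal$threshold)
    truth <- detectable_divisions(s$truth$divisions, n_frames(s$movie))
    mm <- match_divisions(ev, truth)
    tot <- tot + c(mm$Tp, mm$Fp, mm$Fn)
  }
  list(model = fit$model, threshold = cal$threshold,
       dice = dice_score(tot[1], tot[2], tot[3]), counts = tot,
       history = fit$history, val_dice = cal$dice,
       sims_test = sims[idx_test])
}

#' Train and evaluate the desk-scale orientation model
#'
#' Trains the oval-output orientation model on cropped ground-truth
#' divisions from a synthetic corpus and reports the median nematic error
#' between predicted and programmed division axes on held-out movies.
#'
#' @param seed master seed.
#' @param n_movies corpus size (default 40; split as in
#'   [desk_detection_benchmark()]).
#' @param epochs training epochs (default 6).
#' @param base_width network width (default 12; the oval task is easier
#'   than detection, so a slimmer model trains faster at no cost in
#'   accuracy).
#' @param max_per_movie crops per training movie.
#' @return List: `model`, `median_error_deg`, `errors_deg`, `history`.
#' @export
desk_orientation_benchmark <- function(seed = 1L, n_movies = 40,
                                       epochs = 6, base_width = 12,
                                       max_per_movie = 2) {
  sims <- simulate_corpus(n_movies, seed = seed)
  n_test <- max(1L, round(n_movies / 8))
  n_val <- max(1L, round(n_movies / 8))
  idx_test <- seq(n_movies - n_test + 1L, n_movies)
  idx_val <- seq(n_movies - n_test - n_val + 1L, n_movies - n_test)
  idx_train <- setdiff(seq_len(n_movies), c(idx_val, idx_test))
  train_s <- unlist(lapply(idx_train, function(i) {
    orientation_samples(sims[[i]], max_per_movie, seed = seed + i)
  }), recursive = FALSE)
  val_s <- unlist(lapply(idx_val, function(i) {
    orientation_samples(sims[[i]], max_per_movie, seed = seed + i)
  }), recursive = FALSE)
  model <- build_model(net_config(10, base_width, 3), seed = seed + 1L)
  fit <- train_divnet(model, train_s, val_s,
                      train_config(epochs = epochs, batch_size = 4,
                                   learning_rate = 1e-3, seed = seed))
  errors <- c()
  for (s in sims[idx_test]) {
    d <- s$truth$divisions
    TT <- n_frames(s$movie)
    d <- d[d$frame >= 2 & d$frame <= TT - 3, , drop = FALSE]
    if (nrow(d) == 0) next
    est <- estimate_orientation(fit$model, s$movie, d)
    ok <- !is.na(est$theta_rad)
    errors <- c(errors, nematic_diff_deg(est$theta_rad[ok],
                                         d$theta_rad[ok]))
  }
  list(model = fit$model, median_error_deg = median(errors),
       errors_deg = errors, history = fit$history)
}

#' Recovery of the programmed wound burst and suppression zone
#'
#' Samples division schedules for wounded and unwounded movies under the
#' full-field geometry (pooling roughly as many divisions as a
#' hand-labelled multi-movie corpus), runs the banded-density pipeline on
#' the wounded events (wound masks constructed from the programmed
#' closing disc), fits the unwounded linear baseline, and locates the
#' burst and the suppression zone. Because single band-by-time bins hold
#' few events, the burst time is found on the area-weighted density
#' change pooled over bands, and the ring location as the excess of the
#' programmed 20-70 um band range over the remaining bands during the
#' burst bins.
#'
#' @param seed master seed.
#' @param n_wounded,n_unwounded movies per condition.
#' @return List: `heatmap`, `baseline`, `burst_time_bin` (bin start of
#'   the peak pooled density change, minutes), `burst_peak_change`,
#'   `ring_excess` (ring minus non-ring mean change during the burst
#'   bins), `suppression_mean_change` (area-weighted mean change within
#'   20 um of the wound before 60 min).
#' @export
burst_recovery_benchmark <- function(seed = 1L, n_wounded = 9,
                                     n_unwounded = 14) {
  wd_cfg <- sim_config(wound_radius = 10, wound_closure_time = 40)
  uw_cfg <- sim_config()
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      n_wounded + n_unwounded))
  n_px <- wd_cfg$image_size
  TT <- wd_cfg$frame_count
  fi <- wd_cfg$frame_interval
  cx <- n_px / 2 + 0.5
  wound_masks <- array(FALSE, c(n_px, n_px, TT))
  for (t in seq_len(TT)) {
    rw <- wound_radius_at(wd_cfg, (t - 1) * fi) / wd_cfg$pixel_size
    wound_masks[, , t] <- disc_mask(n_px, n_px, cx, cx, rw)
  }
  tissue <- !wound_masks
  flow0 <- data.frame(dx = rep(0, TT - 1), dy = rep(0, TT - 1))
  wt <- wound_track(wound_masks * 1L, flow = flow0,
                    pixel_size = wd_cfg$pixel_size)
  agg <- NULL
  for (i in seq_len(n_wounded)) {
    ev <- sample_division_schedule(wd_cfg, seeds[i])
    bd <- band_division_density(ev, wt, tissue, frame_interval = fi)
    if (is.null(agg)) {
      agg <- bd
    } else {
      agg$count <- agg$count + bd$count
      agg$area_um2 <- agg$area_um2 + bd$area_um2
    }
  }
  agg$area_um2 <- agg$area_um2 / n_wounded
  agg$count <- agg$count / n_wounded
  agg$density <- ifelse(agg$area_um2 > 0, agg$count / agg$area_um2,
                        NA_real_)

  # unwounded baseline: whole-field density per time bin (virtual wound)
  uw_tissue <- array(TRUE, c(n_px, n_px, TT))
  uw_wt <- wound_track(flow = flow0, frames = TT,
                       image_size = c(n_px, n_px),
                       pixel_size = uw_cfg$pixel_size)
  uw_bd <- NULL
  for (i in seq_len(n_unwounded)) {
    ev <- sample_division_schedule(uw_cfg, seeds[n_wounded + i])
    bd <- band_division_density(ev, uw_wt, uw_tissue, frame_interval = fi)
    if (is.null(uw_bd)) {
      uw_bd <- bd
    } else {
      uw_bd$count <- uw_bd$count + bd$count
      uw_bd$area_um2 <- uw_bd$area_um2 + bd$area_um2
    }
  }
  uw_bd$count <- uw_bd$count / n_unwounded
  uw_bd$area_um2 <- uw_bd$area_um2 / n_unwounded
  uw_bd$density <- ifelse(uw_bd$area_um2 > 0,
                          uw_bd$count / uw_bd$area_um2, NA_real_)
  baseline <- unwounded_baseline(uw_bd)
  hm <- density_change_heatmap(agg, baseline)

  # pooled (area-weighted) density change per time bin: sum of counts over
  # bands / sum of observed areas, minus the baseline prediction
  tbins <- sort(unique(agg$t_bin_min))
  tbins <- tbins[tbins <= 180]
  pooled <- vapply(tbins, function(tb) {
    sel <- agg$t_bin_min == tb & agg$area_um2 > 0
    sum(agg$count[sel]) / sum(agg$area_um2[sel]) -
      (baseline$intercept + baseline$slope * tb)
  }, numeric(1))
  burst_time_bin <- tbins[which.max(pooled)]

  # ring excess: change in the programmed 20-70 um bands vs the others,
  # pooled over the two bins straddling the programmed burst time
  burst_bins <- c(wd_cfg$burst_time - 10, wd_cfg$burst_time)
  pool_change <- function(rows) {
    sel <- agg$t_bin_min %in% burst_bins & rows & agg$area_um2 > 0
    tb_mean <- mean(burst_bins) + 5
    sum(agg$count[sel]) / sum(agg$area_um2[sel]) -
      (baseline$intercept + baseline$slope * tb_mean)
  }
  in_ring <- agg$band_r_inner_um >= wd_cfg$burst_r_inner &
    agg$band_r_inner_um < wd_cfg$burst_r_outer
  ring_excess <- pool_change(in_ring) - pool_change(!in_ring)

  # suppression: area-weighted change within 20 um of the wound, before
  # the suppression window ends
  supp_sel <- agg$band_r_inner_um < wd_cfg$suppression_radius &
    agg$t_bin_min < wd_cfg$suppression_until - 10 & agg$area_um2 > 0
  supp_change <- sum(agg$count[supp_sel]) / sum(agg$area_um2[supp_sel]) -
    (baseline$intercept +
       baseline$slope * mean(agg$t_bin_min[supp_sel]))
  list(heatmap = hm, baseline = baseline,
       burst_time_bin = burst_time_bin,
       burst_peak_change = max(pooled),
       ring_excess = ring_excess,
       suppression_mean_change = supp_change)
}

#' Correlation-function null and clustering checks
#'
#' Computes the division-density correlation for (i) a homogeneous
#' Poisson schedule, where it should vanish, and (ii) a clustered
#' schedule, where it should be positive near the origin and decay.
#'
#' @param seed master seed.
#' @return List: `null_max_abs`, `null_scale` (element density N_d/N),
#'   `clustered_origin`, `clustered_far`.
#' @export
correlation_benchmark <- function(seed = 1L) {
  # constant rate: the homogeneous-Poisson null needs a flat intensity
  cfg <- sim_config(baseline_rate_slope = 0)
  ev0 <- sample_division_schedule(cfg, seed)
  dm0 <- division_matrix(ev0)
  dc0 <- density_correlation(dm0, t_bins = c(10, 20, 30),
                             r_bins = c(10, 20, 30), seed = seed)
  evc <- sample_clustered_schedule(cfg, n_clusters = 20,
                                   events_per_cluster = 8,
                                   cluster_radius = 15,
                                   cluster_lifetime = 20, seed = seed)
  dmc <- division_matrix(evc)
  dcc <- density_correlation(dmc, t_bins = c(10, 20, 40, 60),
                             r_bins = c(10, 20, 40, 60), seed = seed)
  list(null_max_abs = max(abs(dc0$values), na.rm = TRUE),
       null_scale = dm0$N_d / dm0$N,
       clustered_origin = dcc$values["10", "10"],
       clustered_far = dcc$values["60", "60"])
}
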