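#' Simulation configuration for synthetic epithelium movies
#'
#' Defines the imaging regime being emulated: a 512-pixel field covering
#' 123.26 um imaged every 2 minutes for 93 frames, cells on a relaxed
#' hexagonal lattice, divisions with a short condensed-metaphase phase
#' followed by anaphase separation over ~6 minutes, an optional circular
#' wound that closes linearly in time (with division suppression near the
#' wound early on and a ring-shaped synchronised burst of divisions at
#' `burst_time`), motile bright debris and immune-cell bait, photobleaching,
#' frame-to-frame drift and confocal-style noise.
#'
#' Baseline division rates are expressed in divisions per (100 um)^2 per
#' 10 min; `baseline_rate_slope` is the per-minute linear decline of that
#' rate, matching the linear decrease of division density with
#' developmental time in unwounded tissue.
#'
#' @param frame_count number of frames.
#' @param frame_interval minutes between frames.
#' @param field_size physical field of view in um (square).
#' @param image_size image side in pixels (pixel size = field_size/image_size).
#' @param cell_spacing mean cell centre spacing, um.
#' @param nucleus_sigma Gaussian nucleus radius, um.
#' @param metaphase_frames frames of condensed bright metaphase nucleus.
#' @param anaphase_duration minutes from anaphase onset to full separation.
#' @param final_separation daughter nucleus separation at end of anaphase, um.
#' @param baseline_rate_intercept,baseline_rate_slope linear-in-time division
#'   rate: divisions (100 um)^-2 (10 min)^-1 and its change per minute.
#' @param wound_radius initial wound radius in um (0 = unwounded).
#' @param wound_closure_time minutes until the wound radius reaches 0.
#' @param suppression_radius,suppression_until,suppression_factor divisions
#'   within `suppression_radius` um of the wound edge before
#'   `suppression_until` minutes have their rate multiplied by
#'   `suppression_factor`.
#' @param burst_time,burst_amplitude,burst_r_inner,burst_r_outer,burst_sigma_t
#'   ring-shaped division burst: between `burst_r_inner` and `burst_r_outer`
#'   um from the wound edge the rate is multiplied by up to `burst_amplitude`
#'   with a Gaussian time profile centred at `burst_time` (sd `burst_sigma_t`
#'   minutes).
#' @param debris_count,immune_count numbers of bright motile false-positive
#'   baits rendered in the nuclear channel.
#' @param bleach_rate per-frame fractional intensity loss.
#' @param drift_sigma per-frame drift step sd, pixels.
#' @param noise_read,noise_photon Gaussian read noise sd and shot-noise gain
#'   (sd = sqrt(I * noise_photon)).
#' @param post_division_rotation degrees by which the daughter-pair axis
#'   rotates over the 20 min following division (models daughter shuffling).
#' @param seed default seed used when none is passed to the generators.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(frame_count = 93, frame_interval = 2,
                       field_size = 123.26, image_size = 512,
                       cell_spacing = 4.5, nucleus_sigma = 1.1,
                       metaphase_frames = 2, anaphase_duration = 6,
                       final_separation = 6,
                       baseline_rate_intercept = 9,
                       baseline_rate_slope = -0.015,
                       wound_radius = 0, wound_closure_time = 60,
                       suppression_radius = 20, suppression_until = 70,
                       suppression_factor = 0,
                       burst_time = 100, burst_amplitude = 2,
                       burst_r_inner = 20, burst_r_outer = 70,
                       burst_sigma_t = 10,
                       debris_count = 0, immune_count = 0,
                       bleach_rate = 0.005, drift_sigma = 0.5,
                       noise_read = 0.02, noise_photon = 0.01,
                       post_division_rotation = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(frame_count >= 1, frame_interval > 0, field_size > 0,
              image_size >= 16, cell_spacing > 0, nucleus_sigma > 0,
              metaphase_frames >= 1, anaphase_duration > 0,
              final_separation > 0, wound_closure_time > 0,
              burst_sigma_t > 0)
  })
  if (cfg$wound_radius < 0 || cfg$wound_radius >= cfg$field_size / 2) {
    stop("wound_radius must lie in [0, field_size/2)")
  }
  cfg$pixel_size <- cfg$field_size / cfg$image_size
  class(cfg) <- "sim_config"
  cfg
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

wound_radius_at <- function(config, t_min) {
  if (config$wound_radius <= 0) return(0)
  config$wound_radius * max(0, 1 - t_min / config$wound_closure_time)
}

# Rate modulation factor at distance d_um from the wound edge, time t_min.
wound_modulation <- function(config, d_um, t_min) {
  m <- rep(1, length(d_um))
  if (config$wound_radius <= 0) return(m)
  supp <- t_min < config$suppression_until & d_um < config$suppression_radius
  m[supp] <- config$suppression_factor
  ring <- !supp & d_um >= config$burst_r_inner & d_um <= config$burst_r_outer
  bump <- (config$burst_amplitude - 1) *
    exp(-(t_min - config$burst_time)^2 / (2 * config$burst_sigma_t^2))
  m[ring] <- m[ring] * (1 + bump)
  m
}

#' Sample a division schedule from the programmed intensity
#'
#' Draws division events from an inhomogeneous Poisson process whose
#' intensity is a linear-in-time baseline multiplied by the wound
#' modulation (suppression disc near the wound before the burst, ring
#' burst around `burst_time`). Events never fall inside the current wound.
#' Negative baseline intensities are clipped to zero.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the schedule is deterministic given
#'   `(config, seed)`.
#' @return Data frame with columns `frame` (1-based), `x_px`, `y_px`,
#'   `theta_rad` in `[0, pi)`.
#' @export
sample_division_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  px <- config$pixel_size
  area <- config$field_size^2
  cx <- config$field_size / 2
  with_seed(seed, {
    out <- vector("list", config$frame_count)
    for (t in seq_len(config$frame_count)) {
      t_min <- (t - 1) * config$frame_interval
      lam0 <- max(0, config$baseline_rate_intercept +
                    config$baseline_rate_slope * t_min) / 1e4 / 10 *
        config$frame_interval
      if (lam0 <= 0) next
      mmax <- max(1, config$burst_amplitude)
      n <- rpois(1, lam0 * mmax * area)
      if (n == 0) next
      x <- runif(n, 0, config$field_size)
      y <- runif(n, 0, config$field_size)
      rw <- wound_radius_at(config, t_min)
      dc <- sqrt((x - cx)^2 + (y - cx)^2)
      d_edge <- dc - rw
      keep <- d_edge > 0 | config$wound_radius <= 0
      m <- wound_modulation(config, pmax(d_edge, 0), t_min)
      acc <- keep & (runif(n) < m / mmax)
      if (!any(acc)) next
      out[[t]] <- data.frame(frame = t, x_px = x[acc] / px,
                             y_px = y[acc] / px,
                             theta_rad = runif(sum(acc), 0, pi))
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- data.frame(frame = integer(), x_px = numeric(),
                                        y_px = numeric(),
                                        theta_rad = numeric())
    rownames(res) <- NULL
    res
  })
}

#' Sample a clustered division schedule
#'
#' Utility generator for correlation-function studies: divisions arrive in
#' clusters, each cluster occupying a disc of radius `cluster_radius` um and
#' a time window of `cluster_lifetime` minutes.
#'
#' @param config a [sim_config()] (geometry and timing are taken from it).
#' @param n_clusters expected number of clusters.
#' @param events_per_cluster expected divisions per cluster.
#' @param cluster_radius spatial cluster radius, um.
#' @param cluster_lifetime temporal cluster extent, minutes.
#' @param seed integer seed.
#' @return Data frame as in [sample_division_schedule()].
#' @export
sample_clustered_schedule <- function(config, n_clusters = 20,
                                      events_per_cluster = 6,
                                      cluster_radius = 15,
                                      cluster_lifetime = 20,
                                      seed = config$seed) {
  px <- config$pixel_size
  t_total <- config$frame_count * config$frame_interval
  with_seed(seed, {
    k <- rpois(1, n_clusters)
    res <- list()
    for (i in seq_len(k)) {
      cx <- runif(1, 0, config$field_size)
      cy <- runif(1, 0, config$field_size)
      ct <- runif(1, 0, t_total)
      n <- rpois(1, events_per_cluster)
      if (n == 0) next
      r <- cluster_radius * sqrt(runif(n))
      a <- runif(n, 0, 2 * pi)
      x <- pmin(pmax(cx + r * cos(a), 0), config$field_size)
      y <- pmin(pmax(cy + r * sin(a), 0), config$field_size)
      tm <- pmin(pmax(ct + runif(n, 0, cluster_lifetime), 0), t_total - 1e-9)
      res[[i]] <- data.frame(frame = floor(tm / config$frame_interval) + 1,
                             x_px = x / px, y_px = y / px,
                             theta_rad = runif(n, 0, pi))
    }
    out <- do.call(rbind, res)
    if (is.null(out)) out <- data.frame(frame = integer(), x_px = numeric(),
                                        y_px = numeric(),
                                        theta_rad = numeric())
    out <- out[order(out$frame), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# Jittered hexagonal lattice of cell seeds covering the image, Lloyd-relaxed
# against the pixel grid (2 iterations).
hex_seeds <- function(image_size, spacing_px, jitter_frac = 0.15) {
  dy <- spacing_px * sqrt(3) / 2
  rows <- seq(-spacing_px, image_size + spacing_px, by = dy)
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing_px / 2 else 0
    xs <- seq(-spacing_px + off, image_size + spacing_px, by = spacing_px)
    cbind(xs, rows[i])
  }))
  pts <- pts + matrix(rnorm(length(pts), 0, jitter_frac * spacing_px),
                      ncol = 2)
  colnames(pts) <- c("x", "y")
  for (it in 1:2) {
    lab <- cpp_nearest_label(image_size, image_size, pts[, 1], pts[, 2])
    xs <- rep(seq_len(image_size), each = image_size)
    ys <- rep(seq_len(image_size), times = image_size)
    v <- as.vector(lab)
    cnt <- tabulate(v, nbins = nrow(pts))
    sx <- rowsum(xs, v); sy <- rowsum(ys, v)
    ids <- as.integer(rownames(sx))
    inside <- cnt[ids] > 0
    pts[ids[inside], 1] <- sx[inside] / cnt[ids][inside]
    pts[ids[inside], 2] <- sy[inside] / cnt[ids][inside]
  }
  pts
}

# Additive Gaussian blob render, vectorised over a local window.
add_blob <- function(img, x, y, sigma_px, amp) {
  n <- nrow(img)
  m <- ncol(img)
  r <- ceiling(4 * sigma_px)
  i0 <- max(1, floor(y - r)); i1 <- min(n, ceiling(y + r))
  j0 <- max(1, floor(x - r)); j1 <- min(m, ceiling(x + r))
  if (i0 > i1 || j0 > j1) return(img)
  gy <- exp(-((i0:i1) - y)^2 / (2 * sigma_px^2))
  gx <- exp(-((j0:j1) - x)^2 / (2 * sigma_px^2))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp * outer(gy, gx)
  img
}

# Relabel a window of the label map after seeds moved (local Voronoi patch).
relabel_window <- function(lab, seeds, cx, cy, win_px) {
  n <- nrow(lab)
  i0 <- max(1, floor(cy - win_px)); i1 <- min(n, ceiling(cy + win_px))
  j0 <- max(1, floor(cx - win_px)); j1 <- min(ncol(lab), ceiling(cx + win_px))
  margin <- win_px * 1.8
  near <- which(abs(seeds[, 1] - cx) < margin & abs(seeds[, 2] - cy) < margin)
  if (length(near) == 0) return(lab)
  sub <- cpp_nearest_label(i1 - i0 + 1, j1 - j0 + 1,
                           seeds[near, 1] - (j0 - 1),
                           seeds[near, 2] - (i0 - 1))
  lab[i0:i1, j0:j1] <- near[sub]
  lab
}

edge_mask <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  e <- matrix(FALSE, n, m)
  dif <- lab[, -1] != lab[, -m]
  e[, -1] <- e[, -1] | dif; e[, -m] <- e[, -m] | dif
  dif <- lab[-1, ] != lab[-n, ]
  e[-1, ] <- e[-1, ] | dif; e[-n, ] <- e[-n, ] | dif
  e
}

disc_mask <- function(n, m, cx, cy, r_px) {
  if (r_px <= 0) return(matrix(FALSE, n, m))
  dy <- (seq_len(n) - cy)^2
  dx <- (seq_len(m) - cx)^2
  outer(dy, dx, "+") <= r_px^2
}

#' Simulate a ground-truthed synthetic epithelium movie
#'
#' Renders a two-channel movie (junction boundary network + Gaussian
#' nuclei) over a Lloyd-relaxed Voronoi tessellation of a jittered
#' hexagonal lattice. Each scheduled division shows `metaphase_frames`
#' frames of a condensed bright nucleus, then two nuclei separating along
#' the division axis to `final_separation` um over `anaphase_duration`
#' minutes; the daughter cells receive a new shared junction edge. A wound
#' is a closing dark disc carrying bright debris puncta and motile immune
#' blobs in the nuclear channel. Photobleaching, drift and noise are
#' applied last; ground truth is recorded pre-noise.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; output is deterministic given `(config, seed)`.
#' @param schedule optional division schedule (data frame as returned by
#'   [sample_division_schedule()]) overriding the sampled one; used for
#'   controlled experiments with programmed divisions.
#' @return A list with `movie` (a [calibrated_movie()]) and `truth`, a list
#'   holding `divisions` (frame, x_px, y_px, theta_rad), `wound_mask_movie`
#'   and `tissue_mask_movie` (`Y x X x T` logical), `cell_label_movie`
#'   (`Y x X x T` integer) and `drift` (per-frame cumulative dx, dy in px).
#' @export
simulate_epithelium <- function(config, seed = config$seed,
                                schedule = NULL) {
  stopifnot(inherits(config, "sim_config"))
  px <- config$pixel_size
  n <- config$image_size
  TT <- config$frame_count
  spacing_px <- config$cell_spacing / px
  nuc_sd <- config$nucleus_sigma / px
  n_ana <- max(1, round(config$anaphase_duration / config$frame_interval))
  sched <- if (is.null(schedule)) sample_division_schedule(config, seed)
           else schedule

  with_seed(seed + 13L, {
    seeds <- hex_seeds(n, spacing_px)
    n_cells <- nrow(seeds)
    amp <- 0.8 + 0.4 * runif(n_cells)

    # Assign each scheduled division to the nearest free cell; ground-truth
    # location is that cell's nucleus (division time = last metaphase frame).
    taken <- rep(FALSE, n_cells)
    div <- list()
    if (nrow(sched) > 0) {
      for (k in seq_len(nrow(sched))) {
        d2 <- (seeds[, 1] - sched$x_px[k])^2 + (seeds[, 2] - sched$y_px[k])^2
        ord <- order(d2)
        cand <- ord[!taken[ord]][1]
        if (is.na(cand) || d2[cand] > (2 * spacing_px)^2) next
        taken[cand] <- TRUE
        div[[length(div) + 1]] <- data.frame(
          frame = sched$frame[k], cell = cand,
          x_px = seeds[cand, 1], y_px = seeds[cand, 2],
          theta_rad = sched$theta_rad[k])
      }
    }
    div <- if (length(div)) do.call(rbind, div) else
      data.frame(frame = integer(), cell = integer(), x_px = numeric(),
                 y_px = numeric(), theta_rad = numeric())

    drift_steps <- matrix(rnorm(2 * TT, 0, config$drift_sigma), ncol = 2)
    drift_steps[1, ] <- 0
    drift <- apply(drift_steps, 2, cumsum)
    colnames(drift) <- c("dx", "dy")

    base_lab <- cpp_nearest_label(n, n, seeds[, 1], seeds[, 2])
    cx_px <- n / 2 + 0.5

    # Motile bait state
    n_deb <- config$debris_count
    deb <- if (n_deb > 0) {
      r0 <- max(2, config$wound_radius / px * 0.8)
      ang <- runif(n_deb, 0, 2 * pi)
      rr <- r0 * sqrt(runif(n_deb))
      cbind(x = cx_px + rr * cos(ang), y = cx_px + rr * sin(ang))
    } else NULL
    n_imm <- config$immune_count
    imm <- if (n_imm > 0)
      cbind(x = runif(n_imm, 1, n), y = runif(n_imm, 1, n),
            dir = runif(n_imm, 0, 2 * pi)) else NULL

    data <- array(0, c(n, n, 2, TT))
    wound_movie <- array(FALSE, c(n, n, TT))
    tissue_movie <- array(TRUE, c(n, n, TT))
    label_movie <- array(0L, c(n, n, TT))
    truth_div <- div

    cur_seeds <- seeds       # grows as daughters appear
    lab <- base_lab

    daughter_axis <- function(k, t) {
      # axis angle including programmed post-division shuffling rotation
      done <- div$frame[k] + n_ana
      extra <- if (config$post_division_rotation != 0 && t > done) {
        frac <- min(1, (t - done) * config$frame_interval / 20)
        config$post_division_rotation * pi / 180 * frac
      } else 0
      div$theta_rad[k] + extra
    }

    for (t in seq_len(TT)) {
      t_min <- (t - 1) * config$frame_interval
      dx <- drift[t, 1]; dy <- drift[t, 2]
      nuc <- matrix(0, n, n)

      rw_px <- wound_radius_at(config, t_min) / px
      wmask <- disc_mask(n, n, cx_px + dx, cx_px + dy, rw_px)

      # non-dividing nuclei (dividing cells render in their own branch)
      active <- rep(TRUE, n_cells)
      if (nrow(div) > 0) active[div$cell] <- FALSE
      for (c in which(active)) {
        if (rw_px > 0 &&
            (seeds[c, 1] - cx_px)^2 + (seeds[c, 2] - cx_px)^2 < rw_px^2) next
        nuc <- add_blob(nuc, seeds[c, 1] + dx, seeds[c, 2] + dy, nuc_sd, amp[c])
      }

      # dividing cells
      if (nrow(div) > 0) {
        for (k in seq_len(nrow(div))) {
          td <- div$frame[k]
          if (t < td - config$metaphase_frames + 1) {
            nuc <- add_blob(nuc, div$x_px[k] + dx, div$y_px[k] + dy,
                            nuc_sd, amp[div$cell[k]])
          } else if (t <= td) {
            nuc <- add_blob(nuc, div$x_px[k] + dx, div$y_px[k] + dy,
                            nuc_sd * 0.65, amp[div$cell[k]] * 1.7)
          } else {
            frac <- min(1, (t - td) / n_ana)
            sep_px <- config$final_separation / px * frac
            th <- daughter_axis(k, t)
            ux <- cos(th) * sep_px / 2; uy <- sin(th) * sep_px / 2
            a <- amp[div$cell[k]] * (1.2 - 0.2 * frac)
            nuc <- add_blob(nuc, div$x_px[k] + ux + dx, div$y_px[k] + uy + dy,
                            nuc_sd * 0.85, a)
            nuc <- add_blob(nuc, div$x_px[k] - ux + dx, div$y_px[k] - uy + dy,
                            nuc_sd * 0.85, a)
            if (t == td + 1) {
              # daughters enter the tessellation: split the parent cell
              s1 <- c(div$x_px[k] + cos(th) * spacing_px / 3,
                      div$y_px[k] + sin(th) * spacing_px / 3)
              s2 <- c(div$x_px[k] - cos(th) * spacing_px / 3,
                      div$y_px[k] - sin(th) * spacing_px / 3)
              cur_seeds[div$cell[k], ] <- s1
              cur_seeds <- rbind(cur_seeds, s2)
              lab <- relabel_window(lab, cur_seeds, div$x_px[k], div$y_px[k],
                                    2.5 * spacing_px)
            }
          }
        }
      }

      # bait: debris random walk with flicker, immune persistent walk
      if (!is.null(deb)) {
        deb[, 1] <- deb[, 1] + rnorm(n_deb, 0, 1.5)
        deb[, 2] <- deb[, 2] + rnorm(n_deb, 0, 1.5)
        fl <- 0.7 + 0.9 * runif(n_deb)
        for (k in seq_len(n_deb)) {
          nuc <- add_blob(nuc, deb[k, 1] + dx, deb[k, 2] + dy,
                          nuc_sd * 0.55, fl[k])
        }
      }
      if (!is.null(imm)) {
        imm[, 3] <- imm[, 3] + rnorm(n_imm, 0, 0.5)
        step <- runif(n_imm, 1, 3)
        imm[, 1] <- pmin(pmax(imm[, 1] + step * cos(imm[, 3]), 1), n)
        imm[, 2] <- pmin(pmax(imm[, 2] + step * sin(imm[, 3]), 1), n)
        bright <- 0.9 + 0.8 * (runif(n_imm) < 0.15)
        for (k in seq_len(n_imm)) {
          nuc <- add_blob(nuc, imm[k, 1] + dx, imm[k, 2] + dy,
                          nuc_sd * 1.2, bright[k])
        }
      }

      # junction channel from the (drift-shifted) label map
      sh <- shift_int(lab, round(dy), round(dx))
      jun <- matrix(0, n, n)
      jun[edge_mask(sh)] <- 1
      jun <- gblur_safe(jun, 0.7)

      if (rw_px > 0) {
        jun[wmask] <- jun[wmask] * 0.05
        nuc[wmask] <- nuc[wmask] * 0.1
      }

      fade <- (1 - config$bleach_rate)^(t - 1)
      # movies live in [0, 1]; the factor 2 leaves headroom so condensed
      # metaphase nuclei stay brighter than interphase ones
      nuc <- pmin(nuc / 2, 1) * fade
      jun <- pmin(jun, 1) * fade

      label_frame <- sh
      label_frame[wmask] <- 0L
      label_movie[, , t] <- label_frame
      wound_movie[, , t] <- wmask
      tissue_movie[, , t] <- !wmask
      data[, , 1, t] <- jun
      data[, , 2, t] <- nuc
    }

    # divisions never inside the wound at their frame (schedule guarantees
    # this pre-snap; re-check post-snap and drop violations)
    if (nrow(truth_div) > 0) {
      keep <- vapply(seq_len(nrow(truth_div)), function(k) {
        t <- truth_div$frame[k]
        x <- truth_div$x_px[k] + drift[t, 1]
        y <- truth_div$y_px[k] + drift[t, 2]
        xi <- min(max(round(x), 1), n); yi <- min(max(round(y), 1), n)
        tissue_movie[yi, xi, t]
      }, logical(1))
      truth_div <- truth_div[keep, , drop = FALSE]
      truth_div$x_px <- truth_div$x_px + drift[truth_div$frame, 1]
      truth_div$y_px <- truth_div$y_px + drift[truth_div$frame, 2]
    }
    truth_div <- truth_div[order(truth_div$frame, truth_div$x_px), ]
    rownames(truth_div) <- NULL

    # noise applied last, after ground truth capture
    if (config$noise_read > 0 || config$noise_photon > 0) {
      nz <- rnorm(length(data), 0, config$noise_read) +
        rnorm(length(data)) * sqrt(pmax(data, 0) * config$noise_photon)
      data <- pmax(data + nz, 0)
    }
    data <- pmin(data, 1)

    movie <- calibrated_movie(data, pixel_size = px,
                              frame_interval = config$frame_interval)
    truth <- list(divisions = truth_div[, c("frame", "x_px", "y_px",
                                            "theta_rad")],
                  wound_mask_movie = wound_movie,
                  tissue_mask_movie = tissue_movie,
                  cell_label_movie = label_movie,
                  drift = as.data.frame(drift))
    list(movie = movie, truth = truth)
  })
}

# Integer-shift a label matrix, replicating border rows/cols.
shift_int <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  ri <- pmin(pmax(seq_len(n) - di, 1), n)
  cj <- pmin(pmax(seq_len(p) - dj, 1), p)
  m[ri, cj, drop = FALSE]
}

#' Render a defocused z-stack from a 2D movie
#'
#' Each z-slice is the 2D image blurred with a Gaussian whose sigma grows
#' with the distance |z - focal_surface(x, y)|; the in-focus slice index at
#' each pixel equals the rounded focal surface. The focal surface is a
#' plane `a + b * (x/X) + c * (y/Y)` expressed in slice-index units.
#'
#' @param movie a [calibrated_movie()].
#' @param focal_surface numeric length-3 `(a, b, c)` plane coefficients in
#'   slice units.
#' @param z_slices number of slices (>= 3).
#' @param z_step slice spacing in um (default 0.75).
#' @param defocus_sigma blur sd in pixels added per slice of defocus.
#' @return 5-D array `[Y, X, C, Z, T]` with attributes `z_step` and
#'   `focal_surface`.
#' @export
render_zstack <- function(movie, focal_surface = c(3, 0, 0), z_slices = 5,
                          z_step = 0.75, defocus_sigma = 1.5) {
  stopifnot(z_slices >= 3)
  d <- dim(movie$data)
  n <- d[1]; m <- d[2]
  fx <- matrix(rep((seq_len(m) - 1) / m, each = n), n, m)
  fy <- matrix(rep((seq_len(n) - 1) / n, times = m), n, m)
  fsurf <- focal_surface[1] + focal_surface[2] * fx + focal_surface[3] * fy
  fsurf <- pmin(pmax(fsurf, 1), z_slices)
  out <- array(0, c(n, m, d[3], z_slices, d[4]))
  max_dz <- z_slices - 1
  for (t in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      img <- movie$data[, , c, t]
      blurred <- vector("list", max_dz + 1)
      blurred[[1]] <- img
      for (k in seq_len(max_dz)) {
        blurred[[k + 1]] <- gblur_safe(img, defocus_sigma * k)
      }
      for (z in seq_len(z_slices)) {
        lev <- pmin(pmax(round(abs(z - fsurf)), 0), max_dz)
        slice <- blurred[[1]]
        for (k in sort(unique(as.vector(lev)))) {
          if (k == 0) next
          sel <- lev == k
          slice[sel] <- blurred[[k + 1]][sel]
        }
        out[, , c, z, t] <- slice
      }
    }
  }
  # FFT-based blurring can overshoot marginally; keep slices in [0, 1]
  out <- pmin(pmax(out, 0), 1)
  attr(out, "z_step") <- z_step
  attr(out, "focal_surface") <- focal_surface
  out
}

#' Write simulation ground truth to disk
#'
#' Divisions go to a CSV with header `frame,x_px,y_px,theta_rad`; wound and
#' tissue masks to 8-bit multi-page TIFFs; cell labels to a 16-bit TIFF.
#'
#' @param truth the `truth` component of [simulate_epithelium()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(truth$divisions, file.path(dir, "divisions.csv"),
            row.names = FALSE)
  write_mask_tiff(truth$wound_mask_movie * 1L,
                  file.path(dir, "wound_mask.tif"), bits = 8L)
  write_mask_tiff(truth$tissue_mask_movie * 1L,
                  file.path(dir, "tissue_mask.tif"), bits = 8L)
  write_mask_tiff(truth$cell_label_movie,
                  file.path(dir, "cell_labels.tif"), bits = 16L)
  invisible(dir)
}
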