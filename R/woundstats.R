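# Wound-referenced measurements: wound-site tracking (with virtual wounds
# for unwounded movies), distance bands, banded division densities, the
# unwounded linear baseline, change heatmaps, and division orientation
# relative to the wound.

# Mean displacement of image content within a window around a point,
# estimated by integer-shift cross-correlation of the nuclear channel.
estimate_local_flow <- function(movie, x, y, frame, window_um = 30,
                                max_shift = 4) {
  if (frame >= n_frames(movie)) return(c(0, 0))
  nc <- if ("nuclear" %in% names(movie$channels)) "nuclear" else 1
  a <- movie_frame(movie, frame, nc)
  b <- movie_frame(movie, frame + 1, nc)
  w <- round(window_um / movie$pixel_size)
  n <- nrow(a); m <- ncol(a)
  i0 <- max(1, round(y) - w); i1 <- min(n, round(y) + w)
  j0 <- max(1, round(x) - w); j1 <- min(m, round(x) + w)
  pa <- a[i0:i1, j0:j1]
  best <- c(0, 0); bestv <- -Inf
  for (di in -max_shift:max_shift) {
    for (dj in -max_shift:max_shift) {
      ii <- (i0:i1) + di; jj <- (j0:j1) + dj
      ok_i <- ii >= 1 & ii <= n; ok_j <- jj >= 1 & jj <= m
      if (!any(ok_i) || !any(ok_j)) next
      pb <- b[ii[ok_i], jj[ok_j]]
      va <- pa[ok_i, ok_j]
      v <- sum(va * pb) / sqrt(sum(va^2) * sum(pb^2) + 1e-12)
      if (v > bestv) { bestv <- v; best <- c(dj, di) }
    }
  }
  best
}

#' Track the wound (or a virtual wound) through a movie
#'
#' Before closure the wound centre is the mask centroid. After closure --
#' or throughout, for unwounded movies, where an arbitrary reference point
#' (the image centre) serves as a virtual wound -- the wound-site point is
#' advected each frame by the mean displacement of the surrounding tissue
#' (estimated from the nuclear channel within `advect_window_um`, or taken
#' from a supplied per-frame flow table). If no flow is available the
#' point is held fixed with a warning.
#'
#' @param wound_masks `Y x X x T` logical/0-1 array of wound masks, or
#'   `NULL` for an unwounded movie.
#' @param movie optional [calibrated_movie()] used for flow estimation.
#' @param flow optional data frame with per-frame `dx`, `dy` displacement
#'   in pixels (applied from each frame to the next).
#' @param frames number of frames (required when both `wound_masks` and
#'   `movie` are `NULL`-ish).
#' @param image_size integer `c(Y, X)`; defaults from masks or movie.
#' @param pixel_size um per pixel.
#' @param advect_window_um advection window radius (default 30 um).
#' @return A list of class `wound_track`: `centres` (frame, x_px, y_px),
#'   `closure_frame` (`NA` if never open), `radius_px` per frame.
#' @export
wound_track <- function(wound_masks = NULL, movie = NULL, flow = NULL,
                        frames = NULL, image_size = NULL,
                        pixel_size = 123.26 / 512,
                        advect_window_um = 30) {
  if (!is.null(movie)) {
    frames <- n_frames(movie)
    image_size <- dim(movie$data)[1:2]
    pixel_size <- movie$pixel_size
  }
  if (!is.null(wound_masks)) {
    if (length(dim(wound_masks)) == 2L) {
      dim(wound_masks) <- c(dim(wound_masks), 1L)
    }
    frames <- dim(wound_masks)[3]
    image_size <- dim(wound_masks)[1:2]
  }
  if (is.null(frames) || is.null(image_size)) {
    stop("supply wound_masks, movie, or frames + image_size")
  }
  centres <- data.frame(frame = seq_len(frames), x_px = NA_real_,
                        y_px = NA_real_)
  radius <- numeric(frames)
  open <- logical(frames)
  if (!is.null(wound_masks)) {
    for (t in seq_len(frames)) {
      w <- wound_masks[, , t] > 0
      if (any(w)) {
        open[t] <- TRUE
        idx <- which(w, arr.ind = TRUE)
        centres$y_px[t] <- mean(idx[, 1])
        centres$x_px[t] <- mean(idx[, 2])
        radius[t] <- sqrt(sum(w) / pi)
      }
    }
  }
  closure_frame <- if (any(open)) {
    last_open <- max(which(open))
    if (last_open < frames) last_open + 1L else NA_integer_
  } else NA_integer_
  # advect from the last known point (or start a virtual wound centrally)
  start_t <- if (any(open)) max(which(open)) else 0L
  if (start_t == 0L) {
    centres$x_px[1] <- (image_size[2] + 1) / 2
    centres$y_px[1] <- (image_size[1] + 1) / 2
    start_t <- 1L
  }
  warned <- FALSE
  if (start_t < frames) {
    for (t in start_t:(frames - 1)) {
      d <- if (!is.null(flow)) {
        c(flow$dx[t], flow$dy[t])
      } else if (!is.null(movie)) {
        estimate_local_flow(movie, centres$x_px[t], centres$y_px[t], t,
                            advect_window_um)
      } else {
        if (!warned) {
          warning("no flow source; holding wound-site point fixed")
          warned <- TRUE
        }
        c(0, 0)
      }
      centres$x_px[t + 1] <- centres$x_px[t] + d[1]
      centres$y_px[t + 1] <- centres$y_px[t] + d[2]
    }
  }
  structure(list(centres = centres, closure_frame = closure_frame,
                 radius_px = radius, wound_masks = wound_masks,
                 pixel_size = pixel_size, image_size = image_size),
            class = "wound_track")
}

#' Distance-to-wound map for one frame
#'
#' Before closure, the exact Euclidean distance (in um) from the wound
#' edge, computed on the calibrated grid; zero inside the wound. After
#' closure (or for virtual wounds), radial distance from the tracked
#' wound-site point.
#'
#' @param wtrack a [wound_track()].
#' @param frame frame index.
#' @return `Y x X` matrix of distances in um.
#' @export
wound_distance <- function(wtrack, frame) {
  sz <- wtrack$image_size
  masks <- wtrack$wound_masks
  if (!is.null(masks) && any(masks[, , frame] > 0)) {
    d <- EBImage::distmap(1 - masks[, , frame])
    return(as.matrix(d) * wtrack$pixel_size)
  }
  cx <- wtrack$centres$x_px[frame]; cy <- wtrack$centres$y_px[frame]
  dy <- (seq_len(sz[1]) - cy)^2
  dx <- (seq_len(sz[2]) - cx)^2
  sqrt(outer(dy, dx, "+")) * wtrack$pixel_size
}

#' Banded division densities around a wound
#'
#' Assigns each division to the 10-um annular band containing its
#' distance-to-wound at its frame, and to a 10-min time bin. The band area
#' is the per-frame visible tissue area within the band (excluding the
#' wound and anything outside the field), averaged over the frames of the
#' bin; the density is count / area, so a band half outside the field of
#' view gets twice the density for the same count. Bins with zero observed
#' area get `NA` density.
#'
#' @param events data frame with `frame`, `x_px`, `y_px`.
#' @param wtrack a [wound_track()].
#' @param tissue_masks `Y x X x T` tissue masks (1 = observed tissue).
#' @param frame_interval minutes per frame.
#' @param band_width band width in um (default 10).
#' @param time_bin bin width in minutes (default 10).
#' @param r_max largest band outer radius (default: field diagonal).
#' @return Data frame with `band_r_inner_um`, `t_bin_min` (bin start),
#'   `count`, `area_um2`, `density` (divisions per um^2 per bin).
#' @export
band_division_density <- function(events, wtrack, tissue_masks,
                                  frame_interval = 2, band_width = 10,
                                  time_bin = 10, r_max = NULL) {
  sz <- wtrack$image_size
  px <- wtrack$pixel_size
  TT <- nrow(wtrack$centres)
  if (is.null(r_max)) {
    r_max <- ceiling(sqrt(sum((sz * px)^2)) / band_width) * band_width
  }
  n_bands <- as.integer(r_max / band_width)
  frames_per_bin <- time_bin / frame_interval
  n_tbin <- ceiling(TT / frames_per_bin)
  counts <- matrix(0L, n_bands, n_tbin)
  area_sum <- matrix(0, n_bands, n_tbin)
  frames_in_bin <- integer(n_tbin)
  for (t in seq_len(TT)) {
    dmap <- wound_distance(wtrack, t)
    tb <- floor((t - 1) / frames_per_bin) + 1L
    frames_in_bin[tb] <- frames_in_bin[tb] + 1L
    tis <- tissue_masks[, , t] > 0
    band_of <- pmin(pmax(ceiling(dmap / band_width), 1L), n_bands)
    ar <- tabulate(band_of[tis & dmap > 0], nbins = n_bands) * px^2
    area_sum[, tb] <- area_sum[, tb] + ar
    sel <- which(events$frame == t)
    for (k in sel) {
      xi <- min(max(round(events$x_px[k]), 1), sz[2])
      yi <- min(max(round(events$y_px[k]), 1), sz[1])
      dv <- dmap[yi, xi]
      if (dv <= 0) next
      b <- min(max(ceiling(dv / band_width), 1L), n_bands)
      counts[b, tb] <- counts[b, tb] + 1L
    }
  }
  mean_area <- sweep(area_sum, 2, pmax(frames_in_bin, 1L), "/")
  out <- data.frame(
    band_r_inner_um = rep((seq_len(n_bands) - 1L) * band_width, n_tbin),
    t_bin_min = rep((seq_len(n_tbin) - 1L) * time_bin, each = n_bands),
    count = as.vector(counts),
    area_um2 = as.vector(mean_area))
  out$density <- ifelse(out$area_um2 > 0, out$count / out$area_um2,
                        NA_real_)
  out
}

#' Linear baseline of unwounded division density over time
#'
#' Ordinary least squares of density against time.
#'
#' @param densities data frame with `t_min` and `density` (one row per
#'   time bin; `NA` densities dropped), or the output of
#'   [band_division_density()] (aggregated over bands per time bin:
#'   total count / total area).
#' @return A list of class `baseline_fit` with `intercept`, `slope` and
#'   the underlying `lm` fit.
#' @export
unwounded_baseline <- function(densities) {
  if (!is.null(densities$band_r_inner_um)) {
    agg <- stats::aggregate(cbind(count, area_um2) ~ t_bin_min,
                            data = densities, FUN = sum)
    densities <- data.frame(t_min = agg$t_bin_min,
                            density = ifelse(agg$area_um2 > 0,
                                             agg$count / agg$area_um2,
                                             NA_real_))
  }
  d <- densities[!is.na(densities$density), , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 time bins")
  fit <- lm(density ~ t_min, data = d)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]), fit = fit),
            class = "baseline_fit")
}

#' Change in division density relative to the unwounded baseline
#'
#' Entry (band, time bin) = wounded density minus the baseline prediction
#' at that time; positive entries mean more divisions than equivalent
#' unwounded tissue, negative fewer. Undefined densities propagate as
#' `NA`.
#'
#' @param band_df output of [band_division_density()] for wounded movies.
#' @param baseline a `baseline_fit` from [unwounded_baseline()].
#' @return Matrix with bands as rows (labelled by inner radius) and time
#'   bins as columns (labelled by bin start, minutes).
#' @export
density_change_heatmap <- function(band_df, baseline) {
  bands <- sort(unique(band_df$band_r_inner_um))
  tbins <- sort(unique(band_df$t_bin_min))
  m <- matrix(NA_real_, length(bands), length(tbins),
              dimnames = list(band_r_inner_um = bands, t_bin_min = tbins))
  pred <- baseline$intercept + baseline$slope * band_df$t_bin_min
  for (k in seq_len(nrow(band_df))) {
    i <- match(band_df$band_r_inner_um[k], bands)
    j <- match(band_df$t_bin_min[k], tbins)
    m[i, j] <- band_df$density[k] - pred[k]
  }
  m
}

#' Division orientation relative to the wound
#'
#' The nematic difference, folded to [0, 90] degrees, between each
#' division axis and the radial direction from the wound centre (at the
#' division's frame) to the division: 0 means dividing towards the wound,
#' 90 tangentially. Events at the wound centre have no radial direction
#' and get `NA`. With isotropic orientations the mean is 45 degrees, the
#' unbiased reference.
#'
#' @param events data frame with `frame`, `x_px`, `y_px`, `theta_rad`.
#' @param wtrack a [wound_track()] (or a list with `centres`).
#' @return `events` with a `wound_angle_deg` column appended.
#' @export
orientation_to_wound <- function(events, wtrack) {
  ang <- rep(NA_real_, nrow(events))
  for (k in seq_len(nrow(events))) {
    th <- events$theta_rad[k]
    if (is.na(th)) next
    t <- events$frame[k]
    cx <- wtrack$centres$x_px[t]; cy <- wtrack$centres$y_px[t]
    dx <- events$x_px[k] - cx; dy <- events$y_px[k] - cy
    if (dx == 0 && dy == 0) next
    phi <- atan2(dy, dx)
    ang[k] <- nematic_diff_deg(th, phi)
  }
  events$wound_angle_deg <- ang
  events
}
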