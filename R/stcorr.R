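# Space-time correlation functions of division density and orientation:
# annular-tube mean mitosis densities with edge correction, the
# subset-sampled density correlation, and the nematic orientation
# correlation.

#' Binarised (x, y, t) division matrix
#'
#' Converts an event table into a binary matrix over 1-um spatial bins and
#' single-frame time bins. The default geometry (123.26 um field, 89
#' usable frames) gives a 124 x 124 x 89 matrix with N = 1,368,464
#' elements; each element represents a 1 um^2 x one-frame space-time
#' slice. Only `usable_frames` frames starting at `first_frame` enter the
#' matrix (division information is incomplete at the movie ends).
#'
#' @param events data frame with `frame`, `x_px`, `y_px` (pixels).
#' @param field_size_um physical field size (spatial bin count is its
#'   ceiling).
#' @param usable_frames number of time slices (default 89).
#' @param first_frame first usable movie frame (default 2, the first
#'   label frame of the 5-frame windows).
#' @param pixel_size um per pixel.
#' @param frame_interval minutes per frame.
#' @return A list of class `division_matrix`: `M` (logical array), `N`,
#'   `N_d`, bin geometry.
#' @export
division_matrix <- function(events, field_size_um = 123.26,
                            usable_frames = 89, first_frame = 2,
                            pixel_size = 123.26 / 512,
                            frame_interval = 2) {
  nx <- as.integer(ceiling(field_size_um))
  nt <- as.integer(usable_frames)
  M <- array(FALSE, c(nx, nx, nt))
  if (nrow(events) > 0) {
    it <- events$frame - first_frame + 1L
    keep <- it >= 1 & it <= nt
    ix <- pmin(pmax(floor(events$x_px[keep] * pixel_size) + 1L, 1L), nx)
    iy <- pmin(pmax(floor(events$y_px[keep] * pixel_size) + 1L, 1L), nx)
    M[cbind(ix, iy, it[keep])] <- TRUE
  }
  structure(list(M = M, N = as.integer(nx) * nx * nt, N_d = sum(M),
                 nx = nx, ny = nx, nt = nt,
                 frame_interval = frame_interval),
            class = "division_matrix")
}

#' @export
print.division_matrix <- function(x, ...) {
  cat(sprintf("division_matrix: %d x %d x %d (N = %s), N_d = %d\n",
              x$nx, x$ny, x$nt, format(x$N, big.mark = ","), x$N_d))
  invisible(x)
}

# Integer offsets (dx, dy) whose euclidean length falls in (r - dr, r],
# grouped per r bin; r = 0 is the single central cell.
annulus_offsets <- function(r_bins, delta_r) {
  rmax <- max(r_bins)
  g <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  d <- sqrt(g$dx^2 + g$dy^2)
  lapply(r_bins, function(r) {
    if (r == 0) cbind(dx = 0L, dy = 0L)
    else as.matrix(g[d > r - delta_r & d <= r, c("dx", "dy")])
  })
}

# Mean mitosis density profile M_i(t, r) for one element, over all bin
# combinations. Numerators count divisions in the annular tube; the
# denominator is the observed space-time volume only (elements outside the
# matrix are excluded). Temporal window is the backward slab
# (T - t, T - t + delta_t] in minutes, i.e. lags in [t - delta_t, t);
# t = 0 uses only the element's own time slice, r = 0 only its own
# spatial cell.
mi_profile <- function(dm, ix, iy, it, t_bins, r_bins, offsets,
                       div_idx, delta_t = 10, delta_r = 10) {
  fi <- dm$frame_interval
  out <- matrix(NA_real_, length(r_bins), length(t_bins),
                dimnames = list(r = r_bins, t = t_bins))
  # spatial in-grid counts per r bin
  sp_count <- integer(length(r_bins))
  for (k in seq_along(r_bins)) {
    off <- offsets[[k]]
    xs <- ix + off[, 1]; ys <- iy + off[, 2]
    ok <- xs >= 1 & xs <= dm$nx & ys >= 1 & ys <= dm$ny
    sp_count[k] <- sum(ok)
  }
  # distances from this element to every division
  if (nrow(div_idx) > 0) {
    dr <- sqrt((div_idx[, 1] - ix)^2 + (div_idx[, 2] - iy)^2)
    lag_min <- (it - div_idx[, 3]) * fi
  } else {
    dr <- numeric(0); lag_min <- numeric(0)
  }
  for (kt in seq_along(t_bins)) {
    t <- t_bins[kt]
    if (t == 0) {
      tmask <- lag_min == 0
      tdepth <- 1L
    } else {
      tmask <- lag_min >= t - delta_t & lag_min < t
      # frames s with (it - s) * fi in [t - delta_t, t), clipped to matrix
      lags <- seq(t - delta_t, t - fi / 2, by = fi)
      s <- it - lags / fi
      tdepth <- sum(s >= 1 & s <= dm$nt)
    }
    if (tdepth == 0) next
    for (kr in seq_along(r_bins)) {
      r <- r_bins[kr]
      if (sp_count[kr] == 0) next
      rmask <- if (r == 0) dr == 0 else dr > r - delta_r & dr <= r
      out[kr, kt] <- sum(rmask & tmask) / (sp_count[kr] * tdepth)
    }
  }
  out
}

#' Annular-tube mean mitosis density around one element
#'
#' @param dm a [division_matrix()].
#' @param element integer `c(ix, iy, it)` matrix indices of the element.
#' @param t_lag temporal bin label in minutes (0, 10, 20, ...).
#' @param r spatial bin label in um (0, 10, 20, ...).
#' @param delta_t,delta_r bin widths (10 min, 10 um).
#' @return The density (divisions per observed space-time element), or
#'   `NA` if the tube is fully unobserved.
#' @export
annular_density <- function(dm, element, t_lag, r, delta_t = 10,
                            delta_r = 10) {
  stopifnot(inherits(dm, "division_matrix"))
  div_idx <- which(dm$M, arr.ind = TRUE)
  offs <- annulus_offsets(r, delta_r)
  mi_profile(dm, element[1], element[2], element[3], t_lag, r, offs,
             div_idx, delta_t, delta_r)[1, 1]
}

#' Division density correlation function
#'
#' Computes `<M(0,0) M(t,r)>_c = <M(0,0) M(t,r)> - <M(0,0)> <M(t,r)>`.
#' The first term is `(1/N) * sum over division elements of M_i(t,r)`
#' (only the densities around divisions contribute); `<M(0,0)> = N_d / N`;
#' `<M(t,r)>` is estimated over a uniform random subset of `n_subset`
#' elements (full enumeration when `n_subset >= N`), deterministic given
#' `seed`.
#'
#' @param dm a [division_matrix()].
#' @param t_bins,r_bins bin labels (minutes / um); 0 is the degenerate bin.
#' @param delta_t,delta_r bin widths.
#' @param n_subset size of the random subset for `<M(t,r)>`
#'   (default 1000).
#' @param seed subset-sampling seed.
#' @return A list of class `correlation_grid` with `values`
#'   (`r_bins x t_bins`), the two component terms, the per-bin variance of
#'   the subset densities (`mi_var`, for sampling-error estimates) and bin
#'   occupancy.
#' @export
density_correlation <- function(dm, t_bins = seq(0, 80, 10),
                                r_bins = seq(0, 60, 10),
                                delta_t = 10, delta_r = 10,
                                n_subset = 1000, seed = 1L) {
  stopifnot(inherits(dm, "division_matrix"), dm$N_d >= 1)
  div_idx <- which(dm$M, arr.ind = TRUE)
  offs <- annulus_offsets(r_bins, delta_r)
  nr <- length(r_bins); nt <- length(t_bins)
  acc <- function(idx_mat) {
    tot <- matrix(0, nr, nt)
    totsq <- matrix(0, nr, nt)
    cnt <- matrix(0L, nr, nt)
    for (q in seq_len(nrow(idx_mat))) {
      mi <- mi_profile(dm, idx_mat[q, 1], idx_mat[q, 2], idx_mat[q, 3],
                       t_bins, r_bins, offs, div_idx, delta_t, delta_r)
      ok <- !is.na(mi)
      tot[ok] <- tot[ok] + mi[ok]
      totsq[ok] <- totsq[ok] + mi[ok]^2
      cnt <- cnt + ok
    }
    list(tot = tot, totsq = totsq, cnt = cnt)
  }
  first_acc <- acc(div_idx)
  first <- first_acc$tot / dm$N
  if (n_subset >= dm$N) {
    sub_lin <- seq_len(dm$N)
  } else {
    sub_lin <- with_seed(seed, sample.int(dm$N, n_subset))
  }
  sub_idx <- arrayInd(sub_lin, c(dm$nx, dm$ny, dm$nt))
  sub_acc <- acc(sub_idx)
  mtr <- ifelse(sub_acc$cnt > 0, sub_acc$tot / sub_acc$cnt, NA_real_)
  mi_var <- ifelse(sub_acc$cnt > 0,
                   pmax(sub_acc$totsq / sub_acc$cnt - mtr^2, 0), NA_real_)
  values <- first - (dm$N_d / dm$N) * mtr
  dimnames(values) <- list(r = r_bins, t = t_bins)
  structure(list(values = values, first_term = first,
                 mean_density = mtr, mi_var = mi_var,
                 occupancy = first_acc$cnt,
                 t_bins = t_bins, r_bins = r_bins,
                 delta_t = delta_t, delta_r = delta_r,
                 n_subset = length(sub_lin), seed = seed),
            class = "correlation_grid")
}

#' Division orientation correlation function
#'
#' `T(t, r)` is the mean nematic dot product `cos(2 (theta_i - theta_j))`
#' over unordered event pairs whose spatial distance falls in
#' `(r - delta_r, r]` and whose time difference falls in
#' `(t - delta_t, t]` (the 0 labels take exact zeros). 1 indicates aligned
#' divisions, -1 perpendicular, 0 uncorrelated; empty bins are `NA`.
#'
#' @param events data frame with `frame`, `x_px`, `y_px`, `theta_rad`.
#' @param t_bins,r_bins bin labels (minutes / um).
#' @param delta_t,delta_r bin widths.
#' @param pixel_size um per pixel.
#' @param frame_interval minutes per frame.
#' @return A list of class `correlation_grid` with `values` and pair
#'   counts per bin.
#' @export
orientation_correlation <- function(events, t_bins = seq(0, 80, 10),
                                    r_bins = seq(0, 60, 10),
                                    delta_t = 10, delta_r = 10,
                                    pixel_size = 123.26 / 512,
                                    frame_interval = 2) {
  ev <- events[!is.na(events$theta_rad), , drop = FALSE]
  if (nrow(ev) < 2) stop("need at least 2 events with orientation")
  n <- nrow(ev)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  dr <- sqrt((ev$x_px[ii] - ev$x_px[jj])^2 +
               (ev$y_px[ii] - ev$y_px[jj])^2) * pixel_size
  dt <- abs(ev$frame[ii] - ev$frame[jj]) * frame_interval
  dot <- cos(2 * (ev$theta_rad[ii] - ev$theta_rad[jj]))
  nr <- length(r_bins); ntb <- length(t_bins)
  values <- matrix(NA_real_, nr, ntb, dimnames = list(r = r_bins,
                                                      t = t_bins))
  pairs <- matrix(0L, nr, ntb, dimnames = dimnames(values))
  for (kt in seq_along(t_bins)) {
    t <- t_bins[kt]
    tmask <- if (t == 0) dt == 0 else dt > t - delta_t & dt <= t
    for (kr in seq_along(r_bins)) {
      r <- r_bins[kr]
      rmask <- if (r == 0) dr == 0 else dr > r - delta_r & dr <= r
      sel <- tmask & rmask
      if (any(sel)) {
        values[kr, kt] <- mean(dot[sel])
        pairs[kr, kt] <- sum(sel)
      }
    }
  }
  structure(list(values = values, pairs = pairs, t_bins = t_bins,
                 r_bins = r_bins, delta_t = delta_t, delta_r = delta_r),
            class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat("correlation_grid over r (um) x t (min):\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Write a correlation grid as a CSV matrix with bin-edge headers
#'
#' @param grid a `correlation_grid`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(grid, path) {
  df <- as.data.frame(grid$values)
  names(df) <- paste0("t_", grid$t_bins, "min")
  df <- cbind(r_um = grid$r_bins, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
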