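#' Calibrated two-channel movie container
#'
#' A `calibrated_movie` holds time-lapse image data together with its
#' physical calibration. Pixel data are stored as a 4-D array indexed
#' `[y, x, channel, frame]`; the default calibration matches a 512-pixel
#' field of view spanning 123.26 um imaged every 2 minutes.
#'
#' @param data numeric 4-D array `[Y, X, C, T]`, or 3-D `[Y, X, T]` for a
#'   single-channel movie (promoted to 4-D).
#' @param pixel_size pixel size in um/px.
#' @param frame_interval frame interval in minutes.
#' @param channels named integer vector mapping channel roles to slots;
#'   must contain `junction` and/or `nuclear`.
#' @return An object of class `calibrated_movie`.
#' @export
calibrated_movie <- function(data,
                             pixel_size = 123.26 / 512,
                             frame_interval = 2,
                             channels = c(junction = 1, nuclear = 2)) {
  if (length(dim(data)) == 3L) {
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  }
  stopifnot(length(dim(data)) == 4L, pixel_size > 0, frame_interval > 0)
  if (max(channels) > dim(data)[3]) {
    stop("channel map refers to channels absent from the data")
  }
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval, channels = channels),
            class = "calibrated_movie")
}

#' @export
print.calibrated_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "calibrated_movie: %d frames, %d channel(s), %d x %d px (%.4f um/px, %g min/frame)\n",
    d[4], d[3], d[2], d[1], x$pixel_size, x$frame_interval))
  cat("channels:", paste(names(x$channels), x$channels, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.calibrated_movie <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[4]

#' Extract one frame of one channel
#'
#' @param movie a [calibrated_movie()].
#' @param frame frame index (1-based).
#' @param channel channel role name (`"junction"`, `"nuclear"`) or index.
#' @return A `Y x X` numeric matrix.
#' @export
movie_frame <- function(movie, frame, channel = "nuclear") {
  ch <- if (is.character(channel)) movie$channels[[channel]] else channel
  movie$data[, , ch, frame]
}

channel_index <- function(movie, role) {
  if (!role %in% names(movie$channels)) {
    stop(sprintf("movie has no '%s' channel", role))
  }
  movie$channels[[role]]
}

#' Write a movie as a multi-page TIFF
#'
#' Pages are ordered frame-major then channel (TCYX). A small JSON
#' sidecar (`<path>.meta.json`) records the axis sizes and calibration so
#' that [read_movie_tiff()] can round-trip the object (the R TIFF writer
#' does not persist description tags).
#'
#' @param movie a [calibrated_movie()].
#' @param path output file path.
#' @param bits bits per sample; 32 writes float data unchanged.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, bits = 32L) {
  d <- dim(movie$data)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      pages[[k]] <- movie$data[, , c, t]
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  jsonlite::write_json(list(axes = "TCYX", channels = d[3], frames = d[4],
                            pixel_size = movie$pixel_size,
                            frame_interval = movie$frame_interval,
                            channel_roles = as.list(movie$channels)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file written by [write_movie_tiff()] or any TCYX stack.
#' @param channels,pixel_size,frame_interval used as fallbacks when the
#'   file has no metadata sidecar.
#' @return A [calibrated_movie()].
#' @export
read_movie_tiff <- function(path, channels = c(junction = 1, nuclear = 2),
                            pixel_size = 123.26 / 512, frame_interval = 2) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(channels)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$channels)) n_ch <- as.integer(meta$channels)
    if (!is.null(meta$pixel_size)) pixel_size <- as.numeric(meta$pixel_size)
    if (!is.null(meta$frame_interval)) {
      frame_interval <- as.numeric(meta$frame_interval)
    }
    if (!is.null(meta$channel_roles)) {
      channels <- unlist(meta$channel_roles)
    }
  }
  n_t <- length(pages) %/% n_ch
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(0, c(h, w, n_ch, n_t))
  k <- 1L
  for (t in seq_len(n_t)) {
    for (c in seq_len(n_ch)) {
      pg <- pages[[k]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # grey written as RGB
      data[, , c, t] <- pg
      k <- k + 1L
    }
  }
  if (n_ch < max(channels)) channels <- stats::setNames(seq_len(n_ch),
                                                        names(channels)[seq_len(n_ch)])
  calibrated_movie(data, pixel_size, frame_interval, channels)
}

#' Write a binary or label mask movie as multi-page TIFF
#'
#' Binary masks are written 8-bit; label maps 16-bit.
#'
#' @param masks `Y x X x T` array (logical/integer).
#' @param path output path.
#' @param bits 8 for binary masks, 16 for label maps.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(masks, path, bits = 8L) {
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  scale <- if (bits == 8L) 255 else 65535
  pages <- lapply(seq_len(dim(masks)[3]),
                  function(t) pmin(masks[, , t] / scale * scale, scale) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  invisible(path)
}

#' Read a mask movie written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @return `Y x X x T` integer array of raw sample values.
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  arr
}

#' Write and read a z-stack movie as multi-page TIFF (TZCYX order)
#'
#' Pages are ordered frame-major, then slice, then channel; a JSON
#' sidecar records the axis sizes.
#'
#' @param stack 5-D array `[Y, X, C, Z, T]` as from [render_zstack()].
#' @param path TIFF path.
#' @return The writer returns `path` invisibly; the reader the 5-D array.
#' @export
write_zstack_tiff <- function(stack, path) {
  d <- dim(stack)
  pages <- vector("list", d[3] * d[4] * d[5])
  k <- 1L
  for (t in seq_len(d[5])) {
    for (z in seq_len(d[4])) {
      for (c in seq_len(d[3])) {
        pages[[k]] <- stack[, , c, z, t]
        k <- k + 1L
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(axes = "TZCYX", channels = d[3],
                            slices = d[4], frames = d[5]),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_zstack_tiff
#' @param n_channels,z_slices fallback axis sizes when the file has no
#'   metadata sidecar.
#' @export
read_zstack_tiff <- function(path, n_channels = 2, z_slices = 5) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$channels)) n_channels <- as.integer(meta$channels)
    if (!is.null(meta$slices)) z_slices <- as.integer(meta$slices)
  }
  n_t <- length(pages) %/% (n_channels * z_slices)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  out <- array(0, c(h, w, n_channels, z_slices, n_t))
  k <- 1L
  for (t in seq_len(n_t)) {
    for (z in seq_len(z_slices)) {
      for (c in seq_len(n_channels)) {
        out[, , c, z, t] <- pages[[k]]
        k <- k + 1L
      }
    }
  }
  out
}

#' Write a matrix (e.g. a density-change or correlation heatmap) to disk
#'
#' The CSV carries row labels in the first column and bin labels as the
#' header; the optional PNG renders a blue-white-red diverging image with
#' rows as bands/radii and columns as time bins.
#'
#' @param m labelled numeric matrix.
#' @param csv_path CSV path.
#' @param png_path optional PNG path.
#' @return `csv_path`, invisibly.
#' @export
write_heatmap <- function(m, csv_path, png_path = NULL) {
  df <- cbind(data.frame(row = rownames(m)), as.data.frame(m))
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 480)
    lim <- max(abs(m), na.rm = TRUE)
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(63)
    graphics::image(x = as.numeric(colnames(m)), y = as.numeric(rownames(m)),
                    z = t(m), zlim = c(-lim, lim), col = pal,
                    xlab = "time (min)", ylab = "distance (um)")
    grDevices::dev.off()
  }
  invisible(csv_path)
}

#' Read and write division-event tables
#'
#' Events CSV schema: `frame,x_px,y_px,theta_rad,wound_angle_deg`; the two
#' angle columns may be empty.
#'
#' @param events data frame with at least `frame`, `x_px`, `y_px`.
#' @param path CSV path.
#' @return For the reader, a data frame; the writer returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("frame", "x_px", "y_px", "theta_rad", "wound_angle_deg")
  for (cl in cols) {
    if (is.null(events[[cl]])) events[[cl]] <- rep(NA_real_, nrow(events))
  }
  write.csv(events[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
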