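# Model inputs and training targets: sliding-window clips, 3- and 10-frame
# encodings, circle / oval / boundary masks, and paired augmentation.

#' Enumerate sliding clip windows over a movie
#'
#' Windows start at every frame except the last four, regardless of window
#' width, so a 93-frame movie yields 89 clips. For 5-frame windows the
#' division-time (label) frame is the second frame of the window (the last
#' metaphase frame, with three anaphase frames following); for 3-frame
#' windows it is the first.
#'
#' @param movie a [calibrated_movie()], or an integer frame count.
#' @param width window width in frames (3 or 5).
#' @return Data frame with columns `start_frame`, `width`, `label_frame`
#'   (all 1-based).
#' @export
extract_clips <- function(movie, width = 5) {
  TT <- if (inherits(movie, "calibrated_movie")) n_frames(movie)
        else as.integer(movie)
  if (!width %in% c(3, 5)) stop("width must be 3 or 5")
  if (TT < 5) stop("movie must have at least 5 frames")
  start <- seq_len(TT - 4L)
  data.frame(start_frame = start, width = width,
             label_frame = if (width == 5) start + 1L else start)
}

#' Dataset manifest over several movies
#'
#' One row per clip window per movie: the movie path, the clip start and
#' the label frame. Written/read as plain CSV.
#'
#' @param movie_paths character vector of movie TIFF paths.
#' @param frame_counts integer frame count per movie.
#' @param width clip width (3 or 5).
#' @return Data frame with `movie`, `start_frame`, `label_frame`.
#' @export
clip_manifest <- function(movie_paths, frame_counts, width = 5) {
  stopifnot(length(movie_paths) == length(frame_counts))
  do.call(rbind, lapply(seq_along(movie_paths), function(i) {
    cl <- extract_clips(frame_counts[i], width)
    data.frame(movie = movie_paths[i], start_frame = cl$start_frame,
               label_frame = cl$label_frame)
  }))
}

rescale01 <- function(m) {
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

#' Encode a clip window as a model input tensor
#'
#' `rgb3` stacks the nuclear channel at the window's first three frames as
#' R, G, B (a stationary nucleus renders grey; a separating pair renders a
#' central red stripe flanked by green and blue). `mc10` stacks the nuclear
#' channel at the window's five frames followed by the junction channel at
#' the same frames. Every channel is min-max rescaled to `[0, 1]`.
#'
#' @param movie a [calibrated_movie()] with the required channels.
#' @param clip one row of [extract_clips()] output (or a list with
#'   `start_frame`).
#' @param mode `"rgb3"` or `"mc10"`.
#' @return Numeric array `[Y, X, 3]` or `[Y, X, 10]`.
#' @export
encode_input <- function(movie, clip, mode = c("mc10", "rgb3")) {
  mode <- match.arg(mode)
  s <- clip$start_frame
  d <- dim(movie$data)
  if (mode == "rgb3") {
    nc <- channel_index(movie, "nuclear")
    stopifnot(s + 2 <= d[4])
    out <- array(0, c(d[1], d[2], 3L))
    for (k in 0:2) out[, , k + 1] <- rescale01(movie$data[, , nc, s + k])
  } else {
    nc <- channel_index(movie, "nuclear")
    jc <- channel_index(movie, "junction")
    stopifnot(s + 4 <= d[4])
    out <- array(0, c(d[1], d[2], 10L))
    for (k in 0:4) out[, , k + 1] <- rescale01(movie$data[, , nc, s + k])
    for (k in 0:4) out[, , k + 6] <- rescale01(movie$data[, , jc, s + k])
  }
  out
}

#' Division-circle target mask for a clip
#'
#' Marks every division whose frame equals the clip's label frame with a
#' filled disc (default radius 10 px, about the size of a cell about to
#' divide). Discs falling partly outside the image are clipped with a
#' warning.
#'
#' @param events data frame with `frame`, `x_px`, `y_px`.
#' @param clip a clip row with `label_frame`.
#' @param shape integer `c(Y, X)` output size.
#' @param radius_px disc radius in pixels.
#' @return Binary `Y x X` matrix of class `target_mask`.
#' @export
division_mask <- function(events, clip, shape, radius_px = 10) {
  mask <- matrix(0, shape[1], shape[2])
  sel <- which(events$frame == clip$label_frame)
  for (k in sel) {
    x <- events$x_px[k]; y <- events$y_px[k]
    if (x < 1 - radius_px || x > shape[2] + radius_px ||
        y < 1 - radius_px || y > shape[1] + radius_px) next
    if (x < 1 || x > shape[2] || y < 1 || y > shape[1]) {
      warning("division event outside image; disc clipped")
    }
    mask[disc_mask(shape[1], shape[2], x, y, radius_px)] <- 1
  }
  structure(mask, kind = "division-circles", class = c("target_mask",
                                                       "matrix", "array"))
}

#' Oriented oval target for the orientation model
#'
#' A centred filled ellipse with semi-axes 50 and 15 px in a 120 x 120
#' image, long axis at angle `theta`.
#'
#' @param theta orientation in radians, `[0, pi)`.
#' @param size image side in pixels.
#' @param semi_major,semi_minor ellipse semi-axes in pixels.
#' @return Binary `size x size` matrix of class `target_mask`.
#' @export
orientation_target <- function(theta, size = 120, semi_major = 50,
                               semi_minor = 15) {
  stopifnot(theta >= 0, theta < pi)
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size) - c0, each = size), size, size)
  y <- matrix(rep(seq_len(size) - c0, times = size), size, size)
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  mask <- (u / semi_major)^2 + (v / semi_minor)^2 <= 1
  structure(mask * 1, kind = "orientation-oval",
            class = c("target_mask", "matrix", "array"))
}

#' Cell-boundary target from a label image
#'
#' The label image is upscaled 2x (nearest neighbour), the one-pixel
#' interface between labels is marked, and the line is thickened to 3 px,
#' mirroring hand-corrected watershed boundaries dilated for training.
#'
#' @param cell_label_image integer `Y x X` dense label map.
#' @param scale integer upscaling factor (default 2: 512 -> 1024).
#' @return Binary `scale*Y x scale*X` matrix of class `target_mask`.
#' @export
boundary_target <- function(cell_label_image, scale = 2L) {
  up <- kronecker(cell_label_image, matrix(1L, scale, scale))
  n <- nrow(up); m <- ncol(up)
  b <- matrix(FALSE, n, m)
  b[, -1] <- b[, -1] | (up[, -1] != up[, -m])
  b[-1, ] <- b[-1, ] | (up[-1, ] != up[-n, ])
  thick <- b
  for (s in c(-1L, 1L)) {
    thick <- thick | shift_int(b, s, 0L) | shift_int(b, 0L, s)
  }
  structure(thick * 1, kind = "boundary",
            class = c("target_mask", "matrix", "array"))
}

# --- paired augmentation ---------------------------------------------------

rot90_mat <- function(m, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Sample augmentation parameters
#'
#' @param seed integer seed.
#' @return List of geometric (`k90`, `hflip`, `vflip`) and photometric
#'   (`blur_sigma`, `gain`, `bias`, `sharpen`) parameters.
#' @export
augment_params <- function(seed) {
  with_seed(seed, {
    list(k90 = sample(0:3, 1), hflip = runif(1) < 0.5,
         vflip = runif(1) < 0.5,
         blur_sigma = if (runif(1) < 0.3) runif(1, 0.3, 1.2) else 0,
         gain = if (runif(1) < 0.5) runif(1, 0.85, 1.15) else 1,
         bias = if (runif(1) < 0.5) runif(1, -0.1, 0.1) else 0,
         sharpen = if (runif(1) < 0.3) runif(1, 0.5, 1.5) else 0)
  })
}

#' Apply the geometric part of an augmentation to an image or mask
#'
#' @param img matrix or `[Y, X, C]` array.
#' @param params from [augment_params()].
#' @return Transformed image of the same type.
#' @export
apply_geometric <- function(img, params) {
  f <- function(m) {
    m <- rot90_mat(m, params$k90)
    if (params$hflip) m <- m[, ncol(m):1, drop = FALSE]
    if (params$vflip) m <- m[nrow(m):1, , drop = FALSE]
    m
  }
  if (length(dim(img)) == 3L) {
    ch <- lapply(seq_len(dim(img)[3]), function(c) f(img[, , c]))
    out <- array(0, c(dim(ch[[1]]), dim(img)[3]))
    for (c in seq_along(ch)) out[, , c] <- ch[[c]]
    out
  } else f(img)
}

#' Map point coordinates through the geometric part of an augmentation
#'
#' @param x,y pixel coordinates (x = column, y = row, 1-based).
#' @param params from [augment_params()].
#' @param size integer `c(Y, X)` of the *input* image.
#' @return List with transformed `x`, `y`.
#' @export
transform_points <- function(x, y, params, size) {
  n <- size[1]; m <- size[2]
  k <- params$k90 %% 4L
  for (i in seq_len(k)) {
    # one CCW quarter turn: (x, y) -> (y, M + 1 - x) on an N x M image
    tmp <- x
    x <- y
    y <- m + 1 - tmp
    t2 <- n; n <- m; m <- t2
  }
  if (params$hflip) x <- m + 1 - x
  if (params$vflip) y <- n + 1 - y
  list(x = x, y = y)
}

#' Augment a paired (input, target) sample
#'
#' Geometric transforms (quarter-turn rotations and flips, which are exact
#' on the pixel grid) are applied identically to input and target;
#' photometric transforms (Gaussian blur, brightness/contrast, sharpen)
#' touch the input only. Deterministic given `seed`.
#'
#' @param input `[Y, X, C]` array or matrix in `[0, 1]`.
#' @param target `Y x X` mask.
#' @param seed integer seed.
#' @return List with `input`, `target`, `params`.
#' @export
augment <- function(input, target, seed) {
  p <- augment_params(seed)
  input <- apply_geometric(input, p)
  target <- apply_geometric(target, p)
  photo <- function(m) {
    if (p$blur_sigma > 0) m <- gblur_safe(m, p$blur_sigma)
    if (p$sharpen > 0) {
      m <- m + p$sharpen * (m - gblur_safe(m, 1))
    }
    pmin(pmax(m * p$gain + p$bias, 0), 1)
  }
  if (length(dim(input)) == 3L) {
    for (c in seq_len(dim(input)[3])) input[, , c] <- photo(input[, , c])
  } else {
    input <- photo(input)
  }
  list(input = input, target = target, params = p)
}
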