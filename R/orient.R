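# Division orientation via the nematic q-tensor of oval response images,
# plus nematic angle utilities.

#' Crop the 10-frame encoding around a division
#'
#' Extracts a 14.4 x 14.4 um box (60 x 60 px at the default calibration)
#' centred on the event from the 10-channel clip encoding whose label
#' frame is the event's frame, and rescales it 2x to 120 x 120. Regions
#' outside the image are zero-padded.
#'
#' @param movie a [calibrated_movie()] with junction and nuclear channels.
#' @param event a list/row with `frame`, `x_px`, `y_px`.
#' @param crop_um physical box side in um (default 14.4).
#' @param out_px output side in pixels (default 120).
#' @return Numeric array `[out_px, out_px, 10]`.
#' @export
crop_division <- function(movie, event, crop_um = 14.4, out_px = 120) {
  TT <- n_frames(movie)
  start <- min(max(event$frame - 1L, 1L), TT - 4L)
  enc <- encode_input(movie, list(start_frame = start), mode = "mc10")
  d <- dim(enc)
  side <- round(crop_um / movie$pixel_size)
  half0 <- floor((side - 1) / 2)
  i0 <- round(event$y_px) - half0; j0 <- round(event$x_px) - half0
  crop <- array(0, c(side, side, d[3]))
  ri <- i0:(i0 + side - 1); rj <- j0:(j0 + side - 1)
  vi <- ri >= 1 & ri <= d[1]; vj <- rj >= 1 & rj <= d[2]
  crop[vi, vj, ] <- enc[ri[vi], rj[vj], , drop = FALSE]
  out <- array(0, c(out_px, out_px, d[3]))
  for (c in seq_len(d[3])) {
    out[, , c] <- as.matrix(EBImage::resize(crop[, , c], w = out_px,
                                            h = out_px))
  }
  out
}

#' Nematic q-tensor of a shape in an image
#'
#' Thresholds the image at `region_threshold` (default half the image
#' maximum), takes pixel coordinates relative to the region centroid, and
#' computes the symmetric traceless second-moment tensor
#' `q_xx = (1/A^2) sum( (x^2 - y^2)/2 )`, `q_xy = (1/A^2) sum(x*y)` over
#' the region, with `A` the region area in pixels. With
#' `weighted = TRUE` the pixel intensities act as weights instead of a
#' hard threshold.
#'
#' @param image numeric matrix (response image in `[0, 1]`).
#' @param region_threshold threshold defining the shape region; default
#'   `0.5 * max(image)`.
#' @param weighted use intensity weighting instead of thresholding.
#' @return A list of class `q_tensor`: `q_xx`, `q_xy`, `q0`
#'   (`sqrt(q_xx^2 + q_xy^2)`), `area`, `centroid`.
#' @export
q_tensor <- function(image, region_threshold = NULL, weighted = FALSE) {
  if (weighted) {
    w <- as.vector(image)
  } else {
    if (is.null(region_threshold)) region_threshold <- 0.5 * max(image)
    w <- as.numeric(as.vector(image) >= region_threshold &
                      as.vector(image) > 0)
  }
  if (sum(w) <= 0) stop("no shape detected")
  n <- nrow(image); m <- ncol(image)
  xs <- rep(seq_len(m), each = n)
  ys <- rep(seq_len(n), times = m)
  A <- sum(w)
  cx <- sum(w * xs) / A; cy <- sum(w * ys) / A
  x <- xs - cx; y <- ys - cy
  q_xx <- sum(w * 0.5 * (x^2 - y^2)) / A^2
  q_xy <- sum(w * x * y) / A^2
  structure(list(q_xx = q_xx, q_xy = q_xy,
                 q0 = sqrt(q_xx^2 + q_xy^2), area = A,
                 centroid = c(x = cx, y = cy)),
            class = "q_tensor")
}

#' Orientation angle from a q-tensor
#'
#' Inverts the decomposition `q = q0 [[cos 2t, sin 2t], [sin 2t, -cos 2t]]`:
#' `theta = atan2(q_xy, q_xx) / 2`, folded into `[0, pi)`.
#'
#' @param q a `q_tensor`.
#' @param tol degeneracy tolerance on `q0` (default 1e-4).
#' @return Angle in radians in `[0, pi)`.
#' @export
theta_from_q <- function(q, tol = 1e-4) {
  if (q$q0 <= tol) stop("degenerate (isotropic) shape")
  th <- 0.5 * atan2(q$q_xy, q$q_xx)
  th %% pi
}

#' Nematic orientation vector
#'
#' `p(theta) = (cos 2 theta, sin 2 theta)`, so that `p(theta) =
#' p(theta + pi)` as required for head-tail symmetric division axes.
#'
#' @param theta angle in radians.
#' @return Unit 2-vector.
#' @export
nematic <- function(theta) c(cos(2 * theta), sin(2 * theta))

#' Nematic alignment of two axes
#'
#' `cos(2 (theta1 - theta2))`: 1 for aligned axes, -1 for perpendicular,
#' 0 for axes differing by pi/4.
#'
#' @param theta1,theta2 angles in radians.
#' @return Value in `[-1, 1]`.
#' @export
nematic_dot <- function(theta1, theta2) cos(2 * (theta1 - theta2))

#' Nematic angular difference in degrees
#'
#' `acos(nematic_dot) / 2`, in `[0, 90]` degrees.
#'
#' @param theta1,theta2 angles in radians.
#' @return Difference in degrees.
#' @export
nematic_diff_deg <- function(theta1, theta2) {
  d <- pmin(pmax(nematic_dot(theta1, theta2), -1), 1)
  0.5 * acos(d) * 180 / pi
}

#' Estimate division orientations with a trained orientation model
#'
#' For each event, crops the 10-frame encoding around the division, runs
#' the orientation model, and extracts the oval's axis with the q-tensor.
#' Events whose response is degenerate (no shape or isotropic) get
#' `NA` orientation.
#'
#' @param model trained orientation model ([build_model()]).
#' @param movie a [calibrated_movie()].
#' @param events events data frame (`frame`, `x_px`, `y_px`).
#' @param weighted passed to [q_tensor()].
#' @return `events` with a `theta_rad` column appended.
#' @export
estimate_orientation <- function(model, movie, events, weighted = FALSE) {
  th <- rep(NA_real_, nrow(events))
  for (k in seq_len(nrow(events))) {
    x <- crop_division(movie, events[k, ])
    resp <- predict_image(model, x)
    th[k] <- tryCatch(theta_from_q(q_tensor(resp, weighted = weighted)),
                      error = function(e) NA_real_)
  }
  events$theta_rad <- th
  events
}
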