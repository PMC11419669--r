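# Focus projection of z-stacks: per-pixel sharpest-slice selection and the
# three-focal-plane (above / focused / below) encoding used by the
# boundary model.

# Gaussian blur with the kernel capped so it never exceeds the image.
gblur_safe <- function(img, sigma) {
  r_full <- 2 * ceiling(3 * sigma) + 1
  r_max <- min(dim(img))
  if (r_max %% 2 == 0) r_max <- r_max - 1
  as.matrix(EBImage::gblur(img, sigma, radius = min(r_full, r_max)))
}

# Exact local box mean via integral image; window (2r+1)^2, borders use
# the clipped window.
box_mean <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  ii <- matrix(0, n + 1, m + 1)
  ii[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  y0 <- pmax(seq_len(n) - r, 1); y1 <- pmin(seq_len(n) + r, n)
  x0 <- pmax(seq_len(m) - r, 1); x1 <- pmin(seq_len(m) + r, m)
  s <- ii[y1 + 1, x1 + 1] - ii[y0, x1 + 1] - ii[y1 + 1, x0] + ii[y0, x0]
  cnt <- outer(y1 - y0 + 1, x1 - x0 + 1)
  s / cnt
}

local_variance <- function(img, r) {
  pmax(box_mean(img * img, r) - box_mean(img, r)^2, 0)
}

sample_stack <- function(stack, zmap) {
  n <- dim(stack)[1]; m <- dim(stack)[2]
  idx <- seq_len(n * m) + (as.vector(zmap) - 1L) * (n * m)
  matrix(stack[idx], n, m)
}

#' Project a z-stack to 2D by per-pixel sharpest-slice selection
#'
#' Sharpness is the local intensity variance in a `(2*radius+1)^2` window.
#' The per-pixel argmax-sharpness slice index is median-smoothed with the
#' same window before sampling, which suppresses speckle in the index map.
#'
#' @param stack numeric array `[Y, X, Z]`.
#' @param radius sharpness window radius in pixels (default 5).
#' @param smooth median-smooth the index map (default `TRUE`).
#' @return A list of class `focus_projection` with `image` (`Y x X`),
#'   `z_index_map` (`Y x X` integer, 1-based) and `radius`.
#' @export
focus_project <- function(stack, radius = 5, smooth = TRUE) {
  if (is.null(dim(stack)) || length(dim(stack)) < 2) {
    stop("stack must be a [Y, X, Z] array")
  }
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  nz <- dim(stack)[3]
  if (nz == 0) stop("empty stack")
  if (nz == 1L) {
    return(structure(list(image = stack[, , 1],
                          z_index_map = matrix(1L, dim(stack)[1],
                                               dim(stack)[2]),
                          radius = radius),
                     class = "focus_projection"))
  }
  sharp <- array(0, dim(stack))
  for (z in seq_len(nz)) sharp[, , z] <- local_variance(stack[, , z], radius)
  zmap <- apply(sharp, c(1, 2), which.max)
  if (smooth && nz > 1) {
    norm <- (zmap - 1) / (nz - 1)
    sm <- EBImage::medianFilter(norm, size = radius)
    zmap <- matrix(as.integer(round(as.matrix(sm) * (nz - 1))) + 1L,
                   nrow(zmap), ncol(zmap))
    zmap <- pmin(pmax(zmap, 1L), nz)
  }
  structure(list(image = sample_stack(stack, zmap),
                 z_index_map = zmap, radius = radius),
            class = "focus_projection")
}

#' Three-focal-plane encoding of a z-stack
#'
#' Builds the RGB-style encoding used for boundary detection: channel 1 is
#' the slice above the in-focus slice, channel 2 the in-focus slice and
#' channel 3 the slice below, with indices clamped to the stack ends.
#'
#' @param stack numeric array `[Y, X, Z]` with `Z >= 3`.
#' @param radius sharpness window radius in pixels.
#' @return Numeric array `[Y, X, 3]`.
#' @export
three_plane_project <- function(stack, radius = 5) {
  if (length(dim(stack)) != 3L || dim(stack)[3] < 3) {
    stop("three_plane_project needs a stack with Z >= 3")
  }
  nz <- dim(stack)[3]
  fp <- focus_project(stack, radius)
  out <- array(0, c(dim(stack)[1:2], 3L))
  out[, , 1] <- sample_stack(stack, pmax(fp$z_index_map - 1L, 1L))
  out[, , 2] <- fp$image
  out[, , 3] <- sample_stack(stack, pmin(fp$z_index_map + 1L, nz))
  out
}
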