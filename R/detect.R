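# Division calling from response movies: scale-matched Laplacian-of-
# Gaussian blob detection followed by cross-frame brightest-wins
# suppression.

log_kernel <- function(sigma) {
  r <- ceiling(3.5 * sigma)
  x <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  g <- g / sum(g)
  lg <- ((x^2 + y^2 - 2 * sigma^2) / sigma^4) * g
  lg - mean(lg)
}

#' Detect bright circular blobs in a response frame
#'
#' Convolves the frame with a scale-normalised Laplacian of Gaussian at
#' sigma = `scale_px / sqrt(2)` (matched to discs of radius `scale_px`) and
#' returns local maxima of the negated response above `threshold`, with
#' sub-pixel positions from a quadratic fit to the peak neighbourhood.
#'
#' @param frame numeric matrix in `[0, 1]`.
#' @param scale_px blob radius the filter is tuned to (default 10 px, the
#'   division-circle radius).
#' @param threshold minimum peak response (calibrated on synthetic
#'   validation data; see [detect_divisions()]).
#' @return Data frame with `x_px`, `y_px`, `response` (possibly empty).
#' @export
log_detect <- function(frame, scale_px = 10, threshold = 0.1) {
  sigma <- scale_px / sqrt(2)
  k <- log_kernel(sigma)
  resp <- -sigma^2 * as.matrix(EBImage::filter2(frame, k))
  n <- nrow(resp); m <- ncol(resp)
  # strict local maxima over the 8-neighbourhood
  is_max <- resp > threshold
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (resp >= shift_int(resp, di, dj))
    }
  }
  is_max[c(1, n), ] <- FALSE; is_max[, c(1, m)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(x_px = numeric(), y_px = numeric(),
                      response = numeric()))
  }
  subpix <- function(a, b, c) {
    den <- a - 2 * b + c
    if (abs(den) < 1e-12) 0 else max(-0.5, min(0.5, 0.5 * (a - c) / den))
  }
  out <- data.frame(x_px = numeric(nrow(idx)), y_px = numeric(nrow(idx)),
                    response = numeric(nrow(idx)))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    out$y_px[r] <- i + subpix(resp[i - 1, j], resp[i, j], resp[i + 1, j])
    out$x_px[r] <- j + subpix(resp[i, j - 1], resp[i, j], resp[i, j + 1])
    out$response[r] <- resp[i, j]
  }
  out[order(-out$response), ]
}

#' Cross-frame suppression of repeated detections
#'
#' Candidates within `link_radius_px` of each other and at most `frame_gap`
#' frames apart are grouped by transitive closure; each group emits exactly
#' one division event at its maximum-response member (the brightest circle
#' marks the division time).
#'
#' @param candidates data frame with `frame`, `x_px`, `y_px`, `response`.
#' @param link_radius_px grouping radius in pixels (default 10, the circle
#'   radius, so re-detections of one division merge).
#' @param frame_gap maximum frame separation for linking (default 1).
#' @return Data frame of events (`frame`, `x_px`, `y_px`, `response`),
#'   sorted by frame then x.
#' @export
temporal_nms <- function(candidates, link_radius_px = 10, frame_gap = 1) {
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(candidates$frame[i] - candidates$frame[j]) > frame_gap) next
      d2 <- (candidates$x_px[i] - candidates$x_px[j])^2 +
        (candidates$y_px[i] - candidates$y_px[j])^2
      if (d2 <= link_radius_px^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), root), function(grp) {
    grp[which.max(candidates$response[grp])]
  }, integer(1))
  out <- candidates[sort(keep), , drop = FALSE]
  out <- out[order(out$frame, out$x_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect division events in a movie with a trained model
#'
#' Composition of [predict_movie()], per-frame [log_detect()] and
#' [temporal_nms()]. The returned table is sorted by frame then x and is
#' idempotent: re-running on the same inputs yields the same events.
#'
#' @param model a trained division-detection model ([build_model()]).
#' @param movie a [calibrated_movie()].
#' @param scale_px,threshold,link_radius_px,frame_gap see [log_detect()]
#'   and [temporal_nms()].
#' @param mode input encoding passed to [predict_movie()].
#' @return Events data frame (`frame`, `x_px`, `y_px`, `response`).
#' @export
detect_divisions <- function(model, movie, scale_px = 10, threshold = 0.1,
                             link_radius_px = 10, frame_gap = 1,
                             mode = "mc10") {
  resp <- predict_movie(model, movie, mode = mode)
  detect_divisions_from_response(resp, scale_px, threshold,
                                 link_radius_px, frame_gap)
}

#' Detect division events from a precomputed response movie
#'
#' @param response a `response_movie` from [predict_movie()].
#' @inheritParams detect_divisions
#' @return Events data frame (`frame`, `x_px`, `y_px`, `response`).
#' @export
detect_divisions_from_response <- function(response, scale_px = 10,
                                           threshold = 0.1,
                                           link_radius_px = 10,
                                           frame_gap = 1) {
  cands <- list()
  for (k in seq_along(response$label_frames)) {
    cc <- log_detect(response$response[, , k], scale_px, threshold)
    if (nrow(cc) > 0) {
      cc$frame <- response$label_frames[k]
      cands[[length(cands) + 1]] <- cc
    }
  }
  cands <- if (length(cands)) do.call(rbind, cands) else
    data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
               response = numeric())
  cands <- cands[order(cands$frame), , drop = FALSE]
  ev <- temporal_nms(cands, link_radius_px, frame_gap)
  ev[, c("frame", "x_px", "y_px", "response")]
}
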