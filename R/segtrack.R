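# Cell segmentation from boundary probability maps, overlap tracking in
# static tissue, track quality filtering, and daughter-pair orientation /
# post-division shuffling.

#' Watershed segmentation of a boundary probability map
#'
#' Cell interiors are the basins of the boundary map: seed regions are the
#' connected components lying within `h` of the map minimum (an
#' h-minima-style suppression of shallow noise basins; tiny seeds are
#' dropped), and basins are grown uphill by intensity-guided propagation.
#' The one-pixel line between adjacent cells is assigned to neither cell
#' (label 0), as are pixels outside the tissue mask. Labels are dense
#' positive integers; a map with no sub-threshold basin (e.g. a uniform
#' map) yields a single region.
#'
#' @param boundary_map `Y x X` matrix in `[0, 1]` (high = boundary).
#' @param h seed depth above the map minimum (default 0.2).
#' @param min_seed minimum seed area in pixels (default 5).
#' @param tissue_mask optional logical mask; outside pixels get label 0.
#' @return Integer `Y x X` label matrix.
#' @export
watershed_segment <- function(boundary_map, h = 0.2, min_seed = 5,
                              tissue_mask = NULL) {
  stopifnot(min(boundary_map) >= 0, max(boundary_map) <= 1)
  seeds <- EBImage::bwlabel(boundary_map <= min(boundary_map) + h)
  seeds <- matrix(as.integer(EBImage::imageData(seeds)),
                  nrow(boundary_map))
  sizes <- tabulate(seeds[seeds > 0])
  drop <- which(sizes < min_seed)
  if (length(drop) > 0) seeds[seeds %in% drop] <- 0L
  if (max(seeds) == 0L) {
    lab <- matrix(1L, nrow(boundary_map), ncol(boundary_map))
  } else {
    lab <- EBImage::propagate(EBImage::as.Image(boundary_map),
                              EBImage::as.Image(seeds))
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(boundary_map))
  }
  # carve a one-pixel line between touching basins
  n <- nrow(lab); m <- ncol(lab)
  line <- matrix(FALSE, n, m)
  dif <- lab[, -1] != lab[, -m] & lab[, -1] > 0 & lab[, -m] > 0
  line[, -1] <- line[, -1] | dif
  dif <- lab[-1, ] != lab[-n, ] & lab[-1, ] > 0 & lab[-n, ] > 0
  line[-1, ] <- line[-1, ] | dif
  lab[line] <- 0L
  if (!is.null(tissue_mask)) lab[!(tissue_mask > 0)] <- 0L
  u <- sort(unique(lab[lab > 0]))
  if (length(u) > 0 && !identical(u, seq_along(u))) {
    lab[lab > 0] <- match(lab[lab > 0], u)
  }
  lab
}

region_stats <- function(lab) {
  sel <- which(lab > 0)
  if (length(sel) == 0) {
    return(data.frame(label = integer(), x_px = numeric(),
                      y_px = numeric(), area_px = integer(),
                      q0 = numeric()))
  }
  v <- lab[sel]
  n <- nrow(lab)
  ys <- (sel - 1) %% n + 1
  xs <- (sel - 1) %/% n + 1
  labs <- sort(unique(v))
  f <- match(v, labs)
  area <- tabulate(f)
  cx <- rowsum(xs, f)[, 1] / area
  cy <- rowsum(ys, f)[, 1] / area
  dx <- xs - cx[f]; dy <- ys - cy[f]
  qxx <- rowsum(0.5 * (dx^2 - dy^2), f)[, 1] / area^2
  qxy <- rowsum(dx * dy, f)[, 1] / area^2
  data.frame(label = labs, x_px = cx, y_px = cy, area_px = area,
             q0 = sqrt(qxx^2 + qxy^2))
}

#' Track cells across a label movie by maximal overlap
#'
#' Links labels in consecutive frames one-to-one by greatest
#' intersection-over-union. A division appears as one track ending and two
#' tracks starting inside its footprint. Per-frame centroid, area and
#' shape anisotropy (q-tensor magnitude) are recorded.
#'
#' @param label_movie `Y x X x T` integer array of per-frame labels.
#' @param min_iou minimum IoU to link (default 0.2).
#' @return Data frame with `track_id`, `frame`, `label`, `x_px`, `y_px`,
#'   `area_px`, `q0`; consecutive frames per track.
#' @export
track_cells <- function(label_movie, min_iou = 0.2) {
  TT <- dim(label_movie)[3]
  out <- list()
  next_id <- 1L
  prev_map <- NULL  # label -> track id in previous frame
  for (t in seq_len(TT)) {
    lab <- label_movie[, , t]
    st <- region_stats(lab)
    cur_map <- integer(0)
    if (t == 1 || length(st$label) == 0 || is.null(prev_map) ||
        length(prev_map) == 0) {
      if (nrow(st) > 0) {
        cur_map <- stats::setNames(seq.int(next_id,
                                           next_id + nrow(st) - 1L),
                                   st$label)
        next_id <- next_id + nrow(st)
      }
    } else {
      prev_lab <- label_movie[, , t - 1]
      both <- prev_lab > 0 & lab > 0
      ov <- table(prev_lab[both], lab[both])
      if (length(ov) > 0) {
        prev_area <- table(prev_lab[prev_lab > 0])
        cur_area <- table(lab[lab > 0])
        cand <- as.data.frame(ov, stringsAsFactors = FALSE)
        names(cand) <- c("p", "c", "inter")
        cand <- cand[cand$inter > 0, , drop = FALSE]
        cand$iou <- cand$inter /
          (as.numeric(prev_area[cand$p]) + as.numeric(cur_area[cand$c]) -
             cand$inter)
        cand <- cand[cand$iou >= min_iou, , drop = FALSE]
        cand <- cand[order(-cand$iou), , drop = FALSE]
        used_p <- character(0); used_c <- character(0)
        cur_map <- integer(0)
        for (r in seq_len(nrow(cand))) {
          p <- cand$p[r]; cc <- cand$c[r]
          if (p %in% used_p || cc %in% used_c) next
          if (!p %in% names(prev_map)) next
          cur_map[cc] <- prev_map[[p]]
          used_p <- c(used_p, p); used_c <- c(used_c, cc)
        }
      }
      new_labels <- setdiff(as.character(st$label), names(cur_map))
      if (length(new_labels) > 0) {
        add <- stats::setNames(seq.int(next_id,
                                       next_id + length(new_labels) - 1L),
                               new_labels)
        cur_map <- c(cur_map, add)
        next_id <- next_id + length(new_labels)
      }
    }
    if (nrow(st) > 0) {
      st$frame <- t
      st$track_id <- unname(cur_map[as.character(st$label)])
      out[[t]] <- st
    }
    prev_map <- cur_map
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(track_id = integer(), frame = integer(),
                      label = integer(), x_px = numeric(),
                      y_px = numeric(), area_px = integer(),
                      q0 = numeric()))
  }
  res <- res[order(res$track_id, res$frame),
             c("track_id", "frame", "label", "x_px", "y_px", "area_px",
               "q0")]
  rownames(res) <- NULL
  res
}

#' Filter unreliable cell tracks
#'
#' Discards tracks showing large sudden changes in size or shape (likely
#' segmentation mistakes): any frame-to-frame relative area change above
#' `max_area_jump`, any shape-anisotropy jump above `max_shape_jump`, or
#' fewer than `min_length` frames.
#'
#' @param tracks data frame from [track_cells()].
#' @param max_area_jump maximum relative area change per frame
#'   (default 0.3).
#' @param max_shape_jump maximum absolute q0 change per frame
#'   (default 0.03).
#' @param min_length minimum track length in frames (default 2).
#' @return Filtered tracks data frame.
#' @export
filter_tracks <- function(tracks, max_area_jump = 0.3,
                          max_shape_jump = 0.03, min_length = 2) {
  keep_id <- vapply(split(tracks, tracks$track_id), function(tr) {
    if (nrow(tr) < min_length) return(FALSE)
    if (nrow(tr) >= 2) {
      da <- abs(diff(tr$area_px)) / tr$area_px[-nrow(tr)]
      if (any(da > max_area_jump)) return(FALSE)
      if (any(abs(diff(tr$q0)) > max_shape_jump)) return(FALSE)
    }
    TRUE
  }, logical(1))
  ids <- as.integer(names(keep_id)[keep_id])
  out <- tracks[tracks$track_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Daughter-pair orientation and post-division shuffling
#'
#' Finds the two daughter tracks born just after a division, measures the
#' axis through their centroids `lag` minutes after the division
#' (`theta_post`), and reports the nematic shift from the division axis
#' (`shuffle_shift`, degrees in [0, 90]). Pairs whose daughters are lost
#' before the lag (or whose lag extends past the movie) are flagged
#' unusable and should be excluded from statistics.
#'
#' @param event a division event row with `frame`, `x_px`, `y_px`,
#'   `theta_rad`.
#' @param tracks data frame from [track_cells()].
#' @param frame_interval minutes per frame.
#' @param lag minutes after division at which to measure (default 20).
#' @param search_radius_px radius around the event within which daughter
#'   tracks must be born.
#' @return A list of class `daughter_pair`: `daughter_ids`,
#'   `theta_division`, `theta_post`, `shuffle_shift`, `usable`.
#' @export
daughter_shuffling <- function(event, tracks, frame_interval = 2,
                               lag = 20, search_radius_px = 15) {
  t0 <- event$frame
  t_post <- t0 + round(lag / frame_interval)
  births <- do.call(rbind, lapply(split(tracks, tracks$track_id),
                                  function(tr) tr[which.min(tr$frame), ]))
  cand <- births[births$frame >= t0 & births$frame <= t0 + 3 &
                   sqrt((births$x_px - event$x_px)^2 +
                          (births$y_px - event$y_px)^2) <=
                   search_radius_px, , drop = FALSE]
  fail <- function() {
    structure(list(event = event, daughter_ids = NA_integer_,
                   theta_division = event$theta_rad,
                   theta_post = NA_real_, shuffle_shift = NA_real_,
                   usable = FALSE), class = "daughter_pair")
  }
  if (nrow(cand) < 2) return(fail())
  d <- sqrt((cand$x_px - event$x_px)^2 + (cand$y_px - event$y_px)^2)
  cand <- cand[order(d), , drop = FALSE][1:2, ]
  pos <- lapply(cand$track_id, function(id) {
    tr <- tracks[tracks$track_id == id & tracks$frame == t_post, ,
                 drop = FALSE]
    if (nrow(tr) == 0) NULL else tr
  })
  if (any(vapply(pos, is.null, logical(1)))) return(fail())
  dx <- pos[[2]]$x_px - pos[[1]]$x_px
  dy <- pos[[2]]$y_px - pos[[1]]$y_px
  theta_post <- atan2(dy, dx) %% pi
  structure(list(event = event, daughter_ids = cand$track_id,
                 theta_division = event$theta_rad,
                 theta_post = theta_post,
                 shuffle_shift = nematic_diff_deg(event$theta_rad,
                                                  theta_post),
                 usable = TRUE), class = "daughter_pair")
}
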