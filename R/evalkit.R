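# Matching predicted events/cells to ground truth and Dice scoring.

match_result <- function(tp, fp, fn, pairs = NULL) {
  structure(list(Tp = tp, Fp = fp, Fn = fn, pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: Tp=%d Fp=%d Fn=%d (dice %.3f)\n",
              x$Tp, x$Fp, x$Fn, dice_score(x$Tp, x$Fp, x$Fn)))
  invisible(x)
}

#' Dice (F1) score from matched-event counts
#'
#' `2 Tp / (2 Tp + Fp + Fn)`, the harmonic mean of precision and recall.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts,
#'   or a `match_result` as the first argument.
#' @return Score in `[0, 1]`.
#' @export
dice_score <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "match_result")) {
    fp <- tp$Fp; fn <- tp$Fn; tp <- tp$Tp
  }
  if (tp == 0 && fp == 0 && fn == 0) {
    stop("dice score undefined for Tp = Fp = Fn = 0")
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Precision and recall from matched-event counts
#'
#' @inheritParams dice_score
#' @return Named vector with `precision` and `recall`.
#' @export
precision_recall <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "match_result")) {
    fp <- tp$Fp; fn <- tp$Fn; tp <- tp$Tp
  }
  c(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

#' Match predicted division events to ground truth
#'
#' Pairs are admissible when their frames differ by at most
#' `temporal_tol` (a detection one frame early or late still counts) and
#' their spatial distance is at most `spatial_tol_px`. Admissible pairs
#' are matched one-to-one at maximum cardinality (augmenting-path
#' matching seeded greedily in order of ascending spatial then temporal
#' distance, so nearer pairs are preferred among equally large
#' matchings). Unmatched predictions are false positives; unmatched
#' truths false negatives.
#'
#' @param pred,truth data frames with `frame`, `x_px`, `y_px`.
#' @param spatial_tol_px spatial tolerance in pixels (default 10).
#' @param temporal_tol temporal tolerance in frames (default 1).
#' @return A `match_result` with a `pairs` data frame
#'   (`pred_row`, `truth_row`, `dist_px`, `dframe`).
#' @export
match_divisions <- function(pred, truth, spatial_tol_px = 10,
                            temporal_tol = 1) {
  np <- nrow(pred); nt <- nrow(truth)
  empty_pairs <- data.frame(pred_row = integer(), truth_row = integer(),
                            dist_px = numeric(), dframe = integer())
  if (np == 0 || nt == 0) {
    return(match_result(0L, np, nt, empty_pairs))
  }
  adj <- vector("list", np)     # admissible truths per pred, nearest first
  dists <- vector("list", np)
  dfs_ <- vector("list", np)
  for (i in seq_len(np)) {
    df <- abs(truth$frame - pred$frame[i])
    ok <- which(df <= temporal_tol)
    if (length(ok) == 0) next
    d <- sqrt((truth$x_px[ok] - pred$x_px[i])^2 +
                (truth$y_px[ok] - pred$y_px[i])^2)
    keep <- d <= spatial_tol_px
    ord <- order(d[keep], df[ok[keep]])
    adj[[i]] <- ok[keep][ord]
    dists[[i]] <- d[keep][ord]
    dfs_[[i]] <- df[ok[keep]][ord]
  }
  match_t <- rep(0L, nt)  # pred matched to each truth (0 = free)
  match_p <- rep(0L, np)
  augment_from <- function(i) {
    visited <- rep(FALSE, nt)
    recurse <- function(i) {
      for (j in adj[[i]]) {
        if (visited[j]) next
        visited[j] <<- TRUE
        if (match_t[j] == 0L || recurse(match_t[j])) {
          match_t[j] <<- i
          match_p[i] <<- j
          return(TRUE)
        }
      }
      FALSE
    }
    recurse(i)
  }
  # seed in order of each prediction's nearest admissible distance
  nearest <- vapply(seq_len(np), function(i) {
    if (length(dists[[i]]) == 0) Inf else dists[[i]][1]
  }, numeric(1))
  for (i in order(nearest)) {
    if (is.finite(nearest[i])) augment_from(i)
  }
  matched <- which(match_p > 0L)
  pairs <- if (length(matched) == 0) empty_pairs else do.call(rbind, lapply(
    matched, function(i) {
      k <- match(match_p[i], adj[[i]])
      data.frame(pred_row = i, truth_row = match_p[i],
                 dist_px = dists[[i]][k], dframe = dfs_[[i]][k])
    }))
  tp <- length(matched)
  match_result(tp, np - tp, nt - tp, pairs)
}

#' Match segmented cells to ground-truth cells by IoU
#'
#' A predicted cell is a true positive iff it is in one-to-one
#' maximal-overlap correspondence with a true cell (each is the other's
#' largest-overlap partner) and their intersection-over-union reaches
#' `iou_threshold`. Remaining predictions are false positives; remaining
#' true cells false negatives. Label 0 is background and ignored.
#'
#' @param pred_labels,true_labels integer label matrices of equal shape.
#' @param iou_threshold IoU acceptance threshold (default 0.75).
#' @return A `match_result` with a `pairs` data frame
#'   (`pred_label`, `true_label`, `iou`).
#' @export
match_cells <- function(pred_labels, true_labels, iou_threshold = 0.75) {
  stopifnot(all(dim(pred_labels) == dim(true_labels)))
  p <- as.vector(pred_labels); t <- as.vector(true_labels)
  sel <- p > 0 | t > 0
  p <- p[sel]; t <- t[sel]
  pl <- sort(unique(p[p > 0])); tl <- sort(unique(t[t > 0]))
  if (length(pl) == 0 || length(tl) == 0) {
    return(match_result(0L, length(pl), length(tl)))
  }
  both <- p > 0 & t > 0
  ov <- table(factor(p[both], levels = pl), factor(t[both], levels = tl))
  ov <- matrix(as.numeric(ov), length(pl), length(tl))
  ap <- tabulate(match(p[p > 0], pl), nbins = length(pl))
  at <- tabulate(match(t[t > 0], tl), nbins = length(tl))
  iou <- ov / (outer(ap, at, "+") - ov)
  pairs <- data.frame(pred_label = integer(), true_label = integer(),
                      iou = numeric())
  tp <- 0L
  if (any(ov > 0)) {
    best_t_for_p <- apply(ov, 1, which.max)
    best_p_for_t <- apply(ov, 2, which.max)
    for (i in seq_along(pl)) {
      j <- best_t_for_p[i]
      if (ov[i, j] > 0 && best_p_for_t[j] == i &&
          iou[i, j] >= iou_threshold) {
        tp <- tp + 1L
        pairs <- rbind(pairs, data.frame(pred_label = pl[i],
                                         true_label = tl[j],
                                         iou = iou[i, j]))
      }
    }
  }
  match_result(tp, length(pl) - tp, length(tl) - tp, pairs)
}

#' Write an evaluation report
#'
#' @param match a `match_result`.
#' @param json_path report JSON path (counts, dice, precision, recall).
#' @param pairs_path optional CSV path for the per-event match table.
#' @return The report list, invisibly.
#' @export
write_evaluation_report <- function(match, json_path, pairs_path = NULL) {
  rep <- list(Tp = match$Tp, Fp = match$Fp, Fn = match$Fn,
              dice = dice_score(match),
              precision = unname(precision_recall(match)["precision"]),
              recall = unname(precision_recall(match)["recall"]))
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(pairs_path) && !is.null(match$pairs)) {
    write.csv(match$pairs, pairs_path, row.names = FALSE)
  }
  invisible(rep)
}
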