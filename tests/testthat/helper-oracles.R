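# Independent brute-force oracles shared across test files.

# Direct triple-loop computation of the annular-tube density M_i(t, r).
oracle_mi <- function(dm, ix, iy, it, t, r, delta_t = 10, delta_r = 10) {
  fi <- dm$frame_interval
  num <- 0; den <- 0
  for (x in seq_len(dm$nx)) {
    for (y in seq_len(dm$ny)) {
      d <- sqrt((x - ix)^2 + (y - iy)^2)
      in_r <- if (r == 0) d == 0 else d > r - delta_r && d <= r
      if (!in_r) next
      for (s in seq_len(dm$nt)) {
        lag <- (it - s) * fi
        in_t <- if (t == 0) lag == 0 else lag >= t - delta_t && lag < t
        if (!in_t) next
        den <- den + 1
        if (dm$M[x, y, s]) num <- num + 1
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Exhaustive maximum-cardinality event matching under the same
# admissibility rule as match_divisions().
oracle_max_matching <- function(pred, truth, spatial_tol = 10,
                                temporal_tol = 1) {
  ok <- outer(seq_len(nrow(pred)), seq_len(nrow(truth)),
              Vectorize(function(i, j) {
                abs(pred$frame[i] - truth$frame[j]) <= temporal_tol &&
                  sqrt((pred$x_px[i] - truth$x_px[j])^2 +
                         (pred$y_px[i] - truth$y_px[j])^2) <= spatial_tol
              }))
  best <- 0L
  recurse <- function(i, used) {
    if (i > nrow(pred)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    recurse(i + 1L, used)
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1L, used)
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nrow(truth)))
  best
}
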