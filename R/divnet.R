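# Configurable residual encoder-decoder dense-prediction network with an
# Adam training loop. The architecture family mirrors classifier-backbone
# U-Nets (residual blocks in the encoder, skip-connected decoder, swappable
# input-channel count) at a width/depth that trains on a CPU; forward and
# backward passes run through the package's C++ conv/pool/upsample kernels.

#' Network configuration
#'
#' @param in_channels input channels (3 for the RGB 3-frame encoding, 10
#'   for the two-channel 5-frame encoding; any value is accepted).
#' @param base_width features at the top resolution level (desk default 16;
#'   larger values mimic classifier-scale backbones).
#' @param depth number of resolution levels; features double and spatial
#'   resolution halves at each level.
#' @param res_blocks residual blocks per level.
#' @return A list of class `net_config`.
#' @export
net_config <- function(in_channels = 10, base_width = 16, depth = 3,
                       res_blocks = 1) {
  stopifnot(in_channels >= 1, base_width >= 1, depth >= 1, res_blocks >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 res_blocks = as.integer(res_blocks)),
            class = "net_config")
}

conv_init <- function(cin, cout) {
  list(W = matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                  9 * cin, cout),
       b = rep(0, cout))
}

#' Build a dense-prediction model
#'
#' Maps `[Y, X, in_channels]` inputs to `[Y, X]` probability maps in
#' `[0, 1]` of the same spatial size (inputs whose sides are not divisible
#' by `2^(depth-1)` are internally zero-padded and the output cropped
#' back). Parameter count grows monotonically with width and depth.
#'
#' @param config a [net_config()].
#' @param seed seed for weight initialisation.
#' @return An object of class `divnet_model`.
#' @export
build_model <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  d <- config$depth
  widths <- config$base_width * 2^(seq_len(d) - 1)
  with_seed(seed, {
    params <- list(stem = conv_init(config$in_channels, widths[1]))
    for (l in seq_len(d)) {
      for (r in seq_len(config$res_blocks)) {
        params[[sprintf("enc%d_rb%d_a", l, r)]] <- conv_init(widths[l],
                                                             widths[l])
        params[[sprintf("enc%d_rb%d_b", l, r)]] <- conv_init(widths[l],
                                                             widths[l])
      }
      if (l < d) {
        params[[sprintf("down%d", l)]] <- conv_init(widths[l], widths[l + 1])
      }
    }
    for (l in rev(seq_len(d - 1))) {
      params[[sprintf("up%d", l)]] <- conv_init(widths[l + 1], widths[l])
      for (r in seq_len(config$res_blocks)) {
        params[[sprintf("dec%d_rb%d_a", l, r)]] <- conv_init(widths[l],
                                                             widths[l])
        params[[sprintf("dec%d_rb%d_b", l, r)]] <- conv_init(widths[l],
                                                             widths[l])
      }
    }
    params$head <- conv_init(widths[1], 1)
    structure(list(config = config, params = params),
              class = "divnet_model")
  })
}

#' Number of trainable parameters
#'
#' @param model a `divnet_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params,
             function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.divnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "divnet_model: in=%d, width=%d, depth=%d, res_blocks=%d (%s parameters)\n",
    cfg$in_channels, cfg$base_width, cfg$depth, cfg$res_blocks,
    format(count_params(x), big.mark = ",")))
  invisible(x)
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

resblock_fwd <- function(params, name, x, cache) {
  a <- cpp_conv3_fwd(x, params[[paste0(name, "_a")]]$W,
                     params[[paste0(name, "_a")]]$b)
  ar <- relu_fwd(a)
  b <- cpp_conv3_fwd(ar, params[[paste0(name, "_b")]]$W,
                     params[[paste0(name, "_b")]]$b)
  y <- relu_fwd(x + b)
  cache[[name]] <- list(x = x, a = a, ar = ar, y = y)
  list(y = y, cache = cache)
}

resblock_bwd <- function(params, name, cache, gy, grads) {
  cc <- cache[[name]]
  gy <- gy * (cc$y > 0)
  gb <- cpp_conv3_bwd(cc$ar, params[[paste0(name, "_b")]]$W, gy)
  grads[[paste0(name, "_b")]] <- list(W = gb$gw, b = gb$gb)
  gar <- gb$gx * (cc$a > 0)
  ga <- cpp_conv3_bwd(cc$x, params[[paste0(name, "_a")]]$W, gar)
  grads[[paste0(name, "_a")]] <- list(W = ga$gw, b = ga$gb)
  list(gx = gy + ga$gx, grads = grads)
}

net_forward <- function(model, x, keep = TRUE) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  cache <- list()
  h <- cpp_conv3_fwd(x, p$stem$W, p$stem$b)
  cache$stem_in <- x; cache$stem_pre <- h
  h <- relu_fwd(h)
  skips <- list()
  for (l in seq_len(d)) {
    for (r in seq_len(cfg$res_blocks)) {
      fr <- resblock_fwd(p, sprintf("enc%d_rb%d", l, r), h, cache)
      h <- fr$y; cache <- fr$cache
    }
    if (l < d) {
      skips[[l]] <- h
      mp <- cpp_maxpool2_fwd(h)
      cache[[sprintf("pool%d", l)]] <- list(idx = mp$idx,
                                            H = dim(h)[1], W = dim(h)[2])
      dn <- cpp_conv3_fwd(mp$y, p[[sprintf("down%d", l)]]$W,
                          p[[sprintf("down%d", l)]]$b)
      cache[[sprintf("down%d", l)]] <- list(x = mp$y, pre = dn)
      h <- relu_fwd(dn)
    }
  }
  for (l in rev(seq_len(d - 1))) {
    u <- cpp_upsample2_fwd(h)
    up <- cpp_conv3_fwd(u, p[[sprintf("up%d", l)]]$W,
                        p[[sprintf("up%d", l)]]$b)
    cache[[sprintf("up%d", l)]] <- list(x = u, pre = up)
    h <- relu_fwd(up) + skips[[l]]
    for (r in seq_len(cfg$res_blocks)) {
      fr <- resblock_fwd(p, sprintf("dec%d_rb%d", l, r), h, cache)
      h <- fr$y; cache <- fr$cache
    }
  }
  z <- cpp_conv3_fwd(h, p$head$W, p$head$b)
  cache$head_in <- h
  prob <- 1 / (1 + exp(-z[, , 1]))
  list(prob = prob, z = z, cache = if (keep) cache else NULL)
}

net_backward <- function(model, cache, gz) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  grads <- list()
  gh <- cpp_conv3_bwd(cache$head_in, p$head$W, gz)
  grads$head <- list(W = gh$gw, b = gh$gb)
  g <- gh$gx
  gskip <- list()
  for (l in seq_len(d - 1)) {
    for (r in rev(seq_len(cfg$res_blocks))) {
      rb <- resblock_bwd(p, sprintf("dec%d_rb%d", l, r), cache, g, grads)
      g <- rb$gx; grads <- rb$grads
    }
    gskip[[l]] <- g  # additive skip: gradient flows to the encoder branch
    cc <- cache[[sprintf("up%d", l)]]
    gu <- g * (cc$pre > 0)
    gc <- cpp_conv3_bwd(cc$x, p[[sprintf("up%d", l)]]$W, gu)
    grads[[sprintf("up%d", l)]] <- list(W = gc$gw, b = gc$gb)
    g <- cpp_upsample2_bwd(gc$gx)
  }
  for (l in rev(seq_len(d))) {
    if (l < d) {
      cc <- cache[[sprintf("down%d", l)]]
      gdn <- g * (cc$pre > 0)
      gc <- cpp_conv3_bwd(cc$x, p[[sprintf("down%d", l)]]$W, gdn)
      grads[[sprintf("down%d", l)]] <- list(W = gc$gw, b = gc$gb)
      pl <- cache[[sprintf("pool%d", l)]]
      g <- cpp_maxpool2_bwd(pl$idx, gc$gx, pl$H, pl$W)
      g <- g + gskip[[l]]
    }
    for (r in rev(seq_len(cfg$res_blocks))) {
      rb <- resblock_bwd(p, sprintf("enc%d_rb%d", l, r), cache, g, grads)
      g <- rb$gx; grads <- rb$grads
    }
  }
  g <- g * (cache$stem_pre > 0)
  gs <- cpp_conv3_bwd(cache$stem_in, p$stem$W, g)
  grads$stem <- list(W = gs$gw, b = gs$gb)
  grads
}

pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  H <- ceiling(d[1] / mult) * mult
  W <- ceiling(d[2] / mult) * mult
  if (H == d[1] && W == d[2]) return(list(x = x, H0 = d[1], W0 = d[2]))
  out <- array(0, c(H, W, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  list(x = out, H0 = d[1], W0 = d[2])
}

#' Run the model on a single input image
#'
#' @param model a `divnet_model`.
#' @param x numeric array `[Y, X, in_channels]` (a matrix is promoted).
#' @return `Y x X` probability matrix in `[0, 1]`.
#' @export
predict_image <- function(model, x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[3] == model$config$in_channels)
  mult <- 2^(model$config$depth - 1)
  pd <- pad_to_multiple(x, mult)
  fw <- net_forward(model, pd$x, keep = FALSE)
  fw$prob[seq_len(pd$H0), seq_len(pd$W0)]
}

# Combined soft-Dice + binary cross-entropy loss; returns the loss and its
# gradient with respect to the pre-sigmoid logits.
dice_bce_loss <- function(prob, target, dice_weight = 1, bce_weight = 1,
                          eps = 1e-6) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  npx <- length(p)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  inter <- sum(p * target)
  denom <- sum(p) + sum(target) + eps
  dice <- 2 * inter / denom
  loss <- bce_weight * bce + dice_weight * (1 - dice)
  gp_dice <- -2 * (target * denom - inter) / denom^2
  gz <- bce_weight * (p - target) / npx +
    dice_weight * gp_dice * p * (1 - p)
  list(loss = loss, gz = gz)
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / c1) /
      (sqrt(s$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) /
      (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param epochs passes over the training set.
#' @param batch_size samples per optimiser step (gradients averaged).
#' @param learning_rate Adam step size.
#' @param dice_weight,bce_weight loss term weights (equal by default).
#' @param seed shuffling seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 4, learning_rate = 1e-3,
                         dice_weight = 1, bce_weight = 1, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(as.list(environment()), class = "train_config")
}

sample_loss <- function(model, s, cfg) {
  mult <- 2^(model$config$depth - 1)
  pd <- pad_to_multiple(s$x, mult)
  ty <- matrix(0, dim(pd$x)[1], dim(pd$x)[2])
  ty[seq_len(pd$H0), seq_len(pd$W0)] <- s$y
  fw <- net_forward(model, pd$x, keep = FALSE)
  dice_bce_loss(fw$prob, ty, cfg$dice_weight, cfg$bce_weight)$loss
}

#' Train a dense-prediction model
#'
#' Adam optimisation of the combined soft-Dice + binary cross-entropy
#' loss. Training is deterministic given the seeds; the weights achieving
#' the best validation loss are retained. A non-finite loss aborts with a
#' diagnostic.
#'
#' @param model a `divnet_model` from [build_model()].
#' @param train,val non-empty, disjoint lists of samples, each a list with
#'   `x` (`[Y, X, C]` input) and `y` (`Y x X` binary target).
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return List with `model` (best-validation weights) and `history`
#'   (data frame of per-epoch train/val loss).
#' @export
train_divnet <- function(model, train, val, config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "divnet_model"),
            inherits(config, "train_config"))
  if (length(train) == 0) stop("empty training set")
  if (length(val) == 0) stop("empty validation set")
  mult <- 2^(model$config$depth - 1)
  state <- adam_init(model$params)
  step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = model$params)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(train))
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        acc <- NULL
        bl <- 0
        for (i in idx) {
          s <- train[[i]]
          pd <- pad_to_multiple(s$x, mult)
          ty <- matrix(0, dim(pd$x)[1], dim(pd$x)[2])
          ty[seq_len(pd$H0), seq_len(pd$W0)] <- s$y
          fw <- net_forward(model, pd$x, keep = TRUE)
          lo <- dice_bce_loss(fw$prob, ty, config$dice_weight,
                              config$bce_weight)
          if (!is.finite(lo$loss)) {
            stop(sprintf("training diverged (non-finite loss at epoch %d)",
                         ep))
          }
          bl <- bl + lo$loss
          gz <- array(lo$gz / length(idx), c(dim(ty), 1L))
          g <- net_backward(model, fw$cache, gz)
          if (is.null(acc)) {
            acc <- g
          } else {
            for (nm in names(acc)) {
              acc[[nm]]$W <- acc[[nm]]$W + g[[nm]]$W
              acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b
            }
          }
        }
        step <- step + 1L
        upd <- adam_step(model$params, acc, state, config$learning_rate,
                         step)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bl
        nb <- nb + length(idx)
      }
      vl <- mean(vapply(val, function(s) sample_loss(model, s, config),
                        numeric(1)))
      if (!is.finite(vl)) stop("validation loss non-finite")
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss / nb,
                                  val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = model$params)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f", ep,
                        ep_loss / nb, vl))
      }
    }
  })
  model$params <- best$params
  list(model = model, history = history)
}

#' Predict a response movie
#'
#' Runs the model on every valid clip window; each response frame is
#' indexed by the window's label frame, so a 93-frame movie yields 89
#' response frames.
#'
#' @param model a trained `divnet_model`.
#' @param movie a [calibrated_movie()].
#' @param mode input encoding (`"mc10"` or `"rgb3"`).
#' @return A list of class `response_movie` with `response`
#'   (`[Y, X, n_clips]` in `[0, 1]`) and `label_frames`.
#' @export
predict_movie <- function(model, movie, mode = "mc10") {
  width <- if (mode == "mc10") 5L else 3L
  clips <- extract_clips(movie, width)
  d <- dim(movie$data)
  resp <- array(0, c(d[1], d[2], nrow(clips)))
  for (k in seq_len(nrow(clips))) {
    x <- encode_input(movie, clips[k, ], mode)
    resp[, , k] <- predict_image(model, x)
  }
  structure(list(response = resp, label_frames = clips$label_frame,
                 pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval),
            class = "response_movie")
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the network configuration alongside the weights.
#'
#' @param model a `divnet_model`.
#' @param path file path (RDS).
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "divnet_model"))
  m
}
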