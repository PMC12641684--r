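# Dual-resolution U-shaped segmentation network with deep supervision.
#
# Two parallel encoders ingest the preprocessed volume at full and half
# resolution; their bottlenecks are fused (half-resolution bottleneck
# upsampled and concatenated) ahead of a single decoder with skip
# connections from the full-resolution encoder. The loss is a weighted
# combination of soft Dice and voxel-wise cross-entropy, summed over the
# full-resolution output and deep-supervision heads at coarser decoder
# stages with per-level weights halving by depth.

#' Multiscale segmentation network configuration
#'
#' @param full_res_shape cubic input grid (voxels per axis); must be
#'   divisible by `2^(depth+1)`.
#' @param base_channels channels of the first encoder stage (doubling per
#'   stage, capped at `bottleneck_channels`).
#' @param depth number of 2x downsamplings per encoder.
#' @param bottleneck_channels channels of the encoder bottleneck.
#' @param deep_supervision_levels number of coarser decoder outputs that
#'   also receive loss (0 = only the full-resolution output).
#' @param single_scale if `TRUE`, only the full-resolution encoder is built.
#' @return A `multiscale_net_config`.
#' @export
multiscale_net_config <- function(full_res_shape = c(16L, 16L, 16L),
                                  base_channels = 8L, depth = 2L,
                                  bottleneck_channels = 32L,
                                  deep_supervision_levels = 1L,
                                  single_scale = FALSE) {
  full_res_shape <- as.integer(rep(full_res_shape, length.out = 3))
  if (any(full_res_shape %% 2L^(depth + 1L) != 0L))
    stop("full_res_shape must be divisible by 2^(depth+1)")
  if (deep_supervision_levels > depth - 1L)
    stop("deep_supervision_levels must be <= depth - 1")
  structure(list(full_res_shape = full_res_shape,
                 half_res_shape = full_res_shape %/% 2L,
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 deep_supervision_levels = as.integer(deep_supervision_levels),
                 single_scale = isTRUE(single_scale)),
            class = "multiscale_net_config")
}

#' Bottleneck tensor shapes implied by a network configuration
#'
#' @param cfg a `multiscale_net_config`.
#' @return List with `full` and (unless single-scale) `half`, each
#'   `(channels, d, h, w)`.
#' @export
bottleneck_shapes <- function(cfg) {
  f <- c(cfg$bottleneck_channels, cfg$full_res_shape %/% 2L^cfg$depth)
  if (cfg$single_scale) return(list(full = f))
  list(full = f, half = c(cfg$bottleneck_channels,
                          cfg$half_res_shape %/% 2L^cfg$depth))
}

seg_channels <- function(cfg) {
  pmin(cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L),
       cfg$bottleneck_channels)
}

seg_encoder_params <- function(cfg, prefix) {
  ch <- seg_channels(cfg)
  pr <- list()
  cin <- 1L
  for (l in seq_len(cfg$depth)) {
    pr[[paste0(prefix, "_l", l, "_W")]] <- nn_param(conv_init(cin, ch[l]))
    pr[[paste0(prefix, "_l", l, "_b")]] <- nn_param(numeric(ch[l]))
    cin <- ch[l]
  }
  pr[[paste0(prefix, "_bn_W")]] <- nn_param(conv_init(cin,
                                                      cfg$bottleneck_channels))
  pr[[paste0(prefix, "_bn_b")]] <- nn_param(numeric(cfg$bottleneck_channels))
  pr
}

#' Build the multiscale segmentation model
#'
#' @param cfg a `multiscale_net_config`.
#' @param seed weight-initialization seed.
#' @return An (untrained) `seg_model`.
#' @export
build_multiscale_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "multiscale_net_config"))
  with_seed(seed, {
    ch <- seg_channels(cfg)
    params <- seg_encoder_params(cfg, "enc_full")
    if (!cfg$single_scale) {
      params <- c(params, seg_encoder_params(cfg, "enc_half"))
      params$fuse_W <- nn_param(conv_init(2L * cfg$bottleneck_channels,
                                          cfg$bottleneck_channels))
      params$fuse_b <- nn_param(numeric(cfg$bottleneck_channels))
    }
    cin <- cfg$bottleneck_channels
    for (l in rev(seq_len(cfg$depth))) {
      params[[paste0("dec_l", l, "_W")]] <-
        nn_param(conv_init(cin + ch[l], ch[l]))
      params[[paste0("dec_l", l, "_b")]] <- nn_param(numeric(ch[l]))
      cin <- ch[l]
    }
    for (l in seq_len(1L + cfg$deep_supervision_levels)) {
      params[[paste0("head_l", l, "_W")]] <-
        nn_param(matrix(stats::rnorm(ch[l], 0, 0.05), 1L, ch[l]))
      params[[paste0("head_l", l, "_b")]] <- nn_param(0)
    }
    structure(list(cfg = cfg, params = params, trained = FALSE,
                   seed = as.integer(seed), train_state = NULL),
              class = "seg_model")
  })
}

seg_encode <- function(params, prefix, x, depth) {
  skips <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    h <- op_lrelu(op_conv3(h, params[[paste0(prefix, "_l", l, "_W")]],
                           params[[paste0(prefix, "_l", l, "_b")]]))
    skips[[l]] <- h
    h <- op_avgpool2(h)
  }
  bn <- op_lrelu(op_conv3(h, params[[paste0(prefix, "_bn_W")]],
                          params[[paste0(prefix, "_bn_b")]]))
  list(bottleneck = bn, skips = skips)
}

# Forward pass; returns logits (list, level 1 = full resolution) and the
# encoder bottleneck nodes.
seg_forward <- function(model, x_full, x_half) {
  cfg <- model$cfg; pr <- model$params
  xf <- nn_node(x_full)
  ef <- seg_encode(pr, "enc_full", xf, cfg$depth)
  bn_half <- NULL
  d <- ef$bottleneck
  if (!cfg$single_scale) {
    xh <- nn_node(x_half)
    eh <- seg_encode(pr, "enc_half", xh, cfg$depth)
    bn_half <- eh$bottleneck
    d <- op_lrelu(op_conv3(op_concat_c(ef$bottleneck,
                                       op_upsample2(eh$bottleneck)),
                           pr$fuse_W, pr$fuse_b))
  }
  dec <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    d <- op_lrelu(op_conv3(op_concat_c(op_upsample2(d), ef$skips[[l]]),
                           pr[[paste0("dec_l", l, "_W")]],
                           pr[[paste0("dec_l", l, "_b")]]))
    dec[[l]] <- d
  }
  logits <- lapply(seq_len(1L + cfg$deep_supervision_levels), function(l)
    op_conv1(dec[[l]], pr[[paste0("head_l", l, "_W")]],
             pr[[paste0("head_l", l, "_b")]]))
  list(logits = logits, bottleneck_full = ef$bottleneck,
       bottleneck_half = bn_half)
}

# binary 2x max-pool of a 3D array
maxpool2_arr <- function(a) {
  d <- dim(a)
  e1 <- seq(1L, d[1], 2L); e2 <- seq(1L, d[2], 2L); e3 <- seq(1L, d[3], 2L)
  m <- a[e1, e2, e3, drop = FALSE]
  for (i in 0:1) for (j in 0:1) for (k in 0:1)
    m <- pmax(m, a[e1 + i, e2 + j, e3 + k, drop = FALSE])
  m
}

# Preprocess one case for the network: window-normalize, resample to the
# input grid, derive the half-resolution input by 2x average pooling, and
# build per-level binary targets by max-pooling the mask.
seg_prepare <- function(vol, mask, cfg, clip = c(0, 100)) {
  nv <- normalize_intensity(vol, clip[1], clip[2])
  tgt <- cfg$full_res_shape
  newsp <- dim(nv$data) * nv$spacing_mm / tgt
  xf <- resample_grid(nv$data, nv$spacing_mm, tgt, newsp)
  x_full <- array(xf, c(1L, tgt))
  ap <- function(a) {
    d <- dim(a)
    e1 <- seq(1L, d[1], 2L); e2 <- seq(1L, d[2], 2L); e3 <- seq(1L, d[3], 2L)
    (a[e1, e2, e3] + a[e1 + 1, e2, e3] + a[e1, e2 + 1, e3] +
       a[e1 + 1, e2 + 1, e3] + a[e1, e2, e3 + 1] + a[e1 + 1, e2, e3 + 1] +
       a[e1, e2 + 1, e3 + 1] + a[e1 + 1, e2 + 1, e3 + 1]) / 8
  }
  x_half <- array(ap(xf), c(1L, tgt %/% 2L))
  out <- list(x_full = x_full, x_half = x_half)
  if (!is.null(mask)) {
    y <- resample_grid(mask$data, mask$spacing_mm, tgt, newsp, nearest = TRUE)
    ys <- list(array(y, c(1L, tgt)))
    yl <- y
    for (l in seq_len(cfg$deep_supervision_levels)) {
      yl <- maxpool2_arr(yl)
      ys[[l + 1L]] <- array(yl, c(1L, dim(yl)))
    }
    out$targets <- ys
  }
  out
}

#' Train the segmentation network
#'
#' Whole-volume batches of one; the loss is
#' `w_dice * softDice + w_ce * crossEntropy` summed over the
#' deep-supervision outputs with per-level weights halving by depth,
#' optimized by Adam with polynomial decay of the base rate. Identical
#' seeds give identical loss histories.
#'
#' @param model a `seg_model`.
#' @param cases list of `synthetic_case` objects (or lists with `image`
#'   and `mask`).
#' @param loss_weights `c(w_dice, w_ce)`, nonnegative, not both zero.
#' @param epochs training epochs.
#' @param seed training seed (shuffling).
#' @param lr initial learning rate.
#' @param val_cases optional held-out cases; if given, median Dice is
#'   recorded each epoch.
#' @return The trained `seg_model` with `$train_state` holding `epoch`,
#'   `loss_history`, `val_dice_history` and `seed`.
#' @export
train_segmentation <- function(model, cases, loss_weights = c(1, 1),
                               epochs = 25L, seed = 1L, lr = 3e-3,
                               val_cases = list()) {
  stopifnot(inherits(model, "seg_model"), length(cases) >= 2)
  if (any(loss_weights < 0) || sum(loss_weights) == 0)
    stop("loss weights must be nonnegative and not both zero")
  if (all(vapply(cases, function(cs) sum(cs$mask$data) == 0, logical(1))))
    stop("degenerate labels: all training masks are empty")
  cfg <- model$cfg
  prep <- lapply(cases, function(cs) seg_prepare(cs$image, cs$mask, cfg))
  nlev <- 1L + cfg$deep_supervision_levels
  lw <- 0.5^(seq_len(nlev) - 1L)
  lw <- lw / sum(lw)
  total_steps <- epochs * length(cases)
  loss_hist <- numeric(epochs)
  val_hist <- rep(NA_real_, epochs)
  with_seed(seed, {
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(length(prep))
      eloss <- 0
      for (i in ord) {
        step <- step + 1L
        nn_zero_grad(model$params)
        tp <- with_tape({
          fw <- seg_forward(model, prep[[i]]$x_full, prep[[i]]$x_half)
          terms <- list(); wts <- numeric(0)
          for (l in seq_len(nlev)) {
            tgt <- prep[[i]]$targets[[l]]
            terms <- c(terms,
                       list(op_softdice_logits(fw$logits[[l]], tgt),
                            op_bce_logits(fw$logits[[l]], tgt)))
            wts <- c(wts, lw[l] * loss_weights[1], lw[l] * loss_weights[2])
          }
          op_wsum(terms, wts)
        })
        nn_backward(tp$result, tp$tape)
        nn_adam_step(model$params, poly_lr(lr, step, total_steps), step)
        eloss <- eloss + tp$result$val
      }
      loss_hist[ep] <- eloss / length(prep)
      if (length(val_cases)) {
        model$trained <- TRUE
        dc <- vapply(val_cases, function(cs)
          dice_coefficient(predict_mask(model, cs$image), cs$mask),
          numeric(1))
        val_hist[ep] <- stats::median(dc)
      }
    }
  })
  model$trained <- TRUE
  model$train_state <- list(epoch = epochs, loss_history = loss_hist,
                            val_dice_history = val_hist,
                            seed = as.integer(seed))
  model
}

#' Predict a lesion mask
#'
#' Thresholds the full-resolution foreground probability map and resamples
#' it (nearest-neighbour) back onto the input volume's grid.
#'
#' @param model a trained `seg_model`.
#' @param vol an `image_volume`.
#' @param threshold probability threshold in (0, 1).
#' @return A `lesion_mask` on `vol`'s grid.
#' @export
predict_mask <- function(model, vol, threshold = 0.5) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  cfg <- model$cfg
  pp <- seg_prepare(vol, NULL, cfg)
  fw <- seg_forward(model, pp$x_full, pp$x_half)
  p <- 1 / (1 + exp(-fw$logits[[1]]$val[1, , , ]))
  m <- (p >= threshold) * 1
  d <- dim(vol$data)
  tgt <- cfg$full_res_shape
  back <- resample_grid(array(m, tgt), dim(vol$data) * vol$spacing_mm / tgt,
                        d, vol$spacing_mm, nearest = TRUE)
  lesion_mask(back != 0, vol$spacing_mm, vol$affine)
}

#' Dice similarity coefficient between two masks
#'
#' `2|A∩B| / (|A|+|B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b `lesion_mask` objects on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)))
    stop("masks must share a grid")
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) return(1)
  2 * sum(a$data * b$data) / (sa + sb)
}
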