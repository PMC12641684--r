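# Generative autoencoder over dilated-mask lesion patches.
#
# The lesion mask is dilated (cubic element, default size 5) so the patch
# covers peri-lesional tissue; the patch is cropped to a cube around the
# dilated region, resampled to a fixed shape, and encoded by a
# convolutional variational autoencoder whose latent mean map is the
# deep-feature vector. An adversarial (non-saturating GAN) term on the
# reconstruction is optional; with weight zero the model is a plain VAE.

#' VAE-GAN configuration
#'
#' @param patch_shape cubic patch grid (voxels per axis), divisible by
#'   `2^depth`.
#' @param latent_channels channels of the latent mean / log-variance maps.
#' @param base_channels first-stage encoder channels (doubling per stage).
#' @param depth number of 2x downsamplings.
#' @param loss_weights `c(recon, kl, adv)`, nonnegative; `adv = 0` disables
#'   the discriminator.
#' @param epochs training epochs.
#' @param lr initial learning rate (Adam, polynomial decay).
#' @param seed training / initialization seed.
#' @return A `vaegan_config`.
#' @export
vaegan_config <- function(patch_shape = c(16L, 16L, 16L),
                          latent_channels = 16L, base_channels = 8L,
                          depth = 2L,
                          loss_weights = c(recon = 1, kl = 1e-3, adv = 0),
                          epochs = 20L, lr = 3e-3, seed = 1L) {
  patch_shape <- as.integer(rep(patch_shape, length.out = 3))
  if (length(unique(patch_shape)) != 1L) stop("patch_shape must be cubic")
  if (any(patch_shape %% 2L^depth != 0L))
    stop("patch_shape must be divisible by 2^depth")
  if (any(loss_weights < 0)) stop("loss weights must be nonnegative")
  structure(list(patch_shape = patch_shape,
                 latent_channels = as.integer(latent_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 loss_weights = loss_weights, epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed)),
            class = "vaegan_config")
}

#' Crop a cubic region of interest around a dilated mask
#'
#' Takes the bounding box of the dilated mask, pads it symmetrically to a
#' cube, resamples to `out_shape` (trilinear) and zeroes voxels outside the
#' dilated mask.
#'
#' @param vol an `image_volume`.
#' @param dmask a nonempty (dilated) `lesion_mask` on the same grid.
#' @param out_shape output grid, voxels per axis.
#' @return An `image_volume` of exactly `out_shape`.
#' @export
crop_roi <- function(vol, dmask, out_shape = c(16L, 16L, 16L)) {
  out_shape <- as.integer(rep(out_shape, length.out = 3))
  idx <- which(dmask$data != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty ROI: dilated mask has no voxels")
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sp <- vol$spacing_mm
  ctr <- (lo + hi) / 2
  side_mm <- max((hi - lo + 1) * sp)
  # sample at the centres of out_shape equal cells spanning the cube, in
  # fractional voxel indices of the source grid (an aligned crop is exact)
  vals <- lapply(1:3, function(ax) {
    half <- side_mm / 2 / sp[ax]
    step <- side_mm / out_shape[ax] / sp[ax]
    ctr[ax] - half + (seq_len(out_shape[ax]) - 0.5) * step
  })
  g <- expand.grid(x = vals[[1]], y = vals[[2]], z = vals[[3]])
  img <- array(interp3_trilinear(vol$data, g$x, g$y, g$z), out_shape)
  msk <- array(interp3_nearest(dmask$data, g$x, g$y, g$z), out_shape)
  # out-of-grid queries were clamped; mark them background
  oob <- g$x < 0.5 | g$x > dim(vol$data)[1] + 0.5 |
    g$y < 0.5 | g$y > dim(vol$data)[2] + 0.5 |
    g$z < 0.5 | g$z > dim(vol$data)[3] + 0.5
  msk[oob] <- 0
  img[msk == 0] <- 0
  image_volume(img, rep(side_mm / out_shape[1], 3))
}

vae_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

build_vaegan_params <- function(cfg) {
  ch <- vae_channels(cfg)
  pr <- list()
  cin <- 1L
  for (l in seq_len(cfg$depth)) {
    pr[[paste0("enc_l", l, "_W")]] <- nn_param(conv_init(cin, ch[l]))
    pr[[paste0("enc_l", l, "_b")]] <- nn_param(numeric(ch[l]))
    cin <- ch[l]
  }
  lc <- cfg$latent_channels
  pr$mu_W <- nn_param(matrix(stats::rnorm(lc * cin, 0, sqrt(1 / cin)), lc, cin))
  pr$mu_b <- nn_param(numeric(lc))
  pr$lv_W <- nn_param(matrix(stats::rnorm(lc * cin, 0, 0.01), lc, cin))
  pr$lv_b <- nn_param(numeric(lc) - 2)   # start with small latent variance
  cin <- lc
  for (l in rev(seq_len(cfg$depth))) {
    pr[[paste0("dec_l", l, "_W")]] <- nn_param(conv_init(cin, ch[l]))
    pr[[paste0("dec_l", l, "_b")]] <- nn_param(numeric(ch[l]))
    cin <- ch[l]
  }
  pr$out_W <- nn_param(matrix(stats::rnorm(cin, 0, 0.05), 1L, cin))
  pr$out_b <- nn_param(0)
  # small discriminator (used only when the adversarial weight is > 0)
  pr$d1_W <- nn_param(conv_init(1L, 8L)); pr$d1_b <- nn_param(numeric(8))
  pr$d2_W <- nn_param(conv_init(8L, 16L)); pr$d2_b <- nn_param(numeric(16))
  pr$d3_W <- nn_param(matrix(stats::rnorm(16, 0, 0.05), 1L, 16L))
  pr$d3_b <- nn_param(0)
  pr
}

vae_encode_nodes <- function(pr, cfg, x) {
  h <- x
  for (l in seq_len(cfg$depth)) {
    h <- op_lrelu(op_conv3(h, pr[[paste0("enc_l", l, "_W")]],
                           pr[[paste0("enc_l", l, "_b")]]))
    h <- op_avgpool2(h)
  }
  list(mu = op_conv1(h, pr$mu_W, pr$mu_b),
       logvar = op_conv1(h, pr$lv_W, pr$lv_b))
}

vae_decode_nodes <- function(pr, cfg, z) {
  h <- z
  for (l in rev(seq_len(cfg$depth))) {
    h <- op_lrelu(op_conv3(op_upsample2(h), pr[[paste0("dec_l", l, "_W")]],
                           pr[[paste0("dec_l", l, "_b")]]))
  }
  op_conv1(h, pr$out_W, pr$out_b)
}

disc_logit <- function(pr, x) {
  h <- op_avgpool2(op_lrelu(op_conv3(x, pr$d1_W, pr$d1_b)))
  h <- op_avgpool2(op_lrelu(op_conv3(h, pr$d2_W, pr$d2_b)))
  op_global_mean(op_conv1(h, pr$d3_W, pr$d3_b))
}

gen_param_names <- function(pr) grep("^d[123]_", names(pr), invert = TRUE,
                                     value = TRUE)

#' Train the variational autoencoder (optionally adversarial)
#'
#' Total generator loss is `w_recon * L1 + w_kl * KL(q || N(0,I)) +
#' w_adv * nonsaturating-GAN`; the discriminator (when `w_adv > 0`) is
#' updated alternately. Seeded runs are reproducible.
#'
#' @param patches list of `image_volume` patches of the configured shape
#'   (at least 8).
#' @param cfg a `vaegan_config`.
#' @return A trained `vaegan_model` with `$loss_history` (per-epoch total)
#'   and `$recon_history` (per-epoch L1).
#' @export
train_vaegan <- function(patches, cfg = vaegan_config()) {
  stopifnot(inherits(cfg, "vaegan_config"))
  if (length(patches) < 8) stop("need at least 8 patches")
  xs <- lapply(patches, function(p) {
    stopifnot(all(dim(p$data) == cfg$patch_shape))
    array(p$data, c(1L, cfg$patch_shape))
  })
  rng <- range(vapply(xs, function(a) max(a) - min(a), numeric(1)))
  if (rng[2] == 0)
    warning("all patches are constant; latent features will be degenerate")
  w <- cfg$loss_weights
  adv <- w[3] > 0
  with_seed(cfg$seed, {
    pr <- build_vaegan_params(cfg)
    gnames <- gen_param_names(pr)
    dnames <- setdiff(names(pr), gnames)
    loss_hist <- numeric(cfg$epochs); recon_hist <- numeric(cfg$epochs)
    total_steps <- cfg$epochs * length(xs)
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(xs))
      el <- 0; er <- 0
      for (i in ord) {
        step <- step + 1L
        x <- xs[[i]]
        lr_t <- poly_lr(cfg$lr, step, total_steps)
        if (adv) {             # discriminator step on real vs reconstruction
          nn_zero_grad(pr)
          tp <- with_tape({
            enc <- vae_encode_nodes(pr, cfg, nn_node(x))
            eps <- array(stats::rnorm(length(enc$mu$val)), dim(enc$mu$val))
            rec <- vae_decode_nodes(pr, cfg, op_reparam(enc$mu, enc$logvar,
                                                        eps))
            fake <- nn_node(rec$val)     # detached copy
            dr <- disc_logit(pr, nn_node(x))
            df <- disc_logit(pr, fake)
            op_wsum(list(op_bce_logits(dr, 1), op_bce_logits(df, 0)),
                    c(1, 1))
          })
          nn_backward(tp$result, tp$tape)
          nn_adam_step(pr[dnames], lr_t, step)
        }
        nn_zero_grad(pr)
        tp <- with_tape({
          enc <- vae_encode_nodes(pr, cfg, nn_node(x))
          eps <- array(stats::rnorm(length(enc$mu$val)), dim(enc$mu$val))
          z <- op_reparam(enc$mu, enc$logvar, eps)
          rec <- vae_decode_nodes(pr, cfg, z)
          terms <- list(op_l1(rec, x), op_kl_gauss(enc$mu, enc$logvar))
          wts <- w[1:2]
          if (adv) {
            terms <- c(terms, list(op_bce_logits(disc_logit(pr, rec), 1)))
            wts <- c(wts, w[3])
          }
          list(loss = op_wsum(terms, wts), recon = terms[[1]]$val)
        })
        nn_backward(tp$result$loss, tp$tape)
        nn_adam_step(pr[gnames], lr_t, step)
        el <- el + tp$result$loss$val
        er <- er + tp$result$recon
      }
      loss_hist[ep] <- el / length(xs)
      recon_hist[ep] <- er / length(xs)
    }
    structure(list(cfg = cfg, params = pr, trained = TRUE,
                   loss_history = loss_hist, recon_history = recon_hist),
              class = "vaegan_model")
  })
}

# Latent mean map (channels, d, h, w) of one patch; sample-free.
vaegan_encode <- function(model, patch) {
  stopifnot(inherits(model, "vaegan_model"))
  x <- array(patch$data, c(1L, model$cfg$patch_shape))
  enc <- vae_encode_nodes(model$params, model$cfg, nn_node(x))
  enc$mu$val
}

#' Latent deep features of one case
#'
#' For a segmentation model, returns the flattened full- and half-scale
#' encoder bottleneck activations; for a VAE model, the latent mean map of
#' the dilated-mask patch (never a sample). Flattening is fixed: the
#' channel index varies fastest, then x, y, z.
#'
#' @param model a trained `seg_model` or `vaegan_model`.
#' @param case a `synthetic_case` (or list with `image` and `mask`).
#' @param dilate_size structuring element for the VAE patch (odd).
#' @return Named list of numeric row vectors: `seg_full` and `seg_half`
#'   for a segmentation model, `vaegan` for a VAE model; each with
#'   attribute `tensor_shape`.
#' @export
extract_latents <- function(model, case, dilate_size = 5L) {
  UseMethod("extract_latents")
}

#' @export
extract_latents.seg_model <- function(model, case, dilate_size = 5L) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  pp <- seg_prepare(case$image, NULL, model$cfg)
  fw <- seg_forward(model, pp$x_full, pp$x_half)
  out <- list(seg_full = structure(as.vector(fw$bottleneck_full$val),
                                   tensor_shape = dim(fw$bottleneck_full$val)))
  if (!model$cfg$single_scale)
    out$seg_half <- structure(as.vector(fw$bottleneck_half$val),
                              tensor_shape = dim(fw$bottleneck_half$val))
  out
}

#' @export
extract_latents.vaegan_model <- function(model, case, dilate_size = 5L) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  dm <- dilate_mask(case$mask, dilate_size)
  patch <- crop_roi(normalize_intensity(case$image), dm,
                    model$cfg$patch_shape)
  mu <- vaegan_encode(model, patch)
  list(vaegan = structure(as.vector(mu), tensor_shape = dim(mu)))
}

#' Assemble latent feature blocks for a cohort
#'
#' @param seg a trained `seg_model`.
#' @param vae a trained `vaegan_model`.
#' @param cases list of cases.
#' @param dilate_size structuring element size for the VAE patches.
#' @return List of `feature_block`s named `seg_full`, `seg_half` (if
#'   multiscale) and `vaegan`.
#' @export
latent_blocks <- function(seg, vae, cases, dilate_size = 5L) {
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  segl <- lapply(cases, function(cs) extract_latents(seg, cs))
  vael <- lapply(cases, function(cs) extract_latents(vae, cs, dilate_size))
  mk <- function(rows, src) {
    M <- do.call(rbind, rows)
    colnames(M) <- sprintf("%s_%05d", src, seq_len(ncol(M)))
    rownames(M) <- ids
    fb <- feature_block(M, "latent")
    attr(fb, "source") <- src
    attr(fb, "tensor_shape") <- attr(rows[[1]], "tensor_shape")
    fb
  }
  out <- list(seg_full = mk(lapply(segl, `[[`, "seg_full"), "seg_full"))
  if (!seg$cfg$single_scale)
    out$seg_half <- mk(lapply(segl, `[[`, "seg_half"), "seg_half")
  out$vaegan <- mk(lapply(vael, `[[`, "vaegan"), "vaegan")
  out
}

#' Write / read a feature block as CSV with a JSON sidecar
#'
#' The matrix is stored as a case-by-feature CSV with a stable header; the
#' sidecar records the family and, for latent blocks, the source, tensor
#' shape and flatten order (channel fastest, then x, y, z).
#'
#' @param block a `feature_block`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return The path, invisibly (`write_feature_block`); the re-read
#'   `feature_block` (`read_feature_block`).
#' @export
write_feature_block <- function(block, path) {
  stopifnot(inherits(block, "feature_block"))
  utils::write.csv(as.data.frame(block$matrix), path)
  ts <- attr(block, "tensor_shape")
  side <- c(sprintf('"family": "%s"', block$family),
            if (!is.null(attr(block, "source")))
              sprintf('"source": "%s"', attr(block, "source")),
            if (!is.null(ts))
              sprintf('"tensor_shape": [%s]', paste(ts, collapse = ", ")),
            '"flatten_order": "channel,x,y,z"')
  writeLines(paste0("{", paste(side, collapse = ", "), "}"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_feature_block
#' @export
read_feature_block <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  meta <- paste(readLines(paste0(path, ".json")), collapse = "")
  fam <- sub('.*"family": "([^"]+)".*', "\\1", meta)
  fb <- feature_block(as.matrix(d), fam)
  if (grepl('"source"', meta))
    attr(fb, "source") <- sub('.*"source": "([^"]+)".*', "\\1", meta)
  if (grepl('"tensor_shape"', meta))
    attr(fb, "tensor_shape") <-
      as.numeric(strsplit(sub('.*"tensor_shape": \\[([^]]*)\\].*', "\\1",
                              meta), ", ")[[1]])
  fb
}

#' Shift a feature block to be nonnegative using training rows only
#'
#' Each column is shifted by the negative of its minimum over the training
#' rows; test rows falling below the training minimum are clipped at zero
#' (count recorded in attribute `clipped_n`).
#'
#' @param block a `feature_block`.
#' @param train_ids row identifiers used to fit the shift.
#' @return The shifted `feature_block` with attributes `shift` and
#'   `clipped_n`.
#' @export
nonneg_shift <- function(block, train_ids) {
  stopifnot(inherits(block, "feature_block"), length(train_ids) >= 1)
  M <- block$matrix
  tr <- rownames(M) %in% train_ids
  if (!any(tr)) stop("no training rows found in block")
  mins <- apply(M[tr, , drop = FALSE], 2, min)
  S <- sweep(M, 2, mins, `-`)
  clipped <- sum(S < 0)
  S[S < 0] <- 0
  out <- feature_block(S, block$family)
  attr(out, "shift") <- -mins
  attr(out, "clipped_n") <- clipped
  attr(out, "source") <- attr(block, "source")
  out
}
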