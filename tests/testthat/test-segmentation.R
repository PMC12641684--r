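test_that("network geometry follows the configuration arithmetic", {
  # published geometry: 128^3/64^3 inputs, depth 4, 512-channel bottleneck
  paper <- multiscale_net_config(full_res_shape = c(128, 128, 128),
                                 base_channels = 32, depth = 4,
                                 bottleneck_channels = 512,
                                 deep_supervision_levels = 2)
  bs <- bottleneck_shapes(paper)
  expect_equal(bs$full, c(512, 8, 8, 8))
  expect_equal(bs$half, c(512, 4, 4, 4))

  desk <- multiscale_net_config(full_res_shape = c(32, 32, 32),
                                base_channels = 64, depth = 3,
                                bottleneck_channels = 64)
  expect_equal(bottleneck_shapes(desk)$full, c(64, 4, 4, 4))
  expect_equal(bottleneck_shapes(desk)$half, c(64, 2, 2, 2))

  single <- multiscale_net_config(single_scale = TRUE)
  expect_length(bottleneck_shapes(single), 1)

  expect_error(multiscale_net_config(full_res_shape = c(20, 20, 20)),
               "divisible")
})

test_that("built models expose the configured bottlenecks in forward passes", {
  cfg <- multiscale_net_config(full_res_shape = c(16, 16, 16),
                               base_channels = 4, depth = 2,
                               bottleneck_channels = 12)
  mdl <- build_multiscale_unet(cfg, seed = 3)
  x <- array(rnorm(16^3), c(1, 16, 16, 16))
  xh <- array(rnorm(8^3), c(1, 8, 8, 8))
  fw <- latentrad:::seg_forward(mdl, x, xh)
  expect_equal(dim(fw$bottleneck_full$val), c(12, 4, 4, 4))
  expect_equal(dim(fw$bottleneck_half$val), c(12, 2, 2, 2))
  expect_equal(dim(fw$logits[[1]]$val), c(1, 16, 16, 16))

  # deep_supervision_levels = 2 -> three output terms in the loss
  cfg3 <- multiscale_net_config(full_res_shape = c(16, 16, 16),
                                base_channels = 4, depth = 3,
                                bottleneck_channels = 8,
                                deep_supervision_levels = 2)
  expect_error(multiscale_net_config(depth = 2, deep_supervision_levels = 2))
  m3 <- build_multiscale_unet(cfg3, seed = 1)
  fw3 <- latentrad:::seg_forward(m3, x, xh)
  expect_length(fw3$logits, 3)

  ss <- build_multiscale_unet(multiscale_net_config(single_scale = TRUE), 1)
  fws <- latentrad:::seg_forward(ss, x, xh)
  expect_null(fws$bottleneck_half)
})

test_that("autodiff gradients match finite differences", {
  set.seed(8)
  W <- latentrad:::nn_param(latentrad:::conv_init(1, 2))
  b <- latentrad:::nn_param(numeric(2))
  Wo <- latentrad:::nn_param(matrix(rnorm(2, 0, 0.3), 1, 2))
  bo <- latentrad:::nn_param(0)
  x <- array(rnorm(4^3), c(1, 4, 4, 4))
  y <- array(rbinom(4^3, 1, 0.4), c(1, 4, 4, 4))
  loss_of <- function() {
    tp <- latentrad:::with_tape({
      h <- latentrad:::op_lrelu(latentrad:::op_conv3(
        latentrad:::nn_node(x), W, b))
      lg <- latentrad:::op_conv1(h, Wo, bo)
      latentrad:::op_wsum(list(latentrad:::op_softdice_logits(lg, y),
                               latentrad:::op_bce_logits(lg, y)),
                          c(0.7, 0.3))
    })
    tp
  }
  tp <- loss_of()
  latentrad:::nn_backward(tp$result, tp$tape)
  for (p in list(W, b, Wo)) {
    idx <- sample(length(p$val), min(3, length(p$val)))
    for (i in idx) {
      eps <- 1e-5
      old <- p$val[i]
      p$val[i] <- old + eps; up <- loss_of()$result$val
      p$val[i] <- old - eps; dn <- loss_of()$result$val
      p$val[i] <- old
      expect_equal((up - dn) / (2 * eps), p$grad[i], tolerance = 1e-4)
    }
  }
})

test_that("combined loss behaves at its boundary cases", {
  y <- array(rbinom(64, 1, 0.5), c(1, 4, 4, 4))
  perfect <- latentrad:::nn_node(array(ifelse(y == 1, 30, -30), dim(y)))
  expect_lt(latentrad:::op_softdice_logits(perfect, y)$val, 1e-6)
  expect_lt(latentrad:::op_bce_logits(perfect, y)$val, 1e-6)
  # non-negative loss for arbitrary predictions
  set.seed(4)
  rnd <- latentrad:::nn_node(array(rnorm(64), dim(y)))
  expect_gte(latentrad:::op_softdice_logits(rnd, y)$val, 0)
  expect_gte(latentrad:::op_bce_logits(rnd, y)$val, 0)
})

test_that("training is seeded-deterministic and decreases the loss", {
  cfg <- tiny_phantom_cfg(lesion_volume_range_ml = c(6, 10),
                          irregularity = 0.1)
  cases <- generate_cohort(cfg, 4, seed = 41)
  net <- multiscale_net_config(full_res_shape = c(8, 8, 8),
                               base_channels = 4, depth = 1,
                               bottleneck_channels = 8,
                               deep_supervision_levels = 0)
  m1 <- train_segmentation(build_multiscale_unet(net, 2), cases,
                           epochs = 4, seed = 9)
  m2 <- train_segmentation(build_multiscale_unet(net, 2), cases,
                           epochs = 4, seed = 9)
  expect_identical(m1$train_state$loss_history, m2$train_state$loss_history)
  expect_lt(m1$train_state$loss_history[4], m1$train_state$loss_history[1])
  expect_length(m1$train_state$loss_history, 4)

  expect_error(train_segmentation(build_multiscale_unet(net, 2), cases,
                                  loss_weights = c(0, 0)), "weights")
  empty <- lapply(cases, function(cs) {
    cs$mask <- lesion_mask(array(FALSE, dim(cs$mask$data)),
                           cs$mask$spacing_mm)
    cs
  })
  expect_error(train_segmentation(build_multiscale_unet(net, 2), empty),
               "degenerate")
})

test_that("mask prediction thresholds probabilities deterministically", {
  cfg <- tiny_phantom_cfg(lesion_volume_range_ml = c(6, 10))
  cases <- generate_cohort(cfg, 4, seed = 51)
  net <- multiscale_net_config(full_res_shape = c(8, 8, 8),
                               base_channels = 4, depth = 1,
                               bottleneck_channels = 8,
                               deep_supervision_levels = 0)
  um <- build_multiscale_unet(net, 2)
  expect_error(predict_mask(um, cases[[1]]$image), "trained")
  tm <- train_segmentation(um, cases, epochs = 3, seed = 9)
  p1 <- predict_mask(tm, cases[[1]]$image)
  p2 <- predict_mask(tm, cases[[1]]$image)
  expect_identical(p1$data, p2$data)
  expect_equal(dim(p1$data), dim(cases[[1]]$image$data))
  expect_error(predict_mask(tm, cases[[1]]$image, threshold = 1.5),
               "threshold")
})

test_that("Dice coefficient follows its definition and symmetry", {
  sp <- c(1, 1, 1)
  mk <- function(v) lesion_mask(array(v, c(2, 2, 2)), sp)
  a <- mk(c(1, 1, 1, 1, 0, 0, 0, 0))
  b <- mk(c(1, 1, 0, 0, 1, 1, 0, 0))
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, mk(c(0, 0, 0, 0, 1, 1, 1, 1))), 0)
  expect_equal(dice_coefficient(a, b), 0.5)     # |A|=4,|B|=4,overlap 2
  expect_equal(dice_coefficient(mk(rep(0, 8)), mk(rep(0, 8))), 1)
  expect_error(dice_coefficient(a, lesion_mask(array(0, c(3, 3, 3)), sp)),
               "grid")
  set.seed(6)
  for (i in 1:10) {
    x <- mk(rbinom(8, 1, 0.5)); y <- mk(rbinom(8, 1, 0.5))
    d1 <- dice_coefficient(x, y)
    expect_equal(d1, dice_coefficient(y, x))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})
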