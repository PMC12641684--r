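test_that("cubic dilation matches its structuring-element geometry", {
  sp <- c(1, 1, 1)
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  expect_equal(sum(dilate_mask(lesion_mask(m, sp), 5)$data), 125)
  expect_identical(dilate_mask(lesion_mask(m, sp), 1)$data,
                   lesion_mask(m, sp)$data)
  corner <- array(FALSE, c(9, 9, 9)); corner[1, 1, 1] <- TRUE
  expect_equal(sum(dilate_mask(lesion_mask(corner, sp), 5)$data), 27)
  expect_error(dilate_mask(lesion_mask(m, sp), 4), "odd")
})

test_that("dilation is extensive and monotone", {
  set.seed(21)
  sp <- c(1, 1, 1)
  for (i in 1:5) {
    a <- array(runif(6^3) < 0.15, c(6, 6, 6))
    b <- a | array(runif(6^3) < 0.15, c(6, 6, 6))
    da <- dilate_mask(lesion_mask(a, sp), 3)$data
    db <- dilate_mask(lesion_mask(b, sp), 3)$data
    expect_true(all(da >= a))            # A subset of D(A)
    expect_true(all(db >= da))           # monotone
  }
})

test_that("ROI cropping is exact for aligned content and centres lesions", {
  set.seed(22)
  # dilated mask covering the whole grid at the output shape: identity
  v <- image_volume(array(rnorm(16^3), c(16, 16, 16)), c(1, 1, 1))
  full <- lesion_mask(array(TRUE, c(16, 16, 16)), c(1, 1, 1))
  cr <- crop_roi(v, full, c(16, 16, 16))
  expect_equal(cr$data, v$data, tolerance = 1e-12)

  cs <- generate_phantom(tiny_phantom_cfg(), 88)
  dm <- dilate_mask(cs$mask, 5)
  roi <- crop_roi(cs$image, dm, c(16, 16, 16))
  expect_equal(dim(roi$data), c(16, 16, 16))
  w <- which(roi$data != 0, arr.ind = TRUE)
  expect_true(all(abs(colMeans(w) - 8.5) <= 2))

  expect_error(crop_roi(v, lesion_mask(array(FALSE, c(16, 16, 16)),
                                       c(1, 1, 1))), "empty")
})

test_that("VAE training is reproducible and reduces reconstruction error", {
  cases <- generate_cohort(tiny_phantom_cfg(), 8, seed = 61)
  patches <- lapply(cases, function(cs)
    crop_roi(normalize_intensity(cs$image), dilate_mask(cs$mask, 5),
             c(8, 8, 8)))
  cfg <- vaegan_config(patch_shape = c(8, 8, 8), latent_channels = 4,
                       base_channels = 4, depth = 2, epochs = 20, seed = 14)
  m1 <- train_vaegan(patches, cfg)
  expect_lt(m1$recon_history[20], m1$recon_history[1])
  m2 <- train_vaegan(patches, cfg)
  expect_identical(m1$loss_history, m2$loss_history)

  # published patch geometry maps to a (512, 4, 4, 4) latent tensor
  pcfg <- vaegan_config(patch_shape = c(64, 64, 64), latent_channels = 512,
                        depth = 4)
  expect_equal(c(pcfg$latent_channels, pcfg$patch_shape %/% 2^pcfg$depth),
               c(512, 4, 4, 4))

  expect_error(train_vaegan(patches[1:4], cfg), "at least 8")
  flat <- lapply(1:8, function(i)
    image_volume(array(0, c(8, 8, 8)), c(1, 1, 1)))
  expect_warning(train_vaegan(flat, vaegan_config(patch_shape = c(8, 8, 8),
                                                  latent_channels = 4,
                                                  base_channels = 4,
                                                  epochs = 1)),
                 "constant")
})

test_that("latent extraction is sample-free, deterministic and separates
           volumes", {
  cases <- generate_cohort(tiny_phantom_cfg(lesion_volume_range_ml = c(2, 2)),
                           8, seed = 71)
  big <- generate_phantom(tiny_phantom_cfg(lesion_volume_range_ml = c(10, 10)),
                          72)
  patches <- lapply(cases, function(cs)
    crop_roi(normalize_intensity(cs$image), dilate_mask(cs$mask, 5),
             c(8, 8, 8)))
  vcfg <- vaegan_config(patch_shape = c(8, 8, 8), latent_channels = 4,
                        base_channels = 4, epochs = 5, seed = 3)
  vm <- train_vaegan(patches, vcfg)
  l1 <- extract_latents(vm, cases[[1]])
  l2 <- extract_latents(vm, cases[[1]])
  expect_identical(l1$vaegan, l2$vaegan)
  expect_equal(length(l1$vaegan), prod(attr(l1$vaegan, "tensor_shape")))
  lbig <- extract_latents(vm, big)
  expect_gt(sqrt(sum((l1$vaegan - lbig$vaegan)^2)), 0)

  net <- multiscale_net_config(full_res_shape = c(8, 8, 8),
                               base_channels = 4, depth = 1,
                               bottleneck_channels = 8,
                               deep_supervision_levels = 0)
  sm <- train_segmentation(build_multiscale_unet(net, 2), cases[1:4],
                           epochs = 2, seed = 5)
  sl <- extract_latents(sm, cases[[1]])
  expect_named(sl, c("seg_full", "seg_half"))
  expect_equal(attr(sl$seg_full, "tensor_shape"), c(8, 4, 4, 4))
  expect_identical(sl$seg_full, extract_latents(sm, cases[[1]])$seg_full)
})

test_that("feature blocks round-trip through CSV plus sidecar", {
  M <- matrix(runif(12), 3, 4,
              dimnames = list(c("a", "b", "c"), sprintf("l%02d", 1:4)))
  fb <- feature_block(M, "latent")
  attr(fb, "source") <- "vaegan"
  attr(fb, "tensor_shape") <- c(4, 1, 1, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_block(fb, path)
  back <- read_feature_block(path)
  expect_equal(back$matrix, fb$matrix)
  expect_equal(back$family, "latent")
  expect_equal(attr(back, "source"), "vaegan")
  expect_equal(attr(back, "tensor_shape"), c(4, 1, 1, 1))
})

test_that("nonnegative shift anchors on training rows and clips test rows", {
  M <- matrix(c(-2, 0, 3,
                5, 6, 7), nrow = 3, dimnames = list(c("a", "b", "c"),
                                                    c("f1", "f2")))
  fb <- feature_block(M, "latent")
  sh <- nonneg_shift(fb, c("a", "b", "c"))
  expect_equal(unname(sh$matrix[, "f1"]), c(0, 2, 5))
  expect_equal(min(sh$matrix), 0)

  # all-nonnegative block with zero minima is unchanged
  P <- matrix(c(0, 1, 2, 0, 3, 4), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  expect_equal(nonneg_shift(feature_block(P, "latent"),
                            c("a", "b", "c"))$matrix, P)

  # test row below the training minimum is clipped, and counted
  Q <- matrix(c(1, 2, -5, 4, 5, 6), nrow = 3,
              dimnames = list(c("tr1", "tr2", "te"), c("f1", "f2")))
  shq <- nonneg_shift(feature_block(Q, "latent"), c("tr1", "tr2"))
  expect_equal(unname(shq$matrix["te", "f1"]), 0)
  expect_equal(attr(shq, "clipped_n"), 1)
})
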