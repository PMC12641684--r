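test_that("shape features match analytic values on canonical solids", {
  sf <- shape_features(make_ball(10))
  expect_gte(sf[["Sphericity"]], 0.97)
  expect_lte(sf[["Sphericity"]], 1.02)
  expect_equal(sf[["Maximum3DDiameter"]], 20, tolerance = 0.1)

  cube <- array(FALSE, c(16, 16, 16)); cube[4:13, 4:13, 4:13] <- TRUE
  sc <- shape_features(lesion_mask(cube, c(1, 1, 1)))
  expect_equal(sc[["Elongation"]], 1, tolerance = 1e-6)
  expect_equal(sc[["Flatness"]], 1, tolerance = 1e-6)
  expect_equal(sc[["VoxelVolume"]], 1000)

  expect_length(sf, 14L)
  expect_error(shape_features(lesion_mask(array(FALSE, c(4, 4, 4)),
                                          c(1, 1, 1))), "empty")
})

test_that("first-order statistics match hand values", {
  cfg <- radiomics_config(bin_width = 1)
  mk <- function(vals) {
    n <- length(vals)
    list(v = image_volume(array(vals, c(n, 1, 1)), c(1, 1, 1)),
         m = lesion_mask(array(TRUE, c(n, 1, 1)), c(1, 1, 1)))
  }
  const <- mk(rep(4, 8))
  fo <- firstorder_features(const$v, const$m, cfg)
  expect_equal(fo[["Variance"]], 0)
  expect_equal(fo[["Entropy"]], 0)
  expect_equal(fo[["Skewness"]], 0)

  sym <- mk(c(1, 1, 3, 3))
  fs <- firstorder_features(sym$v, sym$m, cfg)
  expect_equal(fs[["Mean"]], 2)
  expect_equal(fs[["Variance"]], 1)
  expect_equal(fs[["Skewness"]], 0)
  expect_equal(fs[["Energy"]], 2 * 1 + 2 * 9)

  # four equiprobable bins -> 2 bits
  eq <- mk(c(0.1, 1.1, 2.1, 3.1))
  expect_equal(firstorder_features(eq$v, eq$m, cfg)[["Entropy"]], 2)
})

test_that("GLCM matches the hand-enumerated 2x2 table and brute force", {
  cfg <- radiomics_config(bin_width = 1)
  a <- array(c(1, 1, 2, 2), c(2, 2, 1))   # [[1,2],[1,2]] in x-y
  v <- image_volume(a, c(1, 1, 1))
  m <- lesion_mask(array(TRUE, c(2, 2, 1)), c(1, 1, 1))
  g <- glcm_features(v, m, cfg)
  # hand enumeration: offset (1,0,0) pairs (1,1),(2,2); (0,1,0) pairs
  # (1,2)x2; diagonals (1,2),(2,1) -> per-direction contrasts 0,1,1,1
  expect_equal(g[["Contrast"]], mean(c(0, 1, 1, 1)))

  # constant region convention
  cv <- image_volume(array(5, c(3, 3, 1)), c(1, 1, 1))
  cm <- lesion_mask(array(TRUE, c(3, 3, 1)), c(1, 1, 1))
  gc <- glcm_features(cv, cm, cfg)
  expect_equal(gc[["Contrast"]], 0)
  expect_equal(gc[["Correlation"]], 1)
  expect_equal(gc[["JointEntropy"]], 0)
})

test_that("GLCM accumulation is symmetric for random inputs", {
  set.seed(11)
  for (rep in 1:5) {
    d <- sample(2:5, 3, replace = TRUE)
    lv <- array(sample(1:4, prod(d), replace = TRUE), d)
    off <- offsets13()[sample(13, 1), ]
    cnt <- latentrad:::glcm_counts(lv, off, 4L)
    expect_equal(cnt, t(cnt))
  }
})

test_that("GLRLM matches hand enumeration on a 1D strip", {
  cfg <- radiomics_config(bin_width = 1)
  v <- image_volume(array(c(1, 1, 1, 2, 2), c(5, 1, 1)), c(1, 1, 1))
  m <- lesion_mask(array(TRUE, c(5, 1, 1)), c(1, 1, 1))
  lv <- array(0L, c(5, 1, 1)); lv[, 1, 1] <- c(1L, 1L, 1L, 2L, 2L)
  runs <- latentrad:::glrlm_runs(lv, c(1, 0, 0))
  expect_setequal(paste(runs$level, runs$length), c("1 3", "2 2"))
  # run percentage along that axis is 2/5
  st <- latentrad:::glrlm_stats(runs)
  expect_equal(st[["RunPercentage"]], 2 / 5)

  # all-distinct neighbours: every run has length 1
  vd <- image_volume(array(seq(0, 40, by = 10)[1:5], c(5, 1, 1)), c(1, 1, 1))
  gr <- glrlm_features(vd, m, cfg)
  expect_equal(gr[["LongRunEmphasis"]], 1)
  expect_equal(gr[["ShortRunEmphasis"]], 1)
})

test_that("short-run emphasis is always in (0, 1]", {
  set.seed(12)
  cfg <- radiomics_config(bin_width = 1)
  for (rep in 1:10) {
    d <- sample(3:6, 3, replace = TRUE)
    v <- image_volume(array(sample(1:3, prod(d), TRUE), d), c(1, 1, 1))
    m <- lesion_mask(array(runif(prod(d)) < 0.8, d), c(1, 1, 1))
    if (sum(m$data) == 0) next
    sre <- glrlm_features(v, m, cfg)[["ShortRunEmphasis"]]
    expect_gt(sre, 0); expect_lte(sre, 1)
  }
})

test_that("texture features equal brute-force enumeration exactly", {
  set.seed(13)
  cfg <- radiomics_config(bin_width = 1)
  for (rep in 1:8) {
    d <- sample(2:5, 3, replace = TRUE)
    vals <- sample(1:4, prod(d), replace = TRUE)
    v <- image_volume(array(vals, d), c(1, 1, 1))
    m <- lesion_mask(array(runif(prod(d)) < 0.85, d), c(1, 1, 1))
    if (sum(m$data) < 2) next
    lv <- array(0L, d)
    roi <- m$data != 0
    lv[roi] <- as.integer(vals[roi] - min(vals[roi]) + 1)

    # GLCM: average feature values over directions with nonzero pairs
    accs <- NULL; nd <- 0
    for (k in 1:13) {
      cnt <- bf_glcm_counts(lv, offsets13()[k, ], max(lv))
      if (sum(cnt) == 0) next
      st <- bf_glcm_stats(cnt / sum(cnt))
      accs <- if (is.null(accs)) st else accs + st
      nd <- nd + 1
    }
    if (nd > 0)
      expect_equal(glcm_features(v, m, cfg), accs / nd, tolerance = 1e-12)

    # GLRLM
    accr <- NULL
    for (k in 1:13) {
      runs <- bf_glrlm(lv, offsets13()[k, ])
      st <- bf_glrlm_stats(runs$level, runs$length, sum(roi))
      accr <- if (is.null(accr)) st else accr + st
    }
    expect_equal(glrlm_features(v, m, cfg), accr / 13, tolerance = 1e-12)
  }
})

test_that("features are invariant to whole-voxel translation and shape to
           intensity rescaling", {
  cfg <- radiomics_config(filters = character(0))
  cs <- generate_phantom(tiny_phantom_cfg(), 301)
  r1 <- extract_radiomics(cs$image, cs$mask, cfg)
  # translate image and mask by one voxel along x (content fits)
  shift1 <- function(a) {
    b <- array(0, dim(a)); b[2:dim(a)[1], , ] <- a[1:(dim(a)[1] - 1), , ]
    b
  }
  v2 <- image_volume(shift1(cs$image$data), cs$image$spacing_mm)
  m2 <- lesion_mask(shift1(cs$mask$data), cs$mask$spacing_mm)
  r2 <- extract_radiomics(v2, m2, cfg)
  expect_equal(r1, r2, tolerance = 1e-8)

  # shape block ignores intensity rescaling
  v3 <- image_volume(cs$image$data * 3 + 10, cs$image$spacing_mm)
  r3 <- extract_radiomics(v3, cs$mask, cfg)
  expect_equal(r1[grep("^shape_", names(r1))],
               r3[grep("^shape_", names(r3))])
})

test_that("filtered variants behave like their transforms", {
  cfg <- radiomics_config(bin_width = 1, filters = c("log", "wavelet"),
                          log_sigma_mm = 2)
  # LoG of a constant image responds zero
  v <- image_volume(array(5, c(8, 8, 8)), c(1, 1, 1))
  m <- lesion_mask(array(TRUE, c(8, 8, 8)), c(1, 1, 1))
  ff <- filtered_features(v, m, cfg)
  expect_equal(ff[["log_sigma_2_Variance"]], 0)

  # wavelet level 1 of an N^3 image gives 8 subbands of (N/2)^3
  sb <- latentrad:::haar_subbands(array(rnorm(16^3), c(16, 16, 16)))
  expect_length(sb, 8)
  expect_true(all(vapply(sb, function(s) all(dim(s) == 8), logical(1))))

  # LoG response peaks on a matched-scale Gaussian blob
  n <- 21; ctr <- 11
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  r2 <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2
  blob <- array(exp(-r2 / (2 * 2^2)), c(n, n, n))
  resp <- -latentrad:::log_filter(blob, c(1, 1, 1), 2)
  expect_equal(which.max(resp),
               which.max(blob))

  expect_error(filtered_features(v, m,
                                 radiomics_config(log_sigma_mm = -1)),
               "positive")
})
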