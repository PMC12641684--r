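# Synthetic pseudo-CT phantom cohorts.
#
# Each case is a noisy brain-like background with one hyperdense,
# optionally irregular, ellipsoidal lesion and a hypodense peri-lesional
# rim (edema analogue). Outcome labels carry a planted logistic signal in
# lesion volume, surface irregularity and rim texture, which the feature
# pipelines downstream are expected to recover.

# Evaluate `code` under a private, restorable RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

#' Phantom generator configuration
#'
#' Defaults emulate the hemorrhage cohort the pipeline targets: lesion
#' volumes lognormal with mean 13.1 mL and SD 12.6 mL truncated to
#' `lesion_volume_range_ml`, Hounsfield-like tissue contrasts (parenchyma
#' ~30, lesion 60-80, hypodense rim), and per-case surface irregularity and
#' rim-texture heterogeneity drawn uniformly up to the configured amplitudes.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel edge lengths in mm.
#' @param background_level parenchyma intensity, HU-like units.
#' @param background_noise_sd background noise SD.
#' @param lesion_intensity_range per-case lesion intensity drawn uniformly
#'   from this range.
#' @param lesion_noise_sd intra-lesional noise SD.
#' @param lesion_volume_range_ml truncation range for baseline lesion
#'   volume, mL; `c(0, 0)` produces empty masks.
#' @param volume_meanlog,volume_sdlog lognormal parameters of the baseline
#'   volume before truncation (defaults match mean 13.1, SD 12.6 mL).
#' @param irregularity maximum surface perturbation amplitude (0-1);
#'   per-case amplitude is drawn from U(0, `irregularity`).
#' @param axis_ratio_range ellipsoid semi-axis ratio range (volume
#'   preserving).
#' @param edema_rim_width_mm width of the peri-lesional rim, mm.
#' @param rim_contrast additive rim intensity (negative = hypodense).
#' @param rim_texture_sd_range per-case rim texture noise SD drawn uniformly
#'   from this range; this is the planted peri-lesional texture signal.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L),
                           spacing_mm = c(2, 2, 2),
                           background_level = 30,
                           background_noise_sd = 4,
                           lesion_intensity_range = c(60, 80),
                           lesion_noise_sd = 3,
                           lesion_volume_range_ml = c(1, 60),
                           volume_meanlog = 2.2451,
                           volume_sdlog = 0.8093,
                           irregularity = 0.3,
                           axis_ratio_range = c(0.8, 1.25),
                           edema_rim_width_mm = 4,
                           rim_contrast = -10,
                           rim_texture_sd_range = c(1, 8)) {
  cfg <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
              background_level = background_level,
              background_noise_sd = background_noise_sd,
              lesion_intensity_range = lesion_intensity_range,
              lesion_noise_sd = lesion_noise_sd,
              lesion_volume_range_ml = lesion_volume_range_ml,
              volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
              irregularity = irregularity,
              axis_ratio_range = axis_ratio_range,
              edema_rim_width_mm = edema_rim_width_mm,
              rim_contrast = rim_contrast,
              rim_texture_sd_range = rim_texture_sd_range)
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 4),
            length(cfg$spacing_mm) == 3, all(cfg$spacing_mm > 0),
            diff(cfg$lesion_volume_range_ml) >= 0,
            cfg$lesion_volume_range_ml[1] >= 0,
            diff(cfg$lesion_intensity_range) >= 0,
            diff(cfg$rim_texture_sd_range) >= 0,
            cfg$irregularity >= 0, cfg$irregularity <= 1)
  # the largest permissible lesion (max volume, worst axis ratio, full
  # perturbation) plus the rim must fit inside the field of view
  vmax <- cfg$lesion_volume_range_ml[2]
  if (vmax > 0) {
    r_mm <- (3 * vmax * 1000 / (4 * pi))^(1 / 3)
    q <- cfg$axis_ratio_range
    worst_ratio <- q[2] / (q[1]^2 * q[2])^(1 / 3)
    need <- r_mm * worst_ratio * (1 + cfg$irregularity) + cfg$edema_rim_width_mm
    fov_half <- min(cfg$grid_shape * cfg$spacing_mm) / 2
    if (need > fov_half)
      stop(sprintf(paste0("lesion cannot fit in grid: requires %.1f mm ",
                          "half-extent but field of view allows %.1f mm"),
                   need, fov_half))
  }
  structure(cfg, class = "phantom_config")
}

#' Outcome label model
#'
#' Logistic model for poor 3-month outcome (mRS > 3) and a lognormal growth
#' model for follow-up volume, both driven by standardized planted
#' covariates: z of log baseline volume, z of surface irregularity, z of rim
#' texture SD. Default coefficients plant a strong, shape-dominant signal;
#' the intercepts are calibrated so the marginal poor-outcome prevalence is
#' ~36.5% and the >3 mL expansion prevalence ~11.3% under the default
#' phantom configuration.
#'
#' @param intercept logit-scale intercept of the poor-outcome model.
#' @param beta coefficients on (z log-volume, z irregularity, z rim texture)
#'   for poor outcome.
#' @param growth_intercept,growth_beta,growth_sdlog lognormal growth-factor
#'   model: `followup = baseline * exp(N(g0 + beta'z, sdlog))`.
#' @param shape_center,shape_scale standardization constants for the
#'   realized 1 - sphericity covariate (calibrated once for the default
#'   phantom configuration).
#' @return A `label_model` list.
#' @export
label_model <- function(intercept = -1.044,
                        beta = c(volume = 2.0, shape = 1.2, texture = 0.8),
                        growth_intercept = -0.369,
                        growth_beta = c(volume = 0.12, shape = 0.15,
                                        texture = 0.12),
                        growth_sdlog = 0.45,
                        shape_center = 0.0349, shape_scale = 0.0152) {
  nm <- c("volume", "shape", "texture")
  beta <- stats::setNames(rep(as.numeric(beta), length.out = 3), nm)
  growth_beta <- stats::setNames(rep(as.numeric(growth_beta),
                                     length.out = 3), nm)
  structure(list(intercept = intercept, beta = beta,
                 growth_intercept = growth_intercept,
                 growth_beta = growth_beta, growth_sdlog = growth_sdlog,
                 shape_center = shape_center, shape_scale = shape_scale),
            class = "label_model")
}

# Standardized planted covariates of a case. The shape covariate is the
# realized 1 - sphericity of the voxelized lesion (the geometric quantity
# the labels depend on), standardized with the model's calibration
# constants; volume and rim texture standardize their exact generative
# distributions.
planted_covariates <- function(baseline_ml, one_minus_sph, rim_sd, cfg,
                               model) {
  zv <- if (baseline_ml > 0)
    (log(baseline_ml) - cfg$volume_meanlog) / cfg$volume_sdlog else 0
  zs <- if (is.finite(one_minus_sph))
    (one_minus_sph - model$shape_center) / model$shape_scale else 0
  r <- cfg$rim_texture_sd_range
  zt <- if (diff(r) > 0) (rim_sd - mean(r)) / (diff(r) / sqrt(12)) else 0
  c(volume = zv, shape = zs, texture = zt)
}

# Low-order directional perturbation basis (real spherical-harmonic-style
# polynomials on the unit sphere), rows = directions, cols = basis terms.
sh_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1,
        x * y * z, x * (x^2 - 3 * y^2), z * (5 * z^2 - 3))
}

# Rasterize one perturbed ellipsoid of the target volume (mL); returns a
# logical array. Assumes the RNG stream is already positioned.
rasterize_lesion <- function(cfg, target_ml, irr) {
  d <- cfg$grid_shape; sp <- cfg$spacing_mm
  if (target_ml <= 0) return(array(FALSE, d))
  r_mm <- (3 * target_ml * 1000 / (4 * pi))^(1 / 3)
  q <- stats::runif(3, cfg$axis_ratio_range[1], cfg$axis_ratio_range[2])
  axes <- r_mm * q / prod(q)^(1 / 3)
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  coef <- stats::rnorm(8)
  ctr <- (d + 1) / 2
  xs <- (seq_len(d[1]) - ctr[1]) * sp[1]
  ys <- (seq_len(d[2]) - ctr[2]) * sp[2]
  zs <- (seq_len(d[3]) - ctr[3]) * sp[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  # ellipsoid-frame coordinates scaled by the semi-axes
  u <- g %*% R %*% diag(1 / axes)
  rho <- sqrt(rowSums(u^2))
  dir <- u / pmax(rho, 1e-9)
  f <- as.vector(sh_basis(dir) %*% coef)
  f <- f / max(abs(f), 1e-9)
  # calibrate the global radius scale so the voxelized volume hits target
  s <- 1
  vox_ml <- prod(sp) / 1000
  inside <- NULL
  for (it in 1:6) {
    inside <- rho <= s * (1 + irr * f)
    got <- sum(inside) * vox_ml
    if (got <= 0) { s <- s * 1.3; next }
    if (abs(got - target_ml) <= 0.25) break
    s <- s * (target_ml / got)^(1 / 3)
  }
  largest_component(array(inside, d))
}

#' Generate one pseudo-CT phantom case
#'
#' @param config a `phantom_config`.
#' @param seed integer; the same (config, seed) pair reproduces the case
#'   bit-identically.
#' @param model a `label_model` driving follow-up growth and mRS.
#' @param case_id identifier string.
#' @return A `synthetic_case`: `image` (`image_volume`), `mask`
#'   (`lesion_mask`), `baseline_volume_ml`, `followup_volume_ml`, `mrs`,
#'   `case_id`, `seed`, and `planted` (all planted parameters).
#' @export
generate_phantom <- function(config, seed, model = label_model(),
                             case_id = sprintf("case_%d", seed)) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    cfg <- config
    d <- cfg$grid_shape; sp <- cfg$spacing_mm
    vr <- cfg$lesion_volume_range_ml
    target <- if (vr[2] <= 0) 0 else if (diff(vr) < 1e-9) vr[2] else {
      v <- Inf
      while (v < max(vr[1], 1e-9) || v > vr[2])
        v <- stats::rlnorm(1, cfg$volume_meanlog, cfg$volume_sdlog)
      v
    }
    irr <- stats::runif(1, 0, cfg$irregularity)
    lesion_int <- stats::runif(1, cfg$lesion_intensity_range[1],
                               cfg$lesion_intensity_range[2])
    rim_sd <- stats::runif(1, cfg$rim_texture_sd_range[1],
                           cfg$rim_texture_sd_range[2])
    mask_arr <- rasterize_lesion(cfg, target, irr)
    baseline_ml <- sum(mask_arr) * prod(sp) / 1000

    img <- array(cfg$background_level + stats::rnorm(prod(d), 0,
                                                     cfg$background_noise_sd), d)
    if (baseline_ml > 0) {
      rim_size <- 2L * as.integer(round(cfg$edema_rim_width_mm / min(sp))) + 1L
      rim <- dilate_array(mask_arr * 1, rim_size) != 0 & !mask_arr
      nr <- sum(rim)
      img[rim] <- cfg$background_level + cfg$rim_contrast +
        stats::rnorm(nr, 0, rim_sd)
      nl <- sum(mask_arr)
      img[mask_arr] <- pmax(lesion_int + stats::rnorm(nl, 0, cfg$lesion_noise_sd),
                            cfg$background_level + 10)
    }

    oms <- if (baseline_ml > 0)
      1 - mask_sphericity(mask_arr, sp) else NA_real_
    z <- planted_covariates(baseline_ml, oms, rim_sd, cfg, model)
    p_poor <- stats::plogis(model$intercept + sum(model$beta * z))
    poor <- stats::runif(1) < p_poor
    mrs <- if (poor) sample(4:6, 1) else sample(0:3, 1)
    growth_mulog <- model$growth_intercept + sum(model$growth_beta * z)
    followup <- if (baseline_ml > 0)
      baseline_ml * exp(stats::rnorm(1, growth_mulog, model$growth_sdlog)) else 0

    structure(list(
      image = image_volume(img, sp),
      mask = lesion_mask(mask_arr, sp),
      baseline_volume_ml = baseline_ml,
      followup_volume_ml = followup,
      mrs = as.integer(mrs),
      case_id = case_id,
      seed = as.integer(seed),
      planted = list(target_volume_ml = target, irregularity = irr,
                     one_minus_sphericity = oms,
                     lesion_intensity = lesion_int, rim_texture_sd = rim_sd,
                     covariates = z, p_poor = p_poor,
                     growth_mulog = growth_mulog,
                     growth_sdlog = model$growth_sdlog)),
      class = "synthetic_case")
  })
}

#' Outcome labels of a synthetic case
#'
#' Poor outcome is mRS > 3; expansion at threshold k mL is
#' `followup - baseline > k` for k in 3, 6, 9 (so the three labels nest).
#'
#' @param case a `synthetic_case` (or any list with `baseline_volume_ml`,
#'   `followup_volume_ml`, `mrs`).
#' @return An `outcome_labels` list with binary `poor_outcome`, `exp3`,
#'   `exp6`, `exp9`.
#' @export
assign_labels <- function(case) {
  stopifnot(case$baseline_volume_ml >= 0, case$followup_volume_ml >= 0,
            case$mrs %in% 0:6)
  d <- case$followup_volume_ml - case$baseline_volume_ml
  structure(list(poor_outcome = as.integer(case$mrs > 3),
                 exp3 = as.integer(d > 3), exp6 = as.integer(d > 6),
                 exp9 = as.integer(d > 9)),
            class = "outcome_labels")
}

#' Generate a phantom cohort
#'
#' Per-case seeds are derived deterministically from the cohort seed, so any
#' subset of the cohort is reproducible in isolation.
#'
#' @param config a `phantom_config`.
#' @param n number of cases (>= 1).
#' @param model a `label_model`.
#' @param seed cohort seed.
#' @return A list of `synthetic_case` objects.
#' @export
generate_cohort <- function(config, n, model = label_model(), seed = 1L) {
  stopifnot(n >= 1)
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i)
    generate_phantom(config, case_seeds[i], model,
                     case_id = sprintf("case_%04d", i)))
}

#' Per-case label probabilities implied by the planted model
#'
#' Closed-form event probabilities for a generated case: the logistic
#' poor-outcome probability and the lognormal tail probability of each
#' expansion threshold. Used to check realized cohort prevalences against
#' the generating model.
#'
#' @param case a `synthetic_case`.
#' @return Named numeric: `poor_outcome`, `exp3`, `exp6`, `exp9`.
#' @export
expected_label_probs <- function(case) {
  b <- case$baseline_volume_ml
  pl <- case$planted
  tail_p <- function(k) {
    if (b <= 0) return(0)
    1 - stats::pnorm((log(1 + k / b) - pl$growth_mulog) / pl$growth_sdlog)
  }
  c(poor_outcome = pl$p_poor, exp3 = tail_p(3), exp6 = tail_p(6),
    exp9 = tail_p(9))
}

#' Cohort manifest as a data frame
#'
#' @param cases list of `synthetic_case` objects.
#' @return data.frame with case_id, volumes, mrs, the four binary labels and
#'   the per-case seed.
#' @export
cohort_manifest <- function(cases) {
  rows <- lapply(cases, function(cs) {
    lb <- assign_labels(cs)
    data.frame(case_id = cs$case_id,
               baseline_volume_ml = cs$baseline_volume_ml,
               followup_volume_ml = cs$followup_volume_ml,
               mrs = cs$mrs, poor_outcome = lb$poor_outcome,
               exp3 = lb$exp3, exp6 = lb$exp6, exp9 = lb$exp9,
               seed = cs$seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk (NIfTI images/masks plus a CSV manifest)
#'
#' @param cases list of `synthetic_case` objects.
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in cases) {
    write_volume(cs$image, file.path(dir, paste0(cs$case_id, "_image.nii.gz")))
    write_volume(cs$mask, file.path(dir, paste0(cs$case_id, "_mask.nii.gz")))
  }
  mf <- cohort_manifest(cases)
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(mf)
}
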