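# Handcrafted radiomics: the 14-feature shape set, first-order intensity
# statistics, GLCM and GLRLM texture families, and filtered (LoG, wavelet)
# variants of the intensity families.

# the 13 unique 3D voxel-pair offsets (26-neighbourhood up to sign)
DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(1, -1, -1))

#' Radiomics configuration
#'
#' @param bin_width intensity bin width for texture discretization, anchored
#'   at the ROI minimum (fixed bin width, not fixed bin count).
#' @param glcm_distance voxel-pair offset distance for the GLCM.
#' @param filters character subset of `c("log", "wavelet")`; filtered
#'   variants recompute the intensity families on transformed images.
#' @param log_sigma_mm Laplacian-of-Gaussian scale(s), mm.
#' @return A `radiomics_config` list.
#' @export
radiomics_config <- function(bin_width = 5, glcm_distance = 1L,
                             filters = c("log", "wavelet"),
                             log_sigma_mm = 3) {
  stopifnot(bin_width > 0, glcm_distance >= 1)
  if (length(filters)) filters <- match.arg(filters, c("log", "wavelet"),
                                            several.ok = TRUE)
  structure(list(bin_width = bin_width,
                 glcm_distance = as.integer(glcm_distance),
                 filters = filters, log_sigma_mm = log_sigma_mm),
            class = "radiomics_config")
}

#' Per-family feature matrix
#'
#' @param matrix numeric cases x features matrix (finite, no missing).
#' @param family one of shape, firstorder, glcm, glrlm, filtered, latent.
#' @param case_ids optional row identifiers.
#' @return A `feature_block`.
#' @export
feature_block <- function(matrix, family, case_ids = rownames(matrix)) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  if (anyDuplicated(colnames(matrix))) stop("feature names must be unique")
  if (!all(is.finite(matrix))) stop("feature values must be finite")
  family <- match.arg(family, c("shape", "firstorder", "glcm", "glrlm",
                                "filtered", "latent", "radiomics"))
  if (family == "shape" && ncol(matrix) != 14)
    stop("shape family must have exactly 14 features")
  if (!is.null(case_ids)) rownames(matrix) <- case_ids
  structure(list(names = colnames(matrix), matrix = matrix, family = family),
            class = "feature_block")
}

# ---- shape ------------------------------------------------------------

# interior = voxels whose 6-neighbours are all inside (grid border counts
# as outside); boundary = mask minus interior
boundary_voxels <- function(arr) {
  d <- dim(arr)
  P <- array(0, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (arr != 0) * 1
  interior <- P > 0
  for (ax in 1:3) {
    sh <- function(o) {
      idx <- pmin(pmax(seq_len(d[ax] + 2L) + o, 1L), d[ax] + 2L)
      switch(ax, P[idx, , ], P[, idx, ], P[, , idx])
    }
    interior <- interior & sh(1L) > 0 & sh(-1L) > 0
  }
  inner <- interior[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  arr != 0 & !array(inner, d)
}

max_pairwise_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  m <- 0
  step <- 512L
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(i0 + step - 1L, n)
    dd <- outer(rowSums(pts[ii, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * pts[ii, , drop = FALSE] %*% t(pts)
    m <- max(m, max(dd))
  }
  sqrt(max(m, 0))
}

#' Shape features of a lesion mask
#'
#' Exactly 14 mesh- and moment-based descriptors: mesh volume, voxel
#' volume, surface area, surface-to-volume ratio, sphericity
#' \eqn{\pi^{1/3}(6V)^{2/3}/A}, maximum 3D diameter, maximum in-plane 2D
#' diameters (axial/coronal/sagittal), major/minor/least axis lengths
#' (4 sqrt of the coordinate-covariance eigenvalues), elongation and
#' flatness.
#'
#' @param mask a nonempty `lesion_mask`.
#' @param spacing_mm voxel spacing; defaults to the mask's.
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing_mm = mask$spacing_mm) {
  arr <- mask$data != 0
  if (!any(arr)) stop("empty ROI: shape features undefined")
  idx <- which(arr, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(arr))
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msh <- mask_mesh(sub, spacing_mm)
  vox_vol <- sum(arr) * prod(spacing_mm)
  A <- msh$area; V <- max(msh$volume, 1e-9)
  sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / A

  bnd <- which(boundary_voxels(sub), arr.ind = TRUE)
  pts <- sweep(bnd, 2, spacing_mm, `*`)
  d3 <- max_pairwise_dist(pts)
  # per-slice maxima: axial = plane normal to axis 3, coronal to axis 2,
  # sagittal to axis 1
  plane_max <- function(normal_ax) {
    keep_ax <- setdiff(1:3, normal_ax)
    mx <- 0
    for (s in unique(bnd[, normal_ax])) {
      p <- pts[bnd[, normal_ax] == s, keep_ax, drop = FALSE]
      mx <- max(mx, max_pairwise_dist(p))
    }
    mx
  }
  coords <- sweep(which(arr, arr.ind = TRUE), 2, spacing_mm, `*`)
  n <- nrow(coords)
  cc <- sweep(coords, 2, colMeans(coords), `-`)
  cv <- crossprod(cc) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  c(MeshVolume = V, VoxelVolume = vox_vol, SurfaceArea = A,
    SurfaceVolumeRatio = A / V, Sphericity = sph,
    Maximum3DDiameter = d3,
    Maximum2DDiameterAxial = plane_max(3),
    Maximum2DDiameterCoronal = plane_max(2),
    Maximum2DDiameterSagittal = plane_max(1),
    MajorAxisLength = 4 * sqrt(ev[1]), MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]), Elongation = elong, Flatness = flat)
}

# ---- first order ------------------------------------------------------

discretize_levels <- function(x, bin_width) {
  as.integer(floor((x - min(x)) / bin_width)) + 1L
}

#' First-order intensity statistics within the ROI
#'
#' @param vol an `image_volume`.
#' @param mask a nonempty `lesion_mask` on the same grid.
#' @param cfg a `radiomics_config` (bin width drives the entropy histogram).
#' @return Named numeric vector of 14 first-order features.
#' @export
firstorder_features <- function(vol, mask, cfg = radiomics_config()) {
  x <- vol$data[mask$data != 0]
  if (!length(x)) stop("empty ROI: first-order features undefined")
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  lv <- discretize_levels(x, cfg$bin_width)
  p <- tabulate(lv) / length(lv)
  p <- p[p > 0]
  qs <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  core <- x[x >= qs[1] & x <= qs[4]]
  c(Mean = mean(x), Median = stats::median(x), Variance = m2,
    Skewness = skew, Kurtosis = kurt, Energy = sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x), Maximum = max(x),
    Range = max(x) - min(x), Percentile10 = qs[1], Percentile90 = qs[4],
    InterquartileRange = qs[3] - qs[2],
    RobustMeanAbsoluteDeviation = mean(abs(core - mean(core))))
}

# ---- GLCM -------------------------------------------------------------

# co-occurrence counts for one offset; symmetric accumulation
glcm_counts <- function(lv, offset, L) {
  d <- dim(lv)
  rng <- function(ax) {
    o <- offset[ax]
    if (o >= 0) list(a = seq_len(d[ax] - o), b = seq_len(d[ax] - o) + o)
    else list(a = seq_len(d[ax] + o) - o, b = seq_len(d[ax] + o))
  }
  r1 <- rng(1); r2 <- rng(2); r3 <- rng(3)
  if (!length(r1$a) || !length(r2$a) || !length(r3$a))
    return(matrix(0, L, L))
  la <- lv[r1$a, r2$a, r3$a]; lb <- lv[r1$b, r2$b, r3$b]
  ok <- la > 0 & lb > 0
  la <- la[ok]; lb <- lb[ok]
  if (!length(la)) return(matrix(0, L, L))
  cnt <- tabulate((la - 1L) * L + lb, L * L) +
    tabulate((lb - 1L) * L + la, L * L)
  matrix(cnt, L, L)
}

glcm_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(L) * px)
  sg2 <- sum((seq_len(L) - mu)^2 * px)
  corr <- if (sg2 > 0)
    sum((i - mu) * (j - mu) * P) / sg2 else 1
  pp <- P[P > 0]
  c(Contrast = sum((i - j)^2 * P), Correlation = corr,
    JointEnergy = sum(P^2), JointEntropy = -sum(pp * log2(pp)),
    InverseDifferenceMoment = sum(P / (1 + (i - j)^2)),
    Dissimilarity = sum(abs(i - j) * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P))
}

#' Gray-level co-occurrence features
#'
#' Symmetric co-occurrence over the 13 unique 3D offsets at the configured
#' distance, each direction normalized separately; features are averaged
#' over directions. A constant region follows the convention contrast 0,
#' correlation 1, entropy 0.
#'
#' @inheritParams firstorder_features
#' @return Named numeric vector of 8 GLCM features.
#' @export
glcm_features <- function(vol, mask, cfg = radiomics_config()) {
  roi <- mask$data != 0
  if (!any(roi)) stop("empty ROI")
  x <- vol$data
  lv <- array(0L, dim(x))
  lv[roi] <- discretize_levels(x[roi], cfg$bin_width)
  L <- max(lv)
  acc <- NULL; nd <- 0
  for (k in seq_len(nrow(DIRS13))) {
    cnt <- glcm_counts(lv, DIRS13[k, ] * cfg$glcm_distance, L)
    tot <- sum(cnt)
    if (tot == 0) next
    st <- glcm_stats(cnt / tot)
    acc <- if (is.null(acc)) st else acc + st
    nd <- nd + 1
  }
  if (nd == 0)   # single isolated voxel: constant-region convention
    return(c(Contrast = 0, Correlation = 1, JointEnergy = 1,
             JointEntropy = 0, InverseDifferenceMoment = 1,
             Dissimilarity = 0, ClusterShade = 0, ClusterProminence = 0))
  acc / nd
}

# ---- GLRLM ------------------------------------------------------------

# run-length table (gray level x run length) along one direction,
# restricted to in-mask voxels; returns a list(counts matrix, n_voxels)
glrlm_runs <- function(lv, dir) {
  d <- dim(lv)
  vox <- which(lv > 0, arr.ind = TRUE)
  if (!nrow(vox)) return(NULL)
  steps <- rep(Inf, nrow(vox))
  for (ax in 1:3) {
    if (dir[ax] == 1) steps <- pmin(steps, vox[, ax] - 1L)
    else if (dir[ax] == -1) steps <- pmin(steps, d[ax] - vox[, ax])
  }
  start <- vox - steps * matrix(dir, nrow(vox), 3, byrow = TRUE)
  key <- (start[, 1] - 1) + d[1] * ((start[, 2] - 1) + d[2] * (start[, 3] - 1))
  lev <- lv[vox]
  o <- order(key, steps)
  key <- key[o]; steps <- steps[o]; lev <- lev[o]
  newrun <- c(TRUE, key[-1] != key[-length(key)] |
                steps[-1] != steps[-length(steps)] + 1 |
                lev[-1] != lev[-length(lev)])
  rid <- cumsum(newrun)
  rlen <- tabulate(rid)
  rlev <- lev[newrun]
  list(level = rlev, length = rlen, n = nrow(vox))
}

glrlm_stats <- function(runs) {
  r <- runs$length
  R <- length(r)
  gl <- tabulate(runs$level)            # runs per gray level
  rl <- tabulate(r)                     # runs per length
  lens <- seq_along(rl)
  c(ShortRunEmphasis = sum(rl / lens^2) / R,
    LongRunEmphasis = sum(rl * lens^2) / R,
    GrayLevelNonUniformity = sum(gl^2) / R,
    RunLengthNonUniformity = sum(rl^2) / R,
    RunPercentage = R / runs$n)
}

#' Gray-level run-length features
#'
#' Runs of equal discretized level along each of the 13 directions,
#' in-mask voxels only; features averaged over directions.
#'
#' @inheritParams firstorder_features
#' @return Named numeric vector of 5 GLRLM features.
#' @export
glrlm_features <- function(vol, mask, cfg = radiomics_config()) {
  roi <- mask$data != 0
  if (!any(roi)) stop("empty ROI")
  lv <- array(0L, dim(vol$data))
  lv[roi] <- discretize_levels(vol$data[roi], cfg$bin_width)
  acc <- NULL
  for (k in seq_len(nrow(DIRS13))) {
    runs <- glrlm_runs(lv, DIRS13[k, ])
    st <- glrlm_stats(runs)
    acc <- if (is.null(acc)) st else acc + st
  }
  acc / nrow(DIRS13)
}

# ---- filtered ---------------------------------------------------------

decimate_mask2 <- function(arr) {
  d <- dim(arr)
  pad <- function(a, ax) {
    n <- dim(a)[ax]
    if (n %% 2L == 0L) return(a)
    idx <- c(seq_len(n), n)
    switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  a <- (arr != 0) * 1
  for (ax in 1:3) a <- pad(a, ax)
  d2 <- dim(a) %/% 2L
  o <- seq(1L, dim(a)[1], 2L); p <- seq(1L, dim(a)[2], 2L)
  q <- seq(1L, dim(a)[3], 2L)
  m <- a[o, p, q, drop = FALSE]
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    m <- pmax(m, a[o + dx, p + dy, q + dz, drop = FALSE])
  array(m != 0, d2)
}

#' Filtered-image features (Laplacian of Gaussian, wavelet)
#'
#' Applies each configured filter to the full image and recomputes the
#' first-order, GLCM and GLRLM families on the filtered ROI. Wavelet
#' subbands are decimated (each dimension halved, rounding up) with a
#' matching any-voxel decimation of the mask. Feature names carry the
#' filter prefix.
#'
#' @inheritParams firstorder_features
#' @return Named numeric vector over all configured filters.
#' @export
filtered_features <- function(vol, mask, cfg = radiomics_config()) {
  if (!length(cfg$filters)) return(numeric(0))
  out <- numeric(0)
  intensity_row <- function(v, m) {
    c(firstorder_features(v, m, cfg), glcm_features(v, m, cfg),
      glrlm_features(v, m, cfg))
  }
  if ("log" %in% cfg$filters) {
    for (sg in cfg$log_sigma_mm) {
      if (sg <= 0) stop("LoG sigma must be positive")
      fi <- log_filter(vol$data, vol$spacing_mm, sg)
      row <- intensity_row(image_volume(fi, vol$spacing_mm), mask)
      names(row) <- paste0(sprintf("log_sigma_%g_", sg), names(row))
      out <- c(out, row)
    }
  }
  if ("wavelet" %in% cfg$filters) {
    sb <- haar_subbands(vol$data)
    m2 <- decimate_mask2(mask$data)
    msk2 <- lesion_mask(m2, vol$spacing_mm * 2)
    for (nm in names(sb)) {
      v2 <- image_volume(array(sb[[nm]], dim(sb[[nm]])), vol$spacing_mm * 2)
      row <- intensity_row(v2, msk2)
      names(row) <- paste0("wavelet_", nm, "_", names(row))
      out <- c(out, row)
    }
  }
  out
}

# ---- per-case and per-cohort assembly ---------------------------------

#' All radiomic features of one case
#'
#' @param vol an `image_volume`.
#' @param mask a nonempty `lesion_mask`.
#' @param cfg a `radiomics_config`.
#' @return Named numeric vector over shape, firstorder, glcm, glrlm and any
#'   configured filtered families, with family prefixes on the names.
#' @export
extract_radiomics <- function(vol, mask, cfg = radiomics_config()) {
  sh <- shape_features(mask)
  fo <- firstorder_features(vol, mask, cfg)
  gc <- glcm_features(vol, mask, cfg)
  gr <- glrlm_features(vol, mask, cfg)
  names(sh) <- paste0("shape_", names(sh))
  names(fo) <- paste0("firstorder_", names(fo))
  names(gc) <- paste0("glcm_", names(gc))
  names(gr) <- paste0("glrlm_", names(gr))
  fl <- filtered_features(vol, mask, cfg)
  if (length(fl)) names(fl) <- paste0("filtered_", names(fl))
  c(sh, fo, gc, gr, fl)
}

#' Radiomics feature blocks for a cohort
#'
#' @param cases list of `synthetic_case` objects (or lists with `image`,
#'   `mask`, `case_id`).
#' @param cfg a `radiomics_config`.
#' @return List of `feature_block`s: `shape` (14 features) and `all`
#'   (every family combined).
#' @export
radiomics_blocks <- function(cases, cfg = radiomics_config()) {
  rows <- lapply(cases, function(cs) extract_radiomics(cs$image, cs$mask, cfg))
  M <- do.call(rbind, rows)
  rownames(M) <- vapply(cases, function(cs) cs$case_id, character(1))
  shape_cols <- grep("^shape_", colnames(M))
  list(shape = feature_block(M[, shape_cols, drop = FALSE], "shape"),
       all = feature_block(M, "radiomics"))
}
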