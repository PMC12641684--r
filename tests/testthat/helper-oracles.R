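# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. These re-derive everything with naive loops
# and must never call the vectorized implementation paths they check.

# rasterized ball mask at given radius (mm) and isotropic spacing
make_ball <- function(r, sp = 1) {
  n <- 2L * ceiling(r / sp) + 5L
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  arr <- array(((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) * sp^2 <= r^2,
               c(n, n, n))
  lesion_mask(arr, rep(sp, 3))
}

# naive co-occurrence counts over all voxel pairs, symmetric
bf_glcm_counts <- function(lv, offset, L) {
  d <- dim(lv)
  cnt <- matrix(0, L, L)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + offset
    if (any(q < 1) || any(q > d)) next
    b <- lv[q[1], q[2], q[3]]
    if (b == 0) next
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  cnt
}

# independent GLCM feature formulas from a normalized matrix
bf_glcm_stats <- function(P) {
  L <- nrow(P)
  con <- dis <- ene <- ent <- hom <- sh <- pro <- 0
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((1:L) * px); my <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mx)^2 * px)); sy <- sqrt(sum(((1:L) - my)^2 * py))
  corr_num <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    if (p > 0) ent <- ent - p * log2(p)
    hom <- hom + p / (1 + (i - j)^2)
    sh <- sh + (i + j - mx - my)^3 * p
    pro <- pro + (i + j - mx - my)^4 * p
    corr_num <- corr_num + (i - mx) * (j - my) * p
  }
  corr <- if (sx > 0 && sy > 0) corr_num / (sx * sy) else 1
  c(Contrast = con, Correlation = corr, JointEnergy = ene,
    JointEntropy = ent, InverseDifferenceMoment = hom, Dissimilarity = dis,
    ClusterShade = sh, ClusterProminence = pro)
}

# naive run extraction along one direction: walk every line voxel by voxel
bf_glrlm <- function(lv, dir) {
  d <- dim(lv)
  runs <- list(level = integer(0), length = integer(0))
  visited <- array(FALSE, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lv[x, y, z] == 0 || visited[x, y, z]) next
    prev <- c(x, y, z) - dir
    started_here <- any(prev < 1) || any(prev > d) ||
      lv[prev[1], prev[2], prev[3]] != lv[x, y, z]
    if (!started_here) next
    len <- 0L
    cur <- c(x, y, z)
    while (all(cur >= 1) && all(cur <= d) &&
           lv[cur[1], cur[2], cur[3]] == lv[x, y, z]) {
      visited[cur[1], cur[2], cur[3]] <- TRUE
      len <- len + 1L
      cur <- cur + dir
    }
    runs$level <- c(runs$level, lv[x, y, z])
    runs$length <- c(runs$length, len)
  }
  runs
}

bf_glrlm_stats <- function(levels, lengths, n_vox) {
  R <- length(lengths)
  sre <- sum(1 / lengths^2) / R
  lre <- sum(lengths^2) / R
  gln <- sum(table(levels)^2) / R
  rln <- sum(table(lengths)^2) / R
  c(ShortRunEmphasis = sre, LongRunEmphasis = lre,
    GrayLevelNonUniformity = gln, RunLengthNonUniformity = rln,
    RunPercentage = R / n_vox)
}

# the 13 offsets, identical ordering to the package constant
offsets13 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(1, -1, -1))
}

# small, fast phantom configuration for unit tests (dots override defaults)
tiny_phantom_cfg <- function(...) {
  args <- list(grid_shape = c(20L, 20L, 20L), spacing_mm = c(3, 3, 3),
               lesion_volume_range_ml = c(2, 10))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}
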