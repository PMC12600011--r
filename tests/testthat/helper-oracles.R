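# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# between-class variance of a 3-class split of histogram `counts`
# (levels 0:(L-1)), computed from first principles
oracle_between_var <- function(counts, t1, t2) {
  L <- length(counts)
  lv <- 0:(L - 1)
  n <- sum(counts)
  mu <- sum(lv * counts) / n
  cls <- list(lv <= t1, lv > t1 & lv <= t2, lv > t2)
  v <- 0
  for (c in cls) {
    w <- sum(counts[c]) / n
    if (w == 0) next
    m <- sum(lv[c] * counts[c]) / sum(counts[c])
    v <- v + w * (m - mu)^2
  }
  v
}

# exhaustive search over all threshold pairs
oracle_two_level_otsu <- function(counts) {
  L <- length(counts)
  best <- -Inf
  bt <- c(NA, NA)
  occ <- which(counts > 0) - 1
  for (t1 in occ[1]:(max(occ) - 2)) {
    for (t2 in (t1 + 1):(max(occ) - 1)) {
      if (sum(counts[(t1 + 2):(t2 + 1)]) == 0) next
      if (sum(counts[(t2 + 2):L]) == 0) next
      v <- oracle_between_var(counts, t1, t2)
      if (v > best + 1e-12) {
        best <- v
        bt <- c(t1, t2)
      }
    }
  }
  bt
}

# min anisotropic distance from points (nm) to a voxel set (indices) given
# per-axis spacing, by direct enumeration
oracle_min_dist <- function(points, voxels, spacing) {
  ctr <- cbind((voxels[, 1] - 0.5) * spacing[1],
               (voxels[, 2] - 0.5) * spacing[2],
               (voxels[, 3] - 0.5) * spacing[3])
  apply(points, 1, function(p)
    sqrt(min(colSums((t(ctr) - p)^2))))
}

# two-sample KS statistic by direct ECDF evaluation
oracle_ks_D <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(vapply(g, function(v) mean(x <= v) - mean(y <= v), 0)))
}

# BH step-up adjustment by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# small geometry used across tests (native 15.5 nm pixels would make even a
# few-micron field heavy; 31 nm keeps fields small but anisotropy intact)
test_geometry <- function(shape = c(200, 200, 60), voxel_xy = 31)
  imaging_geometry(shape, voxel_xy = voxel_xy, voxel_z = 70)

# scene parameters scaled for the small test fields
test_scene_params <- function(...) {
  defaults <- list(density_sAZ_eyeA = 0.02, density_sAZ_eyeB = 0.015,
                   density_mAZ_eyeA = 0.015, density_mAZ_eyeB = 0.01,
                   vesicle_volume_per_az = 0.05, cell_body_count = 1,
                   cell_body_radius = 1.5, background_label_rate = 0.05,
                   noise_sd = 10, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_params, args)
}

# stamp a solid axis-aligned ellipsoid into an array (independent of the
# package renderer)
oracle_sphere_mask <- function(shape, center_nm, radius_nm, spacing) {
  arr <- array(FALSE, shape)
  idx <- which(!arr, arr.ind = TRUE)
  d2 <- ((idx[, 1] - 0.5) * spacing[1] - center_nm[1])^2 +
    ((idx[, 2] - 0.5) * spacing[2] - center_nm[2])^2 +
    ((idx[, 3] - 0.5) * spacing[3] - center_nm[3])^2
  arr[idx[d2 <= radius_nm^2, , drop = FALSE]] <- TRUE
  arr
}
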