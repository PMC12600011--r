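# point-like spatial inputs built directly from a table of centroids
point_inputs <- function(df) {
  spatial_inputs(data.frame(input_id = df$input_id, vglut2_id = df$input_id,
                            eye = df$eye, input_class = df$input_class,
                            cx = df$cx, cy = df$cy, cz = df$cz))
}

test_that("shell neighbor counts respect radii and exclude the center", {
  centers <- point_inputs(data.frame(input_id = 1, eye = "dominant",
                                     input_class = "mAZ",
                                     cx = 0, cy = 0, cz = 0))
  saz <- point_inputs(data.frame(input_id = 2, eye = "dominant",
                                 input_class = "sAZ",
                                 cx = 1200, cy = 0, cz = 0))  # 1.2 um away
  rec <- shell_neighbor_counts(centers, saz, radii_um = c(1, 1.5, 2))
  expect_equal(unlist(rec[1, c("n_r1", "n_r1.5", "n_r2")]),
               c(n_r1 = 0L, n_r1.5 = 1L, n_r2 = 1L))
  # a center that is itself an sAZ never counts itself
  both <- point_inputs(data.frame(input_id = c(1, 2), eye = "dominant",
                                  input_class = "sAZ",
                                  cx = c(0, 1200), cy = 0, cz = 0))
  rec2 <- shell_neighbor_counts(both, both, radii_um = c(1, 1.5, 2))
  expect_equal(rec2$n_r2, c(1L, 1L))
  expect_equal(rec2$n_r1, c(0L, 0L))
})

test_that("neighbor counts are monotone in radius and match brute force", {
  set.seed(11)
  n <- 20
  df <- data.frame(input_id = 1:n,
                   eye = sample(c("dominant", "non_dominant"), n, TRUE),
                   input_class = sample(c("mAZ", "sAZ"), n, TRUE,
                                        prob = c(0.4, 0.6)),
                   cx = runif(n, 0, 8000), cy = runif(n, 0, 8000),
                   cz = runif(n, 0, 3000))
  pts <- point_inputs(df)
  radii <- c(1, 1.5, 2, 3, 4)
  rec <- shell_neighbor_counts(pts, pts, radii_um = radii)
  cols <- paste0("n_r", radii)
  cnt <- as.matrix(rec[, cols])
  expect_true(all(cnt[, -1] - cnt[, -length(radii)] >= 0))
  # brute force: all pairwise centroid distances (point-like surfaces)
  for (i in seq_len(n)) {
    for (r in seq_along(radii)) {
      d <- sqrt((df$cx - df$cx[i])^2 + (df$cy - df$cy[i])^2 +
                  (df$cz - df$cz[i])^2)
      want <- sum(d <= radii[r] * 1000 & df$input_id != df$input_id[i] &
                    df$eye == df$eye[i] & df$input_class == "sAZ")
      expect_equal(unname(cnt[i, r]), want)
    }
  }
})

test_that("surface-based distances match a brute-force voxel oracle", {
  g <- test_geometry(c(220, 220, 50))
  p <- test_scene_params(seed = 41L, cell_body_count = 0,
                         background_label_rate = 0, noise_sd = 0)
  s <- generate_scene(p, g)
  v <- suppressWarnings(normalize_section_histograms(render_volume(s)))
  vg <- detect_clusters(v$channels$vglut2, g, channel_name = "vglut2")
  inp <- data.frame(input_id = vg$table$id, vglut2_id = vg$table$id,
                    eye = "dominant", input_class = "sAZ",
                    cx = vg$table$cx, cy = vg$table$cy, cz = vg$table$cz,
                    flagged_many_az = FALSE)
  sp_obj <- spatial_inputs(inp, vg)
  rec <- shell_neighbor_counts(sp_obj, sp_obj, radii_um = c(1, 2, 4))
  for (i in seq_len(nrow(inp))) {
    d_oracle <- oracle_min_dist(
      as.matrix(inp[-i, c("cx", "cy", "cz")]), vg$voxels[[i]], c(31, 31, 70))
    for (r in c(1, 2, 4))
      expect_equal(rec[[paste0("n_r", r)]][i], sum(d_oracle <= r * 1000))
  }
})

test_that("clustered labeling applies the >= 1 neighbor rule at the cutoff", {
  rec <- data.frame(input_id = 1:3, eye = "dominant", input_class = "mAZ",
                    cx = 0, cy = 0, cz = 0,
                    n_r1 = c(0L, 1L, 0L), n_r1.5 = c(0L, 3L, 1L))
  lab <- label_clustered(rec, 1.5)
  expect_equal(lab$clustered, c(FALSE, TRUE, TRUE))
  expect_equal(lab$n_nearby_saz, c(0L, 3L, 1L))
  expect_error(label_clustered(rec, 2.5), "cutoff")
})

test_that("nearest clustered-mAZ distances match construction", {
  df <- data.frame(input_id = 1:4, eye = "dominant", input_class = "mAZ",
                   cx = c(0, 2000, 9000, 20000), cy = 0, cz = 0)
  pts <- point_inputs(df)
  rec <- cbind(pts$table, n_r1.5 = c(1L, 1L, 0L, 0L))
  rec <- label_clustered(rec, 1.5)
  d <- nearest_clustered_maz_distance(rec, pts)
  # clustered mAZ: inputs 1 and 2 (2 um apart); input 3 is 7 um from #2;
  # input 4 is 18 um from #2
  expect_equal(d$dist_to_clustered_maz_um, c(2, 2, 7, 18))
  # with a single clustered mAZ its own distance is undefined
  rec1 <- cbind(pts$table, n_r1.5 = c(1L, 0L, 0L, 0L))
  rec1 <- label_clustered(rec1, 1.5)
  d1 <- nearest_clustered_maz_distance(rec1, pts)
  expect_true(is.na(d1$dist_to_clustered_maz_um[1]))
  expect_equal(d1$dist_to_clustered_maz_um[-1], c(2, 9, 20))
})

test_that("near/far classification uses the boundary-inclusive 1.5 um rule", {
  maz <- point_inputs(data.frame(input_id = 1, eye = "dominant",
                                 input_class = "mAZ", cx = 0, cy = 0, cz = 0))
  saz <- data.frame(input_id = 2:4, vglut2_id = 2:4,
                    eye = c("dominant", "dominant", "non_dominant"),
                    input_class = "sAZ",
                    az_count = 1L,
                    vesicle_volume_um3 = c(0.2, 0.3, 0.25),
                    volume_per_az = c(0.2, 0.3, 0.25),
                    cx = c(1500, 1600, 500), cy = 0, cz = 0,
                    flagged_many_az = FALSE)
  nf <- near_far_saz(saz, maz, cutoff_um = 1.5)
  # exactly 1.5 um -> near (boundary inclusive); 1.6 um -> far;
  # non-dominant sAZ has no like-eye mAZ -> far
  expect_equal(nf$saz$near_far, c("near", "far", "far"))
})

test_that("the shuffle null preserves counts, is seeded, and is calibrated", {
  set.seed(3)
  # CSR points in a box; centers fixed points away from the border
  g <- imaging_geometry(c(100, 100, 100), voxel_xy = 200, voxel_z = 200)
  mask <- array(TRUE, g$shape)           # 20 x 20 x 20 um
  lam <- 0.05
  vol <- physical_volume_um3(g)
  n_saz <- rpois(1, lam * vol)
  saz <- point_inputs(data.frame(input_id = seq_len(n_saz), eye = "dominant",
                                 input_class = "sAZ",
                                 cx = runif(n_saz, 0, 20000),
                                 cy = runif(n_saz, 0, 20000),
                                 cz = runif(n_saz, 0, 20000)))
  n_c <- 150
  centers <- point_inputs(data.frame(input_id = n_saz + seq_len(n_c),
                                     eye = "dominant", input_class = "mAZ",
                                     cx = runif(n_c, 4000, 16000),
                                     cy = runif(n_c, 4000, 16000),
                                     cz = runif(n_c, 4000, 16000)))
  ens <- shuffle_null(centers, saz, mask, g, radii_um = c(1, 1.5, 2),
                      n_iterations = 120, seed = 17L)
  # identical seed reproduces the ensemble exactly
  ens2 <- shuffle_null(centers, saz, mask, g, radii_um = c(1, 1.5, 2),
                       n_iterations = 120, seed = 17L)
  expect_identical(ens$null_fractions, ens2$null_fractions)
  # Poisson closed form at r = 1.5: P(>=1 neighbor) = 1 - exp(-lam*4/3*pi*1.5^3)
  p_theory <- 1 - exp(-lam * 4 / 3 * pi * 1.5^3)
  i15 <- which(ens$summary$radius_um == 1.5)
  expect_lt(abs(ens$summary$null_mean[i15] - p_theory), 3 * max(ens$summary$null_sd[i15], 0.02))
  # CSR observed data fall inside the central 95% band at every radius
  ok <- ens$summary$observed_clustered_fraction >= ens$summary$null_q025 &
    ens$summary$observed_clustered_fraction <= ens$summary$null_q975
  expect_true(all(ok))
  expect_error(shuffle_null(centers, saz, array(FALSE, g$shape), g,
                            n_iterations = 2, seed = 1), "empty neuropil")
})

test_that("cross-eye analysis shows no clustering for like-eye-only structure", {
  set.seed(6)
  # eye-A structure: sAZ placed near mAZ; eye-B sAZ CSR
  n_m <- 60
  maz <- data.frame(input_id = 1:n_m, eye = "dominant", input_class = "mAZ",
                    cx = runif(n_m, 3000, 17000), cy = runif(n_m, 3000, 17000),
                    cz = runif(n_m, 3000, 17000))
  # like-eye sAZ within 1 um of each mAZ
  u <- matrix(rnorm(3 * n_m), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(n_m, 200, 1000)
  saz_a <- data.frame(input_id = n_m + 1:n_m, eye = "dominant",
                      input_class = "sAZ", cx = maz$cx + u[, 1],
                      cy = maz$cy + u[, 2], cz = maz$cz + u[, 3])
  nb <- 60
  saz_b <- data.frame(input_id = 2 * n_m + 1:nb, eye = "non_dominant",
                      input_class = "sAZ", cx = runif(nb, 0, 20000),
                      cy = runif(nb, 0, 20000), cz = runif(nb, 0, 20000))
  centers <- point_inputs(maz)
  saz <- point_inputs(rbind(saz_a, saz_b))
  g <- imaging_geometry(c(100, 100, 100), voxel_xy = 200, voxel_z = 200)
  mask <- array(TRUE, g$shape)
  like <- shuffle_null(centers, saz, mask, g, radii_um = 1.5,
                       n_iterations = 80, seed = 2L, same_eye = TRUE)
  cross <- shuffle_null(centers, saz, mask, g, radii_um = 1.5,
                        n_iterations = 80, seed = 2L, same_eye = FALSE)
  expect_lt(like$summary$p_empirical, 0.05)   # strong like-eye clustering
  expect_gte(cross$summary$observed_clustered_fraction,
             cross$summary$null_q025)
  expect_lte(cross$summary$observed_clustered_fraction,
             cross$summary$null_q975)
})
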