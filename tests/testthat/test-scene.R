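test_that("empty densities give an empty scene and an all-zero render", {
  g <- test_geometry(c(64, 64, 20))
  p <- test_scene_params(density_sAZ_eyeA = 0, density_sAZ_eyeB = 0,
                         density_mAZ_eyeA = 0, density_mAZ_eyeB = 0,
                         cell_body_count = 0, background_label_rate = 0,
                         noise_sd = 0)
  s <- generate_scene(p, g)
  expect_equal(nrow(s$inputs), 0)
  v <- render_volume(s)
  for (ch in v$channels) expect_true(all(ch == 0))
})

test_that("realized class counts are Poisson draws at the requested density", {
  # lambda = 50 expected mAZ inputs; realized count must fall in the central
  # 99% Poisson interval [27, 76] (qpois bounds at lambda = 50)
  g <- imaging_geometry(c(323, 323, 143), voxel_xy = 31, voxel_z = 70)  # ~1000 um^3
  p <- test_scene_params(density_sAZ_eyeA = 0, density_sAZ_eyeB = 0,
                         density_mAZ_eyeA = 50 / physical_volume_um3(g),
                         density_mAZ_eyeB = 0, cell_body_count = 0,
                         background_label_rate = 0, seed = 7L)
  s <- generate_scene(p, g)
  n <- sum(s$inputs$class == "mAZ")
  expect_gte(n, qpois(0.005, 50))
  expect_lte(n, qpois(0.995, 50))
})

test_that("vesicle volume scales exactly linearly with active-zone count", {
  g <- test_geometry()
  p <- test_scene_params(az_count_pmf = c("2" = 1.0),
                         vesicle_volume_per_az = 0.5,
                         density_mAZ_eyeA = 0.005, density_mAZ_eyeB = 0,
                         density_sAZ_eyeA = 0.005, density_sAZ_eyeB = 0)
  s <- generate_scene(p, g)
  maz <- s$inputs[s$inputs$class == "mAZ", ]
  expect_true(all(maz$az_count == 2))
  expect_true(all(maz$vesicle_volume == 1.0))
  saz <- s$inputs[s$inputs$class == "sAZ", ]
  expect_true(all(saz$vesicle_volume == 0.5))
})

test_that("scene structure invariants hold", {
  g <- test_geometry()
  p <- test_scene_params(seed = 5L)
  s <- generate_scene(p, g)
  # AZ counts per class
  azc <- table(s$azs$input_id)
  for (i in seq_len(nrow(s$inputs))) {
    n_az <- as.integer(azc[as.character(s$inputs$id[i])])
    expect_equal(n_az, s$inputs$az_count[i])
    if (s$inputs$class[i] == "sAZ") expect_equal(n_az, 1L)
    else expect_true(n_az >= 2 && n_az <= 4)
  }
  # each Homer partner sits 50-150 nm from its active zone
  d <- sqrt((s$azs$hx - s$azs$x)^2 + (s$azs$hy - s$azs$y)^2 +
              (s$azs$hz - s$azs$z)^2)
  expect_true(all(d >= 50 & d <= 150))
  # eye-B inputs never carry tracer
  expect_true(all(!s$inputs$ctb[s$inputs$eye == "B"]))
  # every AZ centroid lies close to its cluster surface (within 140 nm)
  for (j in seq_len(nrow(s$azs))) {
    az <- s$azs[j, ]
    inp <- s$inputs[s$inputs$id == az$input_id, ]
    q <- sqrt(((az$x - inp$x) / inp$a)^2 + ((az$y - inp$y) / inp$b)^2 +
                ((az$z - inp$z) / inp$c)^2)
    r_dir <- sqrt((az$x - inp$x)^2 + (az$y - inp$y)^2 + (az$z - inp$z)^2)
    surf_r <- r_dir / q
    expect_lt(abs(r_dir - surf_r), 140)
  }
})

test_that("generation and rendering are deterministic given params and seed", {
  g <- test_geometry(c(120, 120, 40))
  p <- test_scene_params(seed = 9L)
  s1 <- generate_scene(p, g)
  s2 <- generate_scene(p, g)
  expect_identical(s1$inputs, s2$inputs)
  expect_identical(s1$azs, s2$azs)
  v1 <- render_volume(s1)
  v2 <- render_volume(s2)
  expect_identical(v1$channels, v2$channels)
})

test_that("a single input renders one suprathreshold blob of the right volume", {
  g <- test_geometry(c(150, 150, 56))
  p <- test_scene_params(density_sAZ_eyeA = 0, density_sAZ_eyeB = 0,
                         density_mAZ_eyeA = 0, density_mAZ_eyeB = 0,
                         cell_body_count = 0, background_label_rate = 0,
                         noise_sd = 0, seed = 2L)
  s <- generate_scene(p, g)
  # plant one sAZ input at the field center by hand
  ext <- g$shape * c(31, 31, 70)
  r <- (3 * 0.15e9 / (4 * pi))^(1 / 3)
  s$inputs <- data.frame(id = 1L, class = "sAZ", eye = "A", ctb = TRUE,
                         x = ext[1] / 2, y = ext[2] / 2, z = ext[3] / 2,
                         az_count = 1L, vesicle_volume = 0.15,
                         a = r, b = r, c = r)
  set.seed(2)
  s$azs <- azstorm:::place_active_zones(s$inputs)
  v <- render_volume(s)
  for (chn in c("vglut2", "bassoon", "homer1")) {
    lab <- azstorm:::cpp_label3d(array(v$channels[[chn]] > 50, g$shape),
                                 g$shape, 26L)
    expect_equal(max(lab), 1L)
  }
  vox <- sum(v$channels$vglut2 > 50) * voxel_volume_um3(g)
  expect_lt(abs(vox - s$inputs$vesicle_volume[1]) / s$inputs$vesicle_volume[1],
            0.2)
})

test_that("rendered vesicle volumes regress on AZ count with the generator slope", {
  g <- imaging_geometry(c(280, 280, 60), voxel_xy = 78, voxel_z = 70)
  p <- scene_params(density_sAZ_eyeA = 0.01, density_sAZ_eyeB = 0.01,
                    density_mAZ_eyeA = 0.015, density_mAZ_eyeB = 0.015,
                    cell_body_count = 0, background_label_rate = 0,
                    noise_sd = 0, seed = 21L)
  s <- generate_scene(p, g)
  v <- render_volume(s)
  lab <- azstorm:::cpp_label3d(array(v$channels$vglut2 > 50, g$shape),
                               g$shape, 26L)
  vols <- tabulate(lab[lab > 0]) * voxel_volume_um3(g)
  # match rendered components to inputs by nearest centroid
  idx <- which(lab > 0)
  vi <- arrayInd(idx, g$shape)
  sp <- c(78, 78, 70)
  comp_mean <- vapply(1:3, function(a)
    tapply((vi[, a] - 0.5) * sp[a], lab[idx], mean), numeric(max(lab)))
  matched_az <- vapply(seq_len(max(lab)), function(k) {
    d <- sqrt((s$inputs$x - comp_mean[k, 1])^2 +
                (s$inputs$y - comp_mean[k, 2])^2 +
                (s$inputs$z - comp_mean[k, 3])^2)
    s$inputs$az_count[which.min(d)]
  }, 0L)
  fit <- stats::lm(vols ~ matched_az)
  expect_lt(abs(coef(fit)[2] - p$vesicle_volume_per_az) /
              p$vesicle_volume_per_az, 0.1)
})

test_that("scene export writes ground truth tables", {
  g <- test_geometry(c(120, 120, 40))
  s <- generate_scene(test_scene_params(seed = 4L), g)
  dir <- tempfile()
  write_scene(s, dir)
  got <- utils::read.csv(file.path(dir, "ground_truth_inputs.csv"))
  expect_equal(nrow(got), nrow(s$inputs))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})

test_that("impossible densities are rejected as overcrowded", {
  g <- test_geometry(c(100, 100, 40))
  p <- test_scene_params(density_sAZ_eyeA = 5, cell_body_count = 0)
  expect_error(generate_scene(p, g), "overcrowded")
})
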