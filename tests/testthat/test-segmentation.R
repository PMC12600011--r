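test_that("two-level Otsu brackets well-separated intensity groups", {
  set.seed(1)
  x <- sample(c(10, 100, 200), 500, replace = TRUE)
  t <- two_level_otsu(x)
  expect_gte(t[["t_low"]], 10)
  expect_lt(t[["t_low"]], 100)
  expect_gte(t[["t_high"]], 100)
  expect_lt(t[["t_high"]], 200)
})

test_that("two-level Otsu finds tertile thresholds of a uniform histogram", {
  counts <- rep(10, 256)
  t <- two_level_otsu(counts = counts)
  expect_lte(abs(t[["t_low"]] - 85), 3)
  expect_lte(abs(t[["t_high"]] - 170), 3)
})

test_that("two-level Otsu rejects degenerate histograms", {
  expect_error(two_level_otsu(c(rep(0, 50), rep(7, 50))), "degenerate")
  expect_error(two_level_otsu(rep(3, 100)), "degenerate")
})

test_that("two-level Otsu matches exhaustive threshold-pair search", {
  set.seed(42)
  for (i in 1:50) {
    counts <- rpois(64, rexp(64, 1 / 20))
    if (sum(counts > 0) < 3) counts[c(3, 30, 60)] <- counts[c(3, 30, 60)] + 5
    got <- two_level_otsu(counts = counts)
    want <- oracle_two_level_otsu(counts)
    expect_equal(unname(got), as.numeric(want), info = paste("instance", i))
  }
})

test_that("section histogram normalization equalizes section intensity scales", {
  g <- test_geometry(c(60, 60, 2))
  base <- array(0, c(60, 60, 2))
  set.seed(3)
  vals <- sample(0:200, 60 * 60, replace = TRUE)
  base[, , 1] <- vals
  base[, , 2] <- round(vals / 2)         # second section at half intensity
  v <- multichannel_volume(g, list(homer1 = base))
  vn <- normalize_section_histograms(v)
  m1 <- mean(vn$channels$homer1[, , 1])
  m2 <- mean(vn$channels$homer1[, , 2])
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("normalization is an 8-bit rescale for already-matched sections", {
  g <- test_geometry(c(40, 40, 3))
  sec <- matrix(sample(0:100, 1600, replace = TRUE), 40, 40)
  arr <- array(rep(sec, 3), c(40, 40, 3))   # identical histograms
  v <- multichannel_volume(g, list(homer1 = arr))
  vn <- normalize_section_histograms(v)
  expect_equal(vn$channels$homer1, round(arr / max(arr) * 255))
  # single-section volume: same property
  g1 <- test_geometry(c(40, 40, 1))
  v1 <- multichannel_volume(g1, list(homer1 = array(sec, c(40, 40, 1))))
  vn1 <- normalize_section_histograms(v1)
  expect_equal(vn1$channels$homer1, round(array(sec, c(40, 40, 1)) / max(sec) * 255))
})

test_that("constant-zero channels are left unchanged with a warning", {
  g <- test_geometry(c(20, 20, 2))
  v <- multichannel_volume(g, list(ctb = array(0, c(20, 20, 2))))
  expect_warning(vn <- normalize_section_histograms(v), "constant zero")
  expect_equal(vn$channels$ctb, v$channels$ctb)
})

test_that("cell-body mask captures large blobs, spares puncta, robust to threshold", {
  g <- test_geometry(c(160, 160, 57))           # ~5 x 5 x 4 um
  sp <- c(31, 31, 70)
  ch <- array(0, g$shape)
  sphere <- oracle_sphere_mask(g$shape, c(1500, 1500, 2000), 1400, sp)
  ch[sphere] <- 140
  # one synaptic-scale punctum far from the blob
  pv <- oracle_sphere_mask(g$shape, c(4000, 4000, 2000), 120, sp)
  ch[pv] <- 230
  mask <- cell_body_mask(ch, g)
  expect_gte(sum(mask & sphere) / sum(sphere), 0.9)
  expect_equal(sum(mask & pv), 0)
  # robust to an order-of-magnitude sweep of the size threshold
  base_vox <- round(3 / voxel_volume_um3(g))
  for (f in c(0.3, 1, 3)) {
    m2 <- cell_body_mask(ch, g, segmentation_config(
      cellbody_min_voxels = base_vox * f))
    expect_equal(m2, mask)
  }
  # no blob above threshold -> empty mask
  ch2 <- array(0, g$shape)
  ch2[pv] <- 230
  expect_equal(sum(cell_body_mask(ch2, g)), 0)
})

test_that("neuropil mask is the per-plane convex hull minus cell bodies", {
  g <- test_geometry(c(60, 60, 4))
  full <- array(200, g$shape)
  expect_equal(mean(neuropil_mask(full, NULL, g)), 1)
  # CTB only in the left half: right of the outermost positive column excluded
  half <- array(0, g$shape)
  half[1:30, , ] <- 200
  m <- neuropil_mask(half, NULL, g)
  expect_true(all(!m[40:60, , ]))
  expect_gte(mean(m[2:25, 2:59, ]), 0.9)
  # cell-body voxels are subtracted
  cbm <- array(FALSE, g$shape)
  cbm[10:15, 10:15, ] <- TRUE
  m2 <- neuropil_mask(full, cbm, g)
  expect_true(all(!m2[10:15, 10:15, ]))
  expect_error(neuropil_mask(array(0, g$shape), NULL, g), "neuropil")
})

test_that("detect_clusters separates puncta and applies span and edge filters", {
  g <- test_geometry(c(160, 160, 40))
  ch <- array(0, g$shape)
  sp <- c(31, 31, 70)
  p1 <- c(1800, 1800, 1400)
  p2 <- c(3300, 3300, 1400)                    # > 1 um apart
  for (p in list(p1, p2)) ch[oracle_sphere_mask(g$shape, p, 140, sp)] <- 220
  cl <- detect_clusters(ch, g, channel_name = "bassoon")
  expect_equal(nrow(cl$table), 2)
  cen <- cl$table[order(cl$table$cx), c("cx", "cy", "cz")]
  expect_lt(sqrt(sum((unlist(cen[1, ]) - p1)^2)), 50)
  expect_lt(sqrt(sum((unlist(cen[2, ]) - p2)^2)), 50)

  # a punctum confined to one section is dropped
  ch1 <- array(0, g$shape)
  ch1[40:45, 40:45, 20] <- 220
  ch1[oracle_sphere_mask(g$shape, p2, 140, sp)] <- 220  # keeps Otsu sane
  cl1 <- detect_clusters(ch1, g, channel_name = "bassoon")
  expect_equal(nrow(cl1$table), 1)
  expect_gt(min(cl1$table$cx), 2000)

  # a punctum on the x = 0 face is dropped by the edge filter
  ch2 <- array(0, g$shape)
  ch2[oracle_sphere_mask(g$shape, c(16, 1800, 1400), 140, sp)] <- 220
  ch2[oracle_sphere_mask(g$shape, p2, 140, sp)] <- 220
  cl2 <- detect_clusters(ch2, g, channel_name = "bassoon")
  expect_equal(nrow(cl2$table), 1)
  expect_gt(min(cl2$table$cx), 2000)
})

test_that("cluster measurements satisfy the type invariants", {
  g <- test_geometry(c(120, 120, 30))
  p <- test_scene_params(seed = 13L)
  s <- generate_scene(p, g)
  v <- suppressWarnings(normalize_section_histograms(render_volume(s)))
  cl <- detect_clusters(v$channels$bassoon, g, channel_name = "bassoon")
  tab <- cl$table
  expect_true(all(tab$volume_voxels >= 1))
  expect_true(all(tab$signal_density >= 0 & tab$signal_density <= 1))
  expect_equal(tab$volume_um3, tab$volume_voxels * voxel_volume_um3(g))
  expect_true(all(tab$section_span >= 2))
  expect_true(all(!tab$is_edge))
  for (i in seq_len(nrow(tab))) {
    vox <- cl$voxels[[i]]
    lo <- azstorm:::voxel_to_nm(matrix(apply(vox, 2, min), 1), g) - c(31, 31, 70)
    hi <- azstorm:::voxel_to_nm(matrix(apply(vox, 2, max), 1), g) + c(31, 31, 70)
    cen <- unlist(tab[i, c("cx", "cy", "cz")])
    expect_true(all(cen >= lo & cen <= hi))
  }
})

test_that("watershed splits a dumbbell but leaves a convex blob intact", {
  g <- test_geometry(c(100, 100, 40))
  sp <- c(31, 31, 70)
  s1 <- oracle_sphere_mask(g$shape, c(1200, 1550, 1400), 350, sp)
  s2 <- oracle_sphere_mask(g$shape, c(2200, 1550, 1400), 350, sp)
  neck <- array(FALSE, g$shape)
  neck[39:71, 48:52, 19:21] <- TRUE              # thin bridge
  dumb <- s1 | s2 | neck
  vox <- which(dumb, arr.ind = TRUE)
  parts <- split_touching_clusters(vox, g)
  expect_equal(length(parts), 2)
  sizes <- sort(vapply(parts, nrow, 0L))
  expect_lt(abs(sizes[1] - sum(s1)) / sum(s1), 0.2)
  expect_lt(abs(sizes[2] - sum(s2)) / sum(s2), 0.2)
  # partition property: union equals input, pieces disjoint
  all_vox <- do.call(rbind, parts)
  expect_equal(nrow(all_vox), nrow(vox))
  expect_equal(nrow(unique(as.data.frame(all_vox))), nrow(vox))

  blob <- which(s1, arr.ind = TRUE)
  expect_equal(length(split_touching_clusters(blob, g)), 1)
})

test_that("synaptic population selection rejects small dim background labels", {
  # constructed confusion-matrix case: 40 planted synaptic clusters (large,
  # dense) and 25 background labels (small, sparse) on one grid
  g <- test_geometry(c(260, 260, 56))
  sp <- c(31, 31, 70)
  set.seed(31)
  lab <- array(0L, g$shape)
  raw <- array(0, g$shape)
  centers <- expand.grid(x = seq(600, 7400, by = 850),
                         y = seq(600, 7400, by = 850))
  k <- 0L
  truth <- logical(0)
  for (i in 1:40) {                                  # synaptic: r ~ 330 nm
    k <- k + 1L
    m <- oracle_sphere_mask(g$shape, c(centers$x[k], centers$y[k], 2000),
                            330, sp)
    lab[m] <- k
    v <- which(m)
    raw[v] <- 200                                    # dense: all raw-positive
    truth <- c(truth, TRUE)
  }
  for (i in 1:25) {                                  # background: r ~ 120 nm
    k <- k + 1L
    m <- oracle_sphere_mask(g$shape, c(centers$x[k], centers$y[k], 2000),
                            120, sp)
    lab[m] <- k
    v <- which(m)
    raw[v[runif(length(v)) < 0.5]] <- 80             # sparse speckled label
    truth <- c(truth, FALSE)
  }
  cl <- azstorm:::measure_clusters(lab, raw, g, "vglut2")
  sel <- select_synaptic_population(cl)
  expect_equal(sel$mode, "auto")
  kept <- truth[sel$synaptic$table$id]
  rejected <- truth[sel$rejected$table$id]
  expect_gte(sum(kept) / sum(truth), 0.95)           # recall of true synapses
  expect_gte(sum(!rejected) / sum(!truth), 0.9)      # background rejection
})

test_that("population selection falls back gracefully on degenerate input", {
  g <- test_geometry(c(50, 50, 10))
  lab <- array(0L, g$shape)
  for (k in 0:11) lab[(2 + 3 * k):(3 + 3 * k), 5:6, 3:4] <- k + 1L
  raw <- array(0, g$shape)
  raw[lab > 0] <- 100
  cl <- azstorm:::measure_clusters(lab, raw, g, "bassoon")
  expect_warning(sel <- select_synaptic_population(cl), "keeping all")
  expect_equal(nrow(sel$synaptic$table), 12)
  expect_equal(nrow(sel$rejected$table), 0)
})

test_that("population selection is deterministic", {
  g <- test_geometry()
  p <- test_scene_params(seed = 17L)
  s <- generate_scene(p, g)
  v <- suppressWarnings(normalize_section_histograms(render_volume(s)))
  cl <- detect_clusters(v$channels$vglut2, g, channel_name = "vglut2")
  s1 <- suppressWarnings(select_synaptic_population(cl))
  s2 <- suppressWarnings(select_synaptic_population(cl))
  expect_identical(s1$synaptic$table, s2$synaptic$table)
})
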