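#' Segmentation configuration
#'
#' Tunable parameters of the cluster segmentation stage. All length scales are
#' physical (nm) and converted to voxels per axis, so the same configuration
#' applies to any grid anisotropy.
#'
#' @param sigma_cellbody Gaussian smoothing scale (nm) for cell-body detection.
#' @param sigma_cluster Gaussian smoothing scale (nm) for synaptic clusters.
#' @param cellbody_min_voxels components larger than this voxel count (after
#'   cell-body smoothing and lower-Otsu binarization) are treated as cell
#'   bodies; `NULL` derives the count from a 3 um^3 physical volume, far above
#'   the synaptic-cluster scale and below any cell-body fragment. Cell bodies
#'   are orders of magnitude larger than synaptic clusters, so the filter is
#'   robust to a wide range of values.
#' @param min_section_span clusters must span at least this many physical
#'   sections.
#' @param watershed_enabled apply watershed splitting to oversized components.
#' @param watershed_marker_sep_nm minimum physical separation of watershed
#'   markers.
#' @param watershed_max_volume_um3 components above this volume are split; if
#'   `NULL`, the trigger is the 99th percentile of component volumes.
#' @param conv_sigma_nm smoothing scale used to derive a conventional-image
#'   counterpart from a rendered channel when none is supplied.
#' @param population_mode `"auto"` (two-component gate in log-volume x
#'   signal-density space) or `"manual"` (polygon gate).
#' @param population_polygon for manual mode: two-column matrix of polygon
#'   vertices in (log10 volume um^3, signal density).
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(sigma_cellbody = 140,
                                sigma_cluster = 77.5,
                                cellbody_min_voxels = NULL,
                                min_section_span = 2L,
                                watershed_enabled = TRUE,
                                watershed_marker_sep_nm = 200,
                                watershed_max_volume_um3 = NULL,
                                conv_sigma_nm = 300,
                                population_mode = c("auto", "manual"),
                                population_polygon = NULL) {
  stopifnot(sigma_cellbody > 0, sigma_cluster > 0, min_section_span >= 1)
  structure(list(sigma_cellbody = sigma_cellbody,
                 sigma_cluster = sigma_cluster,
                 cellbody_min_voxels = cellbody_min_voxels,
                 min_section_span = as.integer(min_section_span),
                 watershed_enabled = watershed_enabled,
                 watershed_marker_sep_nm = watershed_marker_sep_nm,
                 watershed_max_volume_um3 = watershed_max_volume_um3,
                 conv_sigma_nm = conv_sigma_nm,
                 population_mode = match.arg(population_mode),
                 population_polygon = population_polygon),
            class = "segmentation_config")
}

# physical sigma (nm) -> per-axis voxel sigma
sigma_vox <- function(sigma_nm, geometry) sigma_nm / geom_spacing(geometry)

blur_nm <- function(arr, sigma_nm, geometry) {
  cpp_blur3d(arr, dim(arr), sigma_vox(sigma_nm, geometry))
}

quantize_levels <- function(arr, bit_depth = 8L) {
  maxi <- 2^bit_depth - 1
  as.integer(pmin(pmax(round(arr), 0), maxi))
}

#' Normalize per-section intensity histograms
#'
#' Corrects the residual per-section intensity variance of a serial-section
#' stack: each section's intensity histogram is remapped (quantile matching)
#' to the average histogram of all sections, after which the channel is
#' rescaled to use the full bit range.
#'
#' @param volume an [multichannel_volume()].
#' @return the volume with normalized channels; a constant-zero channel is
#'   returned unchanged with a warning.
#' @export
normalize_section_histograms <- function(volume) {
  stopifnot(inherits(volume, "mc_volume"))
  g <- volume$geometry
  maxi <- 2^g$bit_depth - 1
  nz <- g$shape[3]
  for (nm in names(volume$channels)) {
    ch <- volume$channels[[nm]]
    if (max(ch) <= 0) {
      warning("channel '", nm, "' is constant zero; left unchanged")
      next
    }
    # zero = "no signal rendered" and is preserved; positive levels of each
    # section are quantile-matched to the average positive histogram
    counts <- matrix(0, maxi, nz)
    for (z in seq_len(nz)) {
      sec <- as.integer(ch[, , z])
      counts[, z] <- tabulate(sec[sec > 0L], maxi)
    }
    avg_cdf <- cumsum(rowMeans(counts))
    if (avg_cdf[maxi] == 0) next
    avg_cdf <- avg_cdf / avg_cdf[maxi]
    for (z in seq_len(nz)) {
      cdf <- cumsum(counts[, z])
      if (cdf[maxi] == 0) next
      cdf <- cdf / cdf[maxi]
      # smallest positive level of the average histogram with cumulative
      # mass >= this section's
      map <- findInterval(cdf, avg_cdf, left.open = TRUE) + 1L
      map <- pmin(map, maxi)
      sec <- as.integer(ch[, , z])
      pos <- sec > 0L
      sec[pos] <- map[sec[pos]]
      ch[, , z] <- sec
    }
    volume$channels[[nm]] <- round(ch / max(ch) * maxi)
  }
  volume
}

#' Two-level Otsu thresholds
#'
#' Exhaustively maximizes the between-class variance of a three-class
#' partition of an intensity histogram, returning the two inclusive upper
#' thresholds `(t_low, t_high)` of the lower classes: binarizing at the lower
#' threshold keeps intensities `> t_low`, at the higher keeps `> t_high`.
#'
#' @param x numeric vector or array of intensities; binned into 256 levels
#'   over `[0, max(x)]` (exact integer levels for 8-bit data), or `NULL` if
#'   `counts` is given.
#' @param counts optional histogram: counts of levels `0:(length(counts)-1)`.
#' @param bit_depth number of histogram levels is `2^bit_depth`.
#' @return named numeric vector `c(t_low, t_high)`, `t_low < t_high`, in
#'   intensity units.
#' @export
two_level_otsu <- function(x = NULL, counts = NULL, bit_depth = 8L) {
  binw <- 1
  if (is.null(counts)) {
    stopifnot(!is.null(x))
    nlev <- 2^bit_depth
    mx <- max(x)
    if (mx <= 0) stop("degenerate histogram")
    binw <- mx / (nlev - 1)
    lv <- pmin(pmax(as.integer(round(x / binw)), 0L), nlev - 1L)
    counts <- tabulate(lv + 1L, nlev)
  }
  L <- length(counts)
  occupied <- which(counts > 0) - 1L
  if (length(occupied) < 3) stop("degenerate histogram")
  w <- cumsum(counts)
  s <- cumsum(counts * (0:(L - 1)))
  # between-class variance ~ sum_k S_k^2 / W_k (total mean fixed)
  best <- -Inf
  bt <- c(NA, NA)
  lo_min <- occupied[1]
  hi_max <- occupied[length(occupied)]
  for (t1 in lo_min:(hi_max - 2L)) {
    w1 <- w[t1 + 1]; s1 <- s[t1 + 1]
    if (w1 == 0) next
    v1 <- s1^2 / w1
    for (t2 in (t1 + 1L):(hi_max - 1L)) {
      w2 <- w[t2 + 1] - w1
      if (w2 == 0) next
      w3 <- w[L] - w[t2 + 1]
      if (w3 == 0) next
      s2 <- s[t2 + 1] - s1
      s3 <- s[L] - s[t2 + 1]
      v <- v1 + s2^2 / w2 + s3^2 / w3
      if (v > best + 1e-12) {
        best <- v
        bt <- c(t1, t2)
      }
    }
  }
  if (any(is.na(bt))) stop("degenerate histogram")
  c(t_low = bt[1] * binw, t_high = bt[2] * binw)
}

#' Cell-body mask
#'
#' Cell bodies pick up non-specific label in the Homer1 (and Bassoon)
#' channels and must be excluded before synaptic segmentation. The Homer1
#' channel is smoothed at `sigma_cellbody`, binarized at the lower two-level
#' Otsu threshold, and 3D connected components larger than
#' `cellbody_min_voxels` become the mask.
#'
#' @param channel Homer1 intensity array.
#' @param geometry an [imaging_geometry()].
#' @param config a [segmentation_config()].
#' @return logical array; `TRUE` marks cell-body voxels. An empty mask is
#'   valid.
#' @export
cell_body_mask <- function(channel, geometry, config = segmentation_config()) {
  sm <- blur_nm(channel, config$sigma_cellbody, geometry)
  thr <- tryCatch(two_level_otsu(sm, bit_depth = geometry$bit_depth),
                  error = function(e) NULL)
  if (is.null(thr)) return(array(FALSE, dim(channel)))
  min_vox <- config$cellbody_min_voxels
  if (is.null(min_vox)) min_vox <- round(3 / voxel_volume_um3(geometry))
  bin <- array(sm > thr["t_low"], dim(channel))
  lab <- cpp_label3d(bin, dim(channel), 26L)
  sz <- tabulate(lab[lab > 0L])
  keep <- which(sz > min_vox)
  mask <- array(FALSE, dim(channel))
  if (length(keep)) mask[lab %in% keep] <- TRUE
  mask
}

#' Neuropil mask
#'
#' The analysis region: per z-plane convex hull of thresholded CTB-positive
#' voxels (the anterograde tracer fills the labeled projection's neuropil),
#' minus detected cell bodies. Input densities and the shuffle null are
#' restricted to this region.
#'
#' @param ctb_channel CTB intensity array (a conventional-image counterpart is
#'   derived internally by smoothing).
#' @param cell_bodies logical cell-body mask, or `NULL`.
#' @param geometry an [imaging_geometry()].
#' @param config a [segmentation_config()].
#' @return logical array.
#' @export
neuropil_mask <- function(ctb_channel, cell_bodies = NULL, geometry,
                          config = segmentation_config()) {
  conv <- blur_nm(ctb_channel, config$conv_sigma_nm, geometry)
  thr <- tryCatch(two_level_otsu(conv, bit_depth = geometry$bit_depth),
                  error = function(e) {
                    if (max(conv) > 0) c(t_low = 0) else NULL
                  })
  if (is.null(thr)) stop("cannot define neuropil")
  pos <- conv > thr[["t_low"]]
  if (!any(pos)) stop("cannot define neuropil")
  dm <- dim(ctb_channel)
  mask <- array(FALSE, dm)
  for (z in seq_len(dm[3])) {
    idx <- which(pos[, , z], arr.ind = TRUE)
    if (nrow(idx) == 0) next
    if (nrow(idx) <= 2 || length(unique(idx[, 1])) == 1 ||
        length(unique(idx[, 2])) == 1) {
      mask[cbind(idx, z)] <- TRUE
      next
    }
    hull <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
    mask[, , z] <- fill_convex_polygon(hull, dm[1], dm[2])
  }
  if (!is.null(cell_bodies)) mask <- mask & !cell_bodies
  mask
}

# scanline fill of a convex polygon given by hull vertices (voxel coords)
fill_convex_polygon <- function(hull, nx, ny) {
  out <- matrix(FALSE, nx, ny)
  nv <- nrow(hull)
  ys <- hull[, 2]
  for (y in max(1, floor(min(ys))):min(ny, ceiling(max(ys)))) {
    xs <- numeric(0)
    for (e in seq_len(nv)) {
      p1 <- hull[e, ]
      p2 <- hull[if (e == nv) 1 else e + 1, ]
      y1 <- p1[2]; y2 <- p2[2]
      if ((y1 <= y && y2 >= y) || (y2 <= y && y1 >= y)) {
        if (y1 == y2) xs <- c(xs, p1[1], p2[1])
        else xs <- c(xs, p1[1] + (y - y1) / (y2 - y1) * (p2[1] - p1[1]))
      }
    }
    if (length(xs) >= 1) {
      x0 <- max(1, ceiling(min(xs) - 1e-9))
      x1 <- min(nx, floor(max(xs) + 1e-9))
      if (x0 <= x1) out[x0:x1, y] <- TRUE
    }
  }
  out
}

# ---- cluster measurement ----------------------------------------------------

# Build the labeled-cluster object from a label array and the raw channel.
measure_clusters <- function(labels, raw, geometry, channel) {
  dm <- dim(labels)
  fg <- which(labels > 0L)
  empty <- list(
    table = data.frame(id = integer(0), channel = character(0),
                       volume_voxels = integer(0), volume_um3 = numeric(0),
                       total_intensity = numeric(0), signal_density = numeric(0),
                       cx = numeric(0), cy = numeric(0), cz = numeric(0),
                       section_span = integer(0), is_edge = logical(0)),
    voxels = list(), geometry = geometry, channel = channel)
  class(empty) <- "az_clusters"
  if (length(fg) == 0) return(empty)
  lab_fg <- labels[fg]
  ord <- order(lab_fg)
  fg <- fg[ord]
  lab_fg <- lab_fg[ord]
  vox_all <- arrayInd(fg, dm)
  raw_fg <- raw[fg]
  grp <- factor(lab_fg)
  vox_list <- split.data.frame(vox_all, grp)
  int_list <- split(raw_fg, grp)
  sp <- geom_spacing(geometry)
  vv <- voxel_volume_um3(geometry)
  n <- length(vox_list)
  tab <- data.frame(id = seq_len(n), channel = channel,
                    volume_voxels = vapply(vox_list, nrow, 0L),
                    volume_um3 = NA_real_, total_intensity = NA_real_,
                    signal_density = NA_real_, cx = NA_real_, cy = NA_real_,
                    cz = NA_real_, section_span = NA_integer_,
                    is_edge = NA)
  tab$volume_um3 <- tab$volume_voxels * vv
  for (i in seq_len(n)) {
    v <- as.matrix(vox_list[[i]])
    w <- int_list[[i]]
    tab$total_intensity[i] <- sum(w)
    tab$signal_density[i] <- mean(w > 0)
    coords <- voxel_to_nm(v, geometry)
    wt <- if (sum(w) > 0) w / sum(w) else rep(1 / nrow(v), nrow(v))
    tab$cx[i] <- sum(coords[, 1] * wt)
    tab$cy[i] <- sum(coords[, 2] * wt)
    tab$cz[i] <- sum(coords[, 3] * wt)
    tab$section_span[i] <- length(unique(v[, 3]))
    tab$is_edge[i] <- any(v[, 1] == 1L | v[, 1] == dm[1] |
                            v[, 2] == 1L | v[, 2] == dm[2] |
                            v[, 3] == 1L | v[, 3] == dm[3])
  }
  vox_list <- lapply(vox_list, function(v) {
    m <- as.matrix(v)
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  })
  names(vox_list) <- NULL
  rownames(tab) <- NULL
  structure(list(table = tab, voxels = vox_list, geometry = geometry,
                 channel = channel),
            class = "az_clusters")
}

#' @export
print.az_clusters <- function(x, ...) {
  cat(sprintf("%d labeled clusters in channel '%s'\n", nrow(x$table), x$channel))
  invisible(x)
}

# subset an az_clusters object; original cluster ids are preserved so that
# downstream references (pair tables, associations) stay valid
clusters_subset <- function(cl, idx) {
  cl$table <- cl$table[idx, , drop = FALSE]
  cl$voxels <- cl$voxels[idx]
  rownames(cl$table) <- NULL
  cl
}

#' Split an improperly connected cluster by watershed
#'
#' Marker-controlled watershed on the anisotropic distance transform of the
#' cluster's binary mask. Markers are distance-transform maxima at least
#' `marker_sep_nm` apart; fragments separated only by a shallow boundary
#' (boundary depth close to the smaller fragment's peak depth) are merged
#' back, so convex clusters survive unsplit while dumbbell-shaped fusions are
#' divided at the neck.
#'
#' @param voxels integer matrix (n x 3) of the cluster's voxel coordinates.
#' @param geometry an [imaging_geometry()].
#' @param marker_sep_nm minimum marker separation (nm).
#' @param merge_ratio fragments are merged when the watershed-line depth
#'   exceeds this fraction of the shallower fragment's peak depth.
#' @return list of voxel matrices partitioning the input voxel set.
#' @export
split_touching_clusters <- function(voxels, geometry, marker_sep_nm = 200,
                                    merge_ratio = 0.6) {
  stopifnot(is.matrix(voxels), ncol(voxels) == 3)
  lo <- apply(voxels, 2, min) - 1L
  dmc <- apply(voxels, 2, max) - lo + 1L
  rel <- sweep(voxels, 2, lo)
  mask <- array(FALSE, dmc)
  mask[rel] <- TRUE
  sp <- geom_spacing(geometry)
  lab <- cpp_watershed_split(mask, dmc, sp, marker_sep_nm)
  k <- max(lab)
  if (k <= 1) return(list(voxels))
  # merge fragments across shallow watershed lines
  dist <- cpp_edt3d(array(!mask, dmc), dmc, sp)
  peak <- vapply(seq_len(k), function(l) max(dist[lab == l]), 0)
  sal <- matrix(0, k, k)
  idx <- which(mask)
  coords <- arrayInd(idx, dmc)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (o in seq_len(3)) {
    nb <- sweep(coords, 2, offs[o, ], "+")
    ok <- nb[, o] <= dmc[o]
    a <- idx[ok]
    b <- nb[ok, 1] + dmc[1] * (nb[ok, 2] - 1) + dmc[1] * dmc[2] * (nb[ok, 3] - 1)
    inb <- mask[b]
    a <- a[inb]; b <- b[inb]
    la <- lab[a]; lb <- lab[b]
    diffp <- which(la != lb)
    for (i in diffp) {
      s <- min(dist[a[i]], dist[b[i]])
      l1 <- min(la[i], lb[i]); l2 <- max(la[i], lb[i])
      if (s > sal[l1, l2]) sal[l1, l2] <- s
    }
  }
  # iterative saddle-dynamics merging: repeatedly absorb the pair whose
  # shared boundary is deepest relative to the shallower region's peak,
  # updating peaks and saliencies on union. Shallow saddle fragments (e.g.
  # spurious neck maxima) are absorbed into their basin without bridging two
  # genuine attractors across a shallow neck.
  sal <- pmax(sal, t(sal))
  group <- seq_len(k)
  active <- rep(TRUE, k)
  repeat {
    act <- which(active)
    bi <- 0L; bj <- 0L; bs <- -Inf
    for (a in act) for (b in act[act > a]) {
      if (sal[a, b] > merge_ratio * min(peak[a], peak[b]) &&
          sal[a, b] > bs) {
        bs <- sal[a, b]; bi <- a; bj <- b
      }
    }
    if (bi == 0L) break
    group[group == bj] <- bi
    peak[bi] <- max(peak[bi], peak[bj])
    sal[bi, ] <- pmax(sal[bi, ], sal[bj, ])
    sal[, bi] <- pmax(sal[, bi], sal[, bj])
    sal[bi, bi] <- 0
    active[bj] <- FALSE
  }
  lab_m <- group[lab[idx]]
  parts <- split(seq_along(idx), lab_m)
  lapply(parts, function(p) {
    m <- coords[p, , drop = FALSE]
    m <- sweep(m, 2, lo, "+")
    storage.mode(m) <- "integer"
    m
  })
}

#' Detect labeled clusters in one channel
#'
#' The per-channel segmentation pipeline: (1) exclude cell-body voxels;
#' (2) zero voxels outside the conventional-image lower-Otsu foreground mask;
#' (3) smooth at `sigma_cluster` and binarize at the higher two-level Otsu
#' threshold; (4) 3D connected components; (5) watershed-split oversized
#' components; (6) drop clusters spanning fewer than `min_section_span`
#' physical sections; (7) drop clusters touching the volume border. Cluster
#' measurements (volume, total intensity, signal density, weighted centroid)
#' are taken on the raw pre-smoothing intensities.
#'
#' @param channel normalized intensity array.
#' @param geometry an [imaging_geometry()].
#' @param config a [segmentation_config()].
#' @param exclusion_mask logical cell-body mask, or `NULL`.
#' @param conventional conventional-image counterpart of the channel; derived
#'   by smoothing at `conv_sigma_nm` when `NULL`.
#' @param channel_name stored in the output table.
#' @return an `az_clusters` object (possibly empty). The applied thresholds
#'   are attached as attribute `"thresholds"`.
#' @export
detect_clusters <- function(channel, geometry, config = segmentation_config(),
                            exclusion_mask = NULL, conventional = NULL,
                            channel_name = "channel") {
  work <- channel
  if (!is.null(exclusion_mask)) work[exclusion_mask] <- 0
  if (is.null(conventional)) conventional <- blur_nm(work, config$conv_sigma_nm,
                                                     geometry)
  thr_conv <- tryCatch(two_level_otsu(conventional, bit_depth = geometry$bit_depth),
                       error = function(e) NULL)
  if (is.null(thr_conv))
    return(measure_clusters(array(0L, dim(channel)), work, geometry,
                            channel_name))
  work[conventional <= thr_conv[["t_low"]]] <- 0
  sm <- blur_nm(work, config$sigma_cluster, geometry)
  thr <- tryCatch(two_level_otsu(sm, bit_depth = geometry$bit_depth),
                  error = function(e) NULL)
  if (is.null(thr))
    return(measure_clusters(array(0L, dim(channel)), work, geometry,
                            channel_name))
  bin <- array(sm > thr[["t_high"]], dim(channel))
  lab <- cpp_label3d(bin, dim(channel), 26L)

  cl <- measure_clusters(lab, work, geometry, channel_name)
  if (nrow(cl$table) == 0) return(cl)

  if (config$watershed_enabled && nrow(cl$table) >= 2) {
    trigger <- if (!is.null(config$watershed_max_volume_um3))
      config$watershed_max_volume_um3
    else stats::quantile(cl$table$volume_um3, 0.99, names = FALSE)
    big <- which(cl$table$volume_um3 > trigger)
    if (length(big)) {
      keep_vox <- cl$voxels[setdiff(seq_along(cl$voxels), big)]
      for (i in big) {
        parts <- split_touching_clusters(cl$voxels[[i]], geometry,
                                         config$watershed_marker_sep_nm)
        keep_vox <- c(keep_vox, parts)
      }
      lab2 <- array(0L, dim(channel))
      for (i in seq_along(keep_vox)) lab2[keep_vox[[i]]] <- i
      cl <- measure_clusters(lab2, work, geometry, channel_name)
    }
  }

  keep <- cl$table$section_span >= config$min_section_span & !cl$table$is_edge
  out <- clusters_subset(cl, which(keep))
  attr(out, "thresholds") <- c(conv_low = thr_conv[["t_low"]],
                               otsu_low = thr[["t_low"]],
                               otsu_high = thr[["t_high"]])
  out
}

#' Separate synaptic clusters from non-specific labeling
#'
#' True synaptic structures form a population of larger, denser clusters in
#' (log volume, signal density) space; sparse non-specific labels are small
#' and dim. In auto mode a two-component Gaussian mixture is fit and the
#' component with the greater mean on both axes is kept; when the components
#' do not separate on both axes, all clusters are kept with a warning. Manual
#' mode applies a config-supplied polygon gate.
#'
#' @param clusters an `az_clusters` object with at least 2 clusters.
#' @param config a [segmentation_config()].
#' @return list with elements `synaptic` and `rejected` (both `az_clusters`),
#'   `mode`, and `component_means` (auto mode).
#' @export
select_synaptic_population <- function(clusters,
                                       config = segmentation_config()) {
  tab <- clusters$table
  stopifnot(nrow(tab) >= 2)
  feat <- cbind(log10(tab$volume_um3), tab$signal_density)
  if (config$population_mode == "manual") {
    if (is.null(config$population_polygon))
      stop("manual population selection requires a polygon")
    inside <- point_in_polygon(feat, config$population_polygon)
    return(list(synaptic = clusters_subset(clusters, which(inside)),
                rejected = clusters_subset(clusters, which(!inside)),
                mode = "manual", component_means = NULL))
  }
  fallback <- function(msg) {
    warning(msg)
    list(synaptic = clusters, rejected = clusters_subset(clusters, integer(0)),
         mode = "auto-fallback", component_means = NULL)
  }
  if (nrow(tab) < 10)
    return(fallback("too few clusters for a population fit; keeping all"))
  fit <- tryCatch(
    suppressWarnings(Mclust(feat, G = 2, verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters))
    return(fallback("population components not separable; keeping all clusters"))
  mu <- fit$parameters$mean  # 2 x G
  hi <- which(mu[1, ] == max(mu[1, ]))[1]
  lo <- 3 - hi
  # separable means distinctly greater on BOTH axes: a gap in log10 volume
  # and in signal density; otherwise the split reflects within-population
  # structure (e.g. active-zone number), not background labeling
  if (!(mu[1, hi] - mu[1, lo] >= 0.3 && mu[2, hi] - mu[2, lo] >= 0.08))
    return(fallback("population components not separable on both axes; keeping all clusters"))
  keep <- fit$classification == hi
  list(synaptic = clusters_subset(clusters, which(keep)),
       rejected = clusters_subset(clusters, which(!keep)),
       mode = "auto", component_means = mu)
}

# even-odd point-in-polygon test
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
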