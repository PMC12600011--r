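#' Spatial representation of classified inputs
#'
#' Bundles, for each input, its weighted centroid and the physical
#' coordinates of its VGluT2 cluster surface, the geometry every distance in
#' the clustering analysis is measured against: distances from a center input
#' are taken from its cluster surface (expansion shell), membership of a
#' neighbor by its weighted centroid.
#'
#' @param inputs table from [classify_inputs()].
#' @param vglut2 the VGluT2 `az_clusters` the inputs were built from, or
#'   `NULL` to treat every input as point-like (surface = centroid), as in
#'   shuffled-null point processes.
#' @return list of class `spatial_inputs`: `table` (id, eye, class, centroid
#'   nm) and `surfaces` (list of n x 3 nm matrices).
#' @export
spatial_inputs <- function(inputs, vglut2 = NULL) {
  tab <- data.frame(input_id = inputs$input_id, eye = inputs$eye,
                    input_class = inputs$input_class,
                    cx = inputs$cx, cy = inputs$cy, cz = inputs$cz)
  surfaces <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (is.null(vglut2)) {
      surfaces[[i]] <- matrix(c(tab$cx[i], tab$cy[i], tab$cz[i]), 1, 3)
    } else {
      j <- match(inputs$vglut2_id[i], vglut2$table$id)
      surfaces[[i]] <- voxel_to_nm(boundary_voxels(vglut2$voxels[[j]],
                                                   vglut2$geometry),
                                   vglut2$geometry)
    }
  }
  structure(list(table = tab, surfaces = surfaces), class = "spatial_inputs")
}

# counts of points within each radius (nm) of each selected center's surface
center_counts <- function(centers, center_idx, points, radii_nm,
                          exclude_point_idx = NULL) {
  k <- length(center_idx)
  nr <- length(radii_nm)
  if (k == 0) return(matrix(0L, 0, nr))
  if (is.null(points) || nrow(points) == 0) return(matrix(0L, k, nr))
  surf <- centers$surfaces[center_idx]
  lens <- vapply(surf, nrow, 0L)
  cat_surf <- do.call(rbind, surf)
  starts <- c(0L, cumsum(lens))[seq_len(k)]
  bounds <- t(vapply(seq_len(k), function(i) {
    s <- surf[[i]]
    ctr <- c(centers$table$cx[center_idx[i]], centers$table$cy[center_idx[i]],
             centers$table$cz[center_idx[i]])
    c(ctr, sqrt(max(colSums((t(s) - ctr)^2))))
  }, numeric(4)))
  if (is.null(exclude_point_idx)) exclude_point_idx <- rep(0L, k)
  cpp_count_within(points, cat_surf, as.integer(starts), as.integer(lens),
                   bounds, radii_nm, as.integer(exclude_point_idx))
}

#' Neighbor counts in expansion shells
#'
#' For each center input and each search radius, counts the sAZ synapses of
#' the requested eye whose VGluT2 weighted centroid lies within the radius of
#' the center's cluster surface (anisotropic physical distance), excluding
#' the center itself.
#'
#' @param centers a [spatial_inputs()] object (centers may be mAZ or sAZ).
#' @param saz a [spatial_inputs()] object restricted to sAZ synapses.
#' @param radii_um increasing search radii in micrometers.
#' @param same_eye count like-eye (`TRUE`) or opposite-eye (`FALSE`)
#'   neighbors.
#' @return data.frame with the center table plus one `n_r<radius>` column per
#'   radius; radii recorded in attribute `radii_um`.
#' @export
shell_neighbor_counts <- function(centers, saz, radii_um = c(1, 1.5, 2, 3, 4),
                                  same_eye = TRUE) {
  stopifnot(!is.unsorted(radii_um))
  radii_nm <- radii_um * 1e3
  rec <- centers$table
  cnt <- matrix(0L, nrow(rec), length(radii_um))
  for (eye in unique(rec$eye)) {
    target_eye <- if (same_eye) eye else setdiff(unique(saz$table$eye), eye)
    cidx <- which(rec$eye == eye)
    pidx <- which(saz$table$eye %in% target_eye &
                    saz$table$input_class == "sAZ")
    pts <- as.matrix(saz$table[pidx, c("cx", "cy", "cz")])
    excl <- match(rec$input_id[cidx], saz$table$input_id[pidx])
    excl[is.na(excl)] <- 0L
    cnt[cidx, ] <- center_counts(centers, cidx, pts, radii_nm, excl)
  }
  colnames(cnt) <- paste0("n_r", radii_um)
  out <- cbind(rec, as.data.frame(cnt))
  attr(out, "radii_um") <- radii_um
  out
}

#' Label inputs clustered or isolated
#'
#' An input is clustered when at least one like-eye sAZ synapse centroid lies
#' within the cutoff (default 1.5 um) of its cluster surface, isolated
#' otherwise.
#'
#' @param records output of [shell_neighbor_counts()].
#' @param cutoff_um cutoff radius; must be one of the record radii.
#' @return records with `n_nearby_saz` and logical `clustered` columns.
#' @export
label_clustered <- function(records, cutoff_um = 1.5) {
  col <- paste0("n_r", cutoff_um)
  if (!col %in% names(records)) stop("no neighbor counts at the cutoff radius")
  records$n_nearby_saz <- records[[col]]
  records$clustered <- records$n_nearby_saz >= 1
  records
}

#' Distance to the nearest like-eye clustered mAZ input
#'
#' For every mAZ input (clustered and isolated), the distance from its
#' cluster surface to the weighted centroid of the nearest like-eye clustered
#' mAZ input, excluding itself.
#'
#' @param records labeled records from [label_clustered()] (mAZ rows used).
#' @param centers the [spatial_inputs()] the records were computed from.
#' @return data.frame `input_id`, `eye`, `clustered`,
#'   `dist_to_clustered_maz_um` (`NA` when no other like-eye clustered mAZ
#'   exists).
#' @export
nearest_clustered_maz_distance <- function(records, centers) {
  maz <- records[records$input_class == "mAZ", , drop = FALSE]
  out <- data.frame(input_id = maz$input_id, eye = maz$eye,
                    clustered = maz$clustered,
                    dist_to_clustered_maz_um = rep(NA_real_, nrow(maz)))
  for (i in seq_len(nrow(maz))) {
    tgt <- which(records$input_class == "mAZ" & records$clustered &
                   records$eye == maz$eye[i] &
                   records$input_id != maz$input_id[i])
    if (!length(tgt)) next
    ci <- match(maz$input_id[i], centers$table$input_id)
    pts <- as.matrix(records[tgt, c("cx", "cy", "cz")])
    d <- cpp_min_dist_to_set(pts, centers$surfaces[[ci]])
    out$dist_to_clustered_maz_um[i] <- min(d) / 1e3
  }
  out
}

#' Near/far classification of sAZ synapses
#'
#' Each sAZ synapse is near when its centroid lies within the cutoff
#' (boundary inclusive) of the surface of the nearest like-eye mAZ input,
#' far otherwise; per-class vesicle-volume summaries are attached.
#'
#' @param saz_inputs classified inputs table restricted to sAZ rows (must
#'   carry `vesicle_volume_um3`).
#' @param maz_centers [spatial_inputs()] of the mAZ inputs.
#' @param cutoff_um near/far cutoff in micrometers.
#' @return list: `saz` (table with `dist_to_maz_um`, `near_far`) and
#'   `volume_summary` (mean/median vesicle volume by class).
#' @export
near_far_saz <- function(saz_inputs, maz_centers, cutoff_um = 1.5) {
  saz <- saz_inputs[saz_inputs$input_class == "sAZ", , drop = FALSE]
  saz$dist_to_maz_um <- rep(NA_real_, nrow(saz))
  mt <- maz_centers$table
  for (eye in unique(saz$eye)) {
    sidx <- which(saz$eye == eye)
    midx <- which(mt$eye == eye & mt$input_class == "mAZ")
    if (!length(midx)) next            # no like-eye mAZ: stays NA -> far
    pts <- as.matrix(saz[sidx, c("cx", "cy", "cz")])
    dmin <- rep(Inf, length(sidx))
    for (j in midx) {
      d <- cpp_min_dist_to_set(pts, maz_centers$surfaces[[j]])
      dmin <- pmin(dmin, d)
    }
    saz$dist_to_maz_um[sidx] <- dmin / 1e3
  }
  saz$near_far <- ifelse(!is.na(saz$dist_to_maz_um) &
                           saz$dist_to_maz_um <= cutoff_um, "near", "far")
  vs <- do.call(rbind, lapply(split(saz, saz$near_far), function(s)
    data.frame(near_far = s$near_far[1], n = nrow(s),
               mean_volume = mean(s$vesicle_volume_um3),
               median_volume = stats::median(s$vesicle_volume_um3))))
  rownames(vs) <- NULL
  list(saz = saz, volume_summary = vs)
}

#' Position-shuffled null ensemble for the clustering analysis
#'
#' Holds the center inputs fixed and resamples every sAZ centroid uniformly
#' over the neuropil mask (with sub-voxel jitter), recomputing neighbor
#' counts and clustered fractions per iteration. Empirical p-values use
#' `(1 + #\{null >= observed\}) / (1 + n_iterations)`.
#'
#' @param centers [spatial_inputs()] of the (fixed) center inputs.
#' @param saz [spatial_inputs()] of the observed sAZ synapses.
#' @param neuropil_mask logical array (nonempty).
#' @param geometry an [imaging_geometry()].
#' @param radii_um search radii in micrometers.
#' @param n_iterations number of shuffles (>= 1).
#' @param seed RNG seed; identical seeds give identical ensembles.
#' @param same_eye like-eye (`TRUE`) or cross-eye (`FALSE`) analysis.
#' @return list of class `null_ensemble`: `summary` (per radius: observed
#'   clustered fraction, null mean/sd/2.5%/97.5%, z, empirical p),
#'   `null_fractions` (iterations x radii), `observed_records`,
#'   `n_iterations`, `seed`.
#' @export
shuffle_null <- function(centers, saz, neuropil_mask, geometry,
                         radii_um = c(1, 1.5, 2, 3, 4), n_iterations = 1000,
                         seed = 1L, same_eye = TRUE) {
  stopifnot(n_iterations >= 1)
  vox <- which(neuropil_mask)
  if (length(vox) == 0) stop("empty neuropil mask")
  n_saz <- nrow(saz$table)
  if (n_saz > length(vox)) stop("more sAZ synapses than neuropil voxels")
  obs <- shell_neighbor_counts(centers, saz, radii_um, same_eye)
  ccols <- paste0("n_r", radii_um)
  obs_frac <- vapply(ccols, function(cn) mean(obs[[cn]] >= 1), 0)

  set.seed(seed)
  dm <- dim(neuropil_mask)
  sp <- geom_spacing(geometry)
  null_frac <- matrix(NA_real_, n_iterations, length(radii_um))
  null_mean_counts <- matrix(NA_real_, n_iterations, length(radii_um))
  shuf <- saz
  for (it in seq_len(n_iterations)) {
    pick <- vox[sample.int(length(vox), n_saz, replace = TRUE)]
    vi <- arrayInd(pick, dm)
    xyz <- voxel_to_nm(vi, geometry) +
      cbind(stats::runif(n_saz, -0.5, 0.5) * sp[1],
            stats::runif(n_saz, -0.5, 0.5) * sp[2],
            stats::runif(n_saz, -0.5, 0.5) * sp[3])
    shuf$table$cx <- xyz[, 1]
    shuf$table$cy <- xyz[, 2]
    shuf$table$cz <- xyz[, 3]
    # shuffled points are anonymous positions: no self-exclusion applies
    shuf$table$input_id <- -seq_len(n_saz)
    rec <- shell_neighbor_counts(centers, shuf, radii_um, same_eye)
    cnts <- as.matrix(rec[, ccols, drop = FALSE])
    null_frac[it, ] <- colMeans(cnts >= 1)
    null_mean_counts[it, ] <- colMeans(cnts)
  }
  nm <- colMeans(null_frac)
  nsd <- apply(null_frac, 2, stats::sd)
  p_emp <- vapply(seq_along(radii_um), function(r)
    (1 + sum(null_frac[, r] >= obs_frac[r])) / (1 + n_iterations), 0)
  summary <- data.frame(radius_um = radii_um,
                        observed_clustered_fraction = unname(obs_frac),
                        null_mean = nm, null_sd = nsd,
                        null_q025 = apply(null_frac, 2, stats::quantile, 0.025),
                        null_q975 = apply(null_frac, 2, stats::quantile, 0.975),
                        z = (unname(obs_frac) - nm) / ifelse(nsd > 0, nsd, NA),
                        p_empirical = p_emp)
  rownames(summary) <- NULL
  structure(list(summary = summary, null_fractions = null_frac,
                 null_mean_counts = null_mean_counts, observed_records = obs,
                 n_iterations = n_iterations, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("shuffle null ensemble (%d iterations)\n", x$n_iterations))
  print(x$summary, digits = 3)
  invisible(x)
}
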