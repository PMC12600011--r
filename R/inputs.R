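#' Associate active zones with vesicle clusters
#'
#' A 3D shell is extended `shell_nm` from the surface voxels of each VGluT2
#' cluster; a Bassoon cluster is associated when its weighted centroid falls
#' within the shell (or inside the cluster). Each Bassoon cluster is assigned
#' to at most one VGluT2 cluster, by nearest surface distance.
#'
#' @param vglut2 synaptic-population VGluT2 `az_clusters`.
#' @param bassoon Homer1-paired Bassoon `az_clusters`.
#' @param shell_nm association shell (nm).
#' @return data.frame `az_id`, `vglut2_id`, `surface_distance` (nm), one row
#'   per associated Bassoon cluster.
#' @export
associate_azs <- function(vglut2, bassoon, shell_nm = 140) {
  nv <- nrow(vglut2$table)
  nb <- nrow(bassoon$table)
  empty <- data.frame(az_id = integer(0), vglut2_id = integer(0),
                      surface_distance = numeric(0))
  if (nv == 0 || nb == 0) return(empty)
  geometry <- vglut2$geometry
  bz <- as.matrix(bassoon$table[, c("cx", "cy", "cz")])
  vc <- as.matrix(vglut2$table[, c("cx", "cy", "cz")])
  dmat <- matrix(Inf, nb, nv)
  for (j in seq_len(nv)) {
    vox <- vglut2$voxels[[j]]
    surf <- voxel_to_nm(boundary_voxels(vox, geometry), geometry)
    # bounding-sphere prefilter
    ext <- sqrt(max(colSums((t(surf) - vc[j, ])^2)))
    d2c <- sqrt(colSums((t(bz) - vc[j, ])^2))
    cand <- which(d2c <= ext + shell_nm + 200)
    if (!length(cand)) next
    dmat[cand, j] <- cpp_min_dist_to_set(bz[cand, , drop = FALSE], surf)
  }
  best <- apply(dmat, 1, which.min)
  bestd <- dmat[cbind(seq_len(nb), best)]
  hit <- which(bestd <= shell_nm)
  data.frame(az_id = bassoon$table$id[hit],
             vglut2_id = vglut2$table$id[best[hit]],
             surface_distance = bestd[hit])
}

# surface voxels of one cluster (6-connectivity exposure), as voxel indices
boundary_voxels <- function(voxels, geometry) {
  lo <- apply(voxels, 2, min) - 1L
  dmc <- apply(voxels, 2, max) - lo + 1L
  rel <- sweep(voxels, 2, lo)
  mask <- array(FALSE, dmc)
  mask[rel] <- TRUE
  b <- cpp_boundary3d(mask, dmc)
  out <- which(array(b, dmc), arr.ind = TRUE)
  out <- sweep(out, 2, lo, "+")
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Assemble and classify retinogeniculate inputs
#'
#' One retinogeniculate input is a single contiguous VGluT2 vesicle cluster
#' together with its associated Bassoon/Homer1 release sites. Inputs with one
#' active zone are sAZ synapses; inputs with two or more are mAZ inputs.
#' VGluT2 clusters without any associated active zone are dropped (not
#' retinogeniculate inputs); inputs with more than four active zones are kept
#' but flagged.
#'
#' @param vglut2 synaptic-population VGluT2 `az_clusters`.
#' @param assoc association table from [associate_azs()].
#' @param eye_map data.frame from [assign_eye()] (`vglut2_id`, `eye`), or
#'   `NULL` to leave eyes unassigned.
#' @return data.frame of inputs: `input_id`, `vglut2_id`, `eye`,
#'   `input_class`, `az_count`, `vesicle_volume_um3`, `volume_per_az`,
#'   centroid (`cx`, `cy`, `cz` nm), `flagged_many_az`.
#' @export
classify_inputs <- function(vglut2, assoc, eye_map = NULL) {
  keep <- vglut2$table$id %in% assoc$vglut2_id
  tab <- vglut2$table[keep, , drop = FALSE]
  if (nrow(tab) == 0)
    return(data.frame(input_id = integer(0), vglut2_id = integer(0),
                      eye = character(0), input_class = character(0),
                      az_count = integer(0), vesicle_volume_um3 = numeric(0),
                      volume_per_az = numeric(0), cx = numeric(0),
                      cy = numeric(0), cz = numeric(0),
                      flagged_many_az = logical(0)))
  azc <- table(assoc$vglut2_id)
  out <- data.frame(input_id = seq_len(nrow(tab)),
                    vglut2_id = tab$id,
                    eye = NA_character_,
                    input_class = NA_character_,
                    az_count = as.integer(azc[as.character(tab$id)]),
                    vesicle_volume_um3 = tab$volume_um3,
                    volume_per_az = NA_real_,
                    cx = tab$cx, cy = tab$cy, cz = tab$cz)
  out$input_class <- ifelse(out$az_count >= 2, "mAZ", "sAZ")
  out$volume_per_az <- out$vesicle_volume_um3 / out$az_count
  out$flagged_many_az <- out$az_count > 4
  if (!is.null(eye_map))
    out$eye <- eye_map$eye[match(out$vglut2_id, eye_map$vglut2_id)]
  rownames(out) <- NULL
  out
}

#' Docked-vesicle proxy volume around one active zone
#'
#' VGluT2 segmentation-mask volume within `shell_nm` (default 70) of the
#' active zone's surface, a proxy for the readily releasable (docked) vesicle
#' pool. All VGluT2-positive voxels within the shell count, including voxels
#' overlapping the active-zone cluster itself.
#'
#' @param az_voxels integer matrix (n x 3) of the Bassoon cluster's voxels.
#' @param vglut2_mask logical array: binarized VGluT2 segmentation.
#' @param geometry an [imaging_geometry()].
#' @param shell_nm shell thickness in nm.
#' @return volume in um^3.
#' @export
docked_vesicle_volume <- function(az_voxels, vglut2_mask, geometry,
                                  shell_nm = 70) {
  dm <- dim(vglut2_mask)
  sp <- geom_spacing(geometry)
  pad <- ceiling(shell_nm / sp) + 1
  lo <- pmax(apply(az_voxels, 2, min) - pad, 1)
  hi <- pmin(apply(az_voxels, 2, max) + pad, dm)
  dmc <- hi - lo + 1
  rel <- sweep(az_voxels, 2, lo - 1L)
  mask <- array(FALSE, dmc)
  mask[rel] <- TRUE
  dist <- cpp_edt3d(mask, dmc, sp)
  crop <- vglut2_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sum(crop & dist <= shell_nm) * voxel_volume_um3(geometry)
}

#' Group summaries of classified inputs
#'
#' Per (eye, input class): input density over the neuropil volume, the mAZ
#' fraction of all inputs of that eye, vesicle-volume summaries, mean
#' active-zone count, mean volume per active zone and mean docked-vesicle
#' volume.
#'
#' @param inputs table from [classify_inputs()] (optionally with a
#'   `mean_docked_volume` column).
#' @param neuropil_volume_um3 analysis-region volume (> 0).
#' @return summary data.frame, one row per (eye, input_class).
#' @export
summarize_by_group <- function(inputs, neuropil_volume_um3) {
  if (neuropil_volume_um3 <= 0) stop("zero neuropil volume")
  if (nrow(inputs) == 0)
    return(data.frame(eye = character(0), input_class = character(0),
                      n = integer(0), density_per_um3 = numeric(0),
                      maz_fraction = numeric(0),
                      median_vesicle_volume_um3 = numeric(0),
                      mean_vesicle_volume_um3 = numeric(0),
                      mean_az_count = numeric(0),
                      mean_volume_per_az = numeric(0),
                      mean_docked_volume = numeric(0)))
  eyes <- unique(inputs$eye)
  rows <- list()
  for (e in eyes) {
    sub_eye <- inputs[inputs$eye %in% e, , drop = FALSE]
    mazf <- mean(sub_eye$input_class == "mAZ")
    for (cl in intersect(c("mAZ", "sAZ"), unique(sub_eye$input_class))) {
      s <- sub_eye[sub_eye$input_class == cl, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        eye = e, input_class = cl, n = nrow(s),
        density_per_um3 = nrow(s) / neuropil_volume_um3,
        maz_fraction = mazf,
        median_vesicle_volume_um3 = stats::median(s$vesicle_volume_um3),
        mean_vesicle_volume_um3 = mean(s$vesicle_volume_um3),
        mean_az_count = mean(s$az_count),
        mean_volume_per_az = mean(s$volume_per_az),
        mean_docked_volume = if ("mean_docked_volume" %in% names(s))
          mean(s$mean_docked_volume) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
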