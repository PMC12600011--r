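#' Pairing configuration
#'
#' @param shell_nm shell thickness (nm) for opposing-channel intensity.
#' @param min_samples OPTICS neighborhood size; below this many features a
#'   hard-threshold fallback is used (distance <= `shell_nm`, positive shell
#'   intensity), since density clustering is undefined for tiny inputs.
#' @param xi OPTICS steepness threshold.
#' @return list of class `pairing_config`.
#' @export
pairing_config <- function(shell_nm = 140, min_samples = 5L, xi = 0.05) {
  structure(list(shell_nm = shell_nm, min_samples = as.integer(min_samples),
                 xi = xi), class = "pairing_config")
}

# mean opposing-channel intensity in a shell of `shell_nm` around the
# cluster's surface (excluding the cluster's own voxels)
shell_mean_intensity <- function(voxels, opposing_raw, geometry, shell_nm) {
  dm <- dim(opposing_raw)
  sp <- geom_spacing(geometry)
  pad <- ceiling(shell_nm / sp) + 1
  lo <- pmax(apply(voxels, 2, min) - pad, 1)
  hi <- pmin(apply(voxels, 2, max) + pad, dm)
  dmc <- hi - lo + 1
  rel <- sweep(voxels, 2, lo - 1L)
  mask <- array(FALSE, dmc)
  mask[rel] <- TRUE
  dist <- cpp_edt3d(mask, dmc, sp)
  shell <- dist > 0 & dist <= shell_nm
  if (!any(shell)) return(0)
  crop <- opposing_raw[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sum(crop[shell]) / sum(shell)
}

#' Pairing features between two cluster channels
#'
#' For every cluster in `a`: the nearest opposing-channel cluster by weighted
#' centroid distance, and the mean raw opposing-channel intensity within a
#' 140-nm shell around the cluster's surface. Genuinely apposed pre/post
#' partners sit at small centroid distance and high shell intensity.
#'
#' @param a,b `az_clusters` objects (nonempty).
#' @param opposing_raw raw intensity array of `b`'s channel.
#' @param config a [pairing_config()].
#' @return data.frame: `cluster_id`, `partner_id`, `centroid_distance` (nm),
#'   `shell_intensity`.
#' @export
compute_pair_features <- function(a, b, opposing_raw,
                                  config = pairing_config()) {
  if (nrow(b$table) == 0) stop("no opposing clusters")
  stopifnot(nrow(a$table) >= 1)
  ca <- as.matrix(a$table[, c("cx", "cy", "cz")])
  cb <- as.matrix(b$table[, c("cx", "cy", "cz")])
  out <- data.frame(cluster_id = a$table$id, partner_id = NA_integer_,
                    centroid_distance = NA_real_, shell_intensity = NA_real_)
  for (i in seq_len(nrow(ca))) {
    d2 <- colSums((t(cb) - ca[i, ])^2)
    j <- which.min(d2)
    out$partner_id[i] <- b$table$id[j]
    out$centroid_distance[i] <- sqrt(d2[j])
    out$shell_intensity[i] <- shell_mean_intensity(a$voxels[[i]], opposing_raw,
                                                   a$geometry, config$shell_nm)
  }
  out
}

#' Select genuinely paired clusters from pairing features
#'
#' Runs OPTICS with xi extraction on the standardized (centroid distance,
#' shell intensity) features; density components whose median centroid
#' distance is at the apposition scale (within 1.5x the shell) and whose
#' median shell intensity is positive are labeled paired. With fewer than
#' `min_samples` features, or when no component carries the apposition
#' signature, a hard-threshold fallback (distance <= shell, positive shell
#' intensity) is applied.
#'
#' @param features output of [compute_pair_features()].
#' @param config a [pairing_config()].
#' @return the features with columns `is_paired` and `method_tag` added.
#' @export
select_pairs <- function(features, config = pairing_config()) {
  n <- nrow(features)
  feat <- cbind(features$centroid_distance, features$shell_intensity)
  out <- features
  if (n < config$min_samples) {
    out$is_paired <- features$centroid_distance <= config$shell_nm &
      features$shell_intensity > 0
    out$method_tag <- "threshold-smalln"
    if (n == 1) out$is_paired <- FALSE  # a single feature cannot form a pair cluster
    return(out)
  }
  sds <- apply(feat, 2, stats::sd)
  if (all(sds == 0)) {
    warning("all pairing features identical; no pairs selected")
    out$is_paired <- FALSE
    out$method_tag <- "degenerate"
    return(out)
  }
  std <- scale(feat)
  std[, sds == 0] <- 0
  oo <- optics_order(std, config$min_samples)
  labels <- optics_xi(oo$reachability, oo$order, config$xi, config$min_samples)
  out$is_paired <- FALSE
  out$method_tag <- "unreachable"
  for (l in setdiff(unique(labels), 0L)) {
    sel <- labels == l
    if (mean(sel) > 0.95) {
      # a component spanning essentially all features is the root of the
      # reachability plot, not a pairing signature
      out$method_tag[sel & out$method_tag == "unreachable"] <- "optics-root"
      next
    }
    # the paired component sits at apposition-scale centroid distance with
    # opposing-channel signal in the shell; distractor components sit far
    # away with background-level shell intensity
    med_d <- stats::median(features$centroid_distance[sel])
    med_i <- stats::median(features$shell_intensity[sel])
    if (med_d <= 1.5 * config$shell_nm && med_i > 0) {
      out$is_paired[sel] <- TRUE
      out$method_tag[sel] <- sprintf("optics-%d", l)
    } else {
      out$method_tag[sel] <- sprintf("optics-rejected-%d", l)
    }
  }
  if (!any(out$is_paired)) {
    # no resolvable low-distance/high-intensity density component (typical of
    # small or degenerate feature sets): fall back to the hard apposition rule
    warning("OPTICS found no low-distance/high-intensity component; using threshold rule")
    thr <- features$centroid_distance <= config$shell_nm &
      features$shell_intensity > 0
    out$is_paired <- thr
    out$method_tag[thr] <- "threshold-fallback"
  }
  out
}

#' Enforce one-to-one pairing
#'
#' Trans-synaptic apposition is one-to-one, so when two clusters claim the
#' same partner the pair with the smaller centroid distance wins and the
#' loser re-queries its next-nearest unclaimed partner; the re-queried pair
#' is kept only within twice the apposition shell scale.
#'
#' @param decisions output of [select_pairs()].
#' @param a,b the `az_clusters` the features were computed from.
#' @param shell_nm apposition scale; a re-queried pair farther than twice this
#'   is dropped rather than paired.
#' @return `decisions` with conflicts resolved (partner ids unique among
#'   paired rows).
#' @export
reconcile_pairs <- function(decisions, a, b, shell_nm = 140) {
  paired <- which(decisions$is_paired)
  if (!length(paired)) return(decisions)
  ca <- as.matrix(a$table[, c("cx", "cy", "cz")])
  cb <- as.matrix(b$table[, c("cx", "cy", "cz")])
  d <- matrix(NA_real_, nrow(ca), nrow(cb))
  for (i in paired) d[i, ] <- sqrt(colSums((t(cb) - ca[i, ])^2))
  bid <- b$table$id
  # greedy assignment in order of increasing claimed distance
  ord <- paired[order(decisions$centroid_distance[paired])]
  taken <- rep(FALSE, nrow(cb))
  for (i in ord) {
    prefs <- order(d[i, ])
    prefs <- prefs[!taken[prefs]]
    if (!length(prefs)) {
      decisions$is_paired[i] <- FALSE
      next
    }
    j <- prefs[1]
    dij <- d[i, j]
    first_choice <- bid[j] == decisions$partner_id[i]
    if (!first_choice && dij > 2 * shell_nm) {
      decisions$is_paired[i] <- FALSE
      next
    }
    taken[j] <- TRUE
    decisions$partner_id[i] <- bid[j]
    decisions$centroid_distance[i] <- dij
  }
  decisions
}

#' Assign eye of origin from CTB tracer signal
#'
#' Applies the same feature + density-selection machinery used for
#' pre/postsynaptic pairing to (VGluT2, CTB): tracer-paired vesicle clusters
#' are dominant-eye inputs, the rest non-dominant.
#'
#' @param vglut2 synaptic-population VGluT2 `az_clusters`.
#' @param ctb CTB `az_clusters`.
#' @param ctb_raw raw CTB intensity array.
#' @param config a [pairing_config()].
#' @return data.frame `vglut2_id`, `eye` (`dominant`/`non_dominant`).
#' @export
assign_eye <- function(vglut2, ctb, ctb_raw, config = pairing_config()) {
  if (nrow(vglut2$table) == 0)
    return(data.frame(vglut2_id = integer(0), eye = character(0)))
  if (is.null(ctb) || nrow(ctb$table) == 0) {
    warning("no CTB clusters; all inputs assigned non_dominant")
    return(data.frame(vglut2_id = vglut2$table$id, eye = "non_dominant"))
  }
  feats <- compute_pair_features(vglut2, ctb, ctb_raw, config)
  dec <- select_pairs(feats, config)
  data.frame(vglut2_id = vglut2$table$id,
             eye = ifelse(dec$is_paired, "dominant", "non_dominant"))
}
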