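#' Pipeline run configuration
#'
#' Assembles one end-to-end run: either a synthetic scene (via
#' [scene_params()]) or a directory of TIFF volumes, plus segmentation,
#' pairing, spatial and statistical settings. Every stochastic stage receives
#' a seed derived deterministically from `seed`.
#'
#' @param geometry an [imaging_geometry()].
#' @param scene a [scene_params()] for simulated runs, or `NULL`.
#' @param volume_dir directory readable by [read_volume_tiff()] for real
#'   volumes (ignored when `scene` is given).
#' @param segmentation a [segmentation_config()].
#' @param pairing a [pairing_config()].
#' @param radii_um expansion-shell search radii (um).
#' @param cutoff_um clustered/isolated cutoff (um); must be in `radii_um`.
#' @param n_iterations shuffle-null iterations (0 disables the null stage).
#' @param alpha FDR level for downstream statistics.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(geometry, scene = NULL, volume_dir = NULL,
                       segmentation = segmentation_config(),
                       pairing = pairing_config(),
                       radii_um = c(1, 1.5, 2, 3, 4), cutoff_um = 1.5,
                       n_iterations = 200, alpha = 0.05, seed = 1L) {
  if (is.null(geometry)) stop("config requires a geometry")
  stopifnot(inherits(geometry, "imaging_geometry"))
  if (is.null(scene) && is.null(volume_dir))
    stop("config requires either a scene or a volume_dir")
  if (!cutoff_um %in% radii_um) radii_um <- sort(c(radii_um, cutoff_um))
  structure(list(geometry = geometry, scene = scene, volume_dir = volume_dir,
                 segmentation = segmentation, pairing = pairing,
                 radii_um = radii_um, cutoff_um = cutoff_um,
                 n_iterations = n_iterations, alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> normalize -> mask -> segment -> pair -> classify ->
#' spatial analysis -> summaries, recording counts, thresholds and seeds in a
#' manifest. Reruns with an identical config reproduce all outputs exactly.
#'
#' @param config a [run_config()].
#' @param out_dir if non-`NULL`, tables and the manifest are written there via
#'   [write_tables()].
#' @return object of class `az_run`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  g <- config$geometry
  scene <- NULL
  if (!is.null(config$scene)) {
    sp <- config$scene
    sp$seed <- config$seed
    scene <- generate_scene(sp, g)
    volume <- render_volume(scene)
  } else {
    volume <- read_volume_tiff(config$volume_dir)
    g <- volume$geometry
  }

  volume <- suppressWarnings(normalize_section_histograms(volume))
  seg <- config$segmentation

  cb_mask <- cell_body_mask(volume$channels$homer1, g, seg)
  np_mask <- tryCatch(neuropil_mask(volume$channels$ctb, cb_mask, g, seg),
                      error = function(e) {
                        warning("no CTB signal; using the full volume as neuropil")
                        array(TRUE, g$shape) & !cb_mask
                      })
  np_vol <- sum(np_mask) * voxel_volume_um3(g)

  thresholds <- list()
  clusters <- list()
  for (chn in c("homer1", "bassoon", "vglut2", "ctb")) {
    cl <- detect_clusters(volume$channels[[chn]], g, seg,
                          exclusion_mask = cb_mask, channel_name = chn)
    thresholds[[chn]] <- as.list(attr(cl, "thresholds"))
    if (nrow(cl$table) >= 2) {
      selp <- suppressWarnings(select_synaptic_population(cl, seg))
      clusters[[chn]] <- selp$synaptic
      thresholds[[chn]]$population_mode <- selp$mode
      thresholds[[chn]]$n_rejected <- nrow(selp$rejected$table)
    } else {
      clusters[[chn]] <- cl
      thresholds[[chn]]$population_mode <- "none"
      thresholds[[chn]]$n_rejected <- 0L
    }
  }

  # presynaptic active zones: Bassoon clusters with a Homer1 partner
  pairs <- NULL
  bassoon_paired <- clusters_subset(clusters$bassoon, integer(0))
  if (nrow(clusters$bassoon$table) >= 1 && nrow(clusters$homer1$table) >= 1) {
    feats <- compute_pair_features(clusters$bassoon, clusters$homer1,
                                   volume$channels$homer1, config$pairing)
    pairs <- suppressWarnings(select_pairs(feats, config$pairing))
    pairs <- reconcile_pairs(pairs, clusters$bassoon, clusters$homer1)
    bassoon_paired <- clusters_subset(clusters$bassoon,
                                      which(pairs$is_paired))
  }

  eye_map <- suppressWarnings(
    assign_eye(clusters$vglut2, clusters$ctb, volume$channels$ctb,
               config$pairing))

  assoc <- associate_azs(clusters$vglut2, bassoon_paired,
                         config$pairing$shell_nm)
  inputs <- classify_inputs(clusters$vglut2, assoc, eye_map)

  # docked-vesicle proxy per active zone
  az_table <- assoc
  if (nrow(assoc)) {
    vg_mask <- array(FALSE, g$shape)
    for (v in clusters$vglut2$voxels) vg_mask[v] <- TRUE
    az_table$docked_volume_um3 <- NA_real_
    for (i in seq_len(nrow(assoc))) {
      bi <- match(assoc$az_id[i], bassoon_paired$table$id)
      az_table$docked_volume_um3[i] <- docked_vesicle_volume(
        bassoon_paired$voxels[[bi]], vg_mask, g)
    }
    dv <- tapply(az_table$docked_volume_um3, az_table$vglut2_id, mean)
    inputs$mean_docked_volume <- as.numeric(dv[as.character(inputs$vglut2_id)])
  }

  # spatial clustering analysis
  spat <- spatial_inputs(inputs, clusters$vglut2)
  records <- NULL
  distances <- NULL
  nearfar <- NULL
  null_ens <- NULL
  if (nrow(inputs) > 0) {
    records <- shell_neighbor_counts(spat, spat, config$radii_um)
    records <- label_clustered(records, config$cutoff_um)
    distances <- nearest_clustered_maz_distance(records, spat)
    if (any(inputs$input_class == "mAZ"))
      nearfar <- near_far_saz(
        inputs,
        structure(list(table = spat$table, surfaces = spat$surfaces),
                  class = "spatial_inputs"),
        config$cutoff_um)
    if (config$n_iterations > 0 && any(inputs$input_class == "sAZ")) {
      maz_idx <- which(spat$table$input_class == "mAZ")
      if (length(maz_idx)) {
        centers <- structure(list(table = spat$table[maz_idx, , drop = FALSE],
                                  surfaces = spat$surfaces[maz_idx]),
                             class = "spatial_inputs")
        saz_idx <- which(spat$table$input_class == "sAZ")
        sazsp <- structure(list(table = spat$table[saz_idx, , drop = FALSE],
                                surfaces = spat$surfaces[saz_idx]),
                           class = "spatial_inputs")
        null_ens <- shuffle_null(centers, sazsp, np_mask, g, config$radii_um,
                                 config$n_iterations,
                                 seed = config$seed + 1000L)
      }
    }
  }

  group_summary <- summarize_by_group(inputs, np_vol)

  manifest <- list(
    seed = config$seed,
    geometry = list(shape = g$shape, voxel_xy = g$voxel_xy,
                    voxel_z = g$voxel_z),
    neuropil_volume_um3 = np_vol,
    thresholds = thresholds,
    counts = list(
      cell_body_voxels = sum(cb_mask),
      clusters = lapply(clusters, function(cl) nrow(cl$table)),
      paired_azs = nrow(bassoon_paired$table),
      inputs = nrow(inputs),
      maz = sum(inputs$input_class == "mAZ"),
      saz = sum(inputs$input_class == "sAZ"),
      dominant = sum(inputs$eye == "dominant"),
      clustered = if (!is.null(records)) sum(records$clustered) else 0L),
    n_iterations = config$n_iterations)
  manifest$config_hash <- config_hash(config)

  run <- structure(list(config = config, scene = scene,
                        neuropil_volume_um3 = np_vol,
                        neuropil_mask = np_mask, cell_body_mask = cb_mask,
                        clusters = clusters, pairs = pairs,
                        eye_map = eye_map, assoc = az_table, inputs = inputs,
                        records = records, distances = distances,
                        nearfar = nearfar, null_ensemble = null_ens,
                        group_summary = group_summary, manifest = manifest),
                   class = "az_run")
  if (!is.null(out_dir)) write_tables(run, out_dir)
  run
}

# md5 of the JSON-serialized configuration (provenance)
config_hash <- function(config) {
  cfg <- config
  cfg$geometry <- unclass(cfg$geometry)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(lapply(cfg, function(x)
    if (is.list(x)) unclass(x) else x), tmp, auto_unbox = TRUE, digits = NA,
    force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.az_run <- function(x, ...) {
  m <- x$manifest$counts
  cat("azstorm pipeline run\n")
  cat(sprintf("  neuropil volume: %.1f um^3\n", x$neuropil_volume_um3))
  cat(sprintf("  clusters: homer1 %d, bassoon %d, vglut2 %d, ctb %d\n",
              m$clusters$homer1, m$clusters$bassoon, m$clusters$vglut2,
              m$clusters$ctb))
  cat(sprintf("  inputs: %d (%d mAZ / %d sAZ; %d dominant-eye)\n",
              m$inputs, m$maz, m$saz, m$dominant))
  if (!is.null(x$records))
    cat(sprintf("  clustered at %.1f um: %d of %d\n", x$config$cutoff_um,
                sum(x$records$clustered), nrow(x$records)))
  invisible(x)
}

#' @export
summary.az_run <- function(object, ...) {
  print(object)
  cat("\nGroup summary:\n")
  print(object$group_summary, digits = 3)
  if (!is.null(object$null_ensemble)) {
    cat("\nShuffle null (mAZ centers):\n")
    print(object$null_ensemble$summary, digits = 3)
  }
  invisible(object)
}

#' Write pipeline tables and manifest
#'
#' CSV tables (clusters per channel, inputs, clustering records, distances,
#' near/far classes, null summary, group summary) and a JSON manifest. Output
#' is deterministic for a given run.
#'
#' @param run an `az_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tables <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(df, name) {
    if (!is.null(df) && nrow(df))
      utils::write.csv(format(df, digits = 10, scientific = FALSE),
                       file.path(dir, name), row.names = FALSE, quote = TRUE)
  }
  for (chn in names(run$clusters))
    wcsv(run$clusters[[chn]]$table, paste0("clusters_", chn, ".csv"))
  wcsv(run$inputs, "inputs.csv")
  wcsv(run$assoc, "active_zones.csv")
  wcsv(run$records, "clustering_records.csv")
  wcsv(run$distances, "nearest_clustered_maz.csv")
  if (!is.null(run$nearfar)) wcsv(run$nearfar$saz, "near_far_saz.csv")
  if (!is.null(run$null_ensemble))
    wcsv(run$null_ensemble$summary, "null_summary.csv")
  wcsv(run$group_summary, "group_summary.csv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
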