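#' Multi-channel voxel volume
#'
#' Container for an aligned, rendered serial-section stack: one 3D intensity
#' array per fluorescence channel, all sharing one [imaging_geometry()].
#' Channels are referenced by functional role — `homer1` (postsynaptic),
#' `bassoon` (active zone), `vglut2` (retinal vesicle pool), `ctb`
#' (anterograde eye-of-origin tracer) — not by fluorophore.
#'
#' @param geometry an [imaging_geometry()].
#' @param channels named list of 3D numeric arrays with dim = `geometry$shape`;
#'   intensities in `[0, 2^bit_depth - 1]`.
#' @param section_ids optional identifiers of the physical section of each
#'   z-plane (defaults to `1:nz`).
#' @return An object of class `mc_volume`.
#' @export
multichannel_volume <- function(geometry, channels, section_ids = NULL) {
  stopifnot(inherits(geometry, "imaging_geometry"),
            is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  maxi <- 2^geometry$bit_depth - 1
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(ch), geometry$shape) &&
        !identical(as.integer(dim(ch)), geometry$shape))
      stop("channel '", nm, "' does not match the geometry shape")
    if (min(ch) < 0 || max(ch) > maxi)
      stop("channel '", nm, "' has intensities outside the bit depth range")
  }
  if (is.null(section_ids)) section_ids <- seq_len(geometry$shape[3])
  stopifnot(length(section_ids) == geometry$shape[3])
  structure(list(geometry = geometry, channels = channels,
                 section_ids = section_ids),
            class = "mc_volume")
}

#' @export
print.mc_volume <- function(x, ...) {
  cat("multi-channel volume:", paste(names(x$channels), collapse = ", "), "\n")
  print(x$geometry)
  invisible(x)
}

#' Write a multi-channel volume as multi-page TIFF files
#'
#' One 8-bit TIFF per channel (`<channel>.tif`, one page per section) plus a
#' `geometry.json` sidecar carrying voxel sizes, shape, bit depth and section
#' ids. The round trip through [read_volume_tiff()] is bit-exact.
#'
#' @param volume an [multichannel_volume()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_volume_tiff <- function(volume, dir) {
  stopifnot(inherits(volume, "mc_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maxi <- 2^volume$geometry$bit_depth - 1
  for (nm in names(volume$channels)) {
    ch <- volume$channels[[nm]]
    pages <- lapply(seq_len(dim(ch)[3]), function(z) t(ch[, , z]) / maxi)
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 8L)
  }
  meta <- list(shape = volume$geometry$shape,
               voxel_xy = volume$geometry$voxel_xy,
               voxel_z = volume$geometry$voxel_z,
               bit_depth = volume$geometry$bit_depth,
               section_ids = volume$section_ids,
               channels = names(volume$channels))
  jsonlite::write_json(meta, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multi-channel volume written by [write_volume_tiff()]
#'
#' @param dir directory holding `<channel>.tif` files and `geometry.json`.
#' @param channels channel names to load; default = all listed in the sidecar.
#' @return an [multichannel_volume()].
#' @export
read_volume_tiff <- function(dir, channels = NULL) {
  meta_path <- file.path(dir, "geometry.json")
  if (!file.exists(meta_path)) stop("missing geometry.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  geometry <- imaging_geometry(meta$shape, meta$voxel_xy, meta$voxel_z,
                               meta$bit_depth)
  if (is.null(channels)) channels <- meta$channels
  maxi <- 2^geometry$bit_depth - 1
  chan <- list()
  for (nm in channels) {
    path <- file.path(dir, paste0(nm, ".tif"))
    if (!file.exists(path)) stop("missing channel file for '", nm, "'")
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = geometry$shape)
    for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]]) * maxi
    chan[[nm]] <- round(arr)
  }
  multichannel_volume(geometry, chan, meta$section_ids)
}
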