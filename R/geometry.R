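#' Imaging geometry of an aligned serial-section volume
#'
#' Describes the anisotropic voxel grid of a rendered super-resolution stack:
#' square lateral pixels (default 15.5 nm, the rendering scale of the
#' single-molecule images) and a section thickness set by the ultramicrotome
#' (default 70 nm).
#'
#' @param shape integer vector `(nx, ny, nz)`: voxels per axis.
#' @param voxel_xy lateral voxel size in nm (> 0).
#' @param voxel_z section thickness in nm (> 0).
#' @param bit_depth intensity quantization; intensities live in
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `imaging_geometry`.
#' @examples
#' g <- imaging_geometry(c(128, 128, 20))
#' physical_volume_um3(g)
#' @export
imaging_geometry <- function(shape, voxel_xy = 15.5, voxel_z = 70,
                             bit_depth = 8L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            voxel_xy > 0, voxel_z > 0, bit_depth >= 1)
  structure(list(shape = shape, voxel_xy = voxel_xy, voxel_z = voxel_z,
                 bit_depth = as.integer(bit_depth)),
            class = "imaging_geometry")
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat(sprintf("imaging geometry: %d x %d x %d voxels, %.1f x %.1f x %.1f nm, %d-bit (%.1f um^3)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_xy, x$voxel_xy, x$voxel_z, x$bit_depth,
              physical_volume_um3(x)))
  invisible(x)
}

# per-axis voxel spacing in nm
geom_spacing <- function(geometry) {
  c(geometry$voxel_xy, geometry$voxel_xy, geometry$voxel_z)
}

#' Physical volume of the imaged field
#' @param geometry an [imaging_geometry()].
#' @return volume in cubic micrometers.
#' @export
physical_volume_um3 <- function(geometry) {
  prod(geometry$shape) * voxel_volume_um3(geometry)
}

#' Physical volume of one voxel
#' @param geometry an [imaging_geometry()].
#' @return volume in cubic micrometers.
#' @export
voxel_volume_um3 <- function(geometry) {
  geometry$voxel_xy^2 * geometry$voxel_z / 1e9
}

# voxel indices (1-based, n x 3) -> physical coordinates of voxel centers (nm)
voxel_to_nm <- function(vox, geometry) {
  sp <- geom_spacing(geometry)
  cbind((vox[, 1] - 0.5) * sp[1],
        (vox[, 2] - 0.5) * sp[2],
        (vox[, 3] - 0.5) * sp[3])
}

# physical coordinates (nm, n x 3) -> nearest voxel index, clamped into volume
nm_to_voxel <- function(xyz, geometry) {
  sp <- geom_spacing(geometry)
  v <- cbind(ceiling(xyz[, 1] / sp[1]),
             ceiling(xyz[, 2] / sp[2]),
             ceiling(xyz[, 3] / sp[3]))
  for (a in 1:3) v[, a] <- pmin(pmax(v[, a], 1L), geometry$shape[a])
  storage.mode(v) <- "integer"
  v
}
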