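#' Parameters of a synthetic retinogeniculate scene
#'
#' Defines the statistical structure the analysis assumes: two input classes
#' (sAZ with one active zone, mAZ with 2-4 active zones sharing a single
#' vesicle cluster), eye-of-origin labeling with imperfect tracer efficiency,
#' vesicle-pool volume scaling linearly with active-zone count, like-eye
#' spatial clustering of sAZ synapses around mAZ inputs, large nuisance cell
#' bodies, and sparse non-specific background labels.
#'
#' Densities are inputs per cubic micrometer of the imaged field. The default
#' active-zone count distribution over \{2, 3, 4\} reflects that most
#' multi-active-zone inputs carry two release sites, fewer carry three, and
#' under 5% carry four. Tracer efficiency defaults to 0.97 (binocular control
#' injections label over 97% of retinal synapses).
#'
#' @param density_sAZ_eyeA,density_sAZ_eyeB,density_mAZ_eyeA,density_mAZ_eyeB
#'   expected inputs per um^3 by class and eye (eye A is the tracer-injected,
#'   dominant eye).
#' @param az_count_pmf named numeric vector: probability of 2, 3, 4 active
#'   zones for an mAZ input; must sum to 1.
#' @param vesicle_volume_per_az vesicle-pool volume (um^3) contributed by each
#'   active zone; total cluster volume is exactly `az_count` times this.
#' @param clustering_fraction probability that a new sAZ synapse is placed
#'   within `cluster_radius` of an existing like-eye mAZ input.
#' @param cluster_radius like-eye clustering scale in um (surface of the mAZ
#'   vesicle cluster to the sAZ centroid).
#' @param ctb_label_efficiency probability a true eye-A input carries CTB.
#' @param cell_body_count,cell_body_radius nuisance blobs rendered into the
#'   Homer1/Bassoon channels (radius in um).
#' @param background_label_rate spurious small labels per um^3 per channel.
#' @param noise_sd amplitude (8-bit units) of sparse speckle noise added at
#'   render time; 0 disables noise.
#' @param edge_precision_nm rendered vesicle clouds extend this far beyond
#'   their nominal boundary, emulating the localization-precision spread of
#'   single-molecule rendering at the cloud edge.
#' @param seed RNG seed; all scene and render randomness derives from it.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(density_sAZ_eyeA = 0.008,
                         density_sAZ_eyeB = 0.005,
                         density_mAZ_eyeA = 0.006,
                         density_mAZ_eyeB = 0.004,
                         az_count_pmf = c("2" = 0.8, "3" = 0.15, "4" = 0.05),
                         vesicle_volume_per_az = 0.15,
                         clustering_fraction = 0.5,
                         cluster_radius = 1.5,
                         ctb_label_efficiency = 0.97,
                         cell_body_count = 2,
                         cell_body_radius = 3,
                         background_label_rate = 0.02,
                         noise_sd = 15,
                         edge_precision_nm = 15,
                         seed = 1L) {
  p <- list(density_sAZ_eyeA = density_sAZ_eyeA,
            density_sAZ_eyeB = density_sAZ_eyeB,
            density_mAZ_eyeA = density_mAZ_eyeA,
            density_mAZ_eyeB = density_mAZ_eyeB,
            az_count_pmf = az_count_pmf,
            vesicle_volume_per_az = vesicle_volume_per_az,
            clustering_fraction = clustering_fraction,
            cluster_radius = cluster_radius,
            ctb_label_efficiency = ctb_label_efficiency,
            cell_body_count = cell_body_count,
            cell_body_radius = cell_body_radius,
            background_label_rate = background_label_rate,
            noise_sd = noise_sd,
            edge_precision_nm = edge_precision_nm,
            seed = as.integer(seed))
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  dens <- c(p$density_sAZ_eyeA, p$density_sAZ_eyeB,
            p$density_mAZ_eyeA, p$density_mAZ_eyeB)
  stopifnot(all(dens >= 0),
            abs(sum(p$az_count_pmf) - 1) < 1e-8,
            all(names(p$az_count_pmf) %in% c("2", "3", "4")),
            p$clustering_fraction >= 0, p$clustering_fraction <= 1,
            p$ctb_label_efficiency >= 0, p$ctb_label_efficiency <= 1,
            p$vesicle_volume_per_az > 0,
            p$background_label_rate >= 0, p$noise_sd >= 0)
  invisible(p)
}

# radius (nm) of a sphere with volume v um^3
sphere_radius_nm <- function(v_um3) (3 * v_um3 * 1e9 / (4 * pi))^(1 / 3)

#' Generate a ground-truth scene
#'
#' Draws input counts per class and eye as Poisson variates at the requested
#' densities over the field's physical volume, places vesicle clusters with a
#' hard-core minimum separation (sequential rejection sampling), places the
#' requested fraction of sAZ synapses within `cluster_radius` of a like-eye
#' mAZ input, puts each active zone on the surface of its ellipsoidal vesicle
#' cluster with a Homer1 partner 50-150 nm outside it, and assigns CTB labels
#' to eye-A inputs with probability `ctb_label_efficiency`.
#'
#' Inputs are kept away from the volume faces so that planted structures are
#' not removed by the downstream edge filter; cell bodies and background
#' labels may fall anywhere.
#'
#' @param params a [scene_params()].
#' @param geometry an [imaging_geometry()].
#' @return A list of class `gt_scene` with elements `inputs` (one row per
#'   input: id, class, eye, ctb, centroid nm, az_count, vesicle_volume um^3,
#'   ellipsoid semi-axes nm), `azs` (one row per active zone with its Homer1
#'   partner position), `cell_bodies`, `background`, `params`, `geometry`.
#' @export
generate_scene <- function(params, geometry) {
  validate_scene_params(params)
  stopifnot(inherits(geometry, "imaging_geometry"))
  set.seed(params$seed)

  sp <- geom_spacing(geometry)
  ext <- geometry$shape * sp                      # field extent, nm
  vol_um3 <- physical_volume_um3(geometry)

  # expected counts
  lam <- c(sAZ_A = params$density_sAZ_eyeA, sAZ_B = params$density_sAZ_eyeB,
           mAZ_A = params$density_mAZ_eyeA, mAZ_B = params$density_mAZ_eyeB) *
    vol_um3
  counts <- stats::rpois(4, lam)
  names(counts) <- names(lam)

  # hard-core separation: largest cluster radius + clearance for AZ/Homer
  # structures and the watershed-safe 200 nm gap
  r_max <- sphere_radius_nm(4 * params$vesicle_volume_per_az)
  min_sep <- 2 * r_max + 500                      # center-to-center, nm
  margin <- r_max + 450                           # from volume faces, nm
  lo <- rep(margin, 3)
  hi <- ext - margin
  n_inputs <- sum(counts)
  if (n_inputs > 0) {
    if (any(hi <= lo)) stop("geometry too small for the requested blob scale")
    place_vol <- prod(hi - lo) / 1e9              # um^3
    # hard-sphere jamming bound: sequential placement is hopeless beyond this
    if (n_inputs * (4 / 3) * pi * (min_sep / 2e3)^3 > place_vol)
      stop("overcrowded scene")
  }

  # cell bodies (uniform over the field)
  ncb <- params$cell_body_count
  cell_bodies <- data.frame(x = stats::runif(ncb, 0, ext[1]),
                            y = stats::runif(ncb, 0, ext[2]),
                            z = stats::runif(ncb, 0, ext[3]),
                            radius_nm = rep(params$cell_body_radius * 1e3, ncb))

  cb_clear <- function(p) {
    if (ncb == 0) return(TRUE)
    d <- sqrt((cell_bodies$x - p[1])^2 + (cell_bodies$y - p[2])^2 +
                (cell_bodies$z - p[3])^2)
    # clearance covers the AZ/Homer halo and the smoothed cell-body margin
    all(d > cell_bodies$radius_nm + r_max + 800)
  }

  placed <- matrix(numeric(0), ncol = 3)
  placed_r <- numeric(0)
  try_place <- function(sampler, r_self, max_tries = 2000L) {
    for (i in seq_len(max_tries)) {
      p <- sampler()
      if (any(p < lo) || any(p > hi)) next
      if (!cb_clear(p)) next
      if (nrow(placed) > 0) {
        d <- sqrt(colSums((t(placed) - p)^2))
        if (any(d < placed_r + r_self + 500)) next
      }
      return(p)
    }
    stop("overcrowded scene")
  }

  rows <- list()
  add_input <- function(class, eye, center, az_count) {
    v <- az_count * params$vesicle_volume_per_az
    r <- sphere_radius_nm(v)
    # mild axis-aligned eccentricity, volume preserved exactly
    f <- exp(stats::runif(2, log(0.85), log(1.18)))
    semi <- c(r * f[1], r * f[2], r / (f[1] * f[2]))
    placed <<- rbind(placed, center)
    placed_r <<- c(placed_r, max(semi))
    rows[[length(rows) + 1]] <<- data.frame(
      class = class, eye = eye, x = center[1], y = center[2], z = center[3],
      az_count = az_count, vesicle_volume = v,
      a = semi[1], b = semi[2], c = semi[3])
  }

  unif_sampler <- function() stats::runif(3, lo, hi)

  # mAZ inputs first (anchors for clustered sAZ placement)
  az_vals <- as.integer(names(params$az_count_pmf))
  for (eye in c("A", "B")) {
    n <- counts[paste0("mAZ_", eye)]
    for (i in seq_len(n)) {
      ac <- sample(az_vals, 1, prob = params$az_count_pmf)
      add_input("mAZ", eye, try_place(unif_sampler, sphere_radius_nm(
        ac * params$vesicle_volume_per_az)), ac)
    }
  }

  r_sAZ <- sphere_radius_nm(params$vesicle_volume_per_az)
  for (eye in c("A", "B")) {
    n <- counts[paste0("sAZ_", eye)]
    if (n == 0) next
    df <- if (length(rows)) do.call(rbind, rows) else NULL
    anchors <- if (is.null(df)) df else
      df[df$class == "mAZ" & df$eye == eye, , drop = FALSE]
    has_anchor <- !is.null(anchors) && nrow(anchors) > 0
    for (i in seq_len(n)) {
      clustered <- has_anchor && stats::runif(1) < params$clustering_fraction
      if (clustered) {
        sampler <- function() {
          a <- anchors[sample.int(nrow(anchors), 1), ]
          r_anchor <- max(a$a, a$b, a$c)
          dmin <- r_anchor + r_sAZ + 550
          dmax <- r_anchor + params$cluster_radius * 1e3
          if (dmax <= dmin) dmax <- dmin + 1
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          c(a$x, a$y, a$z) + u * stats::runif(1, dmin, dmax)
        }
        center <- tryCatch(try_place(sampler, r_sAZ, 400L), error = function(e) NULL)
        if (is.null(center)) center <- try_place(unif_sampler, r_sAZ)
      } else {
        center <- try_place(unif_sampler, r_sAZ)
      }
      add_input("sAZ", eye, center, 1L)
    }
  }

  inputs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(0), eye = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0), az_count = integer(0),
               vesicle_volume = numeric(0), a = numeric(0), b = numeric(0),
               c = numeric(0))
  if (nrow(inputs)) {
    inputs$id <- seq_len(nrow(inputs))
    inputs$ctb <- ifelse(inputs$eye == "A",
                         stats::runif(nrow(inputs)) < params$ctb_label_efficiency,
                         FALSE)
    inputs <- inputs[, c("id", "class", "eye", "ctb", "x", "y", "z",
                         "az_count", "vesicle_volume", "a", "b", "c")]
  } else {
    inputs$id <- integer(0)
    inputs$ctb <- logical(0)
  }

  # active zones on each cluster surface, with apposed Homer1 partners
  azs <- place_active_zones(inputs)

  bg <- list()
  for (ch in c("homer1", "bassoon", "vglut2", "ctb")) {
    nb <- stats::rpois(1, params$background_label_rate * vol_um3)
    if (nb > 0)
      bg[[ch]] <- data.frame(channel = ch,
                             x = stats::runif(nb, 0, ext[1]),
                             y = stats::runif(nb, 0, ext[2]),
                             z = stats::runif(nb, 0, ext[3]))
  }
  background <- if (length(bg)) do.call(rbind, bg) else
    data.frame(channel = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0))
  rownames(background) <- NULL

  # region the tracer-filled neuropil backdrop occupies (bounds all inputs)
  neuropil_extent <- rbind(lo = pmax(lo - 400, 0), hi = pmin(hi + 400, ext))

  structure(list(inputs = inputs, azs = azs, cell_bodies = cell_bodies,
                 background = background, neuropil_extent = neuropil_extent,
                 params = params, geometry = geometry),
            class = "gt_scene")
}

# AZ centroids sit 20 nm outside the ellipsoid surface along well-separated
# directions; each Homer1 partner is 50-150 nm further out along a jittered
# outward direction, keeping the pair inside the 140-nm association shell.
place_active_zones <- function(inputs) {
  out <- list()
  for (i in seq_len(nrow(inputs))) {
    inp <- inputs[i, ]
    k <- inp$az_count
    dirs <- matrix(0, 0, 3)
    tries <- 0
    while (nrow(dirs) < k && tries < 500) {
      tries <- tries + 1
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      if (nrow(dirs) == 0 || all(dirs %*% u < cos(80 * pi / 180)))
        dirs <- rbind(dirs, u)
    }
    while (nrow(dirs) < k) {  # degenerate fallback: relax the angle rule
      u <- stats::rnorm(3)
      dirs <- rbind(dirs, u / sqrt(sum(u^2)))
    }
    for (j in seq_len(k)) {
      u <- dirs[j, ]
      r_surf <- 1 / sqrt((u[1] / inp$a)^2 + (u[2] / inp$b)^2 + (u[3] / inp$c)^2)
      az <- c(inp$x, inp$y, inp$z) + u * (r_surf + 20)
      w <- u + stats::rnorm(3, 0, 0.25)
      w <- w / sqrt(sum(w^2))
      if (sum(w * u) < 0) w <- -w
      hom <- az + w * stats::runif(1, 50, 150)
      out[[length(out) + 1]] <- data.frame(
        input_id = inp$id, az_index = j,
        x = az[1], y = az[2], z = az[3],
        hx = hom[1], hy = hom[2], hz = hom[3])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(input_id = integer(0), az_index = integer(0), x = numeric(0),
               y = numeric(0), z = numeric(0), hx = numeric(0),
               hy = numeric(0), hz = numeric(0))
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf("ground-truth scene: %d inputs (%d mAZ, %d sAZ), %d cell bodies, %d background labels\n",
              nrow(x$inputs), sum(x$inputs$class == "mAZ"),
              sum(x$inputs$class == "sAZ"), nrow(x$cell_bodies),
              nrow(x$background)))
  invisible(x)
}

#' Export ground truth to CSV and JSON
#' @param scene a [generate_scene()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(scene$inputs, file.path(dir, "ground_truth_inputs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(inputs = scene$inputs, azs = scene$azs,
         cell_bodies = scene$cell_bodies, background = scene$background),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- rendering -------------------------------------------------------------

# patch covered by an axis-aligned ellipsoid: voxel index ranges plus the
# in-patch mask of covered voxels (assigned by the caller to avoid copying
# the full channel array per stamp)
patch_ellipsoid <- function(dm, center, semi, geometry) {
  sp <- geom_spacing(geometry)
  rng <- lapply(1:3, function(a) {
    i0 <- max(1L, floor((center[a] - semi[a]) / sp[a]))
    i1 <- min(dm[a], ceiling((center[a] + semi[a]) / sp[a] + 1))
    if (i0 > i1) return(integer(0))
    i0:i1
  })
  if (any(lengths(rng) == 0)) return(NULL)
  dx2 <- (((rng[[1]] - 0.5) * sp[1] - center[1]) / semi[1])^2
  dy2 <- (((rng[[2]] - 0.5) * sp[2] - center[2]) / semi[2])^2
  dz2 <- (((rng[[3]] - 0.5) * sp[3] - center[3]) / semi[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  list(rng = rng, inside = q <= 1)
}

stamp_ellipsoid_inplace <- function(arr, center, semi, geometry, value) {
  p <- patch_ellipsoid(dim(arr), center, semi, geometry)
  if (is.null(p)) return(arr)
  sub <- arr[p$rng[[1]], p$rng[[2]], p$rng[[3]], drop = FALSE]
  sub[p$inside] <- pmax(sub[p$inside], value)
  arr[p$rng[[1]], p$rng[[2]], p$rng[[3]]] <- sub
  arr
}

# Gaussian punctum patch, thresholded at cutoff_frac * amp; keep_prob < 1
# renders a sparse speckled punctum (low signal density)
patch_gaussian <- function(dm, center, sigma, amp, geometry,
                           cutoff_frac = 0.25, keep_prob = 1) {
  sp <- geom_spacing(geometry)
  rad <- sigma * sqrt(-2 * log(cutoff_frac))
  rng <- lapply(1:3, function(a) {
    i0 <- max(1L, floor((center[a] - rad[a]) / sp[a]))
    i1 <- min(dm[a], ceiling((center[a] + rad[a]) / sp[a] + 1))
    if (i0 > i1) return(integer(0))
    i0:i1
  })
  if (any(lengths(rng) == 0)) return(NULL)
  gx <- (((rng[[1]] - 0.5) * sp[1] - center[1]) / sigma[1])^2
  gy <- (((rng[[2]] - 0.5) * sp[2] - center[2]) / sigma[2])^2
  gz <- (((rng[[3]] - 0.5) * sp[3] - center[3]) / sigma[3])^2
  q <- outer(outer(gx, gy, "+"), gz, "+")
  val <- amp * exp(-0.5 * q)
  val[val < cutoff_frac * amp] <- 0
  if (keep_prob < 1) val[stats::runif(length(val)) > keep_prob] <- 0
  list(rng = rng, values = val)
}

#' Render a ground-truth scene as a four-channel voxel volume
#'
#' Vesicle clusters become contiguous suprathreshold VGluT2 ellipsoids of the
#' planted physical volume; each active zone a compact Bassoon punctum on the
#' cluster surface; each Homer1 punctum apposed to exactly one active zone;
#' CTB is rendered co-extensive with VGluT2 for tracer-labeled inputs; cell
#' bodies are large bright blobs in the Homer1 and Bassoon channels; background
#' labels are small, dim, speckled puncta well below the synaptic population's
#' volume and signal-density scale. Rendering is deterministic given the scene
#' and its seed.
#'
#' @param scene a [generate_scene()] result.
#' @param geometry an [imaging_geometry()]; defaults to the scene's.
#' @param params a [scene_params()]; defaults to the scene's.
#' @return an [multichannel_volume()] with channels homer1, bassoon, vglut2,
#'   ctb.
#' @export
render_volume <- function(scene, geometry = scene$geometry,
                          params = scene$params) {
  set.seed(params$seed + 1L)
  dm <- geometry$shape
  ch <- list(homer1 = array(0, dm), bassoon = array(0, dm),
             vglut2 = array(0, dm), ctb = array(0, dm))
  az_sigma <- c(90, 90, 70)

  # axonal CTB backdrop: the anterograde tracer sparsely labels axons
  # throughout the projection's neuropil (rendered as single-molecule-like
  # speckle), which downstream defines the analysis region via its
  # conventional-image counterpart
  if (!is.null(scene$neuropil_extent) && nrow(scene$inputs) > 0) {
    i0 <- nm_to_voxel(scene$neuropil_extent["lo", , drop = FALSE], geometry)
    i1 <- nm_to_voxel(scene$neuropil_extent["hi", , drop = FALSE], geometry)
    box <- ch$ctb[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    # speckle at a fixed volumetric density so the backdrop looks the same
    # at any voxel size; dense enough that its conventional-image response
    # sits well above the background class of the lower Otsu threshold
    box_vol <- length(box) * voxel_volume_um3(geometry)
    n_speck <- stats::rpois(1, 400 * box_vol)
    hit <- sample.int(length(box), min(n_speck, length(box)))
    box[hit] <- pmax(box[hit], 140)
    ch$ctb[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- box
  }

  # channels are kept as locally-owned arrays during stamping so patch
  # assignments modify them in place (no full-volume copy per structure)
  vg <- ch$vglut2; bs <- ch$bassoon; hm <- ch$homer1; ct <- ch$ctb
  ch <- NULL
  apply_patch <- function(arr, p) {
    if (is.null(p)) return(arr)
    if (!is.null(p$inside)) patch <- p$inside * p$value
    else patch <- p$values
    lo <- vapply(p$rng, function(r) r[1], 0L)
    cpp_patch_max(arr, dim(arr), as.integer(lo), as.numeric(patch),
                  as.integer(vapply(p$rng, length, 0L)))
    arr
  }
  skin <- if (is.null(params$edge_precision_nm)) 0 else params$edge_precision_nm
  for (i in seq_len(nrow(scene$inputs))) {
    inp <- scene$inputs[i, ]
    cen <- c(inp$x, inp$y, inp$z)
    semi <- c(inp$a, inp$b, inp$c) + skin
    p <- patch_ellipsoid(dm, cen, semi, geometry)
    if (!is.null(p)) p$value <- 200
    vg <- apply_patch(vg, p)
    if (isTRUE(inp$ctb)) {
      if (!is.null(p)) p$value <- 180
      ct <- apply_patch(ct, p)
    }
  }
  for (j in seq_len(nrow(scene$azs))) {
    az <- scene$azs[j, ]
    bs <- apply_patch(bs, patch_gaussian(dm, c(az$x, az$y, az$z), az_sigma,
                                         230, geometry))
    hm <- apply_patch(hm, patch_gaussian(dm, c(az$hx, az$hy, az$hz), az_sigma,
                                         230, geometry))
  }
  # cell bodies carry dense broadband non-specific label (single-molecule
  # speckle over a wide intensity range), not a flat plateau; a flat plateau
  # would put a section-dominating delta into the intensity histogram and
  # distort the per-section normalization
  for (b in seq_len(nrow(scene$cell_bodies))) {
    cbod <- scene$cell_bodies[b, ]
    p <- patch_ellipsoid(dm, c(cbod$x, cbod$y, cbod$z),
                         rep(cbod$radius_nm, 3), geometry)
    if (is.null(p)) next
    for (chn in c("hm", "bs")) {
      val <- numeric(length(p$inside))
      keep <- p$inside & stats::runif(length(val)) < 0.85
      val[keep] <- stats::runif(sum(keep), 40, 230)
      q <- list(rng = p$rng, values = array(val, dim(p$inside)))
      if (chn == "hm") hm <- apply_patch(hm, q) else bs <- apply_patch(bs, q)
    }
  }
  for (gi in seq_len(nrow(scene$background))) {
    bgl <- scene$background[gi, ]
    p <- patch_gaussian(dm, c(bgl$x, bgl$y, bgl$z), c(60, 60, 70), 110,
                        geometry, cutoff_frac = 0.35, keep_prob = 0.55)
    if (bgl$channel == "vglut2") vg <- apply_patch(vg, p)
    else if (bgl$channel == "bassoon") bs <- apply_patch(bs, p)
    else if (bgl$channel == "homer1") hm <- apply_patch(hm, p)
    else ct <- apply_patch(ct, p)
  }
  ch <- list(homer1 = hm, bassoon = bs, vglut2 = vg, ctb = ct)
  if (params$noise_sd > 0) {
    n <- prod(dm)
    for (nm in names(ch)) {
      hit <- which(stats::runif(n) < 0.03)
      if (length(hit))
        ch[[nm]][hit] <- ch[[nm]][hit] +
          abs(stats::rnorm(length(hit), 0, params$noise_sd))
    }
  }
  maxi <- 2^geometry$bit_depth - 1
  for (nm in names(ch)) ch[[nm]] <- round(pmin(pmax(ch[[nm]], 0), maxi))
  multichannel_volume(geometry, ch)
}
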