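#' Configuration of the synthetic heart phantom
#'
#' The phantom emulates the statistical and geometric structure that the
#' quantification pipeline measures on a cleared, immunolabeled heart after
#' ischemia/reperfusion: an autofluorescent myocardial shell (outer ellipsoid
#' minus a left-ventricular lumen whose apical pole stays lumen-free), a
#' capillary network channel at a target vessel length density with an infarct
#' void and a denser-branched/shorter-segment "curly" rim, a perfusion channel
#' with an unperfused wedge (the area at risk), and a neutrophil spot channel
#' enriched in a shell around the infarct border. Noise is Poisson shot noise
#' plus Gaussian read noise, quantized to 16 bit. All randomness is fixed by
#' `seed`.
#'
#' @param seed Integer seed fixing all randomness.
#' @param dim Grid size (nx, ny, nz) in voxels.
#' @param geometry A [voxel_geometry()] (default: 3.25 µm lateral, 10 µm z).
#' @param outer_semi_um,lumen_semi_um Ellipsoid semi-axes, µm (heart wall and
#'   LV lumen). `NULL` scales them to the grid.
#' @param lumen_shift_um Axial shift of the lumen towards the base, µm.
#' @param target_vld Capillary length density target, mm/mm³.
#' @param ibd_um Interbranch-distance target, µm.
#' @param capillary_radius_um Vessel tube radius, µm.
#' @param vessel_peak Peak CD31 intensity (grey values).
#' @param aar_fraction Area-at-risk wedge as a fraction of the heart mask.
#' @param aar_depth_frac Apical fraction of the heart's axial extent the wedge
#'   may occupy.
#' @param infarct_fraction_of_aar Infarct-void volume as a fraction of AAR.
#' @param curly_width_um Width of the curly rim around the infarct, µm.
#' @param curly_vld_mult,curly_ibd_mult Curly-zone multipliers (< 1).
#' @param n_spots Number of neutrophil spots in the heart.
#' @param spot_shell_enrichment Sampling-weight multiplier inside the ±30 µm
#'   infarct-border shell (1 = uniform; Inf = shell-bound).
#' @param spot_shell_halfwidth_um Shell half-width, µm.
#' @param spot_fwhm_xy_um,spot_fwhm_z_um Rendered spot FWHM, µm.
#' @param spot_peak_range Peak-intensity band the spots are drawn from.
#' @param spot_min_sep_um Minimum spot separation, µm (0 = none).
#' @param background_level,myo_level Autofluorescence grey levels outside /
#'   inside the myocardium.
#' @param texture_sd,texture_sigma_um Smoothed-noise myocardial texture.
#' @param rim_amplitude,rim_width_um Optional bright edge rim (unbleached-
#'   specimen artifact); amplitude 0 = bleached, homogeneous.
#' @param fitc_level Perfusion-channel grey level in perfused myocardium.
#' @param poisson_gain Photon gain: shot noise is `rpois(I/gain) * gain`.
#' @param read_sigma Gaussian read-noise sd, grey values.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(seed = 1, dim = c(256, 256, 64),
                           geometry = voxel_geometry(3.25, 10, 1.22),
                           outer_semi_um = NULL, lumen_semi_um = NULL,
                           lumen_shift_um = NULL,
                           target_vld = 2900, ibd_um = 65,
                           capillary_radius_um = 2.5, vessel_peak = 20000,
                           aar_fraction = 0.29, aar_depth_frac = 0.8,
                           infarct_fraction_of_aar = 0.3,
                           curly_width_um = 60,
                           curly_vld_mult = 1771 / 2946,
                           curly_ibd_mult = 51 / 67,
                           n_spots = 150, spot_shell_enrichment = 6,
                           spot_shell_halfwidth_um = 30,
                           spot_fwhm_xy_um = 7, spot_fwhm_z_um = 14,
                           spot_peak_range = c(15000, 25000),
                           spot_min_sep_um = 14,
                           background_level = 300, myo_level = 8000,
                           texture_sd = 1200, texture_sigma_um = 10,
                           rim_amplitude = 0, rim_width_um = 10,
                           fitc_level = 12000,
                           poisson_gain = 20, read_sigma = 100) {
  sp <- voxel_spacing(geometry)
  extent <- dim * sp
  if (is.null(outer_semi_um)) outer_semi_um <- 0.44 * extent
  if (is.null(lumen_semi_um)) lumen_semi_um <- c(0.42, 0.42, 0.62) * outer_semi_um
  if (is.null(lumen_shift_um)) lumen_shift_um <- 0.30 * outer_semi_um[3]
  cfg <- as.list(environment())
  stopifnot(all(dim >= 1), target_vld >= 0, n_spots >= 0,
            aar_fraction >= 0, aar_fraction < 1)
  structure(cfg, class = "phantom_config")
}

#' Ellipsoid voxel mask
#' @param dim Grid size (nx, ny, nz).
#' @param geometry A [voxel_geometry()].
#' @param center_um,semi_um Centre and semi-axes, µm.
#' @return Logical 3D array.
#' @export
ellipsoid_mask <- function(dim, geometry, center_um, semi_um) {
  sp <- voxel_spacing(geometry)
  ax <- ((seq_len(dim[1]) - 1) * sp[1] - center_um[1]) / semi_um[1]
  ay <- ((seq_len(dim[2]) - 1) * sp[2] - center_um[2]) / semi_um[2]
  az <- ((seq_len(dim[3]) - 1) * sp[3] - center_um[3]) / semi_um[3]
  outer(outer(ax^2, ay^2, "+"), az^2, "+") <= 1
}

# heart, lumen and derived region masks for a config
phantom_masks <- function(cfg) {
  d <- cfg$dim
  sp <- voxel_spacing(cfg$geometry)
  extent <- d * sp
  centre <- extent / 2
  outer_mask <- ellipsoid_mask(d, cfg$geometry, centre, cfg$outer_semi_um)
  lumen_centre <- centre + c(0, 0, cfg$lumen_shift_um)
  lumen <- ellipsoid_mask(d, cfg$geometry, lumen_centre, cfg$lumen_semi_um) &
    outer_mask
  heart <- outer_mask & !lumen

  # AAR wedge: angular sector about the long (z) axis, apical portion;
  # angular extent solved to hit the target fraction of the heart mask
  aar <- array(FALSE, dim = d)
  if (cfg$aar_fraction > 0) {
    xs <- (seq_len(d[1]) - 1) * sp[1] - centre[1]
    ys <- (seq_len(d[2]) - 1) * sp[2] - centre[2]
    ang <- outer(xs, ys, function(x, y) atan2(y, x))
    hz <- range(which(apply(heart, 3, any)))
    z_max <- hz[1] + cfg$aar_depth_frac * (hz[2] - hz[1])
    in_depth <- heart
    if (z_max < d[3]) in_depth[, , seq_len(d[3]) > z_max] <- FALSE
    n_heart <- sum(heart)
    frac_of <- function(half_width) {
      wedge <- abs(ang) <= half_width  # wedge centred on +x
      sum(in_depth & array(wedge, dim = d)) / n_heart
    }
    lo <- 0; hi <- pi
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (frac_of(mid) < cfg$aar_fraction) lo <- mid else hi <- mid
    }
    aar <- in_depth & array(abs(ang) <= (lo + hi) / 2, dim = d)
  }

  # infarct void: ellipsoid at the AAR centroid, scaled to the target
  # fraction of the AAR volume
  infarct <- array(FALSE, dim = d)
  curly <- array(FALSE, dim = d)
  if (any(aar) && cfg$infarct_fraction_of_aar > 0) {
    ci <- arrayInd(which(aar), d)
    cen <- (colMeans(ci) - 1) * sp
    v_target <- cfg$infarct_fraction_of_aar * sum(aar) * prod(sp)
    r0 <- (3 * v_target / (4 * pi))^(1 / 3)
    semi <- r0 * c(1.25, 1.25, 0.75)
    semi <- semi * (v_target / (4 / 3 * pi * prod(semi)))^(1 / 3)
    for (i in 1:12) {
      infarct <- ellipsoid_mask(d, cfg$geometry, cen, semi) & aar
      got <- sum(infarct) * prod(sp)
      if (abs(got - v_target) / v_target < 0.02 || got == 0) break
      semi <- semi * (v_target / max(got, 1))^(1 / 3)
    }
    if (cfg$curly_width_um > 0)
      curly <- binary_dilate(infarct, cfg$curly_width_um, sp) & aar & !infarct
  }
  list(outer = outer_mask, heart = heart, lumen = lumen, aar = aar,
       infarct = infarct, curly = curly)
}

#' Rasterize a vessel graph into an intensity channel
#'
#' Renders every centerline polyline as a tube of the given radius with
#' anti-aliased (subsampled-coverage) intensity, takes the per-voxel maximum
#' over tubes, zeroes any voxels inside `void_mask` (a CD31-negative infarct
#' body), and quantizes to 16 bit.
#'
#' @param graph A [vessel_graph()].
#' @param geometry A [voxel_geometry()].
#' @param dim Output grid size.
#' @param radius_um Tube radius, µm (sub-voxel radii render as dimmer tubes).
#' @param void_mask Optional logical array zeroed in the output.
#' @param peak Peak intensity (grey values).
#' @param nsub Subsamples per axis for the coverage estimate.
#' @return A 16-bit [volume_image()] labelled "CD31".
#' @export
rasterize_vessels <- function(graph, geometry, dim, radius_um = 2.5,
                              void_mask = NULL, peak = 20000, nsub = 2) {
  sp <- voxel_spacing(geometry)
  segs <- do.call(rbind, lapply(graph$paths, function(p) {
    if (nrow(p) < 2) return(NULL)
    cbind(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE], radius_um)
  }))
  if (is.null(segs)) {
    vox <- array(0, dim = dim)
  } else {
    cov <- cc_raster_tubes(as.integer(dim), sp, segs, as.integer(nsub))
    vox <- array(cov, dim = dim) * peak
  }
  if (!is.null(void_mask)) vox[void_mask] <- 0
  volume_image(round(pmin(vox, 65535)), "CD31", geometry)
}

#' Place immune-cell spots with border-shell enrichment
#'
#' Draws spot centres inside the heart mask with sampling weight
#' `shell_enrichment` inside the ±`shell_halfwidth_um` shell around the border
#' of `border_mask` (weight 1 elsewhere; `Inf` confines all spots to the
#' shell), then renders each spot as an anisotropic Gaussian with the given
#' FWHMs and a peak drawn uniformly from `peak_range`.
#'
#' @param heart_mask Logical 3D array.
#' @param geometry A [voxel_geometry()].
#' @param n_spots Number of spots.
#' @param border_mask Region whose border defines the shell (e.g. infarct);
#'   `NULL` disables enrichment.
#' @param shell_enrichment Weight multiplier in the shell.
#' @param shell_halfwidth_um Shell half-width, µm.
#' @param fwhm_xy_um,fwhm_z_um Rendered FWHMs, µm.
#' @param peak_range Peak-intensity band.
#' @param min_sep_um Minimum pairwise separation, µm.
#' @param channel Channel label for the rendered volume.
#' @return List with `spots` (data frame x_um, y_um, z_um, peak) and
#'   `channel` (a float [volume_image()], noise-free).
#' @export
place_spots <- function(heart_mask, geometry, n_spots = 150,
                        border_mask = NULL, shell_enrichment = 1,
                        shell_halfwidth_um = 30,
                        fwhm_xy_um = 7, fwhm_z_um = 14,
                        peak_range = c(15000, 25000), min_sep_um = 0,
                        channel = "Ly6G") {
  d <- dim(heart_mask)
  sp <- voxel_spacing(geometry)
  vox <- array(0, dim = d)
  if (n_spots == 0) {
    return(list(spots = data.frame(x_um = numeric(), y_um = numeric(),
                                   z_um = numeric(), peak = numeric()),
                channel = volume_image(vox, channel, geometry, float = TRUE)))
  }
  idx <- which(heart_mask)
  if (!length(idx)) stop("heart mask is empty")
  w <- rep(1, length(idx))
  if (!is.null(border_mask) && any(border_mask) && shell_enrichment != 1) {
    sdist <- signed_border_distance(border_mask, sp)
    in_shell <- abs(sdist[idx]) <= shell_halfwidth_um
    if (is.infinite(shell_enrichment)) {
      w[!in_shell] <- 0
    } else {
      w[in_shell] <- shell_enrichment
    }
    if (!any(w > 0)) stop("enrichment shell does not intersect the heart mask")
  }
  # feasibility: spots at min separation must fit into the admissible volume
  if (min_sep_um > 0) {
    v_adm <- sum(w > 0) * prod(sp)
    v_need <- n_spots * 4 / 3 * pi * (min_sep_um / 2)^3
    if (v_need > 0.25 * v_adm)
      stop(sprintf("cannot place %d spots at %.0f um separation in %.2g um3",
                   n_spots, min_sep_um, v_adm))
  }
  coords <- arrayInd(idx, d)
  pos_all <- sweep(coords - 1, 2, sp, "*")
  chosen <- matrix(numeric(), ncol = 3)
  tries <- 0
  while (nrow(chosen) < n_spots && tries < 50 * n_spots) {
    pick <- sample.int(length(idx), 1, prob = w)
    p <- pos_all[pick, ] + runif(3, -0.5, 0.5) * sp
    if (min_sep_um > 0 && nrow(chosen) &&
        min(sqrt(rowSums(sweep(chosen, 2, p)^2))) < min_sep_um) {
      tries <- tries + 1
      next
    }
    chosen <- rbind(chosen, p)
  }
  if (nrow(chosen) < n_spots)
    stop("could not satisfy the minimum spot separation; reduce n_spots")
  peaks <- runif(n_spots, peak_range[1], peak_range[2])

  # render anisotropic Gaussians in local windows
  sig <- c(fwhm_xy_um, fwhm_xy_um, fwhm_z_um) / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sig / sp)
  for (s in seq_len(n_spots)) {
    c_vox <- chosen[s, ] / sp + 1
    i0 <- pmax(floor(c_vox - half), 1)
    i1 <- pmin(ceiling(c_vox + half), d)
    xs <- (i0[1]:i1[1] - 1) * sp[1]
    ys <- (i0[2]:i1[2] - 1) * sp[2]
    zs <- (i0[3]:i1[3] - 1) * sp[3]
    gx <- exp(-(xs - chosen[s, 1])^2 / (2 * sig[1]^2))
    gy <- exp(-(ys - chosen[s, 2])^2 / (2 * sig[2]^2))
    gz <- exp(-(zs - chosen[s, 3])^2 / (2 * sig[3]^2))
    blob <- peaks[s] * outer(outer(gx, gy), gz)
    win <- vox[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    vox[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- pmax(win, blob)
  }
  list(spots = data.frame(x_um = chosen[, 1], y_um = chosen[, 2],
                          z_um = chosen[, 3], peak = peaks),
       channel = volume_image(vox, channel, geometry, float = TRUE))
}

# Poisson shot noise + Gaussian read noise, 16-bit quantization
add_noise <- function(vox, gain, read_sigma) {
  n <- length(vox)
  noisy <- rpois(n, pmax(vox, 0) / gain) * gain +
    rnorm(n, 0, read_sigma)
  array(pmin(pmax(round(noisy), 0), 65535), dim = dim(vox))
}

#' Generate the full multi-channel heart phantom with ground truth
#'
#' Produces the four channels the pipeline consumes — autofluorescence (shell
#' texture, optional edge rim), CD31 (capillary network with infarct void and
#' curly rim), FITC (perfusion everywhere except the AAR wedge) and Ly6G
#' (border-enriched spots) — together with the generator-side truth: region
#' masks and volumes, the true centerline graph and total length, spot
#' positions, and the config echo. Identical seeds give bit-identical output.
#'
#' @param config A [phantom_config()].
#' @return List with `channels` (named [volume_image()]s), `truth` (masks,
#'   network, spots, volumes) and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  cfg <- config
  set.seed(cfg$seed)
  d <- cfg$dim
  sp <- voxel_spacing(cfg$geometry)
  masks <- phantom_masks(cfg)

  # capillaries follow a circumferential fiber field with an axial pitch,
  # as myocardial fibers wrap the ventricle
  centre <- d * sp / 2
  fiber_circ <- function(p) {
    dx <- p[, 1] - centre[1]; dy <- p[, 2] - centre[2]
    r <- pmax(sqrt(dx^2 + dy^2), 1e-9)
    cbind(-dy / r, dx / r, 0.3)
  }
  network <- generate_vessel_network(
    masks$heart, cfg$geometry, target_vld = cfg$target_vld, ibd_um = cfg$ibd_um,
    curly_mask = if (any(masks$curly)) masks$curly else NULL,
    curly_vld_mult = cfg$curly_vld_mult, curly_ibd_mult = cfg$curly_ibd_mult,
    exclude_mask = if (any(masks$infarct)) masks$infarct else NULL,
    fiber = fiber_circ)

  cd31 <- rasterize_vessels(network, cfg$geometry, d,
                            radius_um = cfg$capillary_radius_um,
                            void_mask = masks$infarct, peak = cfg$vessel_peak)

  # autofluorescence: myocardial level + smoothed noise texture + edge rim
  auto <- array(cfg$background_level, dim = d)
  texture <- smooth3d(array(rnorm(prod(d)), dim = d),
                      cfg$texture_sigma_um / sp)
  texture <- texture / max(sd(texture), 1e-12) * cfg$texture_sd
  auto[masks$heart] <- cfg$myo_level + texture[masks$heart]
  if (cfg$rim_amplitude > 0) {
    rim <- masks$outer & !binary_erode(masks$outer, cfg$rim_width_um, sp)
    auto[rim & masks$heart] <- auto[rim & masks$heart] + cfg$rim_amplitude
  }

  # FITC perfusion: bright in perfused myocardium, dark in the AAR wedge
  fitc <- array(cfg$background_level, dim = d)
  fitc[masks$heart & !masks$aar] <- cfg$fitc_level

  spots <- place_spots(masks$heart, cfg$geometry, n_spots = cfg$n_spots,
                       border_mask = if (any(masks$infarct)) masks$infarct else NULL,
                       shell_enrichment = cfg$spot_shell_enrichment,
                       shell_halfwidth_um = cfg$spot_shell_halfwidth_um,
                       fwhm_xy_um = cfg$spot_fwhm_xy_um,
                       fwhm_z_um = cfg$spot_fwhm_z_um,
                       peak_range = cfg$spot_peak_range,
                       min_sep_um = cfg$spot_min_sep_um)

  noisy <- function(vox, label) {
    volume_image(add_noise(vox, cfg$poisson_gain, cfg$read_sigma),
                 label, cfg$geometry)
  }
  channels <- list(
    autofluorescence = noisy(auto, "autofluorescence"),
    CD31 = noisy(as_voxels(cd31), "CD31"),
    FITC = noisy(fitc, "FITC"),
    Ly6G = noisy(as_voxels(spots$channel), "Ly6G"))

  vol_mm3 <- function(m) sum(m) * prod(sp) / UM3_PER_MM3
  truth <- list(
    masks = masks[c("heart", "lumen", "aar", "infarct", "curly")],
    volumes_mm3 = vapply(masks[c("heart", "lumen", "aar", "infarct", "curly")],
                         vol_mm3, numeric(1)),
    network = network,
    total_length_mm = graph_total_length(network) / 1000,
    vld_truth = attr(network, "achieved_vld"),
    spots = spots$spots)
  list(channels = channels, truth = truth, config = cfg)
}

#' Export a phantom to disk (TIFF channels, mask TIFFs, truth JSON/CSV)
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(phantom$channels))
    write_stack(phantom$channels[[nm]], file.path(dir, paste0(nm, ".tif")))
  for (nm in names(phantom$truth$masks))
    write_mask(phantom$truth$masks[[nm]], file.path(dir, paste0("mask_", nm, ".tif")))
  write_geometry_sidecar(phantom$config$geometry, names(phantom$channels),
                         file.path(dir, "geometry.yaml"))
  utils::write.csv(phantom$truth$spots, file.path(dir, "truth_spots.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(volumes_mm3 = as.list(phantom$truth$volumes_mm3),
         total_length_mm = phantom$truth$total_length_mm,
         vld_truth = phantom$truth$vld_truth,
         seed = phantom$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
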