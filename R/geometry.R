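#' Voxel geometry of a light-sheet stack
#'
#' Physical sampling of a stack: lateral pixel size, axial plane spacing, and
#' the linear tissue-shrinkage correction factor applied at volume-reporting
#' stages. Defaults mirror whole-heart acquisition at 2x total magnification
#' (3.25 µm/pixel laterally, 10 µm between optical planes); shrinkage defaults
#' to 1 (no correction) and is typically set to 1.22 for ECi-cleared hearts.
#'
#' @param pixel_size_xy Lateral sampling, µm per pixel (> 0).
#' @param z_step Axial plane spacing, µm (> 0).
#' @param shrinkage_linear Per-axis linear correction factor (>= 1, or exactly
#'   1 for "no correction").
#' @return A `voxel_geometry` object.
#' @export
voxel_geometry <- function(pixel_size_xy = 3.25, z_step = 10,
                           shrinkage_linear = 1) {
  stopifnot(is.numeric(pixel_size_xy), pixel_size_xy > 0,
            is.numeric(z_step), z_step > 0,
            is.numeric(shrinkage_linear), shrinkage_linear > 0)
  if (shrinkage_linear < 1)
    warning("shrinkage_linear < 1: cleared tissue is expected to shrink, not swell")
  structure(list(pixel_size_xy = pixel_size_xy, z_step = z_step,
                 shrinkage_linear = shrinkage_linear),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %.3g x %.3g x %.3g um/voxel, shrinkage %.2f\n",
              x$pixel_size_xy, x$pixel_size_xy, x$z_step, x$shrinkage_linear))
  invisible(x)
}

#' Per-axis voxel spacing in µm
#' @param geometry A [voxel_geometry()].
#' @return Numeric length-3 vector (x, y, z) in µm.
#' @export
voxel_spacing <- function(geometry) {
  c(geometry$pixel_size_xy, geometry$pixel_size_xy, geometry$z_step)
}

#' Volume of one voxel
#' @param geometry A [voxel_geometry()].
#' @return Volume in µm³.
#' @export
voxel_volume_um3 <- function(geometry) prod(voxel_spacing(geometry))

UM3_PER_MM3 <- 1e9

#' Field of view of a camera chip at a given pixel size
#'
#' For a 2560 x 2160 chip at 3.25 µm/pixel the field of view is
#' 8.32 x 7.02 mm — large enough to image a whole mouse heart without tiling.
#'
#' @param n_pixels_x,n_pixels_y Chip size in pixels (positive integers).
#' @param pixel_size_xy µm per pixel.
#' @return List with `extent_x_mm`, `extent_y_mm` (rounded to 2 decimals) and
#'   the raw extents in µm (`extent_x_um`, `extent_y_um`).
#' @export
compute_fov <- function(n_pixels_x, n_pixels_y, pixel_size_xy) {
  if (n_pixels_x <= 0 || n_pixels_y <= 0 || pixel_size_xy <= 0)
    stop("pixel counts and pixel size must be positive")
  ex <- n_pixels_x * pixel_size_xy
  ey <- n_pixels_y * pixel_size_xy
  list(extent_x_mm = round(ex / 1000, 2), extent_y_mm = round(ey / 1000, 2),
       extent_x_um = ex, extent_y_um = ey)
}

#' Tissue shrinkage correction factors
#'
#' Clearing shrinks the specimen; comparing slice thickness before clearing
#' (naive) and at imaging (cleared) gives a linear shrinkage ratio. The
#' reporting chain rounds the ratio to 2 decimals before inverting, so
#' 1.9 mm -> 1.555 mm gives ratio 0.82 and linear factor 1.22; volumes are
#' corrected by the cube of the linear factor. The unrounded chain is returned
#' alongside.
#'
#' @param naive_thickness_mm Thickness before clearing, mm.
#' @param cleared_thickness_mm Thickness at imaging, mm.
#' @return List with `ratio`, `linear_factor`, `volume_factor` (printed,
#'   i.e. rounded chain) and `unrounded` (the same three without rounding).
#' @export
shrinkage_factor <- function(naive_thickness_mm, cleared_thickness_mm) {
  if (naive_thickness_mm <= 0 || cleared_thickness_mm <= 0)
    stop("thicknesses must be positive")
  if (cleared_thickness_mm > naive_thickness_mm)
    warning("cleared thickness exceeds naive thickness; expected shrinkage")
  ratio_raw <- cleared_thickness_mm / naive_thickness_mm
  ratio <- round(ratio_raw, 2)
  linear <- round(1 / ratio, 2)
  list(ratio = ratio, linear_factor = linear, volume_factor = linear^3,
       unrounded = list(ratio = ratio_raw, linear_factor = 1 / ratio_raw,
                        volume_factor = (1 / ratio_raw)^3))
}

#' Acquisition plan for a multi-channel stack
#'
#' @param z_depth_mm Stack depth, mm.
#' @param n_channels Number of channels acquired per plane.
#' @param illumination_time_ms Camera illumination time per exposure, ms.
#' @param n_dynamic_foci Number of dynamic-focus positions per plane.
#' @param n_laser_arms Number of illumination arms (left/right = 2).
#' @return An `acquisition_plan` object.
#' @export
acquisition_plan <- function(z_depth_mm, n_channels, illumination_time_ms,
                             n_dynamic_foci, n_laser_arms) {
  stopifnot(z_depth_mm > 0, illumination_time_ms > 0)
  if (n_channels < 1 || n_dynamic_foci < 1 || n_laser_arms < 1 ||
      any(c(n_channels, n_dynamic_foci, n_laser_arms) %% 1 != 0))
    stop("counts must be positive integers")
  structure(list(z_depth_mm = z_depth_mm, n_channels = n_channels,
                 illumination_time_ms = illumination_time_ms,
                 n_dynamic_foci = n_dynamic_foci, n_laser_arms = n_laser_arms),
            class = "acquisition_plan")
}

#' Plane counts and theoretical acquisition time
#'
#' A 6 mm deep stack at 10 µm z-spacing and 4 channels yields 600 planes per
#' channel, 2400 exposures; at 350 ms illumination with 8x dynamic focus on
#' both laser arms each plane takes 5.6 s, for a theoretical 3.73 h total.
#'
#' @param plan An [acquisition_plan()].
#' @param z_step_um Plane spacing, µm.
#' @return List with `planes_per_channel`, `total_planes`, `per_plane_time_s`
#'   and `total_time_h` (rounded to 2 decimals).
#' @export
plan_acquisition <- function(plan, z_step_um) {
  if (z_step_um <= 0) stop("z step must be positive")
  planes <- floor(plan$z_depth_mm * 1000 / z_step_um)
  total <- planes * plan$n_channels
  per_plane_s <- plan$illumination_time_ms / 1000 *
    plan$n_dynamic_foci * plan$n_laser_arms
  list(planes_per_channel = planes, total_planes = total,
       per_plane_time_s = per_plane_s,
       total_time_h = round(total * per_plane_s / 3600, 2))
}

#' Convert a physical Gaussian sigma to per-axis voxel sigmas
#' @param sigma_um Physical sigma, µm (>= 0).
#' @param geometry A [voxel_geometry()].
#' @return Numeric length-3 vector of sigmas in voxel units (x, y, z).
#' @export
physical_to_voxel_sigma <- function(sigma_um, geometry) {
  if (sigma_um < 0) stop("sigma must be non-negative")
  sigma_um / voxel_spacing(geometry)
}
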