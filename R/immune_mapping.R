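#' Detect immune-cell spots (anisotropic blob detection)
#'
#' Laplacian-of-Gaussian blob detection at a fixed physical scale matched to
#' the neutrophil diameter (7 µm laterally, 14 µm axially). The channel is
#' smoothed with per-axis sigmas `diameter / (2 sqrt(2 ln 2))`, the negated
#' Laplacian (physical units) is searched for local maxima within one spot
#' radius, and detections are kept if the raw peak voxel intensity lies
#' inside the band (inclusive; 4500–35000 grey values by default). Detections
#' closer than one spot radius to a stronger one are suppressed.
#'
#' @param channel A [volume_image()] or 3D array (16-bit spot channel).
#' @param diameter_xy_um,diameter_z_um Assumed spot diameter, µm.
#' @param band Inclusive peak-intensity band (grey values).
#' @param geometry Required for a bare array.
#' @return A data frame (class `spot_set`) with x_um, y_um, z_um, peak,
#'   response; detection parameters attached as attributes.
#' @export
detect_spots <- function(channel, diameter_xy_um = 7, diameter_z_um = 14,
                         band = c(4500, 35000), geometry = NULL) {
  geometry <- geom_of(channel, geometry)
  if (band[1] > band[2]) stop("intensity band is inverted")
  sp <- voxel_spacing(geometry)
  vox <- as_voxels(channel)
  storage.mode(vox) <- "double"
  d <- dim(vox)
  sig_um <- c(diameter_xy_um, diameter_xy_um, diameter_z_um) / (2 * sqrt(2 * log(2)))
  sm <- smooth3d(vox, sig_um / sp)
  lap <- array(0, dim = d)
  for (ax in 1:3) {
    k <- c(1, -2, 1) / sp[ax]^2
    lap <- lap + array(cc_convolve_axis(sm, d, k, ax - 1L), dim = d) * sig_um[ax]^2
  }
  resp <- -lap
  r_vox <- pmax(1L, as.integer(round(c(diameter_xy_um / 2, diameter_xy_um / 2,
                                       diameter_z_um / 2) / sp)))
  is_max <- array(cc_local_max(resp, d, r_vox[1], r_vox[2], r_vox[3]), dim = d)
  idx <- which(is_max & resp > 0)
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      peak = numeric(), response = numeric())
  params <- list(diameter_xy_um = diameter_xy_um, diameter_z_um = diameter_z_um,
                 band = band)
  if (!length(idx)) return(spot_set(empty, params))

  ci <- arrayInd(idx, d)
  # raw peak = maximum voxel in a 1-voxel neighbourhood of the maximum
  peak <- vapply(seq_len(nrow(ci)), function(r) {
    i0 <- pmax(ci[r, ] - 1, 1); i1 <- pmin(ci[r, ] + 1, d)
    max(vox[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]])
  }, numeric(1))
  keep <- peak >= band[1] & peak <= band[2]
  ci <- ci[keep, , drop = FALSE]
  peak <- peak[keep]
  rsp <- resp[idx][keep]
  if (!nrow(ci)) return(spot_set(empty, params))

  pos <- sweep(ci - 1, 2, sp, "*")
  # greedy minimum-separation suppression (one spot radius)
  ord <- order(rsp, decreasing = TRUE)
  min_sep <- diameter_xy_um / 2
  kept <- integer()
  for (i in ord) {
    if (length(kept) &&
        min(sqrt(rowSums(sweep(pos[kept, , drop = FALSE], 2, pos[i, ])^2))) < min_sep)
      next
    kept <- c(kept, i)
  }
  kept <- sort(kept)
  spot_set(data.frame(x_um = pos[kept, 1], y_um = pos[kept, 2],
                      z_um = pos[kept, 3], peak = peak[kept],
                      response = rsp[kept]), params)
}

spot_set <- function(df, params) {
  attr(df, "params") <- params
  class(df) <- c("spot_set", class(df))
  df
}

#' Label spots by region membership
#'
#' Each spot gets the label of the region containing it, with precedence
#' infarct > curly > aar > outside (an infarct body sits inside the AAR, so
#' the most specific region wins).
#'
#' @param spots A `spot_set` / data frame with x_um, y_um, z_um.
#' @param masks Named list with any of `aar`, `infarct`, `curly`
#'   ([region_mask()] or logical arrays sharing the spot geometry).
#' @param geometry A [voxel_geometry()].
#' @return `spots` with a `region` column.
#' @export
classify_spots_by_region <- function(spots, masks, geometry) {
  sp <- voxel_spacing(geometry)
  pos <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  region <- rep("outside", nrow(spots))
  for (nm in c("aar", "curly", "infarct")) {  # ascending precedence
    if (is.null(masks[[nm]])) next
    m <- mask_of(masks[[nm]])
    if (nrow(pos)) {
      inside <- sample_at_um(m, pos, sp) > 0
      region[inside] <- nm
    }
  }
  spots$region <- region
  spots
}

#' Relative spot density in a border shell
#'
#' The border shell is all heart voxels within `half_width_um` of the region
#' border on either side (signed Euclidean distance transform, physical
#' units). The statistic is the dimensionless density ratio
#' `(spots in shell / shell volume) / (spots in heart / heart volume)`,
#' which equals 1 for spatially uniform spots. Raw counts, volumes and
#' per-spot signed distances are returned so other normalizations can be
#' recomputed.
#'
#' @param spots A `spot_set` / data frame with x_um, y_um, z_um.
#' @param mask Region whose border defines the shell ([region_mask()] or
#'   logical array).
#' @param heart_mask Heart mask.
#' @param half_width_um Shell half-width, µm (default 30).
#' @param geometry A [voxel_geometry()].
#' @return List: `relative_density`, `n_shell`, `n_heart`,
#'   `shell_volume_mm3`, `heart_volume_mm3`, `signed_distance_um` (per spot).
#' @export
border_shell_density <- function(spots, mask, heart_mask, geometry,
                                 half_width_um = 30) {
  sp <- voxel_spacing(geometry)
  m <- mask_of(mask)
  heart <- mask_of(heart_mask)
  if (!any(m) || !any(heart)) stop("region and heart masks must be nonempty")
  sdist <- signed_border_distance(m, sp)
  shell <- (abs(sdist) <= half_width_um) & heart
  if (!any(shell)) stop("border shell does not intersect the heart")

  pos <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  in_heart <- if (nrow(pos)) sample_at_um(heart, pos, sp) > 0 else logical()
  in_shell <- if (nrow(pos)) sample_at_um(shell, pos, sp) > 0 else logical()
  dists <- if (nrow(pos)) sample_at_um(sdist, pos, sp) else numeric()

  vv <- voxel_volume_um3(geometry) / UM3_PER_MM3
  n_heart <- sum(in_heart)
  n_shell <- sum(in_shell & in_heart)
  v_shell <- sum(shell) * vv
  v_heart <- sum(heart) * vv
  rel <- if (n_heart == 0) 0 else (n_shell / v_shell) / (n_heart / v_heart)
  list(relative_density = rel, n_shell = n_shell, n_heart = n_heart,
       shell_volume_mm3 = v_shell, heart_volume_mm3 = v_heart,
       signed_distance_um = dists)
}
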