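#' Anisotropy-aware Gaussian smoothing
#'
#' Smooths with a physical sigma (µm): the per-axis voxel sigma is
#' `sigma_um / spacing`, so lateral and axial blur match in physical space.
#' A sigma of 2 µm — less than half the diameter of the smallest capillaries —
#' is the default first step before vessel tracing. Output is floating point.
#'
#' @param volume A [volume_image()] or 3D array.
#' @param sigma_um Physical sigma in µm (>= 0; 0 is the identity).
#' @param geometry Required when `volume` is a bare array.
#' @return A float [volume_image()] (or array, matching the input).
#' @export
gaussian_smooth <- function(volume, sigma_um = 2, geometry = NULL) {
  geometry <- geom_of(volume, geometry)
  if (sigma_um < 0) stop("sigma must be non-negative")
  vox <- as_voxels(volume)
  out <- smooth3d(vox, physical_to_voxel_sigma(sigma_um, geometry))
  vol_like(volume, out, float = TRUE)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with an
#' ellipsoidal structuring element of the given physical radius (anisotropic
#' grids get per-axis voxel radii) and subtracts it, clipping at zero. A
#' radius of 20 µm — more than twice the largest vessel diameter — removes
#' slowly varying background without touching the intensity distribution
#' inside vessels.
#'
#' @param volume A [volume_image()] or 3D array.
#' @param radius_um Ball radius in µm (> 0).
#' @param geometry Required when `volume` is a bare array.
#' @return Background-subtracted float volume.
#' @export
rolling_ball_subtract <- function(volume, radius_um = 20, geometry = NULL) {
  geometry <- geom_of(volume, geometry)
  if (radius_um <= 0) stop("radius must be positive")
  vox <- as_voxels(volume)
  storage.mode(vox) <- "double"
  sp <- voxel_spacing(geometry)
  off <- ball_offsets(radius_um, sp)
  if (nrow(off) <= 1) {
    warning("rolling-ball radius smaller than one voxel; background equals the image")
    bg <- vox
  } else {
    er <- array(cc_gray_morph(vox, dim(vox), off, FALSE), dim = dim(vox))
    bg <- array(cc_gray_morph(er, dim(vox), off, TRUE), dim = dim(vox))
  }
  vol_like(volume, pmax(vox - bg, 0), float = TRUE)
}

#' Multiscale Frangi vesselness
#'
#' Hessian-eigenvalue vesselness for bright tubular structures, maximized over
#' physical scales. At each scale the volume is smoothed with a Gaussian of
#' that sigma (per-axis voxel sigmas from the geometry), the Hessian is taken
#' by central differences in physical units and gamma-normalized by
#' `scale^2`, and the classic three-term response is computed from the sorted
#' eigenvalues (|l1| <= |l2| <= |l3|; response 0 unless l2, l3 < 0):
#' plate-vs-line ratio RA = |l2|/|l3|, blob ratio RB = |l1|/sqrt(|l2 l3|),
#' structure-ness S = sqrt(sum li^2). The constants are not dictated by the
#' acquisition; defaults follow common practice (alpha = beta = 0.5, c = half
#' the maximum Hessian Frobenius norm at each scale).
#'
#' @param volume A [volume_image()] or 3D array (raw or pre-smoothed).
#' @param scales_um Vessel scales in µm, ascending (default 2, 3.5, 5 —
#'   bracketing capillary radii).
#' @param alpha,beta Sensitivity constants (> 0).
#' @param c Structure-ness constant; `NULL` = half the maximum Hessian norm.
#' @param geometry Required when `volume` is a bare array.
#' @return Float volume with vesselness in \[0, 1\].
#' @export
frangi_vesselness <- function(volume, scales_um = c(2, 3.5, 5),
                              alpha = 0.5, beta = 0.5, c = NULL,
                              geometry = NULL) {
  geometry <- geom_of(volume, geometry)
  if (!length(scales_um)) stop("at least one scale is required")
  if (is.unsorted(scales_um) || any(scales_um <= 0))
    stop("scales must be positive and ascending")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  vox <- as_voxels(volume)
  storage.mode(vox) <- "double"
  d <- dim(vox)
  sp <- voxel_spacing(geometry)
  cval <- if (is.null(c)) -1 else c

  best <- array(0, dim = d)
  for (s_um in scales_um) {
    sm <- smooth3d(vox, s_um / sp)
    H <- hessian3d(sm, sp)
    g <- s_um^2  # gamma normalization
    v <- cc_frangi(H$xx * g, H$yy * g, H$zz * g,
                   H$xy * g, H$xz * g, H$yz * g, alpha, beta, cval)
    best <- pmax(best, array(v, dim = d))
  }
  vol_like(volume, best, float = TRUE)
}

# central-difference Hessian in physical units (µm^-2)
hessian3d <- function(vox, sp) {
  d <- dim(vox)
  d1 <- function(v, axis) {
    k <- c(-1, 0, 1) / (2 * sp[axis])
    array(cc_convolve_axis(v, d, k, axis - 1L), dim = d)
  }
  d2 <- function(v, axis) {
    k <- c(1, -2, 1) / sp[axis]^2
    array(cc_convolve_axis(v, d, k, axis - 1L), dim = d)
  }
  gx <- d1(vox, 1); gy <- d1(vox, 2)
  list(xx = d2(vox, 1), yy = d2(vox, 2), zz = d2(vox, 3),
       xy = d1(gx, 2), xz = d1(gx, 3), yz = d1(gy, 3))
}

#' Edge-homogeneity ratio of an intensity profile
#'
#' QC metric for autofluorescence homogenization: along a line profile that
#' enters the tissue from outside, the ratio of the peak intensity in the
#' entry (edge) segment to the median of the interior segment. Unbleached
#' specimens show a bright rim at the tissue edge (ratio >> 1); homogenized
#' signal gives a ratio near 1.
#'
#' @param x Either a numeric intensity profile (ordered from outside the
#'   tissue inwards) or a [volume_image()]/array with `start_um`, `end_um`.
#' @param start_um,end_um Line ROI endpoints in µm (start outside, end inside
#'   the tissue) when `x` is a volume.
#' @param n_samples Number of profile samples for the volume form.
#' @param threshold Tissue threshold; `NULL` = Otsu split of the profile.
#' @param edge_frac Fraction of the tissue run treated as the edge segment
#'   (at least 2 samples).
#' @param geometry Required when `x` is a bare array.
#' @return The edge/interior ratio (>= 0).
#' @export
edge_homogeneity_ratio <- function(x, start_um = NULL, end_um = NULL,
                                   n_samples = 100, threshold = NULL,
                                   edge_frac = 0.1, geometry = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    profile <- as.numeric(x)
  } else {
    geometry <- geom_of(x, geometry)
    if (is.null(start_um) || is.null(end_um))
      stop("start_um and end_um are required for a volume input")
    t_seq <- seq(0, 1, length.out = n_samples)
    pos <- cbind(start_um[1] + t_seq * (end_um[1] - start_um[1]),
                 start_um[2] + t_seq * (end_um[2] - start_um[2]),
                 start_um[3] + t_seq * (end_um[3] - start_um[3]))
    profile <- sample_at_um(as_voxels(x), pos, voxel_spacing(geometry))
  }
  if (is.null(threshold)) threshold <- otsu_threshold(profile)
  tissue <- which(profile >= threshold)
  if (!length(tissue)) stop("profile does not cross into tissue")
  run <- tissue[1]:tissue[length(tissue)]
  n_edge <- max(2L, ceiling(edge_frac * length(run)))
  if (length(run) <= n_edge) stop("profile has no interior segment")
  edge <- profile[run[seq_len(n_edge)]]
  interior <- profile[run[-seq_len(n_edge)]]
  med <- median(interior)
  if (med <= 0) stop("interior median is not positive")
  max(edge) / med
}
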