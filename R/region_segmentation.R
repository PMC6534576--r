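#' Region mask with role and volumes
#'
#' @param voxels Logical 3D array.
#' @param role One of heart, lv_lumen, aar, infarct, curly, diffuse.
#' @param geometry A [voxel_geometry()].
#' @param provenance "computed" or "traced".
#' @return A `region_mask` with raw and shrinkage-corrected volumes (mm³).
#' @export
region_mask <- function(voxels, role, geometry, provenance = "computed") {
  stopifnot(is.logical(voxels) || all(voxels %in% c(0, 1)))
  raw <- sum(voxels != 0) * voxel_volume_um3(geometry) / UM3_PER_MM3
  structure(list(voxels = voxels != 0, role = role, geometry = geometry,
                 provenance = provenance, volume_raw_mm3 = raw,
                 volume_corrected_mm3 = raw * geometry$shrinkage_linear^3),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask '%s' (%s): %.4g mm3 raw, %.4g mm3 corrected\n",
              x$role, x$provenance, x$volume_raw_mm3, x$volume_corrected_mm3))
  invisible(x)
}

mask_of <- function(x) if (inherits(x, "region_mask")) x$voxels else x

#' Heart surface mask from the autofluorescence channel
#'
#' Automatic global (Otsu) threshold on the smoothed autofluorescence, largest
#' connected component, morphological closing and opening at the grain scale
#' (the surface-creation grain, default 25 µm) and per-slice hole filling —
#' yielding the solid heart-muscle mask used as the normalization volume.
#'
#' @param autofluorescence A [volume_image()] or 3D array.
#' @param grain_um Surface grain size, µm.
#' @param fill_holes Fill enclosed per-slice holes (the LV cavity), giving
#'   the solid normalization volume; set FALSE to keep the cavity open
#'   (the myocardium-only mask, from which [lv_lumen_from_heart()] can
#'   extract the lumen).
#' @param geometry Required when the input is a bare array.
#' @return A [region_mask()] with role "heart".
#' @export
heart_surface <- function(autofluorescence, grain_um = 25, fill_holes = TRUE,
                          geometry = NULL) {
  geometry <- geom_of(autofluorescence, geometry)
  sp <- voxel_spacing(geometry)
  sm <- as_voxels(gaussian_smooth(autofluorescence, grain_um / 2, geometry))
  thr <- otsu_threshold(as.vector(sm))
  fg <- sm >= thr
  if (!any(fg) || all(fg)) stop("autofluorescence volume has no foreground/background split")
  fg <- largest_component(fg)
  fg <- binary_close(fg, grain_um, sp)
  fg <- binary_open(fg, grain_um / 2, sp)
  if (fill_holes) fg <- fill_holes_slices(fg)
  region_mask(fg, "heart", geometry)
}

#' LV lumen from the heart mask's internal cavity
#'
#' Per-slice hole analysis of the heart mask: background regions enclosed by
#' myocardium in their slice form the lumen; the largest 3D component is kept.
#'
#' @param heart_mask A [region_mask()] or logical array (solid myocardium,
#'   cavity open).
#' @param geometry Required for a bare array.
#' @return A [region_mask()] with role "lv_lumen".
#' @export
lv_lumen_from_heart <- function(heart_mask, geometry = NULL) {
  if (inherits(heart_mask, "region_mask")) geometry <- heart_mask$geometry
  m <- mask_of(heart_mask)
  cavity <- fill_holes_slices(m) & !m
  if (any(cavity)) cavity <- largest_component(cavity)
  region_mask(cavity, "lv_lumen", geometry)
}

#' Sparse manual contours
#'
#' Operator tracings: closed polygons in pixel coordinates on every k-th
#' slice (stride 5 for CD31 tracings, 10 for AAR in the reference workflow).
#'
#' @param entries List of `list(slice = <int>, poly = <n x 2 matrix>)`.
#' @param stride Tracing stride k.
#' @return A `sparse_contours` object; polygons are checked for
#'   self-intersection, slices for strict increase.
#' @export
sparse_contours <- function(entries, stride = NULL) {
  slices <- vapply(entries, function(e) as.integer(e$slice), integer(1))
  if (any(diff(slices) <= 0)) stop("slice indices must be strictly increasing")
  for (e in entries) {
    if (polygon_self_intersects(e$poly))
      stop(sprintf("polygon on slice %d is self-intersecting", e$slice))
  }
  if (is.null(stride))
    stride <- if (length(slices) > 1) as.integer(round(median(diff(slices)))) else 1L
  structure(list(entries = entries, stride = stride), class = "sparse_contours")
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # shared vertex with the closing edge
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# even-odd point-in-polygon for all pixel centres of a slice
fill_polygon_slice <- function(poly, nx, ny) {
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  inside <- matrix(FALSE, nx, ny)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Interpolate sparse per-slice contours into a volume mask
#'
#' Traced slices get their polygon filled (even-odd rule on pixel centres);
#' slices between two tracings are filled by linear interpolation of the 2D
#' signed distance maps of the bracketing tracings; beyond the first/last
#' traced slice the end shape is extended for half the tracing stride.
#'
#' @param contours A [sparse_contours()].
#' @param dim Output grid size (nx, ny, nz).
#' @param geometry A [voxel_geometry()].
#' @param role Role tag for the resulting [region_mask()].
#' @return A [region_mask()] with provenance "traced".
#' @export
interpolate_sparse_contours <- function(contours, dim, geometry, role = "aar") {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  out <- array(FALSE, dim = dim)
  entries <- contours$entries
  slices <- vapply(entries, function(e) as.integer(e$slice), integer(1))
  filled <- lapply(entries, function(e) fill_polygon_slice(e$poly, nx, ny))

  sdist2d <- function(m) {
    m3 <- array(m, dim = c(nx, ny, 1L))
    d_in <- sqrt(array(cc_edt_sq(!m3, dim(m3), c(1, 1, 1)), dim = dim(m3)))
    d_out <- sqrt(array(cc_edt_sq(as.logical(m3), dim(m3), c(1, 1, 1)), dim = dim(m3)))
    (ifelse(m3, -d_in, d_out))[, , 1]
  }

  for (i in seq_along(slices)) {
    if (slices[i] >= 1 && slices[i] <= nz) out[, , slices[i]] <- filled[[i]]
  }
  if (length(slices) > 1) {
    for (i in seq_len(length(slices) - 1)) {
      s1 <- slices[i]; s2 <- slices[i + 1]
      if (s2 - s1 < 2) next
      d1 <- sdist2d(filled[[i]])
      d2 <- sdist2d(filled[[i + 1]])
      for (s in (s1 + 1):(s2 - 1)) {
        w <- (s - s1) / (s2 - s1)
        if (s >= 1 && s <= nz) out[, , s] <- ((1 - w) * d1 + w * d2) < 0
      }
    }
  }
  ext <- floor(contours$stride / 2)
  if (ext > 0) {
    for (s in (slices[1] - ext):(slices[1] - 1))
      if (s >= 1 && s <= nz) out[, , s] <- filled[[1]]
    last <- length(slices)
    for (s in (slices[last] + 1):(slices[last] + ext))
      if (s >= 1 && s <= nz) out[, , s] <- filled[[last]]
  }
  region_mask(out, role, geometry, provenance = "traced")
}

#' Segment the area at risk from the perfusion (FITC) channel
#'
#' The AAR is the non-perfused myocardium: heart voxels whose smoothed FITC
#' intensity falls below a threshold. The default strategy splits the
#' within-heart histogram at the Otsu point, guarded by a bimodality check —
#' a unimodal histogram (uniformly perfused or uniformly dark heart) falls
#' back to the configured absolute threshold with a warning. Islands smaller
#' than `min_island_um3` are removed.
#'
#' @param fitc A [volume_image()] or 3D array.
#' @param heart_mask A [region_mask()] or logical array.
#' @param threshold_strategy "otsu" or "absolute".
#' @param absolute_threshold Fallback / absolute threshold (grey values).
#' @param smooth_um Pre-smoothing sigma, µm.
#' @param min_island_um3 Minimum island volume, µm³.
#' @param geometry Required for bare arrays.
#' @return List with `mask` (a [region_mask()], role "aar") and
#'   `fraction_of_heart`.
#' @export
segment_aar <- function(fitc, heart_mask, threshold_strategy = c("otsu", "absolute"),
                        absolute_threshold = 1000, smooth_um = 6,
                        min_island_um3 = 1e4, geometry = NULL) {
  threshold_strategy <- match.arg(threshold_strategy)
  geometry <- geom_of(fitc, geometry)
  sp <- voxel_spacing(geometry)
  heart <- mask_of(heart_mask)
  if (!any(heart)) stop("heart mask is empty")
  sm <- as_voxels(gaussian_smooth(fitc, smooth_um, geometry))
  vals <- sm[heart]
  thr <- absolute_threshold
  if (threshold_strategy == "otsu") {
    cand <- otsu_threshold(vals)
    lo <- vals[vals < cand]; hi <- vals[vals >= cand]
    separation <- if (length(lo) && length(hi))
      (mean(hi) - mean(lo)) / max(sd(vals), 1e-9) else 0
    if (separation > 1.5) {
      thr <- cand
    } else {
      warning("FITC histogram within the heart looks unimodal; using the absolute threshold")
    }
  }
  aar <- heart & (sm < thr)
  min_vox <- ceiling(min_island_um3 / prod(sp))
  aar <- filter_small_components(aar, min_vox)
  list(mask = region_mask(aar, "aar", geometry),
       fraction_of_heart = sum(aar) / sum(heart))
}

#' Segment infarct bodies as CD31-negative regions
#'
#' Infarcted tissue shows complete loss of the CD31 signal. A local
#' vessel-density map (fraction of vessel-positive voxels in a sliding
#' physical window) is computed inside the heart; a conservative core is
#' taken where density falls below `floor_frac` of the specimen's median
#' density — regions that are merely CD31-dim (reduced but present signal)
#' stay above this floor and are excluded — and the core is then grown back
#' by the half-window border offset so the detected body matches the true
#' zero-density extent.
#'
#' @param cd31 Vesselness or CD31 intensity volume.
#' @param heart_mask A [region_mask()] or logical array.
#' @param aar_mask Optional: constrain the infarct to the AAR.
#' @param vessel_threshold Threshold for vessel-positive voxels; `NULL` =
#'   Otsu over within-heart intensities.
#' @param window_um Sliding-window size, µm.
#' @param floor_frac Density floor as a fraction of the median density.
#' @param border_offset_um Outward growth of the conservative core, µm
#'   (`NULL` = 0.28 x the window: the box window concentrates its mass, so
#'   the density floor is crossed about a fifth of a window inside the void).
#' @param boundary_margin_um Surface band excluded from core candidacy, µm.
#' @param smooth_um Gaussian pre-smoothing of the channel, µm (stabilizes the
#'   local density estimate against plane-to-plane intensity flicker).
#' @param min_volume_um3 Minimum infarct-body volume, µm³.
#' @param geometry Required for bare arrays.
#' @return A [region_mask()] with role "infarct".
#' @export
segment_infarct <- function(cd31, heart_mask, aar_mask = NULL,
                            vessel_threshold = NULL, window_um = 50,
                            floor_frac = 0.1, border_offset_um = NULL,
                            boundary_margin_um = 8, smooth_um = 2,
                            min_volume_um3 = 1e5, geometry = NULL) {
  geometry <- geom_of(cd31, geometry)
  sp <- voxel_spacing(geometry)
  heart <- mask_of(heart_mask)
  if (!any(heart)) stop("heart mask is empty")
  vox <- as_voxels(cd31)
  if (smooth_um > 0) vox <- as_voxels(gaussian_smooth(vox, smooth_um, geometry))
  if (is.null(vessel_threshold)) vessel_threshold <- otsu_threshold(vox[heart])
  vessel <- (vox >= vessel_threshold) & heart
  # normalize by the local in-heart fraction so windows straddling the heart
  # surface are not diluted by outside-tissue zeros
  half <- (window_um / 2) / sp
  dens_raw <- box_mean3d(array(as.double(vessel), dim = dim(vox)), half)
  heart_frac <- box_mean3d(array(as.double(heart), dim = dim(vox)), half)
  density <- ifelse(heart_frac > 0.05, dens_raw / pmax(heart_frac, 0.05), 0)
  med <- median(density[heart])
  # candidate cores exclude a thin surface band, where density estimates are
  # unreliable; the grown mask may still reach the surface
  core_zone <- binary_erode(heart, boundary_margin_um, sp)
  if (med <= 0) {
    core <- core_zone
  } else {
    core <- core_zone & (density < floor_frac * med)
  }
  # grow the conservative core back towards the density crossing at the
  # true border (the core sits inside the void by roughly the half-window)
  if (is.null(border_offset_um)) border_offset_um <- 0.28 * window_um
  inf_mask <- binary_dilate(core, border_offset_um, sp) & heart
  if (!is.null(aar_mask)) inf_mask <- inf_mask & mask_of(aar_mask)
  min_vox <- ceiling(min_volume_um3 / prod(sp))
  inf_mask <- filter_small_components(inf_mask, min_vox)
  region_mask(inf_mask, "infarct", geometry)
}

#' Classify the remodeled ("curly") vascular zone
#'
#' Day-5 remodeling shows shorter, more branched vessels. From the traced
#' graph, voxel maps of local branch-point density per unit centerline length
#' and local mean segment length are computed in a sliding physical window;
#' curly tissue is vascularized tissue whose branchiness exceeds
#' `branch_mult` times the remote baseline; optionally (`len_mult` not NULL)
#' the local mean segment length must also fall below `len_mult` times
#' baseline. At whole-heart acquisition resolution the branch density per
#' unit centerline length separates remodeled tissue far more robustly than
#' the raw segment length, which is dominated by resolution-driven segment
#' splitting; the length criterion is therefore off by default. The remote
#' baseline comes from `baseline_mask` (myocardium away from the injury).
#'
#' @param graph A [vessel_graph()].
#' @param heart_mask A [region_mask()] or logical array.
#' @param baseline_mask Remote-myocardium mask for the baseline statistics.
#' @param geometry A [voxel_geometry()].
#' @param window_um Sliding-window size, µm.
#' @param branch_mult,len_mult Multipliers on the remote baseline.
#' @param close_um Morphological closing applied to the raw classification.
#' @param halo_um Tissue halo built around curly centerlines, µm.
#' @param min_volume_um3 Minimum component volume kept, µm³.
#' @return A [region_mask()] with role "curly".
#' @export
classify_curly <- function(graph, heart_mask, baseline_mask, geometry,
                           window_um = 150, branch_mult = 1.6,
                           len_mult = NULL, close_um = 15,
                           halo_um = 18, min_volume_um3 = 1e5) {
  sp <- voxel_spacing(geometry)
  heart <- mask_of(heart_mask)
  base <- mask_of(baseline_mask)
  if (!any(base)) stop("no baseline region definable")
  d <- dim(heart)

  deposit <- function(pos_um, weights) {
    arr <- array(0, dim = d)
    if (!nrow(pos_um)) return(arr)
    i <- pmin(pmax(round(pos_um[, 1] / sp[1]) + 1, 1), d[1])
    j <- pmin(pmax(round(pos_um[, 2] / sp[2]) + 1, 1), d[2])
    k <- pmin(pmax(round(pos_um[, 3] / sp[3]) + 1, 1), d[3])
    idx <- cbind(i, j, k)
    for (r in seq_len(nrow(idx)))
      arr[idx[r, 1], idx[r, 2], idx[r, 3]] <-
        arr[idx[r, 1], idx[r, 2], idx[r, 3]] + weights[r]
    arr
  }

  branch_nodes <- graph$nodes[graph$nodes$degree >= 3, c("x", "y", "z")]
  branch_map <- deposit(as.matrix(branch_nodes),
                        rep(1, nrow(branch_nodes)))
  # centerline length deposited at segment midpoints
  mids <- list(); lens <- list()
  for (p in graph$paths) {
    if (nrow(p) < 2) next
    a <- p[-nrow(p), , drop = FALSE]; b <- p[-1, , drop = FALSE]
    mids[[length(mids) + 1]] <- (a + b) / 2
    lens[[length(lens) + 1]] <- sqrt(rowSums((b - a)^2))
  }
  len_map <- deposit(do.call(rbind, mids), unlist(lens))
  # per-edge mean segment length: edge length at its midpoint, edge count
  e_mid <- do.call(rbind, lapply(graph$paths, function(p) p[ceiling(nrow(p) / 2), , drop = FALSE]))
  e_len <- graph$edges$length_um
  elen_map <- deposit(e_mid, e_len)
  ecount_map <- deposit(e_mid, rep(1, length(e_len)))

  half <- (window_um / 2) / sp
  sm_branch <- box_mean3d(branch_map, half)
  sm_len <- box_mean3d(len_map, half)
  sm_elen <- box_mean3d(elen_map, half)
  sm_ecount <- box_mean3d(ecount_map, half)

  branchiness <- ifelse(sm_len > 0, sm_branch / sm_len, 0)
  mean_seg <- ifelse(sm_ecount > 0, sm_elen / sm_ecount, NA)

  base_ok <- base & (sm_len > 0)
  if (!any(base_ok)) stop("baseline region contains no vessels")
  b_branch <- median(branchiness[base_ok])
  b_len <- median(mean_seg[base_ok], na.rm = TRUE)

  # classify at the level of traced edges (curly tissue is where the traced
  # vessels themselves are hyper-branched), then build the mask as a halo
  # around those centerlines — avascular cores never get called
  bness_mid <- sample_at_um(branchiness, e_mid, sp)
  edge_curly <- bness_mid >= branch_mult * b_branch
  if (!is.null(len_mult)) {
    mlen_mid <- sample_at_um(mean_seg, e_mid, sp)
    edge_curly <- edge_curly & !is.na(mlen_mid) & (mlen_mid <= len_mult * b_len)
  }
  curly <- array(FALSE, dim = d)
  if (any(edge_curly)) {
    pts <- do.call(rbind, graph$paths[edge_curly])
    i <- pmin(pmax(round(pts[, 1] / sp[1]) + 1, 1), d[1])
    j <- pmin(pmax(round(pts[, 2] / sp[2]) + 1, 1), d[2])
    k <- pmin(pmax(round(pts[, 3] / sp[3]) + 1, 1), d[3])
    curly[cbind(i, j, k)] <- TRUE
    curly <- binary_dilate(curly, halo_um, sp) & heart
    if (close_um > 0) curly <- binary_close(curly, close_um, sp) & heart
  }
  min_vox <- ceiling(min_volume_um3 / prod(sp))
  curly <- filter_small_components(curly, min_vox)
  region_mask(curly, "curly", geometry)
}

#' Diffuse-signal volume (macrophage channel)
#'
#' When spot detection is infeasible (diffuse staining), the labeled volume
#' itself is rendered: threshold inside the heart, one closing, volumes
#' reported raw and shrinkage-corrected.
#'
#' @param channel A [volume_image()] or 3D array.
#' @param heart_mask A [region_mask()] or logical array.
#' @param threshold Intensity threshold (grey values).
#' @param close_um Closing radius, µm.
#' @param geometry Required for bare arrays.
#' @return A [region_mask()] with role "diffuse".
#' @export
diffuse_signal_volume <- function(channel, heart_mask, threshold,
                                  close_um = 10, geometry = NULL) {
  geometry <- geom_of(channel, geometry)
  sp <- voxel_spacing(geometry)
  heart <- mask_of(heart_mask)
  m <- (as_voxels(channel) >= threshold) & heart
  if (any(m) && close_um > 0) m <- binary_close(m, close_um, sp) & heart
  region_mask(m, "diffuse", geometry)
}

#' Per-region volume report
#'
#' Raw volume, shrinkage-corrected volume and fraction of the heart-mask
#' volume for each region; regions not contained in the heart produce a
#' warning with their overlap fraction.
#'
#' @param masks Named list of [region_mask()]s or logical arrays; must
#'   contain "heart".
#' @param geometry A [voxel_geometry()].
#' @return Data frame with one row per region.
#' @export
region_volume_report <- function(masks, geometry) {
  if (!"heart" %in% names(masks)) stop("a 'heart' mask is required")
  heart <- mask_of(masks$heart)
  vv <- voxel_volume_um3(geometry) / UM3_PER_MM3
  f3 <- geometry$shrinkage_linear^3
  n_heart <- sum(heart)
  rows <- lapply(names(masks), function(nm) {
    m <- mask_of(masks[[nm]])
    n <- sum(m)
    if (nm != "heart" && n > 0) {
      overlap <- sum(m & heart) / n
      if (overlap < 1)
        warning(sprintf("region '%s' extends outside the heart (overlap %.2f)",
                        nm, overlap))
    }
    data.frame(region = nm, voxels = n, volume_raw_mm3 = n * vv,
               volume_corrected_mm3 = n * vv * f3,
               fraction_of_heart = n / n_heart)
  })
  do.call(rbind, rows)
}
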