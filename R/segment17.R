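#' Define the four axial slabs of the 17-segment model
#'
#' The apex slab is the part of the heart's long-axis range that contains no
#' LV lumen; the lumen-containing range is split into three equal-length
#' slabs (apical, mid, basal). Orientation along the axis is auto-resolved:
#' the apex is the side beyond the lumen with the larger heart extension, so
#' a reversed stack gives identical slabs.
#'
#' @param heart_mask A [region_mask()] or logical array.
#' @param lumen_mask LV lumen mask (nonempty).
#' @param axis Long axis (currently "z", the imaging axis).
#' @return List with integer slice ranges `apex`, `apical`, `mid`, `basal`
#'   (each `c(from, to)`, inclusive; apex may be empty, flagged via
#'   `apex_empty`) and `apex_side` ("low" or "high").
#' @export
define_slabs <- function(heart_mask, lumen_mask, axis = "z") {
  if (axis != "z") stop("only the z long axis is supported")
  heart <- mask_of(heart_mask)
  lumen <- mask_of(lumen_mask)
  if (!any(lumen)) stop("lumen mask is empty")
  h_rng <- range(which(apply(heart, 3, any)))
  l_rng <- range(which(apply(lumen, 3, any)))
  below <- l_rng[1] - h_rng[1]
  above <- h_rng[2] - l_rng[2]
  apex_side <- if (below >= above) "low" else "high"
  apex_empty <- max(below, above) <= 0
  if (apex_empty) warning("lumen spans the whole heart; apex slab is empty")

  # three equal slabs over the lumen range, ordered apical -> basal
  cuts <- round(seq(l_rng[1] - 0.5, l_rng[2] + 0.5, length.out = 4))
  thirds <- list(c(cuts[1] + 1, cuts[2]), c(cuts[2] + 1, cuts[3]),
                 c(cuts[3] + 1, cuts[4]))
  if (apex_side == "low") {
    apex <- if (below > 0) c(h_rng[1], l_rng[1] - 1) else c(NA_integer_, NA_integer_)
    apical <- thirds[[1]]; mid <- thirds[[2]]
    basal <- c(thirds[[3]][1], max(thirds[[3]][2], h_rng[2]))
  } else {
    apex <- if (above > 0) c(l_rng[2] + 1, h_rng[2]) else c(NA_integer_, NA_integer_)
    apical <- thirds[[3]]; mid <- thirds[[2]]  # thirds[[3]] is nearest the apex
    basal <- c(min(thirds[[1]][1], h_rng[1]), thirds[[1]][2])
  }
  list(apex = apex, apical = apical, mid = mid, basal = basal,
       apex_side = apex_side, apex_empty = apex_empty)
}

#' Assign AHA 17-segment labels to the LV myocardium
#'
#' Within each slab, voxels are assigned to angular sectors about the slab's
#' lumen centroid (6 sectors of 60 deg in the basal and mid slabs, 4 of
#' 90 deg in the apical slab, the whole apex slab = segment 17), numbered by
#' the standard convention starting at the anterior wall and proceeding
#' counterclockwise in the apex view: basal 1-6, mid 7-12 (12 = mid
#' anterolateral), apical 13-16. Right-ventricular voxels are excluded from
#' all segments.
#'
#' @param heart_mask A [region_mask()] or logical array.
#' @param lumen_mask LV lumen mask.
#' @param slabs Result of [define_slabs()].
#' @param reference_angle_deg Angle (deg, atan2 convention in the x-y plane)
#'   of the anterior wall centre.
#' @param rv_mask Optional right-ventricle mask to exclude.
#' @param geometry A [voxel_geometry()].
#' @return Integer 3D array of labels 0 (unassigned/RV) to 17.
#' @export
assign_segments <- function(heart_mask, lumen_mask, slabs,
                            reference_angle_deg = 0, rv_mask = NULL,
                            geometry = NULL) {
  heart <- mask_of(heart_mask)
  lumen <- mask_of(lumen_mask)
  d <- dim(heart)
  lv <- heart & !lumen
  if (!is.null(rv_mask)) lv <- lv & !mask_of(rv_mask)
  labels <- array(0L, dim = d)
  ref <- reference_angle_deg * pi / 180

  sector_labels <- function(z_range, n_sectors, first_label) {
    if (anyNA(z_range)) return()
    zs <- max(1, z_range[1]):min(d[3], z_range[2])
    if (!length(zs)) return()
    sub_lumen <- lumen[, , zs, drop = FALSE]
    cen <- if (any(sub_lumen)) {
      ci <- arrayInd(which(sub_lumen), dim(sub_lumen))
      colMeans(ci)[1:2]
    } else {
      ci <- arrayInd(which(lv[, , zs, drop = FALSE]), c(d[1], d[2], length(zs)))
      colMeans(ci)[1:2]
    }
    width <- 2 * pi / n_sectors
    for (z in zs) {
      sl <- lv[, , z]
      if (!any(sl)) next
      idx <- which(sl)
      xy <- arrayInd(idx, c(d[1], d[2]))
      theta <- atan2(xy[, 2] - cen[2], xy[, 1] - cen[1])
      s <- floor(((theta - (ref - width / 2)) %% (2 * pi)) / width)
      lab <- labels[, , z]
      lab[idx] <- first_label + as.integer(s)
      labels[, , z] <<- lab
    }
  }
  sector_labels(slabs$basal, 6L, 1L)
  sector_labels(slabs$mid, 6L, 7L)
  sector_labels(slabs$apical, 4L, 13L)
  if (!anyNA(slabs$apex)) {
    zs <- max(1, slabs$apex[1]):min(d[3], slabs$apex[2])
    for (z in zs) {
      lab <- labels[, , z]
      lab[lv[, , z]] <- 17L
      labels[, , z] <- lab
    }
  }
  labels
}

#' Rate segments positive for a feature
#'
#' A segment is positive if its overlap with the feature mask reaches
#' `min_voxels` (default 1: the binary "shows the feature" criterion).
#'
#' @param segment_map Label array from [assign_segments()].
#' @param feature_mask Logical array (infarct, AAR or curly).
#' @param min_voxels Minimum overlapping voxels.
#' @return Logical vector of length 17.
#' @export
rate_positivity <- function(segment_map, feature_mask, min_voxels = 1) {
  f <- mask_of(feature_mask)
  vapply(1:17, function(s) sum(segment_map == s & f) >= min_voxels, logical(1))
}

#' Aggregate per-heart segment ratings into a heat map
#'
#' @param ratings List of logical length-17 vectors (one per heart).
#' @return Data frame with `segment` (1-17) and `count`, plus attribute
#'   `n_hearts`.
#' @export
aggregate_heatmap <- function(ratings) {
  if (!length(ratings)) {
    hm <- data.frame(segment = 1:17, count = 0L)
    attr(hm, "n_hearts") <- 0L
    return(hm)
  }
  if (any(vapply(ratings, length, integer(1)) != 17))
    stop("each rating must have length 17")
  counts <- Reduce(`+`, lapply(ratings, as.integer))
  hm <- data.frame(segment = 1:17, count = counts)
  attr(hm, "n_hearts") <- length(ratings)
  hm
}
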