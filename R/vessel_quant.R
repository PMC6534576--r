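#' Spatial vessel graph
#'
#' Centerline graph of a vascular network: typed nodes (endpoint, branch,
#' isolated) at physical µm positions, and edges carried as centerline
#' polylines with optional per-point radius. Arc length is the polyline length
#' through voxel centres with physical per-axis spacing.
#'
#' @param node_xyz Numeric matrix (n x 3) of node positions, µm.
#' @param edge_paths List of numeric matrices (m x 3), one polyline per edge,
#'   µm; first and last rows must coincide with the end nodes.
#' @param edge_ends Integer matrix (e x 2) of 1-based node indices.
#' @param radii Optional list of per-point radius vectors (µm), one per edge.
#' @param provenance Free-text provenance tag (channel/threshold).
#' @return A `vessel_graph` object with `nodes` and `edges` data frames and
#'   the raw `paths`/`radii` lists.
#' @export
vessel_graph <- function(node_xyz, edge_paths, edge_ends, radii = NULL,
                         provenance = "") {
  node_xyz <- matrix(as.numeric(node_xyz), ncol = 3)
  n_nodes <- nrow(node_xyz)
  edge_ends <- matrix(as.integer(edge_ends), ncol = 2)
  if (length(edge_paths) != nrow(edge_ends)) stop("edge_paths/edge_ends mismatch")
  lengths_um <- vapply(edge_paths, polyline_length, numeric(1))
  if (length(edge_paths) && any(lengths_um == 0 &
                                edge_ends[, 1] != edge_ends[, 2]))
    stop("zero-length edge between distinct nodes")
  degree <- tabulate(c(edge_ends[, 1], edge_ends[, 2]), nbins = n_nodes)
  type <- ifelse(degree == 0, "isolated",
                 ifelse(degree == 1, "endpoint",
                        ifelse(degree == 2, "through", "branch")))
  nodes <- data.frame(id = seq_len(n_nodes), x = node_xyz[, 1],
                      y = node_xyz[, 2], z = node_xyz[, 3],
                      degree = degree, type = type)
  edges <- if (length(edge_paths)) {
    data.frame(id = seq_along(edge_paths), from = edge_ends[, 1],
               to = edge_ends[, 2], length_um = lengths_um)
  } else {
    data.frame(id = integer(), from = integer(), to = integer(),
               length_um = numeric())
  }
  structure(list(nodes = nodes, edges = edges, paths = edge_paths,
                 radii = radii, provenance = provenance),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("vessel_graph: %d nodes (%d branch, %d endpoints), %d edges, total length %.1f um\n",
              nrow(x$nodes), sum(x$nodes$type == "branch"),
              sum(x$nodes$type == "endpoint"), nrow(x$edges),
              graph_total_length(x)))
  invisible(x)
}

polyline_length <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(rowSums((path[-1, , drop = FALSE] -
                    path[-nrow(path), , drop = FALSE])^2)))
}

#' Total centerline length of a graph (µm)
#' @param graph A [vessel_graph()].
#' @return Length in µm.
#' @export
graph_total_length <- function(graph) sum(graph$edges$length_um)

#' Threshold-based vessel segmentation
#'
#' Simple thresholding of a vesselness or intensity volume, followed by one
#' 1-voxel morphological closing (bridging the dips the Frangi filter leaves
#' at branch points) and removal of small connected components.
#'
#' @param volume A [volume_image()] or 3D array (vesselness or intensity).
#' @param threshold Threshold in the volume's value range.
#' @param min_size Minimum component size in voxels (default 5).
#' @param close Logical; apply the 1-voxel closing (default TRUE).
#' @return Logical 3D mask.
#' @export
segment_vessels <- function(volume, threshold, min_size = 5, close = TRUE) {
  vox <- as_voxels(volume)
  mask <- vox >= threshold
  if (!any(mask)) {
    warning("segmentation is empty at this threshold")
    return(array(FALSE, dim = dim(vox)))
  }
  if (close) {
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    m <- array(as.double(mask), dim = dim(mask))
    m <- array(cc_gray_morph(m, dim(mask), off, TRUE), dim = dim(mask))
    m <- array(cc_gray_morph(m, dim(mask), off, FALSE), dim = dim(mask))
    mask <- m > 0.5
  }
  filter_small_components(mask, min_size)
}

#' Skeletonize a vessel mask and build the centerline graph
#'
#' Topology-preserving 3D thinning to a unit-width skeleton, spur removal
#' (terminal branches shorter than `prune_vox` chain voxels are iteratively
#' deleted), then conversion to a spatial graph: skeleton voxels of 26-degree
#' != 2 become nodes (adjacent junction voxels merged), degree-2 chains become
#' edge polylines with anisotropy-aware arc length. Cycles are kept ("with
#' loops" semantics — no tree forcing).
#'
#' Voxel paths are lightly smoothed (moving average, endpoints pinned) to
#' remove the staircase inflation digital 26-connected paths impose on
#' oblique centerlines.
#'
#' @param mask Logical 3D array.
#' @param geometry A [voxel_geometry()].
#' @param prune_vox Spur-length threshold in chain voxels (default 2).
#' @param smooth_passes Moving-average passes over edge polylines (0 = raw
#'   voxel-centre paths).
#' @return A [vessel_graph()]; empty mask gives an empty graph.
#' @export
skeletonize_and_graph <- function(mask, geometry, prune_vox = 2,
                                  smooth_passes = 2) {
  d <- dim(mask)
  sp <- voxel_spacing(geometry)
  if (!any(mask))
    return(vessel_graph(matrix(numeric(), ncol = 3), list(),
                        matrix(integer(), ncol = 2)))
  skel <- array(cc_thin3d(as.logical(mask), d), dim = d)
  for (iter in 1:4) {
    g <- cc_skel_graph(skel, d, sp)
    gr <- graph_from_cc(g)
    spurs <- spur_edges(gr, prune_vox)
    if (!length(spurs)) break
    for (e in spurs) {
      path <- g$edge_paths[[e]]
      # delete the chain voxels and the terminal voxel, keep the junction end
      drop_rows <- 2:nrow(path)
      if (gr$nodes$degree[gr$edges$from[e]] == 1) drop_rows <- 1:(nrow(path) - 1)
      for (r in drop_rows) {
        idx <- round(path[r, ] / sp) + 1
        skel[idx[1], idx[2], idx[3]] <- FALSE
      }
    }
  }
  graph_from_cc(cc_skel_graph(skel, d, sp), smooth_passes)
}

graph_from_cc <- function(g, smooth_passes = 0) {
  paths <- g$edge_paths
  if (smooth_passes > 0)
    paths <- lapply(paths, smooth_polyline, passes = smooth_passes)
  vessel_graph(g$nodes, paths, g$edge_ends)
}

# moving-average polyline smoothing with pinned endpoints
smooth_polyline <- function(p, passes = 1) {
  n <- nrow(p)
  if (n < 3) return(p)
  for (i in seq_len(passes)) {
    q <- p
    q[2:(n - 1), ] <- (p[1:(n - 2), ] + p[2:(n - 1), ] + p[3:n, ]) / 3
    p <- q
  }
  p
}

# terminal edges (one end degree 1, other end branch) with few chain voxels
spur_edges <- function(graph, prune_vox) {
  if (!nrow(graph$edges)) return(integer())
  deg <- graph$nodes$degree
  n_chain <- vapply(graph$paths, nrow, integer(1)) - 2L
  from_d <- deg[graph$edges$from]
  to_d <- deg[graph$edges$to]
  which((pmin(from_d, to_d) == 1) & (pmax(from_d, to_d) >= 3) &
          (n_chain <= prune_vox))
}

#' Re-align centerlines and estimate radii against an intensity channel
#'
#' Two corrections applied after initial tracing, both against the Gaussian
#' smoothed and background-subtracted vessel channel (not the vesselness):
#' each centerline point is moved to the local intensity centroid within a
#' small search radius, with the shift restricted to the plane perpendicular
#' to the local tangent; then the radius at each point is the half-width at
#' half of the local peak-to-background contrast, averaged over ray directions
#' perpendicular to the tangent. Points in zero-contrast regions keep their
#' position and get an `NA` radius.
#'
#' @param graph A [vessel_graph()].
#' @param reference A [volume_image()] or 3D array (smoothed + subtracted
#'   intensity).
#' @param geometry Required when `reference` is a bare array.
#' @param search_vox Half-width of the centroid search window, voxels.
#' @param n_rays Number of perpendicular ray directions (>= 4).
#' @param max_radius_um Upper search bound for the radius, µm.
#' @return The graph with realigned `paths` and per-point `radii` (µm).
#' @export
realign_and_measure_diameters <- function(graph, reference, geometry = NULL,
                                          search_vox = 2, n_rays = 8,
                                          max_radius_um = 15) {
  geometry <- geom_of(reference, geometry)
  sp <- voxel_spacing(geometry)
  vox <- as_voxels(reference)
  if (n_rays < 4) stop("need at least 4 ray directions")

  off <- as.matrix(expand.grid(dx = -search_vox:search_vox,
                               dy = -search_vox:search_vox,
                               dz = -min(search_vox, 1):min(search_vox, 1)))
  off_um <- sweep(off, 2, sp, "*")

  new_paths <- graph$paths
  radii <- vector("list", length(graph$paths))
  for (e in seq_along(graph$paths)) {
    path <- graph$paths[[e]]
    n <- nrow(path)
    tang <- path_tangents(path)
    # perpendicular frame per point
    u <- perp_vector(tang)
    v <- cross3(tang, u)

    # --- realignment: intensity centroid in the perpendicular plane ---
    shifted <- path
    for (chunk in index_chunks(n, 4000)) {
      pts <- path[chunk, , drop = FALSE]
      m <- length(chunk)
      pos <- pts[rep(seq_len(m), each = nrow(off_um)), , drop = FALSE] +
        off_um[rep(seq_len(nrow(off_um)), times = m), , drop = FALSE]
      w <- sample_at_um(vox, pos, sp)
      w <- matrix(w, nrow = nrow(off_um))
      w <- sweep(w, 2, apply(w, 2, min), "-")
      tot <- colSums(w)
      ok <- tot > 0
      cent <- pts
      for (ax in 1:3) {
        delta <- colSums(w * off_um[, ax]) / pmax(tot, .Machine$double.eps)
        cent[, ax] <- pts[, ax] + ifelse(ok, delta, 0)
      }
      # project displacement onto the perpendicular plane
      disp <- cent - pts
      t_chunk <- tang[chunk, , drop = FALSE]
      along <- rowSums(disp * t_chunk)
      shifted[chunk, ] <- pts + disp - along * t_chunk
    }
    # keep edge endpoints pinned to their nodes
    shifted[1, ] <- path[1, ]
    shifted[n, ] <- path[n, ]
    new_paths[[e]] <- shifted

    # --- radius: half-width at half contrast along perpendicular rays ---
    angles <- seq(0, pi, length.out = n_rays + 1)[seq_len(n_rays)]
    steps <- seq(0, max_radius_um, by = min(sp) / 2)
    rad <- rep(NA_real_, n)
    for (chunk in index_chunks(n, 1500)) {
      pts <- shifted[chunk, , drop = FALSE]
      m <- length(chunk)
      prof <- array(NA_real_, dim = c(m, n_rays, length(steps)))
      for (a in seq_len(n_rays)) {
        dir_a <- cos(angles[a]) * u[chunk, , drop = FALSE] +
          sin(angles[a]) * v[chunk, , drop = FALSE]
        for (s in seq_along(steps)) {
          prof[, a, s] <- sample_at_um(vox, pts + steps[s] * dir_a, sp)
        }
      }
      peak <- prof[, , 1, drop = FALSE][, , 1]
      bg <- prof[, , length(steps), drop = FALSE][, , 1]
      for (i in seq_len(m)) {
        pk <- mean(peak[i, ])
        b <- mean(bg[i, ])
        if (pk - b <= .Machine$double.eps * 10 || pk <= 0) next
        level <- b + 0.5 * (pk - b)
        r_rays <- rep(NA_real_, n_rays)
        for (a in seq_len(n_rays)) {
          below <- which(prof[i, a, ] < level)
          if (length(below)) r_rays[a] <- steps[below[1]]
        }
        rad[chunk[i]] <- median(r_rays, na.rm = TRUE)
      }
    }
    radii[[e]] <- rad
  }
  out <- vessel_graph(as.matrix(graph$nodes[, c("x", "y", "z")]), new_paths,
                      as.matrix(graph$edges[, c("from", "to")]), radii,
                      graph$provenance)
  out
}

path_tangents <- function(path) {
  n <- nrow(path)
  if (n == 1) return(matrix(c(1, 0, 0), nrow = 1))
  fwd <- rbind(path[-1, , drop = FALSE], path[n, , drop = FALSE])
  bwd <- rbind(path[1, , drop = FALSE], path[-n, , drop = FALSE])
  t_raw <- fwd - bwd
  nrm <- sqrt(rowSums(t_raw^2))
  nrm[nrm == 0] <- 1
  t_raw / nrm
}

perp_vector <- function(tang) {
  # a unit vector perpendicular to each tangent
  ref <- matrix(rep(c(0, 0, 1), each = nrow(tang)), ncol = 3)
  par <- abs(tang[, 3]) > 0.9
  ref[par, ] <- matrix(rep(c(1, 0, 0), each = sum(par)), ncol = 3)
  u <- cross3(tang, ref)
  nrm <- sqrt(rowSums(u^2))
  nrm[nrm == 0] <- 1
  u / nrm
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

index_chunks <- function(n, size) {
  if (n == 0) return(list())
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' Vessel length density
#'
#' Total centerline length inside a tissue mask divided by the mask volume,
#' in mm per mm³ (healthy left-ventricular myocardium is of the order of
#' 3000 mm/mm³). Shrinkage correction multiplies lengths by the linear factor
#' and volumes by its cube, so VLD is divided by the factor squared.
#'
#' @param graph A [vessel_graph()].
#' @param tissue_mask Logical 3D array (nonempty).
#' @param geometry A [voxel_geometry()].
#' @param shrinkage_correct Apply the geometry's linear factor (default FALSE).
#' @return List with `vld` (mm/mm³), `total_length_mm`, `tissue_volume_mm3`.
#' @export
vessel_length_density <- function(graph, tissue_mask, geometry,
                                  shrinkage_correct = FALSE) {
  if (!any(tissue_mask)) stop("tissue mask is empty")
  sp <- voxel_spacing(geometry)
  len_um <- 0
  for (path in graph$paths) {
    if (nrow(path) < 2) next
    a <- path[-nrow(path), , drop = FALSE]
    b <- path[-1, , drop = FALSE]
    seg_len <- sqrt(rowSums((b - a)^2))
    mid <- (a + b) / 2
    inside <- sample_at_um(tissue_mask, mid, sp) > 0
    len_um <- len_um + sum(seg_len[inside])
  }
  vol_mm3 <- sum(tissue_mask) * voxel_volume_um3(geometry) / UM3_PER_MM3
  len_mm <- len_um / 1000
  if (shrinkage_correct) {
    f <- geometry$shrinkage_linear
    len_mm <- len_mm * f
    vol_mm3 <- vol_mm3 * f^3
  }
  list(vld = len_mm / vol_mm3, total_length_mm = len_mm,
       tissue_volume_mm3 = vol_mm3)
}

#' Interbranch distance distribution
#'
#' Centerline path lengths of edges whose both end nodes are branch points
#' (degree >= 3). Terminal branch-to-endpoint edges are excluded by default —
#' they measure distance to the tracing boundary, not between branchings.
#'
#' @param graph A [vessel_graph()].
#' @param include_terminal Also count branch-to-endpoint edges (default FALSE).
#' @return List with `ibd_um` (distribution), `ibd_median_um`,
#'   `n_branch_points`, and `empty` flag.
#' @export
interbranch_distance <- function(graph, include_terminal = FALSE) {
  deg <- graph$nodes$degree
  n_branch <- sum(deg >= 3)
  if (!nrow(graph$edges)) {
    return(list(ibd_um = numeric(), ibd_median_um = NA_real_,
                n_branch_points = n_branch, empty = TRUE))
  }
  from_d <- deg[graph$edges$from]
  to_d <- deg[graph$edges$to]
  keep <- (from_d >= 3 & to_d >= 3)
  if (include_terminal) keep <- keep | (pmax(from_d, to_d) >= 3)
  ibd <- graph$edges$length_um[keep]
  list(ibd_um = ibd,
       ibd_median_um = if (length(ibd)) median(ibd) else NA_real_,
       n_branch_points = n_branch, empty = length(ibd) == 0)
}

#' 2D capillary density from a counting field of view
#'
#' Extrapolates a manual count (or the component count of a 2D mask) in a
#' square field of view to capillaries per mm². The standard counting field is
#' 251.49 x 251.49 µm, not shrinkage corrected.
#'
#' @param counts_or_mask A single count, or a 2D logical matrix whose
#'   connected components are counted.
#' @param fov_um Side length of the square field of view, µm.
#' @return Capillaries per mm².
#' @export
capillary_count_2d <- function(counts_or_mask, fov_um = 251.49) {
  if (fov_um <= 0) stop("field of view must be positive")
  n <- if (is.matrix(counts_or_mask)) {
    m <- array(counts_or_mask != 0, dim = c(dim(counts_or_mask), 1L))
    max(label_components(m))
  } else {
    as.numeric(counts_or_mask)
  }
  n / (fov_um / 1000)^2
}

#' Full capillary tracing chain
#'
#' The packaged sequence from a raw CD31 channel to a cleaned centerline
#' graph: Gaussian smoothing (2 µm), rolling-ball background subtraction
#' (20 µm), linear z-upsampling to a near-isotropic grid, global thresholding
#' at a fraction of the Otsu split, removal of sub-resolution components,
#' topology-preserving thinning with spur pruning, and graph simplification
#' (junction-complex merging, crossing resolution). Defaults are tuned on
#' phantoms; every step is exposed individually as well.
#'
#' @param volume A [volume_image()] or 3D array (vessel channel).
#' @param geometry Required for a bare array.
#' @param sigma_um Smoothing sigma, µm.
#' @param ball_um Rolling-ball radius, µm.
#' @param z_upsample Integer z-upsampling factor; `NULL` = `round(z/xy)`.
#' @param threshold Absolute threshold; `NULL` = `threshold_frac` x Otsu.
#' @param threshold_frac Fraction of the Otsu threshold (capillary tips and
#'   oblique segments fall well below the Otsu split on 10 µm plane spacing).
#' @param min_size Minimum connected-component size, voxels.
#' @param prune_vox Spur-pruning threshold, chain voxels.
#' @param merge_um,crossing_dot Graph simplification parameters
#'   (see [simplify_vessel_graph()]); `merge_um = 0` disables simplification.
#' @return List with `graph` (simplified — use for branch statistics such as
#'   the interbranch distance), `graph_raw` (un-simplified — use for total
#'   length and VLD, since junction-complex contraction removes short-edge
#'   length), `mask` (on the upsampled grid), `threshold`, and
#'   `geometry_iso` (upsampled geometry).
#' @export
trace_vessels <- function(volume, geometry = NULL, sigma_um = 2, ball_um = 20,
                          z_upsample = NULL, threshold = NULL,
                          threshold_frac = 0.35, min_size = 5, prune_vox = 4,
                          merge_um = 16, crossing_dot = -0.3) {
  geometry <- geom_of(volume, geometry)
  sm <- gaussian_smooth(volume, sigma_um, geometry)
  bs <- rolling_ball_subtract(sm, ball_um, geometry)
  if (is.null(z_upsample))
    z_upsample <- max(1L, as.integer(round(geometry$z_step / geometry$pixel_size_xy)))
  vu <- resample_z(bs, z_upsample, geometry)
  vx <- as_voxels(vu)
  if (is.null(threshold)) threshold <- threshold_frac * otsu_threshold(as.vector(vx))
  mask <- filter_small_components(vx >= threshold, min_size)
  graph_raw <- skeletonize_and_graph(mask, vu$geometry, prune_vox = prune_vox)
  graph <- if (merge_um > 0)
    simplify_vessel_graph(graph_raw, merge_um = merge_um,
                          crossing_dot = crossing_dot)
  else graph_raw
  list(graph = graph, graph_raw = graph_raw, mask = mask,
       threshold = threshold, geometry_iso = vu$geometry)
}
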