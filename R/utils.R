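# Internal raster primitives shared across modules.

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma_vox))
  x <- -h:h
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable Gaussian smoothing with per-axis voxel sigmas
smooth3d <- function(vox, sigma_vox) {
  out <- vox
  storage.mode(out) <- "double"
  d <- dim(vox)
  for (axis in 1:3) {
    if (sigma_vox[axis] <= 0) next
    k <- gaussian_kernel(sigma_vox[axis])
    if (length(k) > 1)
      out <- array(cc_convolve_axis(out, d, k, axis - 1L), dim = d)
  }
  out
}

# separable box mean (local fraction/mean over a physical window)
box_mean3d <- function(vox, half_vox) {
  out <- vox
  storage.mode(out) <- "double"
  d <- dim(vox)
  for (axis in 1:3) {
    h <- max(0L, as.integer(round(half_vox[axis])))
    if (h == 0) next
    k <- rep(1 / (2 * h + 1), 2 * h + 1)
    out <- array(cc_convolve_axis(out, d, k, axis - 1L), dim = d)
  }
  out
}

# offsets (dx, dy, dz) of an ellipsoidal structuring element with physical
# radius r_um on an anisotropic grid
ball_offsets <- function(r_um, spacing) {
  rv <- pmax(r_um / spacing, 0)
  h <- floor(rv)
  g <- expand.grid(dx = -h[1]:h[1], dy = -h[2]:h[2], dz = -h[3]:h[3])
  keep <- (g$dx / max(rv[1], 1e-9))^2 + (g$dy / max(rv[2], 1e-9))^2 +
    (g$dz / max(rv[3], 1e-9))^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# binary dilation/erosion by a physical radius, via the anisotropic EDT
binary_dilate <- function(mask, r_um, spacing) {
  if (!any(mask)) return(mask)
  d2 <- array(cc_edt_sq(as.logical(mask), dim(mask), spacing), dim = dim(mask))
  d2 <= r_um^2
}

binary_erode <- function(mask, r_um, spacing) {
  if (all(mask)) return(mask)
  d2 <- array(cc_edt_sq(!mask, dim(mask), spacing), dim = dim(mask))
  mask & (d2 > r_um^2)
}

binary_close <- function(mask, r_um, spacing) {
  binary_erode(binary_dilate(mask, r_um, spacing), r_um, spacing)
}

binary_open <- function(mask, r_um, spacing) {
  binary_dilate(binary_erode(mask, r_um, spacing), r_um, spacing)
}

# connected components (logical array in, integer labels out)
label_components <- function(mask, connectivity = 26) {
  array(cc_label3d(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim = dim(mask))
}

# drop components smaller than min_voxels
filter_small_components <- function(mask, min_voxels, connectivity = 26) {
  if (!any(mask) || min_voxels <= 1) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim = dim(mask))
}

largest_component <- function(mask, connectivity = 26) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  array(lab == which.max(sizes), dim = dim(mask))
}

# fill internal holes slice by slice (2D, 4-connected background flood)
fill_holes_slices <- function(mask) {
  out <- mask
  d <- dim(mask)
  for (k in seq_len(d[3])) {
    sl <- array(mask[, , k], dim = c(d[1], d[2], 1L))
    bg <- label_components(!sl, connectivity = 6)
    border_labels <- unique(c(bg[1, , 1], bg[d[1], , 1], bg[, 1, 1], bg[, d[2], 1]))
    border_labels <- border_labels[border_labels > 0]
    out[, , k] <- sl[, , 1] | !(bg[, , 1] %in% c(0L, border_labels))
  }
  out
}

# Otsu's bimodal threshold on a numeric vector
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- hist(values, breaks = breaks, plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# signed physical distance (µm) to the boundary of a mask: negative inside,
# positive outside; magnitude = distance to the nearest voxel of the other
# phase (half-voxel surface offset ignored, documented)
signed_border_distance <- function(mask, spacing) {
  d_to_mask <- sqrt(array(cc_edt_sq(as.logical(mask), dim(mask), spacing),
                          dim = dim(mask)))
  d_to_bg <- sqrt(array(cc_edt_sq(!mask, dim(mask), spacing), dim = dim(mask)))
  ifelse(mask, -d_to_bg, d_to_mask)
}

# trilinear-free nearest-voxel lookup of physical positions (µm) in a volume
sample_at_um <- function(vox, pos_um, spacing) {
  d <- dim(vox)
  i <- pmin(pmax(round(pos_um[, 1] / spacing[1]) + 1, 1), d[1])
  j <- pmin(pmax(round(pos_um[, 2] / spacing[2]) + 1, 1), d[2])
  k <- pmin(pmax(round(pos_um[, 3] / spacing[3]) + 1, 1), d[3])
  vox[cbind(i, j, k)]
}

#' @importFrom graphics hist
NULL
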