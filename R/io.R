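#' A 3D image volume with channel label and voxel geometry
#'
#' The universal raster container of the pipeline: a plain R array with
#' dim = (nx, ny, nz) plus a channel label and a [voxel_geometry()]. Acquired
#' channels are 16-bit integers (0..65535); float intermediates (smoothed,
#' background-subtracted, vesselness) set `float = TRUE` and are only
#' re-quantized at export.
#'
#' @param voxels Numeric 3D array, dim (nx, ny, nz).
#' @param channel Channel label, e.g. "autofluorescence", "CD31", "FITC",
#'   "Ly6G", "F4/80".
#' @param geometry A [voxel_geometry()].
#' @param float Logical; `FALSE` enforces the 16-bit integer range.
#' @return A `volume_image` object.
#' @export
volume_image <- function(voxels, channel = "other", geometry = voxel_geometry(),
                         float = FALSE) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1)) stop("all three dimensions must be >= 1")
  if (!inherits(geometry, "voxel_geometry")) stop("geometry must be a voxel_geometry")
  if (!float) {
    rng <- range(voxels)
    if (rng[1] < 0 || rng[2] > 65535)
      stop("intensities outside the 16-bit range 0..65535")
  }
  structure(list(voxels = voxels, channel = channel, geometry = geometry,
                 float = float),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("volume_image '%s': %d x %d x %d voxels (%s)\n", x$channel,
              d[1], d[2], d[3], if (x$float) "float" else "16-bit"))
  print(x$geometry)
  invisible(x)
}

# Accept either a volume_image or a bare array.
as_voxels <- function(x) {
  if (inherits(x, "volume_image")) x$voxels else x
}

vol_like <- function(template, voxels, float = TRUE) {
  if (inherits(template, "volume_image"))
    volume_image(voxels, template$channel, template$geometry, float = float)
  else voxels
}

geom_of <- function(x, geometry = NULL) {
  if (!is.null(geometry)) return(geometry)
  if (inherits(x, "volume_image")) return(x$geometry)
  stop("a voxel_geometry is required")
}

tiff_bits <- function(path) {
  info <- tiff::readTIFF(path, payload = FALSE)
  if (is.data.frame(info) || is.list(info) && !is.null(info$bits.per.sample))
    return(info$bits.per.sample[[1]])
  attr(info, "bits.per.sample")
}

read_planes_16bit <- function(path) {
  bits <- tryCatch(tiff_bits(path), error = function(e) NULL)
  if (!is.null(bits) && !all(bits == 16))
    stop(sprintf("'%s' is %s-bit; only 16-bit stacks are supported",
                 path, paste(unique(bits), collapse = "/")))
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes
}

#' Read a 16-bit TIFF stack (single multi-page file or per-plane directory)
#'
#' Directories must contain one TIFF per optical plane with zero-padded
#' numeric names so that filename order equals acquisition order; the numeric
#' tokens are checked for strict monotonicity. Intensities are returned
#' unmodified; plane 1 of the array is the first acquired plane.
#'
#' @param path Path to an OME-TIFF/multi-page TIFF file or a directory of
#'   per-plane TIFFs.
#' @param channel Channel label to attach.
#' @param geometry A [voxel_geometry()].
#' @return A [volume_image()].
#' @export
read_stack <- function(path, channel = "other", geometry = voxel_geometry()) {
  if (!file.exists(path)) stop(sprintf("no such file or directory: '%s'", path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop(sprintf("no TIFF files in directory '%s'", path))
    files <- sort(files)
    nums <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
    if (anyNA(nums) || any(diff(nums) <= 0))
      stop("plane filenames are not strictly increasing numerically")
    planes <- unlist(lapply(files, read_planes_16bit), recursive = FALSE)
  } else {
    planes <- read_planes_16bit(path)
  }
  # readTIFF returns matrices indexed [row = y, col = x]; transpose to [x, y]
  nx <- ncol(planes[[1]]); ny <- nrow(planes[[1]])
  vox <- array(0L, dim = c(nx, ny, length(planes)))
  for (k in seq_along(planes)) {
    p <- planes[[k]]
    if (ncol(p) != nx || nrow(p) != ny) stop("plane dimensions differ within stack")
    vox[, , k] <- t(p)
  }
  volume_image(vox, channel, geometry)
}

#' Write a volume as a 16-bit multi-page TIFF
#'
#' Float volumes are rounded and clipped to 0..65535 at export.
#'
#' @param volume A [volume_image()] or 3D array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  vox <- as_voxels(volume)
  vox <- pmin(pmax(round(vox), 0), 65535)
  planes <- lapply(seq_len(dim(vox)[3]), function(k) t(vox[, , k]) / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write a binary mask as an 8-bit multi-page TIFF (0/255)
#' @param mask Logical or 0/1 3D array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  vox <- as_voxels(mask)
  planes <- lapply(seq_len(dim(vox)[3]), function(k) t(vox[, , k] != 0) * 1)
  tiff::writeTIFF(planes, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a mask written by [write_mask()]
#' @param path Path to the 8-bit TIFF.
#' @return Logical 3D array.
#' @export
read_mask <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  nx <- ncol(planes[[1]]); ny <- nrow(planes[[1]])
  vox <- array(FALSE, dim = c(nx, ny, length(planes)))
  for (k in seq_along(planes)) vox[, , k] <- t(planes[[k]]) > 0
  vox
}

#' Write / read the channel-metadata sidecar (YAML)
#'
#' Stores pixel size, z step, shrinkage factor and channel names next to a
#' stack so geometry travels with the data.
#'
#' @param geometry A [voxel_geometry()].
#' @param channels Character vector of channel names.
#' @param path Sidecar path (YAML).
#' @return `path` invisibly (write); a list with `geometry` and `channels`
#'   (read).
#' @export
write_geometry_sidecar <- function(geometry, channels, path) {
  yaml::write_yaml(list(pixel_size_xy = geometry$pixel_size_xy,
                        z_step = geometry$z_step,
                        shrinkage_linear = geometry$shrinkage_linear,
                        channels = as.list(channels)), path)
  invisible(path)
}

#' @rdname write_geometry_sidecar
#' @export
read_geometry_sidecar <- function(path) {
  meta <- yaml::read_yaml(path)
  list(geometry = voxel_geometry(meta$pixel_size_xy, meta$z_step,
                                 meta$shrinkage_linear),
       channels = unlist(meta$channels))
}
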