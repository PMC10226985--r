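#' Multi-channel 3D intensity volume with physical voxel spacing
#'
#' The canonical in-memory carrier for a confocal stack. Data are stored as a
#' 4D array indexed `(channel, z, y, x)`; `voxel_spacing` gives the physical
#' size of one voxel along `(z, y, x)` in micrometres. Physical coordinates
#' place the corner of voxel `(1,1,1)` at the origin, with voxel centers at
#' `(index - 0.5) * spacing`.
#'
#' @param data numeric 4D array `(channel, z, y, x)`, or a 3D array for a
#'   single channel.
#' @param voxel_spacing numeric length-3, `(z, y, x)` spacing in um; all
#'   strictly positive.
#' @param channel_names character vector naming each channel.
#' @return A `volume_image` object.
#' @export
volume_image <- function(data, voxel_spacing, channel_names = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  stopifnot(length(dim(data)) == 4L)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0)) {
    stop("voxel_spacing must be 3 strictly positive values (z, y, x) in um")
  }
  nc <- dim(data)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nc, ")")
  }
  structure(list(data = data, voxel_spacing = voxel_spacing,
                 channel_names = as.character(channel_names)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_image: %d channel(s) [%s], %d x %d x %d voxels (z,y,x)\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  voxel spacing (z,y,x): %s um\n",
              paste(signif(x$voxel_spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Extract one channel of a volume as a 3D array
#'
#' @param img a [volume_image()].
#' @param channel channel name or index.
#' @return 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(img, channel) {
  stopifnot(inherits(img, "volume_image"))
  if (is.character(channel)) {
    i <- match(channel, img$channel_names)
    if (is.na(i)) {
      stop("channel '", channel, "' not found; available: ",
           paste(img$channel_names, collapse = ", "))
    }
    channel <- i
  }
  arr <- img$data[channel, , , , drop = FALSE]
  dim(arr) <- dim(img$data)[-1]
  arr
}

#' Integer-labeled 3D mask volume
#'
#' Cell or nucleus labels on the same voxel grid as a paired
#' [volume_image()]. Label 0 is background.
#'
#' @param labels 3D array of non-negative integers `(z, y, x)`.
#' @param voxel_spacing `(z, y, x)` spacing in um.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, voxel_spacing) {
  stopifnot(length(dim(labels)) == 3L)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0)) {
    stop("voxel_spacing must be 3 strictly positive values (z, y, x) in um")
  }
  if (min(labels) < 0) stop("labels must be non-negative (0 = background)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_spacing = voxel_spacing),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- label_ids(x)
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d object(s), %d x %d x %d voxels (z,y,x), spacing %s um\n",
              length(ids), d[1], d[2], d[3],
              paste(signif(x$voxel_spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Labels present in a label volume (background excluded)
#' @param lab a [label_volume()].
#' @return sorted integer vector of object ids.
#' @export
label_ids <- function(lab) {
  stopifnot(inherits(lab, "label_volume"))
  ids <- sort(unique(as.vector(lab$labels)))
  ids[ids > 0L]
}

#' Photobleach recovery time series
#'
#' Raw FRAP measurements: ROI intensity, non-photobleached reference, and a
#' background estimate (scalar or per-frame). `bleach_index` is the index of
#' the first post-bleach frame; frames before it are pre-bleach.
#'
#' @param t time in seconds, strictly increasing.
#' @param roi mean intensity of the bleached region per frame.
#' @param reference mean intensity of a non-bleached reference region.
#' @param background background intensity, scalar or per-frame. Default 0.
#' @param bleach_index index (1-based) of the first post-bleach frame;
#'   at least 2 (one pre-bleach frame must exist).
#' @return A `frap_trace` object.
#' @export
frap_trace <- function(t, roi, reference, background = 0, bleach_index) {
  t <- as.numeric(t); roi <- as.numeric(roi); reference <- as.numeric(reference)
  n <- length(t)
  stopifnot(length(roi) == n, length(reference) == n)
  if (length(background) == 1L) background <- rep(as.numeric(background), n)
  stopifnot(length(background) == n)
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0) {
    stop("time must be strictly increasing; violated at row(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index > n) {
    stop("bleach_index must lie in [2, n]: need at least one pre-bleach frame")
  }
  structure(list(t = t, roi = roi, reference = reference,
                 background = background, bleach_index = bleach_index),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("frap_trace: %d frames (%d pre-bleach), t = %.3g .. %.3g s\n",
              length(x$t), x$bleach_index - 1L, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Object boundary points in physical coordinates
#'
#' @param points numeric matrix with columns x, y, z (um).
#' @param object_id integer id of the originating object.
#' @param source one of "cell", "nucleus", "apical_subset".
#' @return A `surface_points` object.
#' @export
surface_points <- function(points, object_id = NA_integer_,
                           source = c("cell", "nucleus", "apical_subset")) {
  source <- match.arg(source)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix (x, y, z) in um")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, object_id = object_id, source = source),
            class = "surface_points")
}

#' @export
print.surface_points <- function(x, ...) {
  cat(sprintf("surface_points (%s, id %s): %d points\n",
              x$source, x$object_id, nrow(x$points)))
  invisible(x)
}

#' Triangle mesh of an object surface
#'
#' @param vertices n x 3 matrix of vertex coordinates (x, y, z) in um.
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented with outward normals.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  storage.mode(faces) <- "integer"
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}
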