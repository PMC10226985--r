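#' Euclidean distance transform with anisotropic voxel spacing
#'
#' Distance (um) from every foreground voxel to the center of the nearest
#' background voxel, computed by a separable lower-envelope transform with
#' per-axis physical spacing. Background voxels get distance 0.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param voxel_spacing `(z, y, x)` spacing in um.
#' @return numeric 3D array of distances in um.
#' @export
distance_transform <- function(mask, voxel_spacing) {
  stopifnot(length(dim(mask)) == 3L)
  d <- cpp_sq_edt(as.logical(mask), dim(mask), as.numeric(voxel_spacing))
  array(sqrt(d), dim(mask))
}

#' Physical-unit binary erosion and dilation
#'
#' Erosion keeps foreground voxels farther than `r_um` from background;
#' dilation adds background voxels within `r_um` of the foreground. Both
#' threshold the anisotropic Euclidean distance transform, so the band depth
#' is `r_um` micrometres along every axis regardless of voxel shape. The
#' surface is taken at foreground voxel centers.
#'
#' @param mask logical 3D array.
#' @param voxel_spacing `(z, y, x)` um.
#' @param r_um radius in um, `>= 0`.
#' @return logical 3D array.
#' @export
erode_um <- function(mask, voxel_spacing, r_um) {
  stopifnot(r_um >= 0)
  if (r_um == 0) return(mask & TRUE)
  d <- distance_transform(mask, voxel_spacing)
  mask & (d > r_um)
}

#' @rdname erode_um
#' @export
dilate_um <- function(mask, voxel_spacing, r_um) {
  stopifnot(r_um >= 0)
  if (r_um == 0) return(mask | FALSE)
  d <- distance_transform(!mask, voxel_spacing)
  mask | (d <= r_um)
}

#' Subvoxel-refined distance to the object surface
#'
#' The binary voxel-center distance transform localizes the surface only to
#' within half a voxel, which matters when a band of interest (e.g. a 1 um
#' lamina shell) is just a few voxels thick. This refinement resamples the
#' trilinearly interpolated occupancy on a `factor`-times finer grid,
#' thresholds it at 0.5 (placing the surface midway between foreground and
#' background voxel centers), computes the anisotropic EDT there, and
#' samples the result back at the original voxel centers.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param voxel_spacing `(z, y, x)` um.
#' @param factor integer upsampling factor (2 is ample).
#' @return numeric 3D array: distance (um) from each voxel center to the
#'   subvoxel surface estimate (0 outside the object).
#' @export
subvoxel_distance <- function(mask, voxel_spacing, factor = 2L) {
  stopifnot(length(dim(mask)) == 3L, factor >= 1L)
  d <- dim(mask)
  occ <- array(as.numeric(mask), d)
  fine <- occ
  for (axis in 1:3) fine <- upsample_axis(fine, axis, factor)
  fine <- fine >= 0.5
  fed <- array(sqrt(cpp_sq_edt(as.logical(fine), dim(fine),
                               voxel_spacing / factor)), dim(fine))
  for (axis in 1:3) fed <- sample_centers_axis(fed, axis, factor)
  fed[!mask] <- 0
  fed
}

# linear interpolation of a grid onto a factor-times finer grid along one
# axis; fine centers at (j - 0.5) / f in original index units (+ 0.5 shift)
upsample_axis <- function(arr, axis, f) {
  n <- dim(arr)[axis]
  g <- (seq_len(n * f) - 0.5) / f + 0.5
  i0 <- pmin(pmax(floor(g), 1L), n)
  i1 <- pmin(i0 + 1L, n)
  w <- pmin(pmax(g - i0, 0), 1)
  a0 <- switch(axis, arr[i0, , , drop = FALSE], arr[, i0, , drop = FALSE],
               arr[, , i0, drop = FALSE])
  a1 <- switch(axis, arr[i1, , , drop = FALSE], arr[, i1, , drop = FALSE],
               arr[, , i1, drop = FALSE])
  wdim <- c(1L, 1L, 1L); wdim[axis] <- n * f
  wa <- array(rep(w, length.out = length(a0)), dim(a0))
  if (axis == 2) wa <- aperm(array(w, dim(a0)[c(2, 1, 3)]), c(2, 1, 3))
  if (axis == 3) wa <- aperm(array(w, dim(a0)[c(3, 1, 2)]), c(2, 3, 1))
  a0 * (1 - wa) + a1 * wa
}

# linear interpolation of a fine grid back at the original voxel centers
# along one axis; original center i sits at fine index f*(i-0.5)+0.5
sample_centers_axis <- function(fine, axis, f) {
  nf <- dim(fine)[axis]
  n <- nf %/% f
  g <- f * (seq_len(n) - 0.5) + 0.5
  i0 <- pmin(pmax(floor(g), 1L), nf)
  i1 <- pmin(i0 + 1L, nf)
  w <- pmin(pmax(g - i0, 0), 1)
  a0 <- switch(axis, fine[i0, , , drop = FALSE], fine[, i0, , drop = FALSE],
               fine[, , i0, drop = FALSE])
  a1 <- switch(axis, fine[i1, , , drop = FALSE], fine[, i1, , drop = FALSE],
               fine[, , i1, drop = FALSE])
  wa <- array(rep(w, length.out = length(a0)), dim(a0))
  if (axis == 2) wa <- aperm(array(w, dim(a0)[c(2, 1, 3)]), c(2, 1, 3))
  if (axis == 3) wa <- aperm(array(w, dim(a0)[c(3, 1, 2)]), c(2, 3, 1))
  a0 * (1 - wa) + a1 * wa
}

#' Separable Gaussian smoothing in physical units
#'
#' @param arr numeric 3D array `(z, y, x)`.
#' @param voxel_spacing `(z, y, x)` um.
#' @param sigma_um Gaussian sigma in um (scalar, applied along all axes).
#' @return smoothed array, same shape.
#' @export
gaussian_smooth <- function(arr, voxel_spacing, sigma_um) {
  if (sigma_um <= 0) return(arr)
  for (axis in 1:3) {
    s_vox <- sigma_um / voxel_spacing[axis]
    halfw <- max(1L, ceiling(3 * s_vox))
    k <- exp(-0.5 * ((-halfw:halfw) / s_vox)^2)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, axis)
  }
  arr
}

# Convolve along one axis with a symmetric kernel, replicating edges.
convolve_axis <- function(arr, kernel, axis) {
  halfw <- (length(kernel) - 1L) / 2L
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (j in seq_along(kernel)) {
    off <- j - 1L - halfw
    src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate boundary
    idx <- switch(axis,
                  arr[src, , , drop = FALSE],
                  arr[, src, , drop = FALSE],
                  arr[, , src, drop = FALSE])
    out <- out + kernel[j] * idx
  }
  out
}

#' Otsu threshold of an intensity array
#'
#' Maximizes between-class variance on a fixed-width histogram.
#'
#' @param arr numeric array.
#' @param n_bins histogram bins.
#' @return threshold value on the intensity scale.
#' @export
otsu_threshold <- function(arr, n_bins = 256L) {
  v <- as.vector(arr)
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image: no threshold exists")
  h <- tabulate(pmin(pmax(
    as.integer((v - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Connected-component labeling (6-connectivity)
#'
#' @param mask logical 3D array.
#' @return integer 3D array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  array(cpp_label_components(as.logical(mask), dim(mask)), dim(mask))
}

#' Fill interior holes of a 3D mask
#'
#' Background components not connected to the array border become foreground.
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(!mask)
  d <- dim(bg)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  border <- border[border > 0]
  hole <- array(bg > 0 & !(bg %in% border), d)
  mask | hole
}

#' Boundary voxels of a mask
#'
#' Foreground voxels with at least one face-adjacent background neighbor;
#' the volume border counts as background.
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
boundary_mask <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  boundary <- array(FALSE, d)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      shift <- c(0L, 0L, 0L); shift[axis] <- dir
      nb <- pad[2:(d[1] + 1) + shift[1],
                2:(d[2] + 1) + shift[2],
                2:(d[3] + 1) + shift[3]]
      boundary <- boundary | (mask & !nb)
    }
  }
  boundary
}

#' Marker-based watershed restricted to a mask
#'
#' Priority-flood growth of labeled seeds over a relief image (low values
#' flood first), 6-connected, confined to `mask`. Deterministic: ties are
#' broken by queue insertion order.
#'
#' @param relief numeric 3D array (e.g. a membrane channel).
#' @param seeds integer 3D array of seed labels (0 elsewhere).
#' @param mask logical 3D array of allowed territory.
#' @return integer 3D array of labels.
#' @export
seeded_watershed <- function(relief, seeds, mask) {
  stopifnot(all(dim(relief) == dim(seeds)), all(dim(relief) == dim(mask)))
  storage.mode(seeds) <- "integer"
  array(cpp_seeded_watershed(as.numeric(relief), seeds,
                             as.logical(mask), dim(relief)),
        dim(relief))
}
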