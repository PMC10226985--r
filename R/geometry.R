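#' Boundary voxel centers of a mask, in physical coordinates
#'
#' A boundary voxel is a foreground voxel with at least one face-adjacent
#' background neighbor (the volume border counts as background). Returned
#' points are voxel centers `(index - 0.5) * spacing` plus `origin`, as
#' `(x, y, z)` um.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param voxel_spacing `(z, y, x)` um.
#' @param object_id,source metadata for the resulting [surface_points()].
#' @param origin physical offset `(x, y, z)` um of the array corner, for
#'   masks cropped out of a larger volume.
#' @return a [surface_points()] object.
#' @export
surface_points_from_mask <- function(mask, voxel_spacing,
                                     object_id = NA_integer_,
                                     source = "cell", origin = c(0, 0, 0)) {
  if (!any(mask)) stop("empty mask")
  if (all(mask)) {
    stop("mask fills the whole volume: no background to define a surface")
  }
  idx <- which(boundary_mask(mask), arr.ind = TRUE)
  pts <- cbind(x = (idx[, 3] - 0.5) * voxel_spacing[3] + origin[1],
               y = (idx[, 2] - 0.5) * voxel_spacing[2] + origin[2],
               z = (idx[, 1] - 0.5) * voxel_spacing[1] + origin[3])
  surface_points(pts, object_id = object_id, source = source)
}

# minimum distance from each row of `a` to the point set `b`, chunked;
# points of b farther than `limit` from a's bounding box are ignored.
min_dist_to_set <- function(a, b, limit = Inf) {
  out <- rep(Inf, nrow(a))
  if (nrow(b) == 0) return(out)
  if (is.finite(limit)) {
    lo <- apply(a, 2, min) - limit; hi <- apply(a, 2, max) + limit
    keep <- b[, 1] >= lo[1] & b[, 1] <= hi[1] &
            b[, 2] >= lo[2] & b[, 2] <= hi[2] &
            b[, 3] >= lo[3] & b[, 3] <= hi[3]
    b <- b[keep, , drop = FALSE]
    if (nrow(b) == 0) return(out)
  }
  step <- max(1L, floor(2e6 / nrow(b)))
  for (s in seq(1L, nrow(a), by = step)) {
    rows <- s:min(s + step - 1L, nrow(a))
    d2 <- outer(rowSums(a[rows, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[rows, , drop = FALSE] %*% t(b)
    out[rows] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Extract the apical (contact-free) surface of a cell
#'
#' Deletes every surface point lying strictly closer than `cutoff_um` to any
#' neighboring cell's surface; the remainder is the apical surface. Points
#' at exactly the cutoff distance are retained. An empty result is
#' meaningful: a fully internalized (inner) cell has no apical surface.
#'
#' @param cell a [surface_points()] cloud of the cell.
#' @param neighbors list of [surface_points()] clouds of all other cells.
#' @param cutoff_um deletion cutoff in um, > 0.
#' @return a [surface_points()] cloud with `source = "apical_subset"`
#'   (possibly 0 rows).
#' @export
extract_apical_surface <- function(cell, neighbors, cutoff_um = 1.0) {
  stopifnot(inherits(cell, "surface_points"), cutoff_um > 0)
  keep <- rep(TRUE, nrow(cell$points))
  for (nb in neighbors) {
    if (!any(keep)) break
    d <- min_dist_to_set(cell$points[keep, , drop = FALSE], nb$points,
                         limit = cutoff_um)
    keep[keep] <- d >= cutoff_um
  }
  surface_points(cell$points[keep, , drop = FALSE],
                 object_id = cell$object_id, source = "apical_subset")
}

#' Apical surface of a cell directly from a label volume
#'
#' Equivalent to [extract_apical_surface()] on the boundary-voxel point
#' clouds, but computes each surface point's distance to the nearest voxel
#' of any other cell with one Euclidean distance transform on a cropped
#' region, which is exact for voxel-center point sets and much faster than
#' the all-pairs scan. Points at exactly the cutoff distance are retained.
#'
#' @param cells a [label_volume()] of cells.
#' @param id the cell whose apical surface is wanted.
#' @param cutoff_um deletion cutoff in um, > 0.
#' @return a [surface_points()] cloud with `source = "apical_subset"`.
#' @export
apical_surface_from_labels <- function(cells, id, cutoff_um = 1.0) {
  stopifnot(inherits(cells, "label_volume"), cutoff_um > 0)
  sp <- cells$voxel_spacing
  lab <- cells$labels
  own_full <- lab == id
  if (!any(own_full)) stop("no voxels with label ", id)
  pad <- as.integer(ceiling(cutoff_um / min(sp))) + 2L
  bb <- bbox_of(own_full, dim(lab), pad = pad)
  sub <- lab[bb$z, bb$y, bb$x, drop = FALSE]
  own <- sub == id
  other <- sub > 0L & sub != id
  d_other <- distance_transform(!other, sp)
  bnd <- boundary_mask(own)
  keep <- bnd & (d_other >= cutoff_um)
  origin <- c((bb$x[1] - 1) * sp[3], (bb$y[1] - 1) * sp[2],
              (bb$z[1] - 1) * sp[1])
  idx <- which(keep, arr.ind = TRUE)
  pts <- cbind(x = (idx[, 3] - 0.5) * sp[3] + origin[1],
               y = (idx[, 2] - 0.5) * sp[2] + origin[2],
               z = (idx[, 1] - 0.5) * sp[1] + origin[3])
  surface_points(pts, object_id = id, source = "apical_subset")
}

#' Area of a surface patch from its point cloud
#'
#' Projects the points onto their best-fit plane (principal axes), builds a
#' 2D Delaunay triangulation of the projection, maps the triangles back to
#' the 3D points, prunes triangles with any edge longer than
#' `max_edge_factor` times the median nearest-neighbor spacing (these bridge
#' holes or disjoint patches), and sums the 3D triangle areas. With exactly
#' 3 points the area is the area of that triangle.
#'
#' @param apical a [surface_points()] cloud (a patch that is a graph over
#'   its best-fit plane, e.g. an apical cap).
#' @param max_edge_factor pruning multiplier; `Inf` disables pruning.
#' @return area in um^2; 0 for fewer than 3 points.
#' @export
apical_surface_area <- function(apical, max_edge_factor = 4) {
  stopifnot(inherits(apical, "surface_points"))
  p <- apical$points
  if (nrow(p) < 3) return(0)
  if (nrow(p) == 3) return(triangle_area(p[1, ], p[2, ], p[3, ]))
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
  uv <- pc %*% ev$vectors[, 1:2]       # in-plane coordinates
  span <- max(apply(uv, 2, function(x) diff(range(x))))
  if (span == 0) return(0)
  # deterministic tiny jitter to break cocircular grid degeneracies
  jit <- (seq_len(nrow(uv)) %% 97L) / 97 - 0.5
  tri <- cpp_delaunay2d(uv[, 1] + 1e-7 * span * jit,
                        uv[, 2] + 1e-7 * span * rev(jit))
  if (nrow(tri) == 0) return(0)
  e1 <- sqrt(rowSums((p[tri[, 1], ] - p[tri[, 2], ])^2))
  e2 <- sqrt(rowSums((p[tri[, 2], ] - p[tri[, 3], ])^2))
  e3 <- sqrt(rowSums((p[tri[, 3], ] - p[tri[, 1], ])^2))
  if (is.finite(max_edge_factor)) {
    nn <- median(c(e1, e2, e3))
    keep <- pmax(e1, e2, e3) <= max_edge_factor * nn
    tri <- tri[keep, , drop = FALSE]
  }
  if (nrow(tri) == 0) return(0)
  a <- p[tri[, 1], , drop = FALSE]
  b <- p[tri[, 2], , drop = FALSE]
  cc <- p[tri[, 3], , drop = FALSE]
  ab <- b - a; ac <- cc - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

triangle_area <- function(a, b, c) {
  ab <- b - a; ac <- c - a
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  sqrt(sum(cr^2)) / 2
}

#' Radially oriented minimal bounding box of a cell
#'
#' The box z-axis points from the embryo center of mass to the center of
#' mass of the apical surface (falling back to the cell's own center of
#' mass when the apical set is empty; the fallback is recorded in the
#' `radial_fallback` attribute). In-plane axes are chosen to minimize the
#' `Lx * Ly` footprint by a 0.25-degree grid search with golden-section
#' refinement. `Lz_api` is the z-extent of the apical points in the same
#' frame.
#'
#' @param cell a [surface_points()] cloud of the cell.
#' @param embryo_cm embryo center of mass `(x, y, z)` um.
#' @param apical apical [surface_points()] (may have 0 rows).
#' @return an `oriented_box` list: `Lx`, `Ly`, `Lz`, `Lz_api`, `frame`
#'   (3x3 orthonormal, columns x, y, z).
#' @export
oriented_bounding_box <- function(cell, embryo_cm, apical = NULL) {
  stopifnot(inherits(cell, "surface_points"))
  p <- cell$points
  fallback <- is.null(apical) || nrow(apical$points) == 0
  target <- if (fallback) colMeans(p) else colMeans(apical$points)
  zdir <- target - as.numeric(embryo_cm)
  nz <- sqrt(sum(zdir^2))
  if (nz < 1e-12) stop("zero-length radial vector: apical CM coincides with embryo CM")
  zdir <- zdir / nz
  seed <- if (abs(zdir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * zdir) * zdir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(zdir[2] * e1[3] - zdir[3] * e1[2],
          zdir[3] * e1[1] - zdir[1] * e1[3],
          zdir[1] * e1[2] - zdir[2] * e1[1])
  u <- p %*% e1
  v <- p %*% e2
  w <- p %*% zdir

  footprint <- function(phi) {
    cu <- cos(phi) * u + sin(phi) * v
    cv <- -sin(phi) * u + cos(phi) * v
    diff(range(cu)) * diff(range(cv))
  }
  grid <- seq(0, pi / 2, by = 0.25 * pi / 180)
  fp <- vapply(grid, footprint, numeric(1))
  i0 <- which.min(fp)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(footprint, c(lo, hi))
  phi <- if (opt$objective < fp[i0]) opt$minimum else grid[i0]
  cu <- cos(phi) * u + sin(phi) * v
  cv <- -sin(phi) * u + cos(phi) * v
  ex <- cos(phi) * e1 + sin(phi) * e2
  ey <- -sin(phi) * e1 + cos(phi) * e2
  lz_api <- if (fallback) 0 else diff(range(apical$points %*% zdir))
  structure(list(Lx = diff(range(cu)), Ly = diff(range(cv)),
                 Lz = diff(range(w)), Lz_api = lz_api,
                 frame = cbind(x = ex, y = ey, z = zdir)),
            class = "oriented_box", radial_fallback = fallback)
}

#' Aspect ratio of a radially oriented box
#'
#' `(Lz - max(Lx, Ly)) / (Lz + max(Lx, Ly))`, in (-1, 1); positive means
#' radially elongated, negative flattened.
#'
#' @param box an `oriented_box` from [oriented_bounding_box()].
#' @return unitless value in (-1, 1).
#' @export
aspect_ratio <- function(box) {
  mxy <- max(box$Lx, box$Ly)
  if (box$Lz + mxy <= 0) stop("degenerate box: all extents zero")
  (box$Lz - mxy) / (box$Lz + mxy)
}

#' Flatness of a cell: apical z-extent over total z-extent
#'
#' `Lz_api / Lz`, in `[0, 1]`; small values mean a flat apical cap.
#'
#' @param box an `oriented_box`.
#' @return unitless value in `[0, 1]`.
#' @export
flatness <- function(box) {
  if (box$Lz <= 0) stop("degenerate box: Lz = 0")
  box$Lz_api / box$Lz
}

#' Euclidean distance between an object and the embryo center of mass
#'
#' @param object_cm,embryo_cm points `(x, y, z)` um.
#' @return distance in um.
#' @export
distance_to_embryo_cm <- function(object_cm, embryo_cm) {
  sqrt(sum((as.numeric(object_cm) - as.numeric(embryo_cm))^2))
}

#' Least-squares ellipsoid fit of a surface point cloud
#'
#' Algebraic least-squares quadric fit (smallest singular vector of the
#' design matrix), constrained post hoc to describe a real ellipsoid. For
#' points sampled exactly on an ellipsoid the semi-axes are recovered to
#' well below 1%.
#'
#' @param nucleus a [surface_points()] cloud with at least 9 points in
#'   general position.
#' @return an `ellipsoid_fit` list: `center` (x, y, z um), `semi_axes`
#'   (descending, um), `orientation` (columns = axes), `residuals`
#'   (per-point normalized radial distance).
#' @export
fit_ellipsoid <- function(nucleus) {
  stopifnot(inherits(nucleus, "surface_points"))
  p <- nucleus$points
  if (nrow(p) < 9) stop("ellipsoid fit underdetermined: need >= 9 points")
  ctr0 <- colMeans(p)
  sc <- mean(sqrt(rowSums(sweep(p, 2, ctr0)^2)))
  if (sc == 0) stop("degenerate point cloud")
  # pre-align to the cloud's principal axes: makes the algebraic fit
  # rotation-equivariant (the ||v|| = 1 gauge is not, on its own)
  pc <- sweep(p, 2, ctr0)
  ev0 <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
  R0 <- ev0$vectors
  # fix signs deterministically so the frame is unique
  for (j in 1:3) if (R0[which.max(abs(R0[, j])), j] < 0) R0[, j] <- -R0[, j]
  if (det(R0) < 0) R0[, 3] <- -R0[, 3]
  q <- (pc %*% R0) / sc
  x <- q[, 1]; y <- q[, 2]; z <- q[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z,
             2 * x, 2 * y, 2 * z, 1)
  v <- svd(D, nu = 0)$v[, 10]
  A3 <- matrix(c(v[1], v[4], v[5],
                 v[4], v[2], v[6],
                 v[5], v[6], v[3]), 3, 3)
  b3 <- v[7:9]
  det3 <- det(A3)
  if (abs(det3) < 1e-12) stop("quadric fit degenerated: singular form matrix")
  cen <- -solve(A3, b3)
  cprime <- sum(b3 * solve(A3, b3)) - v[10]
  ev <- eigen(A3 / cprime, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    stop("quadric fit is not an ellipsoid (non-positive form); ",
         "eigenvalues: ", paste(signif(ev$values, 3), collapse = ", "))
  }
  semi <- 1 / sqrt(ev$values)              # in scaled units
  ord <- order(semi, decreasing = TRUE)
  semi <- semi[ord] * sc
  orient <- R0 %*% ev$vectors[, ord, drop = FALSE]   # back to world axes
  center <- drop(R0 %*% (cen * sc)) + ctr0
  M <- orient %*% diag(1 / semi^2) %*% t(orient)
  u <- sweep(p, 2, center)
  rp <- sqrt(rowSums(u^2))
  s <- 1 / sqrt(rowSums((u %*% M) * u))    # radial scale to the surface
  res <- abs(rp - s * rp) / rp
  structure(list(center = center, semi_axes = semi, orientation = orient,
                 residuals = res),
            class = "ellipsoid_fit")
}

#' Nuclear deformation index
#'
#' Mean over surface points of the radial distance between the point and
#' the fitted ellipsoid surface (measured along the ray from the ellipsoid
#' center through the point), normalized by the point's distance to the
#' center. Zero iff the points lie exactly on the ellipsoid; grows with
#' surface wrinkling.
#'
#' @param nucleus a [surface_points()] cloud.
#' @param fit an `ellipsoid_fit` from [fit_ellipsoid()].
#' @return unitless index >= 0.
#' @export
nuclear_deformation_index <- function(nucleus, fit) {
  stopifnot(inherits(nucleus, "surface_points"),
            inherits(fit, "ellipsoid_fit"))
  u <- sweep(nucleus$points, 2, fit$center)
  rp <- sqrt(rowSums(u^2))
  if (any(rp < 1e-9)) stop("surface point coincides with the ellipsoid center")
  M <- fit$orientation %*% diag(1 / fit$semi_axes^2) %*% t(fit$orientation)
  s <- 1 / sqrt(rowSums((u %*% M) * u))    # p scaled by s lies on the surface
  re <- s * rp                             # ellipsoid radius along the ray
  mean(abs(rp - re) / rp)
}

# ---- star-convex surface meshing -------------------------------------------

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

#' Unit icosphere mesh
#'
#' Subdivided icosahedron with vertices on the unit sphere and outward
#' consistently oriented faces.
#'
#' @param subdiv number of 4-fold subdivisions (0 = icosahedron).
#' @return a [surface_mesh()].
#' @export
icosphere <- function(subdiv = 3) {
  m <- icosahedron()
  for (s in seq_len(subdiv)) {
    v <- m$vertices; f <- m$faces
    ekey <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      hit <- ekey[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      ekey[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(k - 1) * 4 + 1, ] <- c(a, ab, ca)
      nf[(k - 1) * 4 + 2, ] <- c(b, bc, ab)
      nf[(k - 1) * 4 + 3, ] <- c(cc, ca, bc)
      nf[(k - 1) * 4 + 4, ] <- c(ab, bc, ca)
    }
    m <- list(vertices = rbind(v, do.call(rbind, newv)), faces = nf)
  }
  surface_mesh(m$vertices, m$faces)
}

# trilinear interpolation of a 3D array at physical points (x, y, z um)
trilinear <- function(arr, voxel_spacing, pts) {
  d <- dim(arr)
  gz <- pts[, 3] / voxel_spacing[1] + 0.5
  gy <- pts[, 2] / voxel_spacing[2] + 0.5
  gx <- pts[, 1] / voxel_spacing[3] + 0.5
  gz <- pmin(pmax(gz, 1), d[1]); gy <- pmin(pmax(gy, 1), d[2])
  gx <- pmin(pmax(gx, 1), d[3])
  z0 <- pmin(floor(gz), d[1] - 1); y0 <- pmin(floor(gy), d[2] - 1)
  x0 <- pmin(floor(gx), d[3] - 1)
  fz <- gz - z0; fy <- gy - y0; fx <- gx - x0
  at <- function(dz, dy, dx) arr[cbind(z0 + dz, y0 + dy, x0 + dx)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(0, 0, 1)) +
              fy * ((1 - fx) * at(0, 1, 0) + fx * at(0, 1, 1))) +
  fz * ((1 - fy) * ((1 - fx) * at(1, 0, 0) + fx * at(1, 0, 1)) +
        fy * ((1 - fx) * at(1, 1, 0) + fx * at(1, 1, 1)))
}

#' Triangle mesh of a star-convex mask by radial sampling
#'
#' Casts rays from the mask's center of mass along icosphere directions and
#' places a vertex where the trilinearly interpolated occupancy crosses 0.5
#' (subvoxel surface localization). Valid for star-shaped objects (nuclei
#' and blastomere-like cells); returns a closed, manifold, consistently
#' oriented mesh suitable for area and curvature computation.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param voxel_spacing `(z, y, x)` um.
#' @param subdiv icosphere subdivisions (3 gives 1280 faces).
#' @param origin physical offset `(x, y, z)` um of the array corner.
#' @return a [surface_mesh()].
#' @export
surface_mesh_from_mask <- function(mask, voxel_spacing, subdiv = 3,
                                   origin = c(0, 0, 0)) {
  if (!any(mask)) stop("empty mask")
  occ <- array(as.numeric(mask), dim(mask))
  idx <- which(mask, arr.ind = TRUE)
  ctr <- c(mean((idx[, 3] - 0.5) * voxel_spacing[3]),
           mean((idx[, 2] - 0.5) * voxel_spacing[2]),
           mean((idx[, 1] - 0.5) * voxel_spacing[1]))
  ico <- icosphere(subdiv)
  dirs <- ico$vertices
  rmax <- sqrt(max(rowSums(sweep(cbind((idx[, 3] - 0.5) * voxel_spacing[3],
                                       (idx[, 2] - 0.5) * voxel_spacing[2],
                                       (idx[, 1] - 0.5) * voxel_spacing[1]),
                                 2, ctr)^2))) + max(voxel_spacing)
  step <- min(voxel_spacing) / 2
  nst <- ceiling(rmax / step)
  n <- nrow(dirs)
  lo <- rep(0, n); hi <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  for (k in seq_len(nst)) {
    t_k <- k * step
    pts <- sweep(dirs[alive, , drop = FALSE] * t_k, 2, ctr, "+")
    val <- trilinear(occ, voxel_spacing, pts)
    crossed <- val < 0.5
    ia <- which(alive)
    hi[ia[crossed]] <- t_k
    lo[ia[!crossed]] <- t_k
    alive[ia[crossed]] <- FALSE
    if (!any(alive)) break
  }
  hi[is.na(hi)] <- rmax
  for (it in 1:25) {
    mid <- (lo + hi) / 2
    pts <- sweep(dirs * mid, 2, ctr, "+")
    val <- trilinear(occ, voxel_spacing, pts)
    inside <- val >= 0.5
    lo[inside] <- mid[inside]
    hi[!inside] <- mid[!inside]
  }
  r <- (lo + hi) / 2
  verts <- sweep(dirs * r, 2, ctr, "+")
  verts <- sweep(verts, 2, as.numeric(origin), "+")
  surface_mesh(verts, ico$faces)
}

#' Total area of a triangle mesh
#' @param mesh a [surface_mesh()].
#' @return area in um^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  ab <- v[f[, 2], ] - v[f[, 1], ]
  ac <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Sphericity of a 3D object
#'
#' `psi = pi^(1/3) * (6 V)^(2/3) / A` with the volume from the voxel count
#' times the voxel volume and the area from the radially sampled surface
#' mesh. Equals 1 for a perfect sphere, less for any other shape.
#'
#' @param mask logical 3D array.
#' @param voxel_spacing `(z, y, x)` um.
#' @param subdiv mesh resolution (see [surface_mesh_from_mask()]).
#' @return unitless sphericity in (0, 1].
#' @export
sphericity <- function(mask, voxel_spacing, subdiv = 3) {
  V <- sum(mask) * prod(voxel_spacing)
  A <- mesh_area(surface_mesh_from_mask(mask, voxel_spacing, subdiv))
  if (A <= 0) stop("zero surface area")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Discrete mean curvature of a closed triangle mesh
#'
#' Cotangent-Laplacian estimator with mixed (barycentric) vertex areas:
#' the magnitude of the discrete mean-curvature vector per vertex, signed
#' positive for locally convex (sphere-like) vertices. For a sphere of
#' radius R the estimate is 1/R everywhere.
#'
#' @param mesh a closed, manifold [surface_mesh()].
#' @return list: `H` per-vertex signed mean curvature (1/um), `summary`
#'   with mean, sd (the deformation score) and quartiles.
#' @export
local_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  ekey <- paste0(pmin(f[, c(1, 2, 3)], f[, c(2, 3, 1)]), "_",
                 pmax(f[, c(1, 2, 3)], f[, c(2, 3, 1)]))
  cnt <- table(ekey)
  if (any(cnt != 2)) {
    stop("mesh is not closed/manifold: ", sum(cnt != 2),
         " edge(s) not shared by exactly 2 faces")
  }
  Kx <- rep(0, nv); Ky <- rep(0, nv); Kz <- rep(0, nv)
  A <- rep(0, nv)
  Nx <- rep(0, nv); Ny <- rep(0, nv); Nz <- rep(0, nv)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  fidx <- cbind(i1, i2, i3)
  # face normals and areas
  ab <- v[i2, ] - v[i1, ]; ac <- v[i3, ] - v[i1, ]
  fn <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  fa <- sqrt(rowSums(fn^2)) / 2
  # per-face corner cotangents (angle at corner k is opposite edge i-j)
  cots <- matrix(0, nrow(f), 3)
  for (k in 1:3) {
    cc <- fidx[, k]; a <- fidx[, corners[[k]][2]]; b <- fidx[, corners[[k]][3]]
    u <- v[a, ] - v[cc, ]; w <- v[b, ] - v[cc, ]
    cots[, k] <- rowSums(u * w) / sqrt(pmax(rowSums(u^2) * rowSums(w^2) -
                                              rowSums(u * w)^2, 1e-300))
  }
  for (k in 1:3) {
    cc <- fidx[, k]; a <- fidx[, corners[[k]][2]]; b <- fidx[, corners[[k]][3]]
    cot <- cots[, k]
    e <- v[a, ] - v[b, ]
    # accumulate cot * (x_a - x_b) onto a, and the negative onto b
    Kx <- Kx + tabulate2(a, cot * e[, 1], nv) - tabulate2(b, cot * e[, 1], nv)
    Ky <- Ky + tabulate2(a, cot * e[, 2], nv) - tabulate2(b, cot * e[, 2], nv)
    Kz <- Kz + tabulate2(a, cot * e[, 3], nv) - tabulate2(b, cot * e[, 3], nv)
    # mixed Voronoi area (Meyer et al.): circumcentric for non-obtuse
    # triangles, area/2 at the obtuse corner and area/4 elsewhere otherwise
    obt <- cots[, 1] < 0 | cots[, 2] < 0 | cots[, 3] < 0
    ljk2 <- rowSums((v[a, ] - v[cc, ])^2)   # edge cc-a, opposite corner b
    lkk2 <- rowSums((v[b, ] - v[cc, ])^2)   # edge cc-b, opposite corner a
    avor <- (ljk2 * cots[, corners[[k]][3]] +
               lkk2 * cots[, corners[[k]][2]]) / 8
    amix <- ifelse(obt, ifelse(cot < 0, fa / 2, fa / 4), avor)
    A <- A + tabulate2(cc, amix, nv)
    Nx <- Nx + tabulate2(cc, fn[, 1], nv)
    Ny <- Ny + tabulate2(cc, fn[, 2], nv)
    Nz <- Nz + tabulate2(cc, fn[, 3], nv)
  }
  Kx <- Kx / (2 * A); Ky <- Ky / (2 * A); Kz <- Kz / (2 * A)
  mag <- sqrt(Kx^2 + Ky^2 + Kz^2) / 2
  sgn <- sign(Kx * Nx + Ky * Ny + Kz * Nz)
  H <- mag * ifelse(sgn == 0, 1, sgn)
  list(H = H,
       summary = c(mean = mean(H), sd = sd(H),
                   q25 = unname(quantile(H, 0.25)),
                   median = median(H),
                   q75 = unname(quantile(H, 0.75))))
}

# sum `w` into bins `i` of length n (tabulate with weights)
tabulate2 <- function(i, w, n) {
  out <- rep(0, n)
  agg <- rowsum(w, i)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
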