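test_that("surface points lie at boundary voxel centers in physical units", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  sp <- surface_points_from_mask(m, c(2, 0.5, 0.5))
  expect_equal(nrow(sp$points), 1L)
  expect_equal(unname(sp$points[1, ]), c(0.75, 0.75, 3))  # (x, y, z)
  # digital ball: all points at radius 10 within a voxel diagonal
  h <- 0.5
  ball <- ball_mask(10, c(h, h, h))
  bp <- surface_points_from_mask(ball, c(h, h, h))
  ctr <- dim(ball) * h / 2
  r <- sqrt(rowSums(sweep(bp$points, 2, c(ctr[3], ctr[2], ctr[1]))^2))
  expect_lt(max(abs(r - 10)), sqrt(3) * h)
  expect_error(surface_points_from_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1)),
               "fills")
  expect_error(surface_points_from_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1)),
               "empty")
})

test_that("apical extraction keeps contact-free points and handles edge cases", {
  # two spheres 20 um apart: retained cap faces away from the contact
  s1 <- surface_points(unit_sphere_points(800) * 10, 1, "cell")
  p2 <- sweep(unit_sphere_points(800) * 10, 2, c(0, 0, 20), "+")
  s2 <- surface_points(p2, 2, "cell")
  ap <- extract_apical_surface(s1, list(s2), cutoff_um = 2)
  expect_gt(nrow(ap$points), 0)
  expect_lt(nrow(ap$points), nrow(s1$points))
  # brute-force check of the deletion rule
  keep_bf <- apply(s1$points, 1, function(p) {
    min(sqrt(colSums((t(p2) - p)^2))) >= 2
  })
  expect_equal(nrow(ap$points), sum(keep_bf))
  expect_true(all(ap$points[, 3] < 20 - 8))  # cap faces away from contact
  # no neighbors: full surface retained
  ap2 <- extract_apical_surface(s1, list(), 2)
  expect_equal(nrow(ap2$points), nrow(s1$points))
  # everything within cutoff: empty apical set is meaningful
  ap3 <- extract_apical_surface(s1, list(s1), 2)
  expect_equal(nrow(ap3$points), 0L)
  expect_equal(apical_surface_area(ap3), 0)
})

test_that("EDT-based apical extraction equals the point-cloud rule on labels", {
  ph <- generate_embryo_phantom(phantom_spec(n_cells = 2, embryo_radius = 14,
                                             cell_radius_mean = 11, seed = 5))
  cl <- ph$truth_cells
  s1 <- surface_points_from_mask(cl$labels == 1L, cl$voxel_spacing, 1, "cell")
  s2 <- surface_points_from_mask(cl$labels == 2L, cl$voxel_spacing, 2, "cell")
  a_pc <- extract_apical_surface(s1, list(s2), 1.0)
  a_ed <- apical_surface_from_labels(cl, 1L, 1.0)
  key <- function(p) paste(round(p[, 1], 6), round(p[, 2], 6),
                           round(p[, 3], 6))
  expect_setequal(key(a_pc$points), key(a_ed$points))
})

test_that("apical surface area matches the analytic spherical cap", {
  R <- 10; h <- 3
  pts <- unit_sphere_points(6000) * R
  cap <- pts[pts[, 3] >= R - h, ]
  a <- apical_surface_area(surface_points(cap))
  expect_lt(abs(a / (2 * pi * R * h) - 1), 0.05)
  # 3 points: single facet
  tri <- surface_points(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  expect_equal(apical_surface_area(tri), 6)
})

test_that("oriented bounding box matches construction and brute-force search", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 1), y = seq(0, 10, 1),
                             z = seq(0, 20, 1)))
  surf <- g[g[, 1] %in% c(0, 10) | g[, 2] %in% c(0, 10) |
              g[, 3] %in% c(0, 20), ]
  box <- oriented_bounding_box(surface_points(surf), c(5, 5, -30),
                               surface_points(surf[surf[, 3] == 20, ]))
  expect_equal(c(box$Lx, box$Ly, box$Lz), c(10, 10, 20), tolerance = 1e-9)
  expect_equal(aspect_ratio(box), 1 / 3, tolerance = 1e-12)
  # sphere: all extents equal the diameter
  u <- unit_sphere_points(2000) * 7
  bs <- oriented_bounding_box(surface_points(u), c(0, 0, -20),
                              surface_points(u[u[, 3] > 6, , drop = FALSE]))
  expect_lt(max(abs(c(bs$Lx, bs$Ly, bs$Lz) - 14)), 0.05)
  expect_equal(unname(crossprod(bs$frame)), diag(3), tolerance = 1e-9)
  # brute-force in-plane rotation search at 0.5 degree grid
  set.seed(17)
  for (rep in 1:10) {
    pts <- matrix(rnorm(1200), ncol = 3) %*% diag(c(3, 1.5, 1)) %*%
      qr.Q(qr(matrix(rnorm(9), 3)))
    ap <- surface_points(pts[pts[, 3] > quantile(pts[, 3], 0.8), ,
                             drop = FALSE])
    b <- oriented_bounding_box(surface_points(pts), c(0, 0, -25), ap)
    zdir <- b$frame[, 3]
    seed <- if (abs(zdir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- seed - sum(seed * zdir) * zdir; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(zdir[2] * e1[3] - zdir[3] * e1[2],
            zdir[3] * e1[1] - zdir[1] * e1[3],
            zdir[1] * e1[2] - zdir[2] * e1[1])
    uu <- pts %*% e1; vv <- pts %*% e2
    best <- Inf
    for (a in seq(0, 90, 0.5) * pi / 180) {
      cu <- cos(a) * uu + sin(a) * vv
      cv <- -sin(a) * uu + cos(a) * vv
      f <- diff(range(cu)) * diff(range(cv))
      if (f < best) best <- f
    }
    expect_lt(b$Lx * b$Ly, best * 1.01)
  }
})

test_that("aspect ratio and flatness implement the printed formulas", {
  box <- structure(list(Lx = 10, Ly = 8, Lz = 5, Lz_api = 2),
                   class = "oriented_box")
  expect_equal(aspect_ratio(box), (5 - 10) / (5 + 10))
  expect_equal(flatness(box), 2 / 5)
  cube <- structure(list(Lx = 7, Ly = 7, Lz = 7, Lz_api = 7),
                    class = "oriented_box")
  expect_equal(aspect_ratio(cube), 0)
  expect_equal(flatness(cube), 1)
  # hemispherical apical cap on a sphere: flatness ~ 0.5
  u <- unit_sphere_points(4000) * 9
  hemi <- u[u[, 3] >= 0, , drop = FALSE]
  bh <- oriented_bounding_box(surface_points(u), c(0, 0, -30),
                              surface_points(hemi))
  expect_lt(abs(flatness(bh) - 0.5), 0.02)
  degen <- structure(list(Lx = 0, Ly = 0, Lz = 0, Lz_api = 0),
                     class = "oriented_box")
  expect_error(aspect_ratio(degen), "degenerate")
  expect_error(flatness(degen), "degenerate")
})

test_that("distance to embryo CM is the plain 2-norm", {
  expect_equal(distance_to_embryo_cm(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(distance_to_embryo_cm(c(4, 6, 3), c(1, 2, 3)), 5)
})

test_that("ellipsoid fit recovers exact surfaces within 1%", {
  u <- unit_sphere_points(500)
  f_sph <- fit_ellipsoid(surface_points(u * 8))
  expect_lt(max(abs(f_sph$semi_axes - 8)) / 8, 0.01)
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  ell <- sweep(u, 2, c(10, 7, 5), "*") %*% t(Q) +
    matrix(c(3, -2, 5), nrow(u), 3, byrow = TRUE)
  f <- fit_ellipsoid(surface_points(ell))
  expect_lt(max(abs(f$semi_axes - c(10, 7, 5)) / c(10, 7, 5)), 0.01)
  expect_equal(unname(f$center), c(3, -2, 5), tolerance = 1e-6)
  expect_error(fit_ellipsoid(surface_points(u[1:5, ])), "underdetermined")
})

test_that("deformation index is zero on the fit, matches brute force, and is monotone", {
  u <- unit_sphere_points(1500)
  ell <- sweep(u, 2, c(9, 7, 6), "*")
  f <- fit_ellipsoid(surface_points(ell))
  expect_lt(nuclear_deformation_index(surface_points(ell), f), 1e-9)
  # radially perturbed sphere: index ~ (2/pi) * a for r = R(1 + a cos(k theta))
  a0 <- 0.1; k <- 6; R <- 8
  th <- acos(pmin(pmax(u[, 3], -1), 1)); ph <- atan2(u[, 2], u[, 1])
  rr <- R * (1 + a0 * cos(k * th))
  P <- cbind(rr * sin(th) * cos(ph), rr * sin(th) * sin(ph), rr * cos(th))
  fp <- fit_ellipsoid(surface_points(P))
  di <- nuclear_deformation_index(surface_points(P), fp)
  # brute-force oracle: numeric radial distance point by point
  M <- fp$orientation %*% diag(1 / fp$semi_axes^2) %*% t(fp$orientation)
  bf <- mean(vapply(seq_len(nrow(P)), function(i) {
    uu <- P[i, ] - fp$center
    rp <- sqrt(sum(uu^2))
    s <- 1 / sqrt(drop(t(uu) %*% M %*% uu))
    abs(rp - s * rp) / rp
  }, numeric(1)))
  expect_lt(abs(di / bf - 1), 0.02)
  expect_lt(abs(di - 2 / pi * a0), 0.01)
  # monotone in the wrinkle amplitude
  set.seed(3); coef <- rnorm(13)
  W <- laminmorph:::sh_perturbation(6, th, ph, coef)
  idx <- vapply(c(0, 0.05, 0.1, 0.2), function(a) {
    s <- surface_points(u * R * (1 + a * W))
    nuclear_deformation_index(s, fit_ellipsoid(s))
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("geometric outputs are rigid-invariant and scale-covariant", {
  set.seed(21)
  u <- unit_sphere_points(600)
  th <- acos(pmin(pmax(u[, 3], -1), 1))
  pts <- sweep(u, 2, c(9, 6, 5), "*") * (1 + 0.03 * sin(6 * th))
  ap_idx <- pts[, 3] > 3
  cm <- c(0, 0, -20)
  Q <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tv <- c(12, -5, 8)
  move <- function(p) p %*% t(Q) + matrix(tv, nrow(p), 3, byrow = TRUE)
  f1 <- fit_ellipsoid(surface_points(pts))
  f2 <- fit_ellipsoid(surface_points(move(pts)))
  expect_equal(f1$semi_axes, f2$semi_axes, tolerance = 1e-5)
  d1 <- nuclear_deformation_index(surface_points(pts), f1)
  d2 <- nuclear_deformation_index(surface_points(move(pts)), f2)
  expect_equal(d1, d2, tolerance = 1e-5)
  b1 <- oriented_bounding_box(surface_points(pts), cm,
                              surface_points(pts[ap_idx, ]))
  b2 <- oriented_bounding_box(surface_points(move(pts)), drop(move(rbind(cm))),
                              surface_points(move(pts[ap_idx, ])))
  expect_equal(b1$Lz, b2$Lz, tolerance = 1e-6)
  expect_equal(b1$Lx * b1$Ly, b2$Lx * b2$Ly, tolerance = 1e-4)
  a1 <- apical_surface_area(surface_points(pts[ap_idx, ]))
  a2 <- apical_surface_area(surface_points(move(pts[ap_idx, ])))
  expect_equal(a1, a2, tolerance = 1e-6)
  # scaling: lengths linear, areas quadratic, indices invariant
  f3 <- fit_ellipsoid(surface_points(pts * 2))
  expect_equal(f3$semi_axes, 2 * f1$semi_axes, tolerance = 1e-6)
  expect_equal(nuclear_deformation_index(surface_points(pts * 2), f3), d1,
               tolerance = 1e-9)
  expect_equal(apical_surface_area(surface_points(pts[ap_idx, ] * 2)),
               4 * a1, tolerance = 1e-6)
})

test_that("sphericity matches closed forms for ball and ellipsoid", {
  h <- c(0.5, 0.25, 0.25)
  ball <- ball_mask(10, h)
  expect_gt(sphericity(ball, h), 0.97)
  # ellipsoid semi-axes (10, 5, 5): Thomsen-approximation oracle
  dims <- ceiling(2 * c(11, 11, 11) / h)
  az <- (seq_len(dims[1]) - 0.5) * h[1] - 11
  ay <- (seq_len(dims[2]) - 0.5) * h[2] - 11
  ax <- (seq_len(dims[3]) - 0.5) * h[3] - 11
  m <- outer(outer(az^2 / 25, ay^2 / 25, "+"), ax^2 / 100, "+") <= 1
  p <- 1.6075; axs <- c(10, 5, 5)
  A <- 4 * pi * ((axs[1]^p * axs[2]^p + axs[1]^p * axs[3]^p +
                    axs[2]^p * axs[3]^p) / 3)^(1 / p)
  psi_true <- pi^(1 / 3) * (6 * 4 / 3 * pi * prod(axs))^(2 / 3) / A
  expect_lt(abs(sphericity(m, h) / psi_true - 1), 0.03)
})

test_that("wrinkled phantom nuclei are less spherical and more deformed than smooth ones", {
  smooth <- tiny_phantom(wrinkle = 0)
  wrinkled <- tiny_phantom(wrinkle = 0.12)
  sp <- smooth$image$voxel_spacing
  psi_s <- sphericity(smooth$truth_nuclei$labels == 1L, sp)
  psi_w <- sphericity(wrinkled$truth_nuclei$labels == 1L, sp)
  expect_gt(psi_s, psi_w)
  ds <- surface_points_from_mask(smooth$truth_nuclei$labels == 1L, sp)
  dw <- surface_points_from_mask(wrinkled$truth_nuclei$labels == 1L, sp)
  expect_gt(nuclear_deformation_index(dw, fit_ellipsoid(dw)),
            nuclear_deformation_index(ds, fit_ellipsoid(ds)))
})

test_that("mean curvature is 1/R on spheres, ~0 on plane-like patches, larger SD on lobed shapes", {
  ic <- icosphere(4)
  mesh <- surface_mesh(ic$vertices * 8, ic$faces)
  cv <- local_curvature(mesh)
  expect_lt(max(abs(cv$H - 1 / 8)) / (1 / 8), 0.10)
  # lobed (4-cell-like) shape has a wider curvature distribution
  th <- acos(pmin(pmax(ic$vertices[, 3], -1), 1))
  ph <- atan2(ic$vertices[, 2], ic$vertices[, 1])
  lobed <- ic$vertices * 8 * (1 + 0.15 * sin(th)^2 * cos(2 * ph))
  cv2 <- local_curvature(surface_mesh(lobed, ic$faces))
  expect_gt(cv2$summary["sd"], 3 * cv$summary["sd"])
  # open mesh is rejected
  expect_error(local_curvature(surface_mesh(ic$vertices,
                                            ic$faces[-1, , drop = FALSE])),
               "manifold")
})

test_that("flat patches of a mesh have near-zero curvature", {
  # flatten a band of a large sphere: curvature there far below 1/R of the
  # curved part is impractical on a closed mesh; use a huge radius instead
  ic <- icosphere(3)
  mesh <- surface_mesh(ic$vertices * 1000, ic$faces)
  cv <- local_curvature(mesh)
  expect_lt(max(abs(cv$H)), 0.002)  # 1/1000 per um, plane-like
})

test_that("radial mesh area converges to analytic sphere area", {
  h <- c(0.5, 0.25, 0.25)
  ball <- ball_mask(9, h)
  mesh <- surface_mesh_from_mask(ball, h)
  expect_lt(abs(mesh_area(mesh) / (4 * pi * 81) - 1), 0.02)
})
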