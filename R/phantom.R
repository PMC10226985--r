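#' Specification of a synthetic embryo phantom
#'
#' Describes a 2-32 cell embryo packed around a common center, with nuclei
#' whose lamina shell has a configurable intensity ratio to the nucleoplasm,
#' configurable nuclear-surface wrinkling, cortical plus cytoplasmic
#' filament-meshwork signal, designated fully-enclosed inner cells, and a
#' Poisson-Gaussian noise model. Cells are realized as a seeded power-diagram
#' partition of the embryo ball: centers for inner cells sit near the embryo
#' center, the rest on an outer shell, so the partition is space-filling
#' (blastomere-like) and inner cells are watertightly enclosed.
#'
#' Default dimensions emulate an 8-cell mouse embryo (embryo radius 26 um,
#' blastomere radius about 10 um, nuclei a bit over half the cell radius)
#' imaged on a confocal with sub-micrometre xy sampling and a coarser z step,
#' so every downstream computation is forced through anisotropic
#' physical-unit code paths.
#'
#' @param n_cells number of cells (2-32; 1 allowed for single-object tests).
#' @param embryo_radius embryo radius in um.
#' @param voxel_spacing `(z, y, x)` voxel size in um.
#' @param cell_radius_mean,cell_radius_sd power-diagram radius weights in um;
#'   the sd jitters relative cell sizes.
#' @param nucleus_radius_fraction nucleus radius as a fraction of the
#'   effective (equal-volume sphere) cell radius, in (0, 1).
#' @param true_ln_ratio per-cell lamina:nucleoplasm intensity ratio (>= 0);
#'   recycled to `n_cells`.
#' @param lamina_thickness radial thickness of the lamina shell in um.
#' @param wrinkle_amplitude RMS relative radial perturbation of the nuclear
#'   surface (0 = smooth sphere).
#' @param wrinkle_order spherical-harmonic degree of the wrinkling.
#' @param cortical_intensity intensity of the cortical band in the membrane
#'   and actin channels.
#' @param cytoplasmic_mesh_density per-cell mean intensity of the cytoplasmic
#'   F-actin-like meshwork; recycled to `n_cells`.
#' @param dapi_intensity nuclear DNA-stain intensity.
#' @param nucleoplasm_intensity lamin-channel nucleoplasm intensity; the
#'   lamina shell is `true_ln_ratio` times this.
#' @param marker_nuclear,marker_cytoplasmic optional per-cell intensities for
#'   an extra "marker" channel (for nuclear:cytoplasmic ratio tests); both
#'   NULL omits the channel.
#' @param noise_gaussian_sd Gaussian read-noise sd (intensity units).
#' @param noise_poisson_scale gain of scaled-Poisson shot noise; 0 disables.
#' @param inner_cell_ids integer ids (in `1:n_cells`) of cells that must be
#'   fully enclosed by other cells.
#' @param seed integer RNG seed; the same seed gives bit-identical phantoms.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(n_cells = 8,
                         embryo_radius = 26,
                         voxel_spacing = c(0.7, 0.35, 0.35),
                         cell_radius_mean = 10,
                         cell_radius_sd = 0.8,
                         nucleus_radius_fraction = 0.55,
                         true_ln_ratio = 2.0,
                         lamina_thickness = 1.0,
                         wrinkle_amplitude = 0,
                         wrinkle_order = 6L,
                         cortical_intensity = 150,
                         cytoplasmic_mesh_density = 40,
                         dapi_intensity = 100,
                         nucleoplasm_intensity = 100,
                         marker_nuclear = NULL,
                         marker_cytoplasmic = NULL,
                         noise_gaussian_sd = 5,
                         noise_poisson_scale = 1,
                         inner_cell_ids = integer(0),
                         seed = 1L) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L || n_cells > 32L) stop("n_cells must be in 1..32")
  stopifnot(embryo_radius > 0, cell_radius_mean > 0, cell_radius_sd >= 0,
            lamina_thickness > 0, wrinkle_amplitude >= 0,
            nucleus_radius_fraction > 0, nucleus_radius_fraction < 1,
            noise_gaussian_sd >= 0, noise_poisson_scale >= 0)
  true_ln_ratio <- rep_len(as.numeric(true_ln_ratio), n_cells)
  if (any(true_ln_ratio < 0)) stop("true_ln_ratio must be >= 0")
  cytoplasmic_mesh_density <- rep_len(as.numeric(cytoplasmic_mesh_density),
                                      n_cells)
  inner_cell_ids <- as.integer(inner_cell_ids)
  if (length(inner_cell_ids) > 0 &&
      (any(inner_cell_ids < 1L) || any(inner_cell_ids > n_cells))) {
    stop("inner_cell_ids must lie in 1..n_cells")
  }
  if (!is.null(marker_nuclear)) {
    marker_nuclear <- rep_len(as.numeric(marker_nuclear), n_cells)
  }
  if (!is.null(marker_cytoplasmic)) {
    marker_cytoplasmic <- rep_len(as.numeric(marker_cytoplasmic), n_cells)
  }
  structure(list(
    n_cells = n_cells, embryo_radius = embryo_radius,
    voxel_spacing = as.numeric(voxel_spacing),
    cell_radius_mean = cell_radius_mean, cell_radius_sd = cell_radius_sd,
    nucleus_radius_fraction = nucleus_radius_fraction,
    true_ln_ratio = true_ln_ratio, lamina_thickness = lamina_thickness,
    wrinkle_amplitude = wrinkle_amplitude,
    wrinkle_order = as.integer(wrinkle_order),
    cortical_intensity = cortical_intensity,
    cytoplasmic_mesh_density = cytoplasmic_mesh_density,
    dapi_intensity = dapi_intensity,
    nucleoplasm_intensity = nucleoplasm_intensity,
    marker_nuclear = marker_nuclear,
    marker_cytoplasmic = marker_cytoplasmic,
    noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson_scale = noise_poisson_scale,
    inner_cell_ids = inner_cell_ids, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Evaluate a seeded random real spherical-harmonic perturbation field of
# degree l at directions (theta, phi), normalized to unit RMS over the
# sphere. coeffs: numeric length 2l+1 (m = 0, cos 1..l, sin 1..l).
sh_perturbation <- function(l, theta, phi, coeffs) {
  x <- cos(theta)
  P <- pracma::legendre(l, x)              # rows m = 0..l
  if (is.null(dim(P))) P <- matrix(P, ncol = 1)
  norm_c <- sum(coeffs^2) / (4 * pi)       # RMS^2 of the raw combination
  coeffs <- coeffs / sqrt(norm_c)
  w <- coeffs[1] * sqrt((2 * l + 1) / (4 * pi)) * P[1, ]
  for (m in seq_len(l)) {
    nlm <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    w <- w + coeffs[1 + m] * sqrt(2) * nlm * P[m + 1, ] * cos(m * phi)
    w <- w + coeffs[1 + l + m] * sqrt(2) * nlm * P[m + 1, ] * sin(m * phi)
  }
  w
}

# Deterministic quasi-uniform directions on the unit sphere.
fibonacci_sphere <- function(m) {
  if (m == 1) return(matrix(c(0, 0, 1), 1))
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  cbind(x = r * cos(golden * i), y = r * sin(golden * i), z = z)
}

# Evaluate code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic embryo phantom with known ground truth
#'
#' Produces a multi-channel volume (channels `dapi`, `membrane`, `lamin`,
#' `actin`, and optionally `marker`) together with ground-truth cell,
#' nucleus and lamina-shell label volumes and a per-cell truth table. Before
#' noise, the lamin channel is piecewise constant, so the voxel-mean
#' lamina:nucleoplasm ratio measured on the truth masks equals
#' `true_ln_ratio` exactly; the cytoplasmic mesh is normalized so its mean
#' over each cell's cytoplasm equals `cytoplasmic_mesh_density` exactly.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` ([volume_image()]), `truth_cells`,
#'   `truth_nuclei`, `truth_lamina` ([label_volume()]s; the lamina volume is
#'   labeled by nucleus id) and `truth_table` (data.frame with per-cell
#'   ground truth: `cell_id`, `inner`, `true_ln_ratio`, centroid, nucleus
#'   radius, wrinkle amplitude, mesh density, volumes).
#' @export
generate_embryo_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  sp <- spec$voxel_spacing
  margin <- 2.5
  half <- spec$embryo_radius + margin
  nvox <- pmax(8L, as.integer(ceiling(2 * half / sp)))
  dims <- nvox                                  # (z, y, x)
  ctr <- nvox * sp / 2                          # embryo center, um
  az <- (seq_len(dims[1]) - 0.5) * sp[1] - ctr[1]
  ay <- (seq_len(dims[2]) - 0.5) * sp[2] - ctr[2]
  ax <- (seq_len(dims[3]) - 0.5) * sp[3] - ctr[3]

  r2 <- outer(outer(az^2, ay^2, "+"), ax^2, "+")
  embryo <- r2 <= spec$embryo_radius^2

  n <- spec$n_cells
  inner <- spec$inner_cell_ids
  k <- length(inner)
  centers <- matrix(0, n, 3)                    # (x, y, z) um, embryo-centered
  if (k > 0) {
    if (k == 1) centers[inner, ] <- 0
    else centers[inner, ] <- fibonacci_sphere(k) * 0.18 * spec$embryo_radius
  }
  outer_ids <- setdiff(seq_len(n), inner)
  if (length(outer_ids) > 0) {
    # 0.62 R places the inner/outer power bisector so that designated inner
    # cells receive volumes comparable to outer cells (blastomere-like
    # proportions) instead of being starved by the surrounding shell
    shell_r <- if (n == 1) 0 else 0.62 * spec$embryo_radius
    centers[outer_ids, ] <- fibonacci_sphere(length(outer_ids)) * shell_r
  }
  centers <- centers + matrix(rnorm(3 * n, sd = 0.02 * spec$embryo_radius),
                              n, 3)
  radii <- pmax(rnorm(n, spec$cell_radius_mean, spec$cell_radius_sd),
                0.3 * spec$cell_radius_mean)

  # power-diagram assignment over the embryo ball
  zc <- array(rep(az, times = dims[2] * dims[3]), dims)
  yc <- array(rep(rep(ay, each = dims[1]), times = dims[3]), dims)
  xc <- array(rep(ax, each = dims[1] * dims[2]), dims)
  best <- array(Inf, dims)
  cells <- array(0L, dims)
  for (i in seq_len(n)) {
    pd <- (xc - centers[i, 1])^2 + (yc - centers[i, 2])^2 +
          (zc - centers[i, 3])^2 - radii[i]^2
    take <- embryo & (pd < best)
    best[take] <- pd[take]
    cells[take] <- i
  }

  counts <- tabulate(cells[cells > 0L], n)
  if (any(counts == 0L)) {
    stop("phantom packing failure: cell(s) ",
         paste(which(counts == 0L), collapse = ", "),
         " received no voxels at the requested radii")
  }

  # channels
  nc <- if (is.null(spec$marker_nuclear) && is.null(spec$marker_cytoplasmic))
          4L else 5L
  chn <- c("dapi", "membrane", "lamin", "actin", if (nc == 5L) "marker")
  vol <- array(0, c(nc, dims))
  nuclei <- array(0L, dims)
  lamina <- array(0L, dims)

  vox_vol <- prod(sp)
  truth <- data.frame(cell_id = seq_len(n))
  truth$inner <- seq_len(n) %in% inner
  truth$true_ln_ratio <- spec$true_ln_ratio
  truth$mesh_density <- spec$cytoplasmic_mesh_density
  truth$wrinkle_amplitude <- spec$wrinkle_amplitude
  cmx <- cmy <- cmz <- nr <- numeric(n)

  l <- spec$wrinkle_order
  for (i in seq_len(n)) {
    idx <- which(cells == i)
    cmx[i] <- mean(xc[idx]); cmy[i] <- mean(yc[idx]); cmz[i] <- mean(zc[idx])
    r_eff <- (3 * counts[i] * vox_vol / (4 * pi))^(1 / 3)
    rn <- spec$nucleus_radius_fraction * r_eff
    wr_coef <- rnorm(2 * l + 1)                 # drawn even when unused,
                                                # keeps RNG stream stable

    # nucleus center = the cell's inscribed-sphere center (EDT argmax):
    # nuclei self-center within blastomeres, and this maximizes clearance
    cidx <- which(cells == i, arr.ind = TRUE)
    cz <- range(cidx[, 1]); cy <- range(cidx[, 2]); cx <- range(cidx[, 3])
    cbz <- max(1, cz[1] - 1):min(dims[1], cz[2] + 1)
    cby <- max(1, cy[1] - 1):min(dims[2], cy[2] + 1)
    cbx <- max(1, cx[1] - 1):min(dims[3], cx[2] + 1)
    dcell_full <- distance_transform(cells[cbz, cby, cbx] == i, sp)
    mpos <- arrayInd(which.max(dcell_full), dim(dcell_full))
    d_free <- max(dcell_full)
    ncz <- az[cbz[mpos[1]]]; ncy <- ay[cby[mpos[2]]]; ncx <- ax[cbx[mpos[3]]]

    # bounding box around the nucleus, with room for wrinkles
    reach0 <- rn * (1 + 3.5 * spec$wrinkle_amplitude)
    bz <- which(abs(az - ncz) <= reach0 + sp[1])
    by <- which(abs(ay - ncy) <= reach0 + sp[2])
    bx <- which(abs(ax - ncx) <= reach0 + sp[3])
    sub_cell <- cells[bz, by, bx] == i
    dz <- az[bz] - ncz; dy <- ay[by] - ncy; dx <- ax[bx] - ncx
    rr <- sqrt(outer(outer(dz^2, dy^2, "+"), dx^2, "+"))

    if (spec$wrinkle_amplitude > 0) {
      zrel <- array(rep(dz, length(dy) * length(dx)), dim(rr))
      yrel <- array(rep(rep(dy, each = length(dz)), length(dx)), dim(rr))
      xrel <- array(rep(dx, each = length(dz) * length(dy)), dim(rr))
      rs <- pmax(rr, 1e-9)
      theta <- acos(pmin(pmax(zrel / rs, -1), 1))
      phi <- atan2(yrel, xrel)
      w <- array(sh_perturbation(l, theta, phi, wr_coef), dim(rr))
      wmax <- max(abs(w))
    } else {
      w <- 0
      wmax <- 0
    }

    # keep the whole nucleus inside its cell
    cap <- 0.9 * d_free / (1 + spec$wrinkle_amplitude * max(wmax, 1))
    rn <- min(rn, cap)
    if (rn < 2 * max(sp)) {
      stop("phantom packing failure: nucleus of cell ", i,
           " does not fit (radius ", signif(rn, 3), " um)")
    }
    nr[i] <- rn

    r_loc <- rn * (1 + spec$wrinkle_amplitude * w)
    nuc <- sub_cell & (rr <= r_loc)
    shell <- nuc & (rr > r_loc - spec$lamina_thickness)
    nucleop <- nuc & !shell
    if (!any(shell) || !any(nucleop)) {
      stop("phantom packing failure: degenerate lamina split for cell ", i)
    }

    nsub <- nuclei[bz, by, bx]; nsub[nuc] <- i; nuclei[bz, by, bx] <- nsub
    lsub <- lamina[bz, by, bx]; lsub[shell] <- i; lamina[bz, by, bx] <- lsub

    dsub <- vol[1, bz, by, bx]; dsub[nuc] <- spec$dapi_intensity
    vol[1, bz, by, bx] <- dsub
    lamsub <- vol[3, bz, by, bx]
    lamsub[nucleop] <- spec$nucleoplasm_intensity
    lamsub[shell] <- spec$nucleoplasm_intensity * spec$true_ln_ratio[i]
    vol[3, bz, by, bx] <- lamsub
  }

  # cortical band + cytoplasmic meshwork, cell by cell (cropped)
  cortex_half <- 0.6
  for (i in seq_len(n)) {
    idx <- which(cells == i, arr.ind = TRUE)
    bz <- max(1, min(idx[, 1]) - 2):min(dims[1], max(idx[, 1]) + 2)
    by <- max(1, min(idx[, 2]) - 2):min(dims[2], max(idx[, 2]) + 2)
    bx <- max(1, min(idx[, 3]) - 2):min(dims[3], max(idx[, 3]) + 2)
    sub_cell <- cells[bz, by, bx] == i
    dcell <- distance_transform(sub_cell, sp)
    # the one-voxel boundary layer is always included so the cortical shell
    # stays watertight even where voxel spacing exceeds the band width
    band <- sub_cell & ((dcell <= cortex_half) | boundary_mask(sub_cell))
    sub_nuc <- nuclei[bz, by, bx] == i
    cyto <- sub_cell & !band & !sub_nuc

    msub <- vol[2, bz, by, bx]; msub[band] <- spec$cortical_intensity
    vol[2, bz, by, bx] <- msub

    asub <- vol[4, bz, by, bx]
    asub[band] <- spec$cortical_intensity
    if (any(cyto) && spec$cytoplasmic_mesh_density[i] > 0) {
      speck <- array(rbinom(length(sub_cell), 1, 0.15), dim(sub_cell))
      mesh <- gaussian_smooth(speck, sp, 0.5)
      mv <- mesh[cyto]
      asub[cyto] <- mv / mean(mv) * spec$cytoplasmic_mesh_density[i]
    }
    vol[4, bz, by, bx] <- asub

    if (nc == 5L) {
      ksub <- vol[5, bz, by, bx]
      if (!is.null(spec$marker_nuclear)) {
        ksub[sub_nuc] <- spec$marker_nuclear[i]
      }
      if (!is.null(spec$marker_cytoplasmic)) {
        ksub[sub_cell & !sub_nuc] <- spec$marker_cytoplasmic[i]
      }
      vol[5, bz, by, bx] <- ksub
    }
  }

  # enclosure check for designated inner cells (face adjacency to label 0)
  if (k > 0) {
    touching <- outer_touching_ids(cells)
    bad <- intersect(inner, touching)
    if (length(bad) > 0) {
      stop("phantom packing failure: inner cell(s) ",
           paste(bad, collapse = ", "), " touch the embryo exterior")
    }
  }

  # Poisson-Gaussian noise, applied after structure synthesis
  if (spec$noise_poisson_scale > 0) {
    g <- spec$noise_poisson_scale
    vol[] <- g * rpois(length(vol), pmax(vol, 0) / g)
  }
  if (spec$noise_gaussian_sd > 0) {
    vol <- vol + rnorm(length(vol), sd = spec$noise_gaussian_sd)
  }

  truth$centroid_x <- cmx + ctr[3]
  truth$centroid_y <- cmy + ctr[2]
  truth$centroid_z <- cmz + ctr[1]
  truth$nucleus_radius_um <- nr
  truth$cell_volume_um3 <- counts * vox_vol
  truth$nucleus_volume_um3 <- tabulate(nuclei[nuclei > 0L], n) * vox_vol

  list(image = volume_image(vol, sp, chn),
       truth_cells = label_volume(cells, sp),
       truth_nuclei = label_volume(nuclei, sp),
       truth_lamina = label_volume(lamina, sp),
       truth_table = truth)
}

# ids of cells with at least one voxel face-adjacent to background,
# where "background" includes the volume border
outer_touching_ids <- function(labels) {
  d <- dim(labels)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- labels
  touch <- integer(0)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      shift <- c(0L, 0L, 0L); shift[axis] <- dir
      i1 <- 2:(d[1] + 1) + shift[1]
      i2 <- 2:(d[2] + 1) + shift[2]
      i3 <- 2:(d[3] + 1) + shift[3]
      nb <- pad[i1, i2, i3]
      touch <- union(touch, unique(labels[labels > 0L & nb == 0L]))
    }
  }
  sort(touch)
}

#' Generate a synthetic FRAP trace with known recovery parameters
#'
#' The noiseless normalized recovery follows
#' `y(t) = i_inf * (1 - exp(-t / tau))` after the bleach. The raw trace is
#' assembled so that a correct normalization must undo an additive
#' background and a multiplicative reference photofade: both ROI and
#' reference decay by `reference_decay` per frame, and `background` is added
#' to both.
#'
#' @param i_inf mobile fraction / normalized plateau, in `[0, 1]` (values up
#'   to slightly above 1 are tolerated by the fitter but not generated).
#' @param tau recovery time constant in seconds, > 0.
#' @param pre_bleach_level pre-bleach ROI intensity.
#' @param n_pre number of pre-bleach frames (>= 2).
#' @param n_post number of post-bleach frames.
#' @param dt frame interval in seconds, > 0.
#' @param noise_sd Gaussian noise sd added to ROI and reference.
#' @param bleach_depth fraction of intensity removed by the bleach, in (0, 1].
#' @param reference_decay multiplicative photofade per frame, in `[0, 1)`.
#' @param background additive background intensity.
#' @param seed integer RNG seed.
#' @return a [frap_trace()] with attribute `truth` (list of the generating
#'   parameters).
#' @export
generate_frap_trace <- function(i_inf, tau, pre_bleach_level = 100,
                                n_pre = 5, n_post = 60, dt = 1,
                                noise_sd = 0, bleach_depth = 0.8,
                                reference_decay = 0, background = 0,
                                seed = 1L) {
  if (i_inf < 0 || i_inf > 1) stop("i_inf must lie in [0, 1]")
  if (tau <= 0) stop("tau must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (n_pre < 2) stop("need at least 2 pre-bleach frames")
  stopifnot(bleach_depth > 0, bleach_depth <= 1,
            reference_decay >= 0, reference_decay < 1)
  with_seed(seed, {
    nfr <- n_pre + n_post
    frame <- seq_len(nfr)
    t <- (frame - 1) * dt
    t_bleach <- t[n_pre + 1]
    P <- pre_bleach_level
    y <- numeric(nfr)
    post <- frame > n_pre
    y[!post] <- 1
    y[post] <- (1 - bleach_depth) +
      bleach_depth * i_inf * (1 - exp(-(t[post] - t_bleach) / tau))
    fade <- (1 - reference_decay)^(frame - 1)
    roi <- P * y * fade + background
    ref <- P * fade + background
    if (noise_sd > 0) {
      roi <- roi + rnorm(nfr, sd = noise_sd)
      ref <- ref + rnorm(nfr, sd = noise_sd)
    }
    tr <- frap_trace(t, roi, ref, background, bleach_index = n_pre + 1L)
    attr(tr, "truth") <- list(i_inf = i_inf, tau = tau,
                              immobile_fraction = 1 - i_inf,
                              bleach_depth = bleach_depth)
    tr
  })
}
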