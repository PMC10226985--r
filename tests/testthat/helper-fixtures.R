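# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

# quasi-uniform unit directions (independent of the package's internal
# generator on purpose: spiral vs golden-angle lattice)
unit_sphere_points <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - n - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ang <- i * pi * (3 - sqrt(5))
  cbind(r * cos(ang), r * sin(ang), z)
}

# digital ball mask centered in its own grid
ball_mask <- function(radius, spacing, margin = 1.5) {
  half <- radius + margin
  dims <- as.integer(ceiling(2 * half / spacing))
  ctr <- dims * spacing / 2
  az <- (seq_len(dims[1]) - 0.5) * spacing[1] - ctr[1]
  ay <- (seq_len(dims[2]) - 0.5) * spacing[2] - ctr[2]
  ax <- (seq_len(dims[3]) - 0.5) * spacing[3] - ctr[3]
  outer(outer(az^2, ay^2, "+"), ax^2, "+") <= radius^2
}

# small noiseless one-cell phantom used across tests
tiny_phantom <- function(true_ln = 2, seed = 4, noise_g = 0, noise_p = 0,
                         wrinkle = 0) {
  generate_embryo_phantom(phantom_spec(
    n_cells = 1, embryo_radius = 11, cell_radius_mean = 10.5,
    nucleus_radius_fraction = 0.6, true_ln_ratio = true_ln,
    wrinkle_amplitude = wrinkle,
    noise_gaussian_sd = noise_g, noise_poisson_scale = noise_p, seed = seed))
}

# brute-force inner/outer oracle: explicit per-voxel neighbor scan
brute_force_outer_ids <- function(labels) {
  d <- dim(labels)
  fg <- which(labels > 0L, arr.ind = TRUE)
  touching <- integer(0)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(fg))) {
    id <- labels[fg[r, 1], fg[r, 2], fg[r, 3]]
    if (id %in% touching) next
    for (k in 1:6) {
      zz <- fg[r, 1] + offs[k, 1]
      yy <- fg[r, 2] + offs[k, 2]
      xx <- fg[r, 3] + offs[k, 3]
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
          xx < 1 || xx > d[3] || labels[zz, yy, xx] == 0L) {
        touching <- c(touching, id)
        break
      }
    }
  }
  sort(unique(touching))
}

# map segmented label ids to truth ids by majority voxel overlap
match_labels <- function(seg, truth) {
  vapply(sort(unique(seg[seg > 0L])), function(id) {
    ov <- truth[seg == id]
    ov <- ov[ov > 0L]
    as.integer(names(which.max(table(ov))))
  }, integer(1))
}
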