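make_two_mask_img <- function() {
  arr <- array(0, c(2, 6, 6, 6))
  arr[1, , , ] <- 100                      # dapi
  arr[2, , , ] <- 100                      # marker
  img <- volume_image(arr, c(1, 1, 1), c("dapi", "marker"))
  m1 <- array(FALSE, c(6, 6, 6)); m1[2:3, 2:3, 2:3] <- TRUE
  m2 <- array(FALSE, c(6, 6, 6)); m2[4:5, 4:5, 4:5] <- TRUE
  list(img = img, m1 = m1, m2 = m2)
}

test_that("ln_ratio is the plain mean ratio with the documented errors", {
  f <- make_two_mask_img()
  expect_equal(ln_ratio(f$img, "marker", f$m1, f$m2), 1.0)
  f$img$data[2, , , ][f$m1] <- 250
  expect_equal(ln_ratio(f$img, "marker", f$m1, f$m2), 2.5)
  expect_error(ln_ratio(f$img, "marker", f$m1 & FALSE, f$m2), "non-empty")
  f$img$data[2, , , ][f$m2] <- 0
  expect_error(ln_ratio(f$img, "marker", f$m1, f$m2), "zero nucleoplasm")
})

test_that("ln_ratio is gain-invariant and responds predictably to offsets", {
  ph <- tiny_phantom(true_ln = 2)
  shell <- ph$truth_lamina$labels == 1L
  nucleop <- ph$truth_nuclei$labels == 1L & !shell
  base <- ln_ratio(ph$image, "lamin", shell, nucleop)
  g <- ph$image
  g$data[3, , , ] <- g$data[3, , , ] * 7.3
  expect_equal(ln_ratio(g, "lamin", shell, nucleop), base, tolerance = 1e-12)
  o <- ph$image
  o$data[3, , , ] <- o$data[3, , , ] + 50
  lam <- mean(get_channel(ph$image, "lamin")[shell])
  nup <- mean(get_channel(ph$image, "lamin")[nucleop])
  expect_equal(ln_ratio(o, "lamin", shell, nucleop), (lam + 50) / (nup + 50))
})

test_that("ratio operations are pure functions of the voxel multiset", {
  ph <- tiny_phantom(true_ln = 2, noise_g = 5, noise_p = 1)
  shell <- ph$truth_lamina$labels == 1L
  nucleop <- ph$truth_nuclei$labels == 1L & !shell
  a <- ln_ratio(ph$image, "lamin", shell, nucleop)
  # permute the volume consistently: reverse all axes
  img2 <- ph$image
  img2$data <- img2$data[, dim(img2$data)[2]:1,
                         dim(img2$data)[3]:1, dim(img2$data)[4]:1,
                         drop = FALSE]
  rev3 <- function(m) m[dim(m)[1]:1, dim(m)[2]:1, dim(m)[3]:1, drop = FALSE]
  expect_equal(ln_ratio(img2, "lamin", rev3(shell), rev3(nucleop)), a)
})

test_that("DNA-stain standardization behaves linearly with the right reference", {
  f <- make_two_mask_img()
  expect_equal(dapi_standardized_intensity(f$img, "dapi", f$m1), 1.0)
  f$img$data[2, , , ] <- f$img$data[1, , , ] * 3
  expect_equal(dapi_standardized_intensity(f$img, "marker", f$m1), 3.0)
  # cytoplasmic marker 50 standardized to nuclear dapi 100 -> 0.5
  ph <- generate_embryo_phantom(phantom_spec(
    n_cells = 1, embryo_radius = 11, cell_radius_mean = 10.5,
    marker_cytoplasmic = 50, noise_gaussian_sd = 0, noise_poisson_scale = 0,
    seed = 4))
  nuc <- ph$truth_nuclei$labels == 1L
  cyto <- ph$truth_cells$labels == 1L & !nuc
  expect_equal(dapi_standardized_intensity(ph$image, "marker", cyto,
                                           dapi_mask = nuc), 0.5)
  f$img$data[1, , , ] <- 0
  expect_error(dapi_standardized_intensity(f$img, "marker", f$m1),
               "zero DNA-stain")
})

test_that("nuclear:cytoplasmic ratio validates masks and recovers construction", {
  f <- make_two_mask_img()
  expect_equal(nuclear_cytoplasmic_ratio(f$img, "marker", f$m1, f$m2), 1.0)
  ph <- generate_embryo_phantom(phantom_spec(
    n_cells = 1, embryo_radius = 11, cell_radius_mean = 10.5,
    marker_nuclear = 200, marker_cytoplasmic = 100,
    noise_gaussian_sd = 0, noise_poisson_scale = 0, seed = 4))
  nuc <- ph$truth_nuclei$labels == 1L
  cyto <- ph$truth_cells$labels == 1L & !nuc
  expect_equal(nuclear_cytoplasmic_ratio(ph$image, "marker", nuc, cyto), 2.0)
  expect_error(nuclear_cytoplasmic_ratio(f$img, "marker", f$m1,
                                         f$m1 & FALSE), "empty cytoplasm")
  expect_error(nuclear_cytoplasmic_ratio(f$img, "marker", f$m1, f$m1),
               "overlap")
})

test_that("mesh density recovers the constructed inner/outer contrast and is guarded", {
  ph <- generate_embryo_phantom(phantom_spec(
    n_cells = 2, embryo_radius = 14, cell_radius_mean = 11,
    cytoplasmic_mesh_density = c(80, 40),
    noise_gaussian_sd = 0, noise_poisson_scale = 0, seed = 6))
  sp <- ph$image$voxel_spacing
  dens <- numeric(2)
  for (i in 1:2) {
    cell <- ph$truth_cells$labels == i
    nuc <- ph$truth_nuclei$labels == i
    cm <- make_cortex_cytoplasm_masks(cell, nuc, sp, 1)
    cm$cortex <- cm$cortex & !(ph$truth_cells$labels > 0L &
                                 ph$truth_cells$labels != i)
    dens[i] <- cytoplasmic_mesh_density(ph$image, "actin", cm$cytoplasm,
                                        nuc, cm$cortex)
    # cortex accidentally included must fail loudly
    expect_error(cytoplasmic_mesh_density(ph$image, "actin",
                                          cm$cytoplasm | (cm$cortex & !nuc),
                                          nuc, cm$cortex), "cortex")
    expect_error(cytoplasmic_mesh_density(ph$image, "actin",
                                          cm$cytoplasm | nuc, nuc),
                 "nucleus")
  }
  expect_lt(abs(dens[1] / dens[2] - 2), 2 * 0.10)
})

test_that("L:N recovery through the full pipeline is accurate at default noise", {
  # 3 seeds here (the broader grid runs in the acceptance suite)
  errs <- vapply(1:3, function(s) {
    ph <- generate_embryo_phantom(phantom_spec(
      n_cells = 4, embryo_radius = 18, cell_radius_mean = 10,
      true_ln_ratio = 2, seed = 40 + s))
    nuc <- segment_nuclei(ph$image)
    sp <- ph$image$voxel_spacing
    lns <- vapply(label_ids(nuc), function(id) {
      s2 <- split_lamina_nucleoplasm(nuc$labels == id, sp, 1.0)
      ln_ratio(ph$image, "lamin", s2$lamina_shell, s2$nucleoplasm)
    }, numeric(1))
    median(abs(lns - 2) / 2)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
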