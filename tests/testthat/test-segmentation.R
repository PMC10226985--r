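test_that("lamina/nucleoplasm split matches analytic sphere-shell volumes", {
  h <- 0.25
  mask <- ball_mask(10, c(h, h, h))
  vv <- h^3
  split <- split_lamina_nucleoplasm(mask, c(h, h, h), 1.0)
  shell_true <- 4 / 3 * pi * (10^3 - 9^3)
  core_true <- 4 / 3 * pi * 9^3
  expect_lt(abs(sum(split$lamina_shell) * vv / shell_true - 1), 0.10)
  expect_lt(abs(sum(split$nucleoplasm) * vv / core_true - 1), 0.10)
  # partition of the nucleus
  expect_true(all(xor(split$lamina_shell[mask], split$nucleoplasm[mask])))
  expect_false(any(split$lamina_shell & !mask))
})

test_that("erosion depth is isotropic in physical units despite anisotropic voxels", {
  sp <- c(0.5, 0.25, 0.25)
  mask <- ball_mask(10, sp, margin = 2.6)
  core <- erode_um(mask, sp, 2.0)
  half_z <- diff(range(which(apply(core, 1, any)))) * sp[1] / 2
  half_x <- diff(range(which(apply(core, 3, any)))) * sp[3] / 2
  expect_lt(abs(half_z - 8), 0.5)
  expect_lt(abs(half_x - 8), 0.3)
  expect_lt(abs(half_z - half_x), 0.5)
})

test_that("distance transform equals brute force on random masks", {
  set.seed(2)
  sp <- c(0.7, 0.3, 0.4)
  mm <- array(runif(20 * 15 * 12) > 0.7, c(20, 15, 12))
  d <- distance_transform(mm, sp)
  bg <- which(!mm, arr.ind = TRUE)
  bgp <- sweep(bg, 2, sp, "*")
  for (i in sample(which(mm), 40)) {
    co <- arrayInd(i, dim(mm))
    p <- as.numeric(co) * sp
    bf <- min(sqrt(colSums((t(bgp) - p)^2)))
    expect_equal(d[i], bf, tolerance = 1e-12)
  }
})

test_that("split contracts: zero thickness and over-thick shells error", {
  mask <- ball_mask(3, c(0.5, 0.5, 0.5))
  expect_error(split_lamina_nucleoplasm(mask, c(0.5, 0.5, 0.5), 0),
               "shell_thickness")
  expect_error(split_lamina_nucleoplasm(mask, c(0.5, 0.5, 0.5), 5),
               "consumes")
  expect_error(split_lamina_nucleoplasm(array(FALSE, c(3, 3, 3)),
                                        c(1, 1, 1), 1), "empty")
})

test_that("cortex/cytoplasm masks obey the compartment algebra and analytic volumes", {
  h <- 0.25
  sp <- c(h, h, h)
  cell <- ball_mask(15, sp, margin = 2)
  nuc <- ball_mask(15, sp, margin = 2) & FALSE
  ctr <- dim(cell) / 2
  nuc <- {
    az <- (seq_len(dim(cell)[1]) - 0.5) * h - ctr[1] * h
    ay <- (seq_len(dim(cell)[2]) - 0.5) * h - ctr[2] * h
    ax <- (seq_len(dim(cell)[3]) - 0.5) * h - ctr[3] * h
    outer(outer(az^2, ay^2, "+"), ax^2, "+") <= 7^2
  }
  cm <- make_cortex_cytoplasm_masks(cell, nuc, sp, band_um = 1)
  vv <- h^3
  cortex_true <- 4 / 3 * pi * (16^3 - 14^3)
  expect_lt(abs(sum(cm$cortex) * vv / cortex_true - 1), 0.10)
  expect_identical(cm$cortex, cm$cell_dilated & !cm$cell_eroded)
  expect_false(any(cm$cytoplasm & !cm$cell_eroded))
  expect_false(any(cm$cytoplasm & cm$nucleus))
  # band 0: no cortex, cytoplasm = cell minus nucleus
  cm0 <- make_cortex_cytoplasm_masks(cell, nuc, sp, band_um = 0)
  expect_false(any(cm0$cortex))
  expect_identical(cm0$cytoplasm, cell & !nuc)
  # degenerate inputs
  expect_error(make_cortex_cytoplasm_masks(cell, cell, sp, 1),
               "no cytoplasm")
  expect_error(make_cortex_cytoplasm_masks(nuc, cell, sp, 1), "contained")
})

test_that("compartment partition covers the cell with small residue", {
  ph <- generate_embryo_phantom(phantom_spec(n_cells = 2, embryo_radius = 14,
                                             cell_radius_mean = 11, seed = 5))
  sp <- ph$image$voxel_spacing
  for (i in 1:2) {
    cell <- ph$truth_cells$labels == i
    nuc <- ph$truth_nuclei$labels == i
    cm <- make_cortex_cytoplasm_masks(cell, nuc, sp, 1)
    covered <- nuc | cm$cytoplasm | (cm$cortex & cell)
    residue <- sum(cell & !covered) / sum(cell)
    expect_lt(residue, 0.02)
  }
})

test_that("shell volumes are stable under resolution doubling", {
  shell_vol <- function(h) {
    mask <- ball_mask(10, c(h, h, h))
    s <- split_lamina_nucleoplasm(mask, c(h, h, h), 1.0)
    sum(s$lamina_shell) * h^3
  }
  v1 <- shell_vol(0.25)
  v2 <- shell_vol(0.125)
  expect_lt(abs(v2 / v1 - 1), 0.05)
})

test_that("nucleus segmentation recovers phantom nuclei with high overlap", {
  ph <- generate_embryo_phantom(phantom_spec(n_cells = 4, embryo_radius = 18,
                                             cell_radius_mean = 10, seed = 9))
  nuc <- segment_nuclei(ph$image)
  expect_length(label_ids(nuc), 4L)
  m <- match_labels(nuc$labels, ph$truth_nuclei$labels)
  expect_setequal(m, 1:4)
  for (id in label_ids(nuc)) {
    a <- nuc$labels == id
    b <- ph$truth_nuclei$labels == m[id]
    expect_gt(sum(a & b) / sum(a | b), 0.9)
  }
  expect_error(segment_nuclei(volume_image(array(0, c(1, 8, 8, 8)),
                                           c(1, 1, 1), "dapi")),
               "no nuclei|constant")
})

test_that("cell segmentation partitions the embryo with each nucleus in its cell", {
  ph <- generate_embryo_phantom(phantom_spec(n_cells = 2, embryo_radius = 14,
                                             cell_radius_mean = 11, seed = 5))
  nuc <- segment_nuclei(ph$image)
  cells <- segment_cells(ph$image, "membrane", nuc)
  expect_length(label_ids(cells), 2L)
  for (id in label_ids(cells)) {
    host <- unique(cells$labels[nuc$labels == id])
    expect_identical(host, id)   # each cell contains exactly its seed
  }
  # bypass mode: truth labels pass straight through
  byp <- segment_cells(ph$image, nuclei = nuc,
                       bypass_labels = ph$truth_cells)
  expect_identical(byp, ph$truth_cells)
  expect_error(segment_cells(ph$image, "nope", nuc), "not found")
})

test_that("inner/outer classification matches the brute-force voxel scan", {
  set.seed(31)
  for (rep in 1:4) {
    ph <- generate_embryo_phantom(phantom_spec(
      n_cells = sample(5:8, 1), embryo_radius = 13, cell_radius_mean = 6,
      voxel_spacing = c(0.9, 0.45, 0.45), nucleus_radius_fraction = 0.5,
      seed = 100 + rep))
    cls <- classify_inner_outer(ph$truth_cells)
    outer_ids <- cls$cell_id[cls$position_class == "outer"]
    expect_identical(outer_ids, brute_force_outer_ids(ph$truth_cells$labels))
  }
  # single cell is outer by definition
  ph1 <- tiny_phantom()
  expect_identical(classify_inner_outer(ph1$truth_cells)$position_class,
                   "outer")
})
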