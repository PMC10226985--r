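#' Lamina:nucleoplasm (L:N) intensity ratio
#'
#' Mean raw voxel intensity over the lamina shell divided by the mean over
#' the nucleoplasm. No background subtraction is applied: the ratio is a
#' pure function of the voxel multisets and is invariant under any global
#' intensity gain.
#'
#' @param img a [volume_image()].
#' @param channel lamin channel name or index.
#' @param lamina_shell,nucleoplasm logical 3D masks (disjoint, non-empty).
#' @return unitless ratio > 0.
#' @export
ln_ratio <- function(img, channel, lamina_shell, nucleoplasm) {
  arr <- get_channel(img, channel)
  if (!any(lamina_shell) || !any(nucleoplasm)) {
    stop("lamina and nucleoplasm masks must both be non-empty")
  }
  den <- mean(arr[nucleoplasm])
  if (den == 0) stop("zero nucleoplasm mean intensity")
  mean(arr[lamina_shell]) / den
}

#' DNA-stain-standardized channel intensity
#'
#' Mean intensity of `channel` over `mask`, divided by the mean DNA-stain
#' (DAPI/Hoechst) intensity over `dapi_mask`. For cytoplasmic regions the
#' standardization reference defaults to the same cell's nucleus, since the
#' DNA stain is nuclear.
#'
#' @param img a [volume_image()].
#' @param channel channel to measure.
#' @param mask logical 3D mask for the measurement.
#' @param dapi_channel DNA-stain channel (default `"dapi"`).
#' @param dapi_mask reference region for the DNA stain; defaults to `mask`.
#' @return unitless standardized intensity.
#' @export
dapi_standardized_intensity <- function(img, channel, mask,
                                        dapi_channel = "dapi",
                                        dapi_mask = mask) {
  if (!any(mask) || !any(dapi_mask)) stop("masks must be non-empty")
  den <- mean(get_channel(img, dapi_channel)[dapi_mask])
  if (den == 0) stop("zero DNA-stain mean intensity in the reference region")
  mean(get_channel(img, channel)[mask]) / den
}

#' Nuclear:cytoplasmic intensity ratio
#'
#' @param img a [volume_image()].
#' @param channel channel to measure.
#' @param nucleus_mask,cytoplasm_mask disjoint, non-empty logical 3D masks.
#' @return unitless ratio.
#' @export
nuclear_cytoplasmic_ratio <- function(img, channel, nucleus_mask,
                                      cytoplasm_mask) {
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  if (!any(cytoplasm_mask)) stop("empty cytoplasm mask")
  if (any(nucleus_mask & cytoplasm_mask)) {
    stop("nucleus and cytoplasm masks overlap")
  }
  arr <- get_channel(img, channel)
  den <- mean(arr[cytoplasm_mask])
  if (den == 0) stop("zero cytoplasmic mean intensity")
  mean(arr[nucleus_mask]) / den
}

#' Cytoplasmic meshwork density
#'
#' DNA-stain-standardized mean filament-stain (phalloidin/actin) intensity
#' over the cytoplasm. This is an intensity-based density proxy, not a
#' skeletonized filament-length density. The cytoplasm mask must exclude
#' both cortex and nucleus; overlap with either is an error so cortical
#' signal can never inflate the cytoplasmic readout.
#'
#' @param img a [volume_image()].
#' @param actin_channel filament-stain channel.
#' @param cytoplasm_mask logical 3D mask of the cytoplasm.
#' @param nucleus_mask nucleus mask: the DNA-stain reference region, and a
#'   validation that the cytoplasm excludes it.
#' @param cortex_mask optional cortex mask for validation.
#' @param dapi_channel DNA-stain channel.
#' @return unitless standardized density.
#' @export
cytoplasmic_mesh_density <- function(img, actin_channel, cytoplasm_mask,
                                     nucleus_mask, cortex_mask = NULL,
                                     dapi_channel = "dapi") {
  if (any(cytoplasm_mask & nucleus_mask)) {
    stop("cytoplasm mask overlaps the nucleus: invalid compartmentation")
  }
  if (!is.null(cortex_mask) && any(cytoplasm_mask & cortex_mask)) {
    stop("cytoplasm mask overlaps the cortex: invalid compartmentation")
  }
  dapi_standardized_intensity(img, actin_channel, cytoplasm_mask,
                              dapi_channel, dapi_mask = nucleus_mask)
}

# crop a bounding box (with pad) around a labeled object; returns index list
bbox_of <- function(mask, dims, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  list(z = max(1L, min(idx[, 1]) - pad):min(dims[1], max(idx[, 1]) + pad),
       y = max(1L, min(idx[, 2]) - pad):min(dims[2], max(idx[, 2]) + pad),
       x = max(1L, min(idx[, 3]) - pad):min(dims[3], max(idx[, 3]) + pad))
}

#' Per-object intensity and shape records for a segmented embryo
#'
#' Runs the compartment split and every intensity statistic for each cell of
#' a segmented volume, pairing each cell with the nucleus it contains, and
#' attaches the geometric descriptors. All physical quantities are in um,
#' um^2 or um^3.
#'
#' @param img a [volume_image()].
#' @param cells,nuclei [label_volume()]s from [segment_cells()] /
#'   [segment_nuclei()] (or truth labels).
#' @param lamin_channel,dapi_channel,actin_channel channel names.
#' @param marker_channels named character vector of additional channels for
#'   nuclear:cytoplasmic ratios (e.g. `c(marker = "marker")`).
#' @param shell_um lamina shell thickness, um.
#' @param band_um cortex band half-width, um.
#' @param cutoff_um apical-surface neighbor cutoff distance, um.
#' @return list with data.frames `cell_records` and `nucleus_records`.
#' @export
quantify_embryo <- function(img, cells, nuclei,
                            lamin_channel = "lamin",
                            dapi_channel = "dapi",
                            actin_channel = "actin",
                            marker_channels = NULL,
                            shell_um = 1.0, band_um = 1.0, cutoff_um = 1.0) {
  stopifnot(inherits(img, "volume_image"), inherits(cells, "label_volume"),
            inherits(nuclei, "label_volume"))
  sp <- img$voxel_spacing
  dims <- dim(cells$labels)
  ids <- label_ids(cells)
  pos <- classify_inner_outer(cells)

  # embryo center of mass from the union of all cells
  allcells <- cells$labels > 0L
  idxa <- which(allcells, arr.ind = TRUE)
  embryo_cm <- c(mean((idxa[, 3] - 0.5) * sp[3]),
                 mean((idxa[, 2] - 0.5) * sp[2]),
                 mean((idxa[, 1] - 0.5) * sp[1]))   # (x, y, z) um

  # match nuclei to cells by majority overlap
  nuc_ids <- label_ids(nuclei)
  nuc_of_cell <- setNames(rep(NA_integer_, length(ids)), ids)
  for (nid in nuc_ids) {
    inside <- cells$labels[nuclei$labels == nid]
    inside <- inside[inside > 0L]
    if (length(inside) == 0) next
    host <- as.integer(names(which.max(table(inside))))
    nuc_of_cell[as.character(host)] <- nid
  }

  cell_rows <- list()
  nuc_rows <- list()
  vox_vol <- prod(sp)

  # one cell's full record; errors (degenerate compartments, failed fits)
  # are caught by the caller, which skips the cell with a warning
  quantify_one_cell <- function(id) {
    nid <- nuc_of_cell[as.character(id)]
    if (is.na(nid)) stop("no matched nucleus")
    bb <- bbox_of(cells$labels == id, dims,
                  pad = as.integer(ceiling(max(band_um, cutoff_um) /
                                             min(sp))) + 2L)
    sub <- function(a) a[bb$z, bb$y, bb$x, drop = FALSE]
    cell_m <- sub(cells$labels) == id
    nuc_m <- sub(nuclei$labels) == nid
    if (!any(nuc_m)) stop("matched nucleus has no voxels in the crop")
    sub_img <- volume_image(img$data[, bb$z, bb$y, bb$x, drop = FALSE],
                            sp, img$channel_names)
    comp <- make_cortex_cytoplasm_masks(cell_m, nuc_m, sp, band_um,
                                        object_id = id)
    # clip the dilated/cortex masks to this cell's own territory plus
    # background, so neighboring cells' voxels are not counted
    other <- sub(cells$labels) != id & sub(cells$labels) > 0L
    comp$cortex <- comp$cortex & !other
    split <- split_lamina_nucleoplasm(nuc_m, sp, shell_um)

    lnr <- ln_ratio(sub_img, lamin_channel, split$lamina_shell,
                    split$nucleoplasm)
    mesh <- cytoplasmic_mesh_density(sub_img, actin_channel, comp$cytoplasm,
                                     nuc_m, comp$cortex, dapi_channel)
    cortex_int <- dapi_standardized_intensity(sub_img, actin_channel,
                                              comp$cortex, dapi_channel,
                                              dapi_mask = nuc_m)

    # geometry
    sub_origin <- c((bb$x[1] - 1) * sp[3], (bb$y[1] - 1) * sp[2],
                    (bb$z[1] - 1) * sp[1])
    cell_surf <- surface_points_from_mask(cell_m, sp, object_id = id,
                                          source = "cell",
                                          origin = sub_origin)
    apical <- apical_surface_from_labels(cells, id, cutoff_um)
    api_area <- apical_surface_area(apical)
    total_area <- mesh_area(surface_mesh_from_mask(cell_m, sp,
                                                   origin = sub_origin))
    box <- oriented_bounding_box(cell_surf, embryo_cm, apical)

    nuc_idx <- which(nuc_m, arr.ind = TRUE)
    nuc_cm <- c(mean((bb$x[nuc_idx[, 3]] - 0.5) * sp[3]),
                mean((bb$y[nuc_idx[, 2]] - 0.5) * sp[2]),
                mean((bb$z[nuc_idx[, 1]] - 0.5) * sp[1]))
    d_cm <- distance_to_embryo_cm(nuc_cm, embryo_cm)

    nuc_surf <- surface_points_from_mask(nuc_m, sp, object_id = nid,
                                         source = "nucleus",
                                         origin = c((bb$x[1] - 1) * sp[3],
                                                    (bb$y[1] - 1) * sp[2],
                                                    (bb$z[1] - 1) * sp[1]))
    fit <- fit_ellipsoid(nuc_surf)
    defo <- nuclear_deformation_index(nuc_surf, fit)
    sph <- sphericity(nuc_m, sp)

    crow <- data.frame(
      cell_id = id,
      position_class = pos$position_class[pos$cell_id == id],
      nucleus_id = nid,
      distance_to_embryo_cm = d_cm,
      aspect_ratio = aspect_ratio(box),
      flatness = flatness(box),
      apical_area = api_area,
      total_area = total_area,
      apical_fraction = if (total_area > 0) api_area / total_area else 0,
      cell_volume = sum(cell_m) * vox_vol,
      ln_ratio = lnr,
      mesh_density = mesh,
      cortex_actin = cortex_int
    )
    if (!is.null(marker_channels)) {
      for (mn in names(marker_channels)) {
        crow[[paste0("nc_ratio_", mn)]] <-
          nuclear_cytoplasmic_ratio(sub_img, marker_channels[[mn]],
                                    nuc_m, comp$cytoplasm)
        crow[[paste0(mn, "_cytoplasm")]] <-
          dapi_standardized_intensity(sub_img, marker_channels[[mn]],
                                      comp$cytoplasm, dapi_channel,
                                      dapi_mask = nuc_m)
      }
    }
    arr_l <- get_channel(sub_img, lamin_channel)
    nrow_df <- data.frame(
      nucleus_id = nid,
      cell_id = id,
      position_class = crow$position_class,
      ln_ratio = lnr,
      lamina_mean = mean(arr_l[split$lamina_shell]),
      nucleoplasm_mean = mean(arr_l[split$nucleoplasm]),
      nucleus_total = sum(arr_l[nuc_m]),
      volume = sum(nuc_m) * vox_vol,
      sphericity = sph,
      deformation_index = defo,
      distance_to_embryo_cm = d_cm
    )
    list(cell = crow, nucleus = nrow_df)
  }

  for (id in ids) {
    rowres <- tryCatch(quantify_one_cell(id), error = function(e) {
      warning("cell ", id, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(rowres)) {
      cell_rows[[length(cell_rows) + 1L]] <- rowres$cell
      nuc_rows[[length(nuc_rows) + 1L]] <- rowres$nucleus
    }
  }

  list(cell_records = do.call(rbind, cell_rows),
       nucleus_records = do.call(rbind, nuc_rows))
}
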