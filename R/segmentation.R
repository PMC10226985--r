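#' Segment nuclei from a DNA-stain channel
#'
#' Gaussian smoothing, Otsu thresholding, connected-component labeling, an
#' optional distance-transform watershed split of touching components, and a
#' physical-unit size filter.
#'
#' @param img a [volume_image()].
#' @param channel DNA-stain channel name or index (default `"dapi"`).
#' @param smooth_sigma_um Gaussian sigma in um.
#' @param min_volume_um3 components smaller than this are discarded.
#' @param split_touching split candidate components whose interior carries
#'   several distance-transform cores.
#' @return a [label_volume()] of nuclei.
#' @export
segment_nuclei <- function(img, channel = "dapi", smooth_sigma_um = 0.5,
                           min_volume_um3 = 25, split_touching = TRUE) {
  stopifnot(inherits(img, "volume_image"))
  sp <- img$voxel_spacing
  arr <- gaussian_smooth(get_channel(img, channel), sp, smooth_sigma_um)
  thr <- otsu_threshold(arr)
  mask <- arr > thr
  if (!any(mask)) stop("no nuclei found: nothing above threshold")
  lab <- label_components(mask)

  if (split_touching) {
    d <- distance_transform(mask, sp)
    out <- array(0L, dim(mask))
    nxt <- 0L
    for (id in seq_len(max(lab))) {
      comp <- lab == id
      dmax <- max(d[comp])
      cores <- label_components(comp & (d > 0.55 * dmax))
      ncore <- max(cores)
      if (ncore <= 1L) {
        nxt <- nxt + 1L
        out[comp] <- nxt
      } else {
        seeds <- array(0L, dim(mask))
        seeds[cores > 0L] <- cores[cores > 0L] + nxt
        w <- seeded_watershed(-d, seeds, comp)
        out[comp] <- w[comp]
        nxt <- nxt + ncore
      }
    }
    lab <- out
  }

  vox_vol <- prod(sp)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * vox_vol >= min_volume_um3)
  if (length(keep) == 0) stop("no nuclei found: all components below size filter")
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  label_volume(lab, sp)
}

#' Segment cells by seeded watershed on a membrane/cortex channel
#'
#' The embryo foreground is the hole-filled largest connected component of
#' the thresholded membrane channel; the space inside it is partitioned
#' among cells by flooding from the nucleus seeds, with the membrane signal
#' as the relief so cell boundaries lock onto cortical ridges.
#'
#' @param img a [volume_image()].
#' @param membrane_channel channel name or index of the boundary stain.
#' @param nuclei a [label_volume()] of seed nuclei.
#' @param smooth_sigma_um Gaussian sigma for the relief, um.
#' @param close_um morphological closing radius (um) applied to the
#'   thresholded membrane mask before hole filling, sealing sub-voxel gaps
#'   in the cortical shell so the embryo interior is watertight.
#' @param bypass_labels optional pre-made [label_volume()] of cells: returned
#'   as-is (validated for geometry), for running downstream stages on truth
#'   masks.
#' @return a [label_volume()] of cells; every cell contains its seed nucleus.
#' @export
segment_cells <- function(img, membrane_channel = "membrane", nuclei,
                          smooth_sigma_um = 0.7, close_um = 1.2,
                          bypass_labels = NULL) {
  stopifnot(inherits(img, "volume_image"))
  if (!is.null(bypass_labels)) {
    stopifnot(inherits(bypass_labels, "label_volume"))
    if (!all(dim(bypass_labels$labels) == dim(img$data)[-1])) {
      stop("bypass labels do not match the image grid")
    }
    return(bypass_labels)
  }
  stopifnot(inherits(nuclei, "label_volume"))
  sp <- img$voxel_spacing
  relief <- gaussian_smooth(get_channel(img, membrane_channel), sp,
                            smooth_sigma_um)
  thr <- otsu_threshold(relief)
  fg <- relief > thr
  if (close_um > 0) {
    fg <- dilate_um(fg, sp, close_um)
    fg <- fill_holes(fg)
    fg <- erode_um(fg, sp, close_um)
  } else {
    fg <- fill_holes(fg)
  }
  cc <- label_components(fg)
  if (max(cc) == 0L) stop("no embryo foreground found in membrane channel")
  main <- which.max(tabulate(cc[cc > 0L]))
  fg <- cc == main
  fg <- fg | nuclei$labels > 0L
  seeds <- nuclei$labels
  outside <- seeds > 0L & !fg
  if (any(outside)) {
    stop("nucleus seed(s) ", paste(unique(seeds[outside]), collapse = ", "),
         " lie outside the embryo foreground")
  }
  lab <- seeded_watershed(relief, seeds, fg)
  label_volume(lab, sp)
}

#' Split a nucleus into lamina shell and nucleoplasm
#'
#' The nucleoplasm is the physical-unit erosion of the nucleus mask by
#' `shell_thickness_um` (Euclidean distance transform with anisotropic
#' spacing); the lamina shell is what the erosion removes. The two
#' compartments partition the nucleus. Because the shell is only a few
#' voxels thick at confocal sampling, the erosion depth is measured on the
#' subvoxel-refined surface distance by default ([subvoxel_distance()]);
#' `subvoxel = FALSE` falls back to the plain voxel-center transform.
#'
#' @param nucleus_mask logical 3D array.
#' @param voxel_spacing `(z, y, x)` um.
#' @param shell_thickness_um shell depth in um, > 0. The value is a
#'   configuration choice (default 1 um, matching the cortex band scale and
#'   the apparent lamina width at confocal resolution).
#' @param subvoxel use the subvoxel-refined surface distance (default TRUE).
#' @return list with logical arrays `lamina_shell` and `nucleoplasm`.
#' @export
split_lamina_nucleoplasm <- function(nucleus_mask, voxel_spacing,
                                     shell_thickness_um = 1.0,
                                     subvoxel = TRUE) {
  if (shell_thickness_um <= 0) {
    stop("shell_thickness_um must be > 0 (zero would leave an empty lamina)")
  }
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  d <- if (subvoxel) subvoxel_distance(nucleus_mask, voxel_spacing)
       else distance_transform(nucleus_mask, voxel_spacing)
  nucleoplasm <- nucleus_mask & (d > shell_thickness_um)
  if (!any(nucleoplasm)) {
    stop("nucleus too small: a ", shell_thickness_um,
         " um shell consumes the whole nucleus")
  }
  list(lamina_shell = nucleus_mask & !nucleoplasm, nucleoplasm = nucleoplasm)
}

#' Cortex and cytoplasm compartment masks around a cell
#'
#' Builds masks about `band_um` larger and smaller than the cell by
#' physical-unit dilation/erosion; the cortex is the large mask minus the
#' small one, the cytoplasm is the small mask minus the nucleus.
#'
#' @param cell_mask,nucleus_mask logical 3D arrays; the nucleus must lie
#'   inside the cell.
#' @param voxel_spacing `(z, y, x)` um.
#' @param band_um half-width of the cortex band in um (default 1).
#' @param object_id optional id carried through to the result.
#' @return a `compartment_masks` list: `nucleus`, `lamina_shell` = NULL
#'   placeholder (see [split_lamina_nucleoplasm()]), `cell`, `cell_eroded`,
#'   `cell_dilated`, `cortex`, `cytoplasm`.
#' @export
make_cortex_cytoplasm_masks <- function(cell_mask, nucleus_mask,
                                        voxel_spacing, band_um = 1.0,
                                        object_id = NA_integer_) {
  stopifnot(band_um >= 0)
  if (!any(cell_mask)) stop("empty cell mask")
  if (any(nucleus_mask & !cell_mask)) {
    stop("nucleus mask is not contained in the cell mask")
  }
  eroded <- erode_um(cell_mask, voxel_spacing, band_um)
  dilated <- dilate_um(cell_mask, voxel_spacing, band_um)
  if (!any(eroded)) stop("erosion by ", band_um, " um empties the cell")
  cortex <- dilated & !eroded
  cytoplasm <- eroded & !nucleus_mask
  if (!any(cytoplasm)) {
    stop("no cytoplasm left: nucleus fills the eroded cell")
  }
  structure(list(object_id = object_id, nucleus = nucleus_mask,
                 cell = cell_mask, cell_eroded = eroded,
                 cell_dilated = dilated, cortex = cortex,
                 cytoplasm = cytoplasm),
            class = "compartment_masks")
}

#' Classify cells as inner or outer
#'
#' A cell is outer iff any of its voxels is face-adjacent (6-connectivity)
#' to the background label 0 (the volume border counts as background);
#' otherwise it is inner. This is the strictest reading of "no part of the
#' cell surface touches the embryo exterior".
#'
#' @param cells a [label_volume()] of cells.
#' @return data.frame with columns `cell_id` and `position_class`
#'   (`"inner"` / `"outer"`).
#' @export
classify_inner_outer <- function(cells) {
  stopifnot(inherits(cells, "label_volume"))
  ids <- label_ids(cells)
  touching <- outer_touching_ids(cells$labels)
  data.frame(cell_id = ids,
             position_class = ifelse(ids %in% touching, "outer", "inner"),
             stringsAsFactors = FALSE)
}
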