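#' Write a multi-channel volume as TIFF plus a JSON metadata sidecar
#'
#' Pages are ordered z-within-channel and stored at 16-bit depth (the
#' native bit depth of confocal acquisitions), after shifting by an integer
#' `offset` and dividing by `scale = 65535 * 2^j`; both factors are recorded
#' in the sidecar (`<path>.json`) together with voxel spacing, channel names
#' and array shape. With this scale the stored sample for an integer
#' intensity `v` is exactly `(v - offset) / 2^j`, so integer-valued volumes
#' round-trip bit-exactly whenever their range fits in `65535 * 2^j`;
#' non-integer data are quantized once to the 16-bit grid (step
#' `scale / 65535`) and are stable under repeated write/read cycles.
#'
#' @param img a [volume_image()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "volume_image"))
  d <- dim(img$data)
  offset <- min(floor(min(img$data)), 0)
  hi <- max(max(img$data) - offset, 1e-12)
  j <- ceiling(log2(hi / 65535))
  # integer-valued data keep an integer quantization step (exact round trip)
  if (all(img$data == round(img$data))) j <- max(0, j)
  scale <- 65535 * 2^j
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ci in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      pages[[k]] <- round((img$data[ci, zi, , ] - offset) / scale * 65535) /
        65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    kind = "volume_image",
    shape = d,                      # (channel, z, y, x)
    voxel_spacing_um = img$voxel_spacing,
    channel_names = img$channel_names,
    offset = offset, scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()], or a plain TIFF with explicit
#' spacing
#'
#' Without the JSON sidecar, the file is treated as a single-channel z-stack
#' and `voxel_spacing` must be supplied; refusing to invent a unit-less
#' default keeps every downstream measurement in true micrometres.
#'
#' @param path TIFF path.
#' @param voxel_spacing optional `(z, y, x)` um override; required when the
#'   sidecar is absent, and takes precedence over it when given.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, voxel_spacing = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(meta)) {
    if (is.null(voxel_spacing)) {
      stop("no voxel-spacing metadata found for '", path,
           "' and no voxel_spacing override given; refusing a unit-less read")
    }
    shape <- c(1L, length(pages), dim(pages[[1]]))
    offset <- 0; scale <- 1
    channel_names <- "ch1"
  } else {
    shape <- as.integer(meta$shape)
    offset <- meta$offset; scale <- meta$scale
    channel_names <- meta$channel_names
    if (is.null(voxel_spacing)) voxel_spacing <- meta$voxel_spacing_um
  }
  data <- array(0, shape)
  k <- 1L
  for (ci in seq_len(shape[1])) {
    for (zi in seq_len(shape[2])) {
      data[ci, zi, , ] <- pages[[k]] * scale + offset
      k <- k + 1L
    }
  }
  volume_image(data, voxel_spacing, channel_names)
}

#' Write / read a label volume as 16-bit TIFF plus JSON sidecar
#'
#' @param lab a [label_volume()].
#' @param path output TIFF path.
#' @return `path` invisibly (write); a [label_volume()] (read).
#' @export
write_labels <- function(lab, path) {
  stopifnot(inherits(lab, "label_volume"))
  mx <- max(lab$labels)
  if (mx > 65535L) stop("more than 65535 labels cannot be stored as 16-bit")
  pages <- lapply(seq_len(dim(lab$labels)[1]),
                  function(zi) lab$labels[zi, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(kind = "label_volume", shape = dim(lab$labels),
               voxel_spacing_um = lab$voxel_spacing)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @param voxel_spacing optional `(z, y, x)` um override.
#' @export
read_labels <- function(path, voxel_spacing = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  if (is.null(meta) && is.null(voxel_spacing)) {
    stop("no voxel-spacing metadata found for '", path,
         "' and no voxel_spacing override given")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  shape <- if (!is.null(meta)) as.integer(meta$shape)
           else c(length(pages), dim(pages[[1]]))
  labels <- array(0L, shape)
  for (zi in seq_along(pages)) {
    labels[zi, , ] <- as.integer(round(pages[[zi]] * 65535))
  }
  if (is.null(voxel_spacing)) voxel_spacing <- meta$voxel_spacing_um
  label_volume(labels, voxel_spacing)
}

#' Read a FRAP trace from CSV
#'
#' Expected columns: `time`, `roi`, `reference`, optionally `background`
#' (absent means 0) and optionally `bleach_index` (a constant column or an
#' attribute; when absent the bleach frame is auto-detected as the largest
#' single-frame ROI drop).
#'
#' @param path CSV path.
#' @return A [frap_trace()].
#' @export
read_frap_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time", "roi", "reference")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("FRAP CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  bg <- if ("background" %in% names(df)) df$background else 0
  bi <- if ("bleach_index" %in% names(df)) as.integer(df$bleach_index[1])
        else which.min(diff(df$roi)) + 1L
  frap_trace(df$time, df$roi, df$reference, bg, bi)
}

#' Write a FRAP trace to CSV
#'
#' @param trace a [frap_trace()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_frap_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  df <- data.frame(time = trace$t, roi = trace$roi,
                   reference = trace$reference,
                   background = trace$background,
                   bleach_index = trace$bleach_index)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-object record tables with stable column order
#'
#' @param records a data.frame of per-cell or per-nucleus records.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  first <- intersect(c("cell_id", "nucleus_id", "position_class"),
                     names(records))
  records <- records[, c(first, setdiff(names(records), first)), drop = FALSE]
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
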