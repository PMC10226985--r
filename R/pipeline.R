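#' Configuration for an end-to-end pipeline run
#'
#' @param phantom a [phantom_spec()] to generate the input volume, or NULL
#'   to read `input_volume` from disk.
#' @param input_volume optional path to a volume TIFF (see [read_volume()]).
#' @param channels named list mapping roles (`dapi`, `membrane`, `lamin`,
#'   `actin`, optional extra markers) to channel names in the volume.
#' @param shell_um lamina shell thickness (um).
#' @param band_um cortex band half-width (um).
#' @param cutoff_um apical-surface neighbor cutoff (um).
#' @param use_truth_labels when a phantom is generated, run quantification
#'   on the ground-truth labels instead of re-segmenting.
#' @param metrics metric columns compared between inner and outer cells.
#' @param seed integer seed recorded in provenance (the phantom spec's own
#'   seed governs generation).
#' @return a `run_config` list.
#' @export
run_config <- function(phantom = NULL, input_volume = NULL,
                       channels = list(dapi = "dapi", membrane = "membrane",
                                       lamin = "lamin", actin = "actin"),
                       shell_um = 1.0, band_um = 1.0, cutoff_um = 1.0,
                       use_truth_labels = FALSE,
                       metrics = c("ln_ratio", "mesh_density",
                                   "distance_to_embryo_cm"),
                       seed = 1L) {
  if (is.null(phantom) && is.null(input_volume)) {
    stop("either a phantom spec or an input volume path is required")
  }
  structure(list(phantom = phantom, input_volume = input_volume,
                 channels = channels, shell_um = shell_um, band_um = band_um,
                 cutoff_um = cutoff_um, use_truth_labels = use_truth_labels,
                 metrics = metrics, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline: volume -> labels -> records -> group report
#'
#' Stages: (1) obtain the volume (generate the phantom or read from disk);
#' (2) segment nuclei and cells (or adopt truth labels); (3) compute all
#' per-cell/per-nucleus intensity and geometry records; (4) classify inner
#' vs outer cells and produce the routed inner-vs-outer statistical report
#' for each requested metric. When `out_dir` is given, writes `records.csv`,
#' `nucleus_records.csv`, `geometry.csv`, `report.json` and
#' `provenance.json` there.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list: `cell_records`, `nucleus_records`, `summary`,
#'   `comparisons` (per metric [route_and_test()] results), `truth`
#'   (phantom truth table or NULL), `labels` (cells, nuclei).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  res <- tryCatch({
    truth <- NULL
    if (!is.null(config$phantom)) {
      ph <- generate_embryo_phantom(config$phantom)
      img <- ph$image
      truth <- ph$truth_table
    } else {
      img <- read_volume(config$input_volume)
    }

    stage <- "segmentation"
    if (isTRUE(config$use_truth_labels)) {
      nuclei <- ph$truth_nuclei
      cells <- ph$truth_cells
    } else {
      nuclei <- segment_nuclei(img, channel = config$channels$dapi)
      cells <- segment_cells(img, membrane_channel = config$channels$membrane,
                             nuclei = nuclei)
    }

    stage <- "quantification"
    extra <- setdiff(names(config$channels),
                     c("dapi", "membrane", "lamin", "actin"))
    marker_channels <- if (length(extra) > 0)
      setNames(unlist(config$channels[extra]), extra)
    rec <- quantify_embryo(img, cells, nuclei,
                           lamin_channel = config$channels$lamin,
                           dapi_channel = config$channels$dapi,
                           actin_channel = config$channels$actin,
                           marker_channels = marker_channels,
                           shell_um = config$shell_um,
                           band_um = config$band_um,
                           cutoff_um = config$cutoff_um)

    stage <- "statistics"
    cr <- rec$cell_records
    metrics <- intersect(config$metrics, names(cr))
    comparisons <- list()
    both <- length(unique(cr$position_class)) == 2 &&
      all(table(cr$position_class) >= 3)
    if (both) {
      for (mname in metrics) {
        g <- split(cr[[mname]], cr$position_class)
        comparisons[[mname]] <- route_and_test(g)
      }
    }
    summary_tab <- summarize_groups(cr, "position_class", metrics)

    list(cell_records = cr, nucleus_records = rec$nucleus_records,
         summary = summary_tab, comparisons = comparisons, truth = truth,
         labels = list(cells = cells, nuclei = nuclei))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records_csv(res$cell_records, file.path(out_dir, "records.csv"))
    write_records_csv(res$nucleus_records,
                      file.path(out_dir, "nucleus_records.csv"))
    geom_cols <- intersect(c("cell_id", "position_class", "aspect_ratio",
                             "flatness", "apical_area", "total_area",
                             "apical_fraction", "distance_to_embryo_cm",
                             "cell_volume"), names(res$cell_records))
    write_records_csv(res$cell_records[, geom_cols],
                      file.path(out_dir, "geometry.csv"))
    report <- list(
      summary = res$summary,
      comparisons = lapply(res$comparisons, function(cmp) {
        list(test_used = cmp$test_used, statistic = cmp$statistic,
             p_value = cmp$p_value,
             normality_p = as.list(cmp$normality_p), flags = cmp$flags)
      }))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    prov <- list(package_version = as.character(utils::packageVersion("laminmorph")),
                 seed = config$seed,
                 parameters = config[c("shell_um", "band_um", "cutoff_um",
                                       "use_truth_labels", "metrics")],
                 phantom = if (!is.null(config$phantom))
                   Filter(Negate(is.null), unclass(config$phantom)),
                 input_volume = config$input_volume,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}
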