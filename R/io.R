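# Readers, writers, configuration and the pipeline runner.
#
# CSV is the canonical tabular interchange. Spreadsheets (.xlsx) are read
# only to ingest externally supplied census tables; TIFF stacks carry the
# image data with a YAML sidecar holding the geometry that TIFF metadata
# cannot be trusted to carry (axis order, voxel sizes, frame interval,
# intensity scale).

#' Read a census table
#'
#' Reads a per-sample census from CSV/TSV (or `.xlsx` when readxl is
#' available), together with optional long-format pouch-histogram and
#' distance tables, and validates all invariants (reporting offending rows).
#'
#' Wide pouch columns `pouch_1 ... pouch_N` in the census file are accepted
#' as an alternative to the long `pouches` table and are converted to it.
#'
#' @param path Census file: columns `sample_id`, `group`, `apo_total`,
#'   `apo_phagocytosed`, `microglia_total`, optional `region_volume_mm3` and
#'   `pouch_1..pouch_N`.
#' @param pouches_path Optional long table `(sample_id, n_pouches, count)`.
#' @param distances_path Optional long table `(sample_id, distance_um)`.
#' @return List with tibbles `census`, `pouches` (possibly `NULL`),
#'   `distances` (possibly `NULL`).
#' @export
read_census <- function(path, pouches_path = NULL, distances_path = NULL) {
  census <- read_table_file(path)
  pouch_cols <- grep("^pouch_[0-9]+$", names(census), value = TRUE)
  pouches <- NULL
  if (length(pouch_cols) > 0) {
    pouches <- census %>%
      select("sample_id", dplyr::all_of(pouch_cols)) %>%
      tidyr::pivot_longer(dplyr::all_of(pouch_cols), names_to = "n_pouches",
                          values_to = "count") %>%
      mutate(n_pouches = as.integer(sub("^pouch_", "", .data$n_pouches))) %>%
      filter(!is.na(.data$count), .data$count > 0)
    census <- select(census, -dplyr::all_of(pouch_cols))
  }
  if (!is.null(pouches_path)) {
    if (length(pouch_cols) > 0) {
      abort_validation("Supply pouch counts either wide in the census file ",
                       "or long via pouches_path, not both.")
    }
    pouches <- read_table_file(pouches_path)
    need <- c("sample_id", "n_pouches", "count")
    if (!all(need %in% names(pouches))) {
      abort_validation("Pouch table needs columns: ", paste(need, collapse = ", "), ".")
    }
  }
  distances <- NULL
  if (!is.null(distances_path)) {
    distances <- read_table_file(distances_path)
    if (!all(c("sample_id", "distance_um") %in% names(distances))) {
      abort_validation("Distance table needs columns sample_id, distance_um.")
    }
  }
  census <- validate_census(census, pouches)
  list(census = census, pouches = pouches, distances = distances)
}

#' @keywords internal
read_table_file <- function(path) {
  if (!file.exists(path)) abort_validation("File not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort_validation("Reading spreadsheets requires the readxl package.")
    }
    return(as_tibble(readxl::read_excel(path)))
  }
  delim <- if (ext == "tsv") "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write a time-lapse z-stack as multi-page TIFF with a YAML sidecar
#'
#' Pages are written frame-major (all slices of frame 1, then frame 2, ...)
#' as 32-bit floats rescaled to `[0, 1]`; the sidecar records the axis
#' layout, dimensions, voxel sizes, frame interval and intensity scale needed
#' to reconstruct the array exactly.
#'
#' @param stack A [zstack_series()].
#' @param path Output `.tif` path; the sidecar is written next to it as
#'   `<path>.yml`.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack_series"))
  a <- stack$intensities
  d <- dim(a)
  offset <- min(a)
  scale <- max(a) - offset
  if (scale == 0) scale <- 1
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (f in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      i <- i + 1L
      pages[[i]] <- (a[f, z, , ] - offset) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    axes = "tzyx", n_frames = d[1], n_slices = d[2], n_lines = d[3],
    n_columns = d[4], voxel_size_um = as.list(stack$voxel_size),
    frame_interval_min = stack$frame_interval,
    intensity_offset = offset, intensity_scale = scale
  )
  yaml::write_yaml(sidecar, paste0(path, ".yml"))
  invisible(path)
}

#' Read a time-lapse z-stack written by [write_zstack()]
#'
#' @param path `.tif` path; the `<path>.yml` sidecar must exist (it resolves
#'   the t/z page interleaving, which raw TIFF cannot express).
#' @param sidecar Optional explicit sidecar path.
#' @return A [zstack_series()].
#' @export
read_zstack <- function(path, sidecar = paste0(path, ".yml")) {
  if (!file.exists(path)) abort_validation("File not found: ", path)
  if (!file.exists(sidecar)) {
    abort_validation("Sidecar ", sidecar, " not found; axis order (t vs z ",
                     "pages) is ambiguous without it.")
  }
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_frames * meta$n_slices) {
    abort_validation("TIFF has ", length(pages), " pages but sidecar declares ",
                     meta$n_frames * meta$n_slices, ".")
  }
  a <- array(NA_real_, dim = c(meta$n_frames, meta$n_slices,
                               meta$n_lines, meta$n_columns))
  i <- 0L
  for (f in seq_len(meta$n_frames)) {
    for (z in seq_len(meta$n_slices)) {
      i <- i + 1L
      a[f, z, , ] <- pages[[i]] * meta$intensity_scale + meta$intensity_offset
    }
  }
  zstack_series(a, unlist(meta$voxel_size_um), meta$frame_interval_min)
}

# Pipeline ----------------------------------------------------------------

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages against file inputs and writes per-stage
#' CSV outputs plus a JSON run report. Supported stages: `census`
#' (phagocytosis metrics + distance histograms), `clearance` (test-condition
#' clearance-time inference), `qpcr` (relative expression), `motility`
#' (per-process lengths and motility from a TIFF stack).
#'
#' The configuration is a named list (or a YAML file path) with one entry
#' per stage; every defaulted under-specified parameter (observation window,
#' border parameters, bin edges) is echoed in the report.
#'
#' @param config Named list or YAML path. Stage entries:
#'   * `census`: `path`, optional `pouches_path`, `distances_path`,
#'     `baseline`, `bin_edges`.
#'   * `clearance`: `apo_present_ref`, `apo_present_test`, optional
#'     `tau_ref`, `delta_t`.
#'   * `qpcr`: `path` (long Ct CSV), `reference_gene` or
#'     `reference_candidates`, `control_group`, optional `efficiencies`
#'     (named list), `convention`.
#'   * `motility`: `path` (TIFF with sidecar), optional `roi`, `angle`,
#'     `background`, border parameters.
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stages <- intersect(names(config), c("census", "clearance", "qpcr", "motility"))
  if (length(stages) == 0) {
    abort_validation("Config defines no runnable stage ",
                     "(census/clearance/qpcr/motility).")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    package = "phagoquant",
    version = as.character(utils::packageVersion("phagoquant")),
    stages = stages, warnings = character(), defaults_used = list()
  )

  if ("census" %in% stages) {
    cfg <- config$census
    inp <- read_census(cfg$path, cfg$pouches_path, cfg$distances_path)
    summ <- phagocytosis_summary(inp$census, inp$pouches,
                                 baseline = cfg$baseline)
    readr::write_csv(summ, file.path(out_dir, "census_summary.csv"))
    readr::write_csv(phagocytosis_group_summary(summ),
                     file.path(out_dir, "census_group_summary.csv"))
    report$warnings <- c(report$warnings,
                         summ$notes[nzchar(summ$notes)])
    if (!is.null(inp$distances)) {
      edges <- cfg$bin_edges %||% c(0, 0.5, 3, 10)
      if (is.null(cfg$bin_edges)) {
        report$defaults_used$distance_bin_edges <- edges
      }
      dh <- distance_histogram(inp$distances$distance_um, edges)
      readr::write_csv(dh, file.path(out_dir, "distance_histogram.csv"))
    }
    report$census <- list(n_samples = nrow(inp$census))
  }

  if ("clearance" %in% stages) {
    cfg <- config$clearance
    tau_ref <- cfg$tau_ref %||% 1.5
    delta_t <- cfg$delta_t %||% 24
    if (is.null(cfg$tau_ref)) report$defaults_used$tau_ref_h <- tau_ref
    if (is.null(cfg$delta_t)) report$defaults_used$delta_t_h <- delta_t
    res <- infer_clearance_time(cfg$apo_present_ref, cfg$apo_present_test,
                                tau_ref = tau_ref, delta_t = delta_t,
                                details = TRUE)
    readr::write_csv(res, file.path(out_dir, "clearance.csv"))
    report$clearance <- as.list(res)
  }

  if ("qpcr" %in% stages) {
    cfg <- config$qpcr
    ct <- read_table_file(cfg$path)
    ref <- cfg$reference_gene %||%
      choose_reference_gene(ct, cfg$reference_candidates)
    folds <- relative_expression(
      ct, efficiencies = unlist(cfg$efficiencies),
      reference_gene = ref, control_group = cfg$control_group,
      convention = cfg$convention %||% "conventional"
    )
    if (is.null(cfg$convention)) {
      report$defaults_used$qpcr_convention <- "conventional"
    }
    readr::write_csv(folds, file.path(out_dir, "qpcr_fold_changes.csv"))
    report$qpcr <- list(reference_gene = ref, n_rows = nrow(folds))
  }

  if ("motility" %in% stages) {
    cfg <- config$motility
    stack <- read_zstack(cfg$path)
    pm <- measure_process(
      stack, roi = cfg$roi, angle = cfg$angle %||% 0,
      background = cfg$background,
      prominence_fraction = cfg$prominence_fraction %||% 0.5,
      use_inflexion = cfg$use_inflexion %||% TRUE,
      smooth_sigma = cfg$smooth_sigma %||% 2,
      floor_fraction = cfg$floor_fraction %||% 0.3
    )
    report$defaults_used$border_params <- pm$params
    readr::write_csv(tidy(pm), file.path(out_dir, "process_lengths.csv"))
    readr::write_csv(glance(pm), file.path(out_dir, "process_summary.csv"))
    report$warnings <- c(report$warnings, pm$dropped_frames)
    report$motility <- as.list(glance(pm))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
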