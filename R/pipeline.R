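#' Run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: the phantom
#' generator settings, the sector geometry, the transform model and the
#' output directory. A run archives its configuration as YAML beside its
#' outputs.
#'
#' @param phantom a [phantom_spec()].
#' @param sectors a [sector_config()].
#' @param transform_model `"similarity"`, `"rigid"` or `"affine"`.
#' @param n_excluded slides flagged excluded in the generated study.
#' @param output_dir directory for reports (created if needed); `NULL` keeps
#'   everything in memory.
#' @param write_plots also emit Bland-Altman PNG plots (needs ggplot2).
#' @export
run_config <- function(phantom = phantom_spec(), sectors = sector_config(),
                       transform_model = c("similarity", "rigid", "affine"),
                       n_excluded = 3L, output_dir = NULL, write_plots = FALSE) {
  transform_model <- match.arg(transform_model)
  stopifnot(inherits(phantom, "phantom_spec"), inherits(sectors, "sector_config"))
  structure(list(phantom = phantom, sectors = sectors,
                 transform_model = transform_model,
                 n_excluded = as.integer(n_excluded),
                 output_dir = output_dir, write_plots = isTRUE(write_plots)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to write to / read from.
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  flat <- list(phantom = unclass(config$phantom),
               sectors = unclass(config$sectors),
               transform_model = config$transform_model,
               n_excluded = config$n_excluded)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path, output_dir = NULL) {
  y <- yaml::yaml.load_file(path)
  ph <- do.call(phantom_spec, y$phantom)
  sc <- do.call(sector_config, y$sectors)
  run_config(phantom = ph, sectors = sc,
             transform_model = y$transform_model %||% "similarity",
             n_excluded = y$n_excluded %||% 0L, output_dir = output_dir)
}

#' Write report tables as CSV
#'
#' One CSV per table with fixed, documented headers. Empty tables produce a
#' headers-only file.
#'
#' @param tables named list of data.frames (e.g. `tre_per_slide`,
#'   `measurements`, `agreement`, `manifest`).
#' @param output_dir target directory (created if needed).
#' @return Character vector of files written.
#' @export
write_report <- function(tables, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(output_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  files
}

#' Run the full phantom study pipeline
#'
#' Phantom generation, per-slide registration with leave-one-out TRE,
#' annotation transfer, margin and thickness measurement, and the agreement
#' report — one seeded, deterministic run. Excluded slides are generated and
#' listed in the manifest but skipped by the analysis.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `study`, `tre_per_slide`, `measurements`,
#'   `agreement`, `manifest`, and (if `output_dir` is set) `files`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  study <- generate_study(config$phantom, n_excluded = config$n_excluded)
  included <- which(study$manifest$included)
  if (!length(included)) stop_sp("run_study: no included slides in the study")
  tre_rows <- list(); meas_rows <- list()
  for (k in included) {
    el <- study$pairs[[k]]
    reg <- tryCatch(register_slice_pair(el$pair, model = config$transform_model),
                    error = function(e) stop_sp("slide %s: registration failed: %s",
                                                el$pair$id, conditionMessage(e)))
    meas <- tryCatch(measure_all(el$pair, reg, config$sectors),
                     error = function(e) stop_sp("slide %s: measurement failed: %s",
                                                 el$pair$id, conditionMessage(e)))
    tre_rows[[length(tre_rows) + 1L]] <- data.frame(
      slide_id = el$pair$id, patient = el$pair$patient, slice = el$pair$slice,
      best_variant = reg$best_variant, best_tre_mm = reg$best_tre_mm,
      n_variants = length(reg$per_variant_tre_mm), stringsAsFactors = FALSE)
    meas_rows[[length(meas_rows) + 1L]] <- meas
  }
  tre_per_slide <- do.call(rbind, tre_rows)
  measurements <- do.call(rbind, meas_rows)
  agreement <- agreement_report(measurements)
  out <- list(study = study, tre_per_slide = tre_per_slide,
              measurements = measurements, agreement = agreement,
              manifest = study$manifest)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out$files <- write_report(
      list(tre_per_slide = tre_per_slide, measurements = measurements,
           agreement = agreement, manifest = study$manifest),
      config$output_dir)
    write_run_config(config, file.path(config$output_dir, "config.yaml"))
    if (config$write_plots && requireNamespace("ggplot2", quietly = TRUE)) {
      for (src in intersect(c("US_M", "US_Reg"), unique(measurements$source))) {
        p <- plot_bland_altman(paired_measurements(measurements, src),
                               title = sprintf("%s vs WSI", src))
        f <- file.path(config$output_dir, sprintf("bland_altman_%s.png", src))
        grDevices::png(f, width = 900, height = 700, res = 120)
        print(p)
        grDevices::dev.off()
        out$files <- c(out$files, f)
      }
    }
  }
  invisible(out)
}
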