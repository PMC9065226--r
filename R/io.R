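#' Read a flat run-configuration file
#'
#' Parses a `key: value` text file (one pair per line, `#` comments and
#' blank lines ignored, lists comma-separated) and merges it with the
#' default protocol, geometry, grid and calibration. Unknown keys are
#' rejected.
#'
#' Recognised keys: `initial_activity_MBq`, `vial_volume_mL`,
#' `phase_end_min`, `flow_mL_h`, `tube_radius_mm`, `tube_length_cm`,
#' `vein_length_cm`, `density_g_cm3`, `viscosity_Pa_s`, `axial_step_mm`,
#' `radial_step_mm`, `time_step_min`, `angular_step_deg`,
#' `ellipse_radial_step_mm`, `cal_a`, `cal_b`, `cal_c`,
#' `cal_activity_MBq`, `cal_window_cm`, `seed`.
#'
#' @param path Path to the configuration file, or NULL for pure defaults.
#' @return A list of class `run_config` with elements `protocol`,
#'   `geometry`, `grid`, `curve` and `seed`.
#' @export
read_run_config <- function(path = NULL) {
  known <- c("initial_activity_MBq", "vial_volume_mL", "phase_end_min",
             "flow_mL_h", "tube_radius_mm", "tube_length_cm",
             "vein_length_cm", "density_g_cm3", "viscosity_Pa_s",
             "axial_step_mm", "radial_step_mm", "time_step_min",
             "angular_step_deg", "ellipse_radial_step_mm",
             "cal_a", "cal_b", "cal_c", "cal_activity_MBq",
             "cal_window_cm", "seed")
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl(":", ln, fixed = TRUE)) {
        stop("malformed configuration line (expected 'key: value'): ", ln)
      }
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (!key %in% known) stop("unknown configuration key: ", key)
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (any(is.na(num))) stop("non-numeric value for key ", key, ": ", val)
      vals[[key]] <- num
    }
  }
  pick <- function(key, default) if (!is.null(vals[[key]])) vals[[key]] else default
  protocol <- infusion_protocol(
    initial_activity = pick("initial_activity_MBq", 7232),
    vial_volume = pick("vial_volume_mL", 25),
    phase_end = pick("phase_end_min", c(10, 20, 40)),
    flow_rate = pick("flow_mL_h", c(50, 100, 200))
  )
  geometry <- flow_geometry(
    tube_radius = pick("tube_radius_mm", 1.25),
    tube_length = pick("tube_length_cm", 115),
    vein_length = pick("vein_length_cm", 30),
    density = pick("density_g_cm3", 1.0053),
    viscosity = pick("viscosity_Pa_s", 1.02e-3)
  )
  grid <- simulation_grid(
    axial_step = pick("axial_step_mm", 1),
    radial_step = pick("radial_step_mm", 0.005),
    time_step = pick("time_step_min", 1),
    angular_step = pick("angular_step_deg", 0.5),
    ellipse_radial_step = pick("ellipse_radial_step_mm", 0.1)
  )
  curve <- calibration_curve(
    a = pick("cal_a", 516.4),
    b = pick("cal_b", 4.065),
    c = pick("cal_c", -1.917),
    calibration_activity = pick("cal_activity_MBq", 11.01),
    window_halfwidth = pick("cal_window_cm", 20)
  )
  structure(list(protocol = protocol, geometry = geometry, grid = grid,
                 curve = curve, seed = pick("seed", NULL)),
            class = "run_config")
}

# write a delimited table with '#' comment header lines
.write_table <- function(x, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}

#' Read/write EDR monitoring series
#'
#' Tab-delimited text with a single header row (`time_min`, `edr_uSv_h`);
#' lines starting with `#` are metadata comments.
#'
#' @param path File path.
#' @return `read_monitoring()` returns a [monitoring_series()].
#' @export
read_monitoring <- function(path) {
  tab <- .read_table(path)
  if (!all(c("time_min", "edr_uSv_h") %in% names(tab))) {
    stop("monitoring file needs columns time_min and edr_uSv_h")
  }
  monitoring_series(tab$time_min, tab$edr_uSv_h)
}

#' @rdname read_monitoring
#' @param series A [monitoring_series()].
#' @param comments Optional comment lines written as `#` headers.
#' @export
write_monitoring <- function(series, path, comments = character(0)) {
  .write_table(series, path, comments)
}

#' Read point-source calibration measurements
#'
#' Tab-delimited text with columns `position_cm` and `edr_uSv_h`.
#'
#' @param path File path.
#' @return `data.frame` with columns `position_cm`, `edr_uSv_h`.
#' @export
read_calibration <- function(path) {
  tab <- .read_table(path)
  if (!all(c("position_cm", "edr_uSv_h") %in% names(tab))) {
    stop("calibration file needs columns position_cm and edr_uSv_h")
  }
  tab
}
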