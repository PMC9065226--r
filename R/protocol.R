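#' Infusion protocol: vial state and flow-rate schedule
#'
#' Describes a gravity-method infusion: saline dripped into the sealed vial
#' displaces the radiopharmaceutical into the line, so the vial volume stays
#' constant while its activity concentration is diluted exponentially, with a
#' dilution rate set by the current flow rate. The schedule is a sequence of
#' piecewise-constant flow phases; the default is the clinical Lutathera
#' protocol (50 mL/h for 10 min, 100 mL/h to 20 min, 200 mL/h to 40 min) with
#' a median initial vial activity of 7232 MBq in 25 mL.
#'
#' @param initial_activity Initial activity in the vial (MBq).
#' @param vial_volume Constant vial volume (mL).
#' @param phase_end Strictly increasing phase end times (minutes); the last
#'   entry is the total infusion time.
#' @param flow_rate Flow rate during each phase (mL/h); same length as
#'   `phase_end`.
#'
#' @return An object of class `infusion_protocol`: a list with fields
#'   `initial_activity`, `vial_volume`, `phase_end`, `flow_rate`,
#'   `total_time` and the derived per-phase dilution rates `alpha` (1/h).
#' @examples
#' p <- infusion_protocol()
#' p$alpha # 2, 4, 8 per hour
#' @export
infusion_protocol <- function(initial_activity = 7232,
                              vial_volume = 25,
                              phase_end = c(10, 20, 40),
                              flow_rate = c(50, 100, 200)) {
  initial_activity <- as.numeric(initial_activity)
  vial_volume <- as.numeric(vial_volume)
  phase_end <- as.numeric(phase_end)
  flow_rate <- as.numeric(flow_rate)
  if (length(initial_activity) != 1L || !is.finite(initial_activity) ||
      initial_activity <= 0) {
    stop("`initial_activity` must be a single positive number (MBq)")
  }
  if (length(vial_volume) != 1L || !is.finite(vial_volume) || vial_volume <= 0) {
    stop("`vial_volume` must be a single positive number (mL)")
  }
  if (length(phase_end) < 1L || length(phase_end) != length(flow_rate)) {
    stop("`phase_end` and `flow_rate` must be non-empty and of equal length")
  }
  if (any(!is.finite(phase_end)) || phase_end[1] <= 0 ||
      any(diff(phase_end) <= 0)) {
    stop("`phase_end` must be positive and strictly increasing (minutes)")
  }
  if (any(!is.finite(flow_rate)) || any(flow_rate <= 0)) {
    stop("all flow rates must be positive (mL/h)")
  }
  structure(
    list(
      initial_activity = initial_activity,
      vial_volume = vial_volume,
      phase_end = phase_end,
      flow_rate = flow_rate,
      total_time = phase_end[length(phase_end)],
      alpha = flow_rate / vial_volume # dilution rates, 1/h
    ),
    class = "infusion_protocol"
  )
}

#' @export
print.infusion_protocol <- function(x, ...) {
  cat("Gravity infusion protocol\n")
  cat(sprintf("  initial activity: %.1f MBq in %.1f mL (constant volume)\n",
              x$initial_activity, x$vial_volume))
  start <- c(0, x$phase_end[-length(x$phase_end)])
  for (j in seq_along(x$phase_end)) {
    cat(sprintf("  phase %d: %g-%g min at %g mL/h (dilution rate %.3g /h)\n",
                j, start[j], x$phase_end[j], x$flow_rate[j], x$alpha[j]))
  }
  invisible(x)
}

#' Flow geometry of the infusion line and forearm vein
#'
#' The line and the vein are modelled as a single straight pipe of constant
#' internal radius; the curvilinear abscissa s runs from the vial outlet
#' (s = 0) through the tube/vein junction (the injection site, s =
#' `tube_length`) to the downstream end of the modelled vein. Defaults:
#' internal diameter 2.5 mm (radius 1.25 mm), 115 cm of tubing, 30 cm of
#' vein, saline fluid properties at room temperature.
#'
#' @param tube_radius Internal radius of the tubing (mm).
#' @param tube_length Length of the tubing (cm).
#' @param vein_length Length of the modelled vein segment (cm); same
#'   diameter as the tubing.
#' @param density Fluid density (g/cm^3).
#' @param viscosity Dynamic viscosity (Pa s).
#'
#' @return Object of class `flow_geometry`; `injection_site` (cm) is the
#'   tube/vein junction, i.e. equal to `tube_length`.
#' @export
flow_geometry <- function(tube_radius = 1.25,
                          tube_length = 115,
                          vein_length = 30,
                          density = 1.0053,
                          viscosity = 1.02e-3) {
  vals <- c(tube_radius = tube_radius, tube_length = tube_length,
            vein_length = vein_length, density = density,
            viscosity = viscosity)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all flow-geometry parameters must be positive and finite")
  }
  structure(
    list(
      tube_radius = as.numeric(tube_radius),
      tube_length = as.numeric(tube_length),
      vein_length = as.numeric(vein_length),
      density = as.numeric(density),
      viscosity = as.numeric(viscosity),
      injection_site = as.numeric(tube_length)
    ),
    class = "flow_geometry"
  )
}

#' @export
print.flow_geometry <- function(x, ...) {
  cat("Flow geometry\n")
  cat(sprintf("  tube: radius %g mm, length %g cm; vein: %g cm (same radius)\n",
              x$tube_radius, x$tube_length, x$vein_length))
  cat(sprintf("  fluid: density %g g/cm3, viscosity %g Pa s\n",
              x$density, x$viscosity))
  cat(sprintf("  injection site at s = %g cm\n", x$injection_site))
  invisible(x)
}

#' Discretisation grid for the transport and dose-rate quadratures
#'
#' Midpoint-rule bin sizes. Defaults reproduce the reference resolution:
#' 1 mm axial bins, 0.005 mm radial bins, 1-min time sampling, and for the
#' elliptical extravasation region 0.5 degree angular and 0.1 mm radial bins.
#'
#' @param axial_step Axial bin size along s (mm).
#' @param radial_step Radial bin size across the pipe section (mm); must cut
#'   the tube radius into at least 50 bins.
#' @param time_step Time sampling step (minutes).
#' @param angular_step Angular bin for the elliptical-disc quadrature
#'   (degrees).
#' @param ellipse_radial_step Radial bin for the elliptical-disc quadrature
#'   (mm).
#' @return Object of class `simulation_grid`.
#' @export
simulation_grid <- function(axial_step = 1,
                            radial_step = 0.005,
                            time_step = 1,
                            angular_step = 0.5,
                            ellipse_radial_step = 0.1) {
  vals <- c(axial_step, radial_step, time_step, angular_step,
            ellipse_radial_step)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all grid steps must be positive and finite")
  }
  structure(
    list(
      axial_step = as.numeric(axial_step),
      radial_step = as.numeric(radial_step),
      time_step = as.numeric(time_step),
      angular_step = as.numeric(angular_step),
      ellipse_radial_step = as.numeric(ellipse_radial_step)
    ),
    class = "simulation_grid"
  )
}

#' Point-source dose-rate response of the survey meter
#'
#' Calibration of the survey meter reading 1 cm from the line against the
#' axial position s (cm) of a point source inside the tubing:
#' `H_T(s) = a * (s^2 + b^2)^(c/2)`. Defaults are the reference calibration
#' of an AT1123 meter with an 11.01 MBq point source (a = 516.4, b = 4.065,
#' c = -1.917); the line integral converting simulated activity into EDR is
#' restricted to +/- `window_halfwidth` around the injection site.
#'
#' @param a Amplitude (uSv/h cm^-c); positive.
#' @param b Off-axis softening length (cm); positive.
#' @param c Power-law exponent; negative.
#' @param calibration_activity Activity of the calibration point source (MBq).
#' @param window_halfwidth Integration half-width m around the injection
#'   site (cm).
#' @param r_squared,rmse Optional goodness-of-fit criteria carried along by
#'   [fit_point_response()].
#' @return Object of class `calibration_curve`.
#' @seealso [point_source_response()], [fit_point_response()]
#' @export
calibration_curve <- function(a = 516.4,
                              b = 4.065,
                              c = -1.917,
                              calibration_activity = 11.01,
                              window_halfwidth = 20,
                              r_squared = NULL,
                              rmse = NULL) {
  if (!is.finite(a) || a <= 0) stop("`a` must be positive")
  if (!is.finite(b) || b <= 0) stop("`b` must be positive")
  if (!is.finite(c) || c >= 0) stop("`c` must be negative")
  if (!is.finite(calibration_activity) || calibration_activity <= 0) {
    stop("`calibration_activity` must be positive (MBq)")
  }
  if (!is.finite(window_halfwidth) || window_halfwidth <= 0) {
    stop("`window_halfwidth` must be positive (cm)")
  }
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         calibration_activity = as.numeric(calibration_activity),
         window_halfwidth = as.numeric(window_halfwidth),
         r_squared = r_squared, rmse = rmse),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Survey-meter point-source response H_T(s) = a.(s^2 + b^2)^(c/2)\n")
  cat(sprintf("  a = %.4g uSv/h cm^-c, b = %.4g cm, c = %.4g\n", x$a, x$b, x$c))
  cat(sprintf("  calibration activity %.4g MBq, window half-width %g cm\n",
              x$calibration_activity, x$window_halfwidth))
  if (!is.null(x$r_squared)) {
    cat(sprintf("  fit: R^2 = %.4f, RMSE = %.3f uSv/h\n", x$r_squared, x$rmse))
  }
  invisible(x)
}

#' Extravasation scenario
#'
#' An extravasation starting at `onset_time` at the injection site; the
#' extravascular pool is modelled as a perfectly mixed elliptical slab whose
#' along-arm/across-arm aspect ratio is fixed at `aspect_ratio`.
#'
#' @param onset_time Onset time t_E (minutes from the start of the infusion).
#' @param aspect_ratio Elliptical aspect ratio AR = beta/alpha (>= 1);
#'   AR = 2 is the radiologically precautionary default.
#' @return Object of class `extravasation_scenario`.
#' @export
extravasation_scenario <- function(onset_time, aspect_ratio = 2) {
  if (!is.finite(onset_time) || onset_time < 0) {
    stop("`onset_time` must be a nonnegative time in minutes")
  }
  if (!is.finite(aspect_ratio) || aspect_ratio < 1) {
    stop("`aspect_ratio` must be >= 1")
  }
  structure(
    list(onset_time = as.numeric(onset_time),
         aspect_ratio = as.numeric(aspect_ratio)),
    class = "extravasation_scenario"
  )
}

# phase bookkeeping -----------------------------------------------------

.phase_table <- function(protocol) {
  end <- protocol$phase_end
  list(start = c(0, end[-length(end)]), end = end, q = protocol$flow_rate)
}

# Phase index with half-open intervals (T_{j-1}, T_j]; t = 0 belongs to
# phase 1, evaluation exactly at a boundary uses the earlier phase.
.phase_of <- function(t, protocol) {
  end <- protocol$phase_end
  n <- length(end)
  if (n == 1L) return(rep(1L, length(t)))
  1L + as.integer(rowSums(outer(t, end[-n], ">")))
}

.check_time <- function(t, protocol, what = "t") {
  if (any(!is.finite(t)) || any(t < 0) || any(t > protocol$total_time)) {
    stop(sprintf("`%s` must lie in [0, %g] minutes", what, protocol$total_time))
  }
  invisible(TRUE)
}
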