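#' Survey-meter response to a point source inside the line
#'
#' `H_T(s) = a * (s^2 + b^2)^(c/2)`: the meter reading 1 cm from the tubing
#' when the calibration point source sits at axial distance `s` from the
#' measurement point. Even in `s`, strictly decreasing in `|s|`; the 1-cm
#' standoff of the measurement is absorbed into the fitted constants.
#'
#' @param s Axial source-detector distance(s) (cm); any finite value.
#' @param curve A [calibration_curve()].
#' @return EDR in uSv/h.
#' @examples
#' point_source_response(0) # ~35.1 uSv/h for the default calibration
#' @export
point_source_response <- function(s, curve = calibration_curve()) {
  if (any(!is.finite(s))) stop("`s` must be finite (cm)")
  curve$a * (s^2 + curve$b^2)^(curve$c / 2)
}

#' Fit the point-source response to calibration measurements
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `EDR ~ a * (s^2 + b^2)^(c/2)` to measured (position, EDR) pairs, as
#' obtained by stepping a calibrated point source along the tubing at a
#' fixed 1-cm meter standoff.
#'
#' @param measurements A `data.frame` with columns `position_cm` and
#'   `edr_uSv_h` (as read by [read_calibration()]), or a numeric vector of
#'   positions when `edr` is supplied separately.
#' @param edr Optional numeric vector of EDR readings (uSv/h).
#' @param calibration_activity Activity of the point source (MBq), carried
#'   into the returned curve.
#' @param window_halfwidth Integration half-width (cm) carried into the
#'   returned curve.
#' @return A [calibration_curve()] with `r_squared` and `rmse`
#'   goodness-of-fit criteria filled in.
#' @export
fit_point_response <- function(measurements, edr = NULL,
                               calibration_activity = 11.01,
                               window_halfwidth = 20) {
  if (is.data.frame(measurements)) {
    if (!all(c("position_cm", "edr_uSv_h") %in% names(measurements))) {
      stop("`measurements` needs columns position_cm and edr_uSv_h")
    }
    s <- measurements$position_cm
    y <- measurements$edr_uSv_h
  } else {
    s <- as.numeric(measurements)
    y <- as.numeric(edr)
  }
  if (length(s) != length(y) || any(!is.finite(s)) || any(!is.finite(y))) {
    stop("positions and EDR readings must be finite and of equal length")
  }
  if (length(unique(s)) < 4L) {
    stop("at least 4 distinct source positions are required for the fit")
  }
  if (any(y <= 0)) stop("EDR readings must be positive")
  b0 <- 3
  c0 <- -2
  a0 <- max(y) * b0^(-c0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * (s^2 + b^2)^(cc / 2),
      start = list(a = a0, b = b0, cc = c0),
      lower = c(a = 1e-9, b = 1e-9, cc = -10),
      upper = c(a = Inf, b = Inf, cc = -1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("point-response fit failed: ",
                             conditionMessage(e))
  )
  cf <- stats::coef(fit)
  res <- y - stats::predict(fit)
  calibration_curve(
    a = cf[["a"]], b = cf[["b"]], c = cf[["cc"]],
    calibration_activity = calibration_activity,
    window_halfwidth = window_halfwidth,
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean(res^2))
  )
}

#' Equivalent dose rate at the injection site during a nonextravasated
#' infusion
#'
#' Line integral of the simulated linear activity density against the
#' point-source response, scaled by the calibration activity:
#' `EDR(t) = (1/A_cal) * int lambda(s, t) H_T(s_a - s) ds` over
#' `s in [s_a - m, s_a + m]`, clipped to the physical line. Only activity
#' within the +/- m window contributes by construction.
#'
#' @param t Time(s) (minutes); vectorised.
#' @param protocol An [infusion_protocol()].
#' @param geometry A [flow_geometry()].
#' @param grid A [simulation_grid()].
#' @param curve A [calibration_curve()].
#' @return EDR in uSv/h.
#' @export
infusion_edr <- function(t, protocol = infusion_protocol(),
                         geometry = flow_geometry(),
                         grid = simulation_grid(),
                         curve = calibration_curve()) {
  .check_time(t, protocol)
  sa_mm <- .units$cm_to_mm(geometry$injection_site)
  total_mm <- .units$cm_to_mm(geometry$tube_length + geometry$vein_length)
  m_mm <- .units$cm_to_mm(curve$window_halfwidth)
  s_from <- max(0, sa_mm - m_mm)
  s_to <- min(total_mm, sa_mm + m_mm)
  vapply(t, function(ti) {
    ld <- .line_density(ti, protocol, geometry, grid,
                        s_from_mm = s_from, s_to_mm = s_to)
    ht <- point_source_response(.units$mm_to_cm(sa_mm - ld$s_mid), curve)
    sum(ld$lambda * ld$width * ht) / curve$calibration_activity
  }, numeric(1))
}

#' Polar equation of the extravasation ellipse
#'
#' `r(theta) = beta / sqrt(1 - cos^2(theta) + (beta/alpha)^2 cos^2(theta))`:
#' the angle is measured from the across-arm (minor) axis, so `r(0) = alpha`
#' and `r(pi/2) = beta`; period pi.
#'
#' @param theta Angle(s) in radians.
#' @param alpha Semi-minor axis (across the arm), mm.
#' @param beta Semi-major axis (along the arm), mm.
#' @return Radius in mm.
#' @export
ellipse_polar_radius <- function(theta, alpha, beta) {
  if (any(!is.finite(c(alpha, beta))) || any(c(alpha, beta) <= 0)) {
    stop("semi-axes must be positive")
  }
  c2 <- cos(theta)^2
  beta / sqrt(1 - c2 + (beta / alpha)^2 * c2)
}

#' Semi-axes of the extravasation region from its volume
#'
#' The pool is a slab of elliptical footprint and fixed thickness equal to
#' the tubing diameter `2R` (the geometry in which the point-source response
#' was calibrated), so `alpha * beta = V_E / (2 R pi)` with the aspect ratio
#' `AR = beta/alpha` fixed.
#'
#' @param volume Extravasated volume V_E (mL), > 0.
#' @param aspect_ratio AR = beta/alpha, >= 1.
#' @param tube_radius Tubing radius R (mm).
#' @return Object of class `ellipse_region`: list with `alpha`, `beta`
#'   (mm) and `thickness` (mm). A zero volume signals a distinct
#'   degenerate-region error.
#' @examples
#' ellipse_semi_axes(2.2, 2) # alpha ~11.8 mm, beta ~23.7 mm
#' @export
ellipse_semi_axes <- function(volume, aspect_ratio = 2, tube_radius = 1.25) {
  if (!is.finite(aspect_ratio) || aspect_ratio < 1) {
    stop("`aspect_ratio` must be >= 1")
  }
  if (!is.finite(tube_radius) || tube_radius <= 0) {
    stop("`tube_radius` must be positive (mm)")
  }
  if (!is.finite(volume) || volume < 0) stop("`volume` must be >= 0 (mL)")
  if (volume == 0) {
    stop(structure(
      class = c("extravasim_degenerate", "error", "condition"),
      list(message = "zero extravasated volume: degenerate ellipse region",
           call = sys.call(-1))
    ))
  }
  prod_mm2 <- .units$ml_to_mm3(volume) / (2 * tube_radius * pi)
  alpha <- sqrt(prod_mm2 / aspect_ratio)
  structure(
    list(alpha = alpha, beta = aspect_ratio * alpha,
         thickness = 2 * tube_radius),
    class = "ellipse_region"
  )
}

# Midpoint quadrature of H_T(r) * r over the elliptical disc, distances in
# cm. Evaluated as a ring sum: each radial ring contributes H(r) r dr times
# the angular measure of the ellipse sector reaching past it, which is
# algebraically identical to the full theta x r midpoint grid (angular bins
# grid$angular_step deg, radial bins grid$ellipse_radial_step mm) but avoids
# materialising the 2-D mask. Quarter symmetry of cos^2 is used.
.ellipse_ht_integral <- function(alpha_mm, beta_mm, curve, grid) {
  n_th <- max(1L, round(90 / grid$angular_step))
  dth <- (pi / 2) / n_th
  th_mid <- (seq_len(n_th) - 0.5) * dth
  dr_cm <- grid$ellipse_radial_step / 10
  r_theta <- ellipse_polar_radius(th_mid, alpha_mm, beta_mm) / 10 # cm
  r <- .bins(0, beta_mm / 10, dr_cm)
  # number of angular midpoints whose ellipse boundary lies beyond each ring
  n_beyond <- length(r_theta) -
    findInterval(r$mid, sort(r_theta))
  ht <- point_source_response(r$mid, curve)
  4 * sum(ht * r$mid * r$width * dth * n_beyond)
}

#' Equivalent dose rate above an extravasated pool
#'
#' The perfectly mixed elliptical pool of concentration `C_E` is converted
#' to a meter reading 1 cm above the injection site by integrating the
#' point-source response over the elliptical disc:
#' `EDR = (C_E / A_cal) * int_0^{2pi} int_0^{r(theta)} H_T(r) r dr dtheta`
#' (in-plane distances in cm, concentration in MBq/mL, following the
#' calibration geometry in which `H_T` was measured). Zero whenever no
#' activity has accumulated. At fixed time and onset the reading decreases
#' with the aspect ratio: elongated pools push activity away from the
#' detector.
#'
#' @param t Evaluation time(s) (minutes), `>=` the scenario onset.
#' @param scenario An [extravasation_scenario()].
#' @param protocol,geometry,grid,curve Model components.
#' @return EDR in uSv/h, same length as `t`.
#' @export
extravasation_edr <- function(t, scenario,
                              protocol = infusion_protocol(),
                              geometry = flow_geometry(),
                              grid = simulation_grid(),
                              curve = calibration_curve()) {
  if (!inherits(scenario, "extravasation_scenario")) {
    stop("`scenario` must be an extravasation_scenario()")
  }
  .check_time(t, protocol)
  if (any(t < scenario$onset_time)) stop("`t` must be >= the onset time")
  up_onset <- upstream_activity(scenario$onset_time, protocol, geometry, grid)
  vapply(t, function(ti) {
    a_e <- max(0, up_onset -
                 upstream_activity(ti, protocol, geometry, grid))
    v_e <- extravasated_volume(ti, scenario$onset_time, protocol)
    .pool_edr(a_e, v_e, scenario$aspect_ratio, geometry, grid, curve)
  }, numeric(1))
}

# EDR of a mixed pool given activity (MBq) and volume (mL)
.pool_edr <- function(a_e, v_e, aspect_ratio, geometry, grid, curve) {
  if (a_e <= 0 || v_e <= 0) return(0)
  region <- ellipse_semi_axes(v_e, aspect_ratio, geometry$tube_radius)
  conc <- a_e / v_e # MBq/mL
  conc / curve$calibration_activity *
    .ellipse_ht_integral(region$alpha, region$beta, curve, grid)
}
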