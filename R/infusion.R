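#' Activity remaining in the vial
#'
#' Constant-volume dilution of the vial by the saline drip: within each flow
#' phase the activity decays exponentially with rate `alpha_j = Q_j / V_V`,
#' and the phases chain continuously, giving
#' `A_V(t) = A_0 * exp(-sum_j alpha_j * dt_j)` where `dt_j` is the time spent
#' in phase j up to `t`. Radioactive decay is neglected (the infusion lasts
#' 0.4% of the 177Lu half-life).
#'
#' @param t Time(s) since the start of the infusion (minutes); must lie in
#'   `[0, total_time]`.
#' @param protocol An [infusion_protocol()].
#' @return Vial activity in MBq, same length as `t`; strictly decreasing and
#'   continuous across phase boundaries.
#' @examples
#' vial_activity(c(0, 40), infusion_protocol())
#' @export
vial_activity <- function(t, protocol = infusion_protocol()) {
  .check_time(t, protocol)
  .vial_activity_num(t, protocol)
}

# no-validation closed form, safe for large internal vectors
.vial_activity_num <- function(t, protocol) {
  ph <- .phase_table(protocol)
  alpha_min <- protocol$alpha / 60 # 1/min
  expo <- numeric(length(t))
  for (j in seq_along(ph$end)) {
    expo <- expo + alpha_min[j] * pmax(0, pmin(t, ph$end[j]) - ph$start[j])
  }
  protocol$initial_activity * exp(-expo)
}

# vial concentration in MBq/mL
.vial_concentration_num <- function(t, protocol) {
  .vial_activity_num(t, protocol) / protocol$vial_volume
}

#' Cross-sectional mean flow velocity
#'
#' `v_mean = Q / (pi R^2)`.
#'
#' @param flow_rate Flow rate (mL/h), positive.
#' @param radius Internal pipe radius (mm), positive.
#' @return Mean velocity in mm/s.
#' @examples
#' mean_velocity(50, 1.25) # ~2.83 mm/s
#' @export
mean_velocity <- function(flow_rate, radius) {
  if (any(!is.finite(flow_rate)) || any(flow_rate <= 0)) {
    stop("`flow_rate` must be positive (mL/h)")
  }
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("`radius` must be positive (mm)")
  }
  .units$mlh_to_mm3s(flow_rate) / (pi * radius^2)
}

#' Reynolds number of the tube + vein compartment
#'
#' `Re = 2 rho v_mean R / eta`. For the clinical flow rates (50/100/200
#' mL/h) the regime is deeply laminar, which justifies the Poiseuille
#' velocity profile used by the transport model. The radius is an explicit
#' argument so the number can be evaluated for any stated pipe size.
#'
#' @param flow_rate Flow rate (mL/h).
#' @param radius Pipe radius (mm).
#' @param density Fluid density (g/cm^3).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(c(50, 100, 200), 2.5) # 3.5, 7.0, 13.9
#' @export
reynolds_number <- function(flow_rate, radius, density = 1.0053,
                            viscosity = 1.02e-3) {
  vals <- c(flow_rate, radius, density, viscosity)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all arguments must be positive and finite")
  }
  q_m3s <- flow_rate * 1e-6 / 3600
  r_m <- radius / 1000
  rho <- density * 1000 # kg/m3
  v <- q_m3s / (pi * r_m^2)
  2 * rho * v * r_m / viscosity
}

#' Parabolic (Poiseuille) radial velocity profile
#'
#' `v(r) = 2 v_mean (1 - r^2/R^2)`: twice the mean velocity on the axis,
#' zero at the wall (no slip).
#'
#' @param r Radial position(s) (mm), in `[0, radius]`.
#' @param flow_rate Flow rate (mL/h).
#' @param radius Pipe radius (mm).
#' @return Axial velocity in mm/s.
#' @export
radial_velocity <- function(r, flow_rate, radius) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > radius)) {
    stop("`r` must lie in [0, radius]")
  }
  2 * mean_velocity(flow_rate, radius) * (1 - (r / radius)^2)
}

# per-phase mean velocities in mm/min
.phase_vmean_mm_min <- function(protocol, geometry) {
  .units$mlh_to_mm3min(protocol$flow_rate) / (pi * geometry$tube_radius^2)
}

#' Distance travelled by a fluid parcel since the start of the infusion
#'
#' For the parcel flowing at radius `r`, the total distance covered by time
#' `t` is the sum over the elapsed flow phases of `v_j(r)` times the phase
#' duration: piecewise linear in `t`, nondecreasing in `t`, nonincreasing in
#' `r`, zero at the wall. This is the position of the advancing activity
#' front for fluid that left the vial at t = 0.
#'
#' @param r Radial position(s) (mm), in `[0, R]`.
#' @param t Time(s) (minutes), in `[0, total_time]`.
#' @param protocol An [infusion_protocol()].
#' @param geometry A [flow_geometry()].
#' @return Distance in mm (recycling `r` and `t` to a common length).
#' @export
front_distance <- function(r, t, protocol = infusion_protocol(),
                           geometry = flow_geometry()) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > geometry$tube_radius)) {
    stop("`r` must lie in [0, R]")
  }
  .check_time(t, protocol)
  ph <- .phase_table(protocol)
  vm <- .phase_vmean_mm_min(protocol, geometry)
  n <- max(length(r), length(t))
  r <- rep_len(r, n)
  t <- rep_len(t, n)
  acc <- numeric(n)
  for (j in seq_along(ph$end)) {
    acc <- acc + vm[j] * pmax(0, pmin(t, ph$end[j]) - ph$start[j])
  }
  2 * (1 - (r / geometry$tube_radius)^2) * acc
}

#' Transit delay of the fluid element at (s, r) at time t
#'
#' The time it took the fluid element now sitting at curvilinear abscissa
#' `s` and radius `r` to travel from the vial outlet, accounting for every
#' flow-rate change it lived through. The delay is reconstructed by walking
#' the distance `s` backwards through the flow phases at the radius-specific
#' velocities `v_j(r)`; in the earliest phase the velocity is extrapolated
#' backwards without bound, which reproduces the piecewise closed form of
#' the transport model (e.g. `s / v_1(r)` whenever `t <= T_1`).
#'
#' At the wall (`r = R`) the fluid is stationary and the delay is returned
#' as `Inf`.
#'
#' @param s Curvilinear abscissa (cm), >= 0 (0 = vial outlet).
#' @param r Radial position (mm), in `[0, R]`.
#' @param t Evaluation time (minutes).
#' @param protocol An [infusion_protocol()].
#' @param geometry A [flow_geometry()].
#' @return Delay in minutes (arguments recycled to a common length).
#' @export
time_delay <- function(s, r, t, protocol = infusion_protocol(),
                       geometry = flow_geometry()) {
  if (any(!is.finite(s)) || any(s < 0)) stop("`s` must be >= 0 (cm)")
  if (any(!is.finite(r)) || any(r < 0) || any(r > geometry$tube_radius)) {
    stop("`r` must lie in [0, R]")
  }
  .check_time(t, protocol)
  .time_delay_num(.units$cm_to_mm(s), r, t, protocol, geometry)
}

# Backward phase walk; s_mm, r_mm, t recycled. profile = "poiseuille" uses
# v_j(r); "plug" uses the uniform mean velocity (used by the piston-flow
# consistency checks).
.time_delay_num <- function(s_mm, r_mm, t, protocol, geometry,
                            profile = "poiseuille") {
  n <- max(length(s_mm), length(r_mm), length(t))
  s_mm <- rep_len(s_mm, n)
  r_mm <- rep_len(r_mm, n)
  t <- rep_len(t, n)
  ph <- .phase_table(protocol)
  vm <- .phase_vmean_mm_min(protocol, geometry)
  fac <- if (profile == "plug") {
    rep(1, n)
  } else {
    2 * (1 - (r_mm / geometry$tube_radius)^2)
  }
  p <- .phase_of(t, protocol)
  delay <- numeric(n)
  rem <- s_mm
  for (j in rev(seq_along(ph$end))) {
    act <- p >= j & rem > 0
    if (!any(act)) next
    vj <- vm[j] * fac # mm/min, 0 at the wall
    distj <- vj * pmax(0, pmin(t, ph$end[j]) - ph$start[j])
    take <- if (j > 1L) pmin(rem, distj) else rem
    dt <- numeric(n)
    idx <- act & take > 0
    dt[idx] <- take[idx] / vj[idx] # Inf at the wall
    delay <- delay + dt
    rem <- rem - ifelse(act, take, 0)
  }
  delay
}

# midpoint bins over [from, to]; returns mids and widths
.bins <- function(from, to, step) {
  breaks <- seq(from, to, by = step)
  if (breaks[length(breaks)] < to) breaks <- c(breaks, to)
  list(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
       width = diff(breaks))
}

.check_radial_bins <- function(geometry, grid) {
  if (geometry$tube_radius / grid$radial_step < 50) {
    stop("`radial_step` must cut the tube radius into at least 50 bins")
  }
  invisible(TRUE)
}

# Linear activity density lambda(s) in MBq/mm at time t over the axial
# window [s_from_mm, s_to_mm]: the radial quadrature of
# C_V(t - T_delay(s, r, t)) * 2 pi r, zero ahead of the advancing front.
.line_density <- function(t, protocol, geometry, grid,
                          profile = "poiseuille",
                          s_from_mm = 0,
                          s_to_mm = .units$cm_to_mm(geometry$tube_length +
                                                      geometry$vein_length)) {
  .check_radial_bins(geometry, grid)
  ax <- .bins(s_from_mm, s_to_mm, grid$axial_step)
  ra <- .bins(0, geometry$tube_radius, grid$radial_step)
  ns <- length(ax$mid)
  nr <- length(ra$mid)
  s_big <- rep(ax$mid, times = nr)
  r_big <- rep(ra$mid, each = ns)
  w_big <- rep(ra$width, each = ns)
  fac <- if (profile == "plug") {
    rep(1, length(r_big))
  } else {
    2 * (1 - (r_big / geometry$tube_radius)^2)
  }
  # front position for each radius
  ph <- .phase_table(protocol)
  vm <- .phase_vmean_mm_min(protocol, geometry)
  acc <- 0
  for (j in seq_along(ph$end)) {
    acc <- acc + vm[j] * max(0, min(t, ph$end[j]) - ph$start[j])
  }
  behind <- s_big <= fac * acc
  conc <- numeric(length(s_big))
  if (any(behind)) {
    delay <- .time_delay_num(s_big[behind], r_big[behind], t, protocol,
                             geometry, profile = profile)
    u <- pmax(0, t - delay)
    conc[behind] <- .vial_concentration_num(u, protocol) / 1000 # MBq/mm3
  }
  contrib <- conc * 2 * pi * r_big * w_big
  list(s_mid = ax$mid, width = ax$width,
       lambda = rowSums(matrix(contrib, nrow = ns)))
}

#' Activity contained in an axial segment of the line
#'
#' Double midpoint quadrature (axial x radial) of the advected vial
#' concentration over the window `[s_min, s_max]` of the tube + vein pipe:
#' each fluid element carries the vial concentration it left with, delayed
#' by its radius-dependent transit time, and the concentration is zero ahead
#' of the advancing front.
#'
#' @param t Time (minutes).
#' @param s_min,s_max Axial window (cm), within the physical line
#'   `[0, tube_length + vein_length]`.
#' @param protocol An [infusion_protocol()].
#' @param geometry A [flow_geometry()].
#' @param grid A [simulation_grid()].
#' @param profile `"poiseuille"` (parabolic profile; default) or `"plug"`
#'   (uniform mean velocity), the latter mainly for numerical verification
#'   against the closed-form piston solution.
#' @return Activity in MBq.
#' @export
segment_activity <- function(t, s_min, s_max,
                             protocol = infusion_protocol(),
                             geometry = flow_geometry(),
                             grid = simulation_grid(),
                             profile = c("poiseuille", "plug")) {
  profile <- match.arg(profile)
  .check_time(t, protocol)
  total <- geometry$tube_length + geometry$vein_length
  if (!is.finite(s_min) || !is.finite(s_max) || s_min < 0 || s_max > total ||
      s_min >= s_max) {
    stop(sprintf("window must satisfy 0 <= s_min < s_max <= %g cm", total))
  }
  ld <- .line_density(t, protocol, geometry, grid, profile = profile,
                      s_from_mm = .units$cm_to_mm(s_min),
                      s_to_mm = .units$cm_to_mm(s_max))
  sum(ld$lambda * ld$width)
}

#' Activity remaining upstream of the patient (vial + tubing)
#'
#' The "apparatus" compartment whose depletion feeds an extravasated pool:
#' closed-form vial activity plus the quadrature tubing activity over
#' `[0, tube_length]`.
#'
#' @inheritParams segment_activity
#' @param t Time(s) (minutes); vectorised.
#' @return Activity in MBq, same length as `t`.
#' @export
upstream_activity <- function(t, protocol = infusion_protocol(),
                              geometry = flow_geometry(),
                              grid = simulation_grid()) {
  .check_time(t, protocol)
  tube <- vapply(t, function(ti) {
    segment_activity(ti, 0, geometry$tube_length, protocol, geometry, grid)
  }, numeric(1))
  .vial_activity_num(t, protocol) + tube
}

#' Simulate the nonextravasated infusion
#'
#' Runs the transport model on the time grid and books the activity into
#' four compartments: vial (closed form), tubing and vein (quadrature of
#' the advected concentration over their axial windows), and patient (the
#' conservation remainder, since decay is neglected and delivery is
#' one-way).
#'
#' @param protocol An [infusion_protocol()].
#' @param geometry A [flow_geometry()].
#' @param grid A [simulation_grid()].
#' @param times Optional time samples (minutes); default
#'   `seq(0, total_time, by = grid$time_step)`.
#' @return A `data.frame` of class `infusion_sim` with columns `time_min`,
#'   `vial_MBq`, `tubing_MBq`, `vein_MBq`, `patient_MBq`; the four
#'   compartments sum to the initial activity at every sample.
#' @examples
#' \donttest{
#' sim <- simulate_infusion(grid = simulation_grid(radial_step = 0.025,
#'                                                 axial_step = 5))
#' sim$time_min[which.max(sim$vein_MBq)]
#' }
#' @export
simulate_infusion <- function(protocol = infusion_protocol(),
                              geometry = flow_geometry(),
                              grid = simulation_grid(),
                              times = NULL) {
  if (is.null(times)) {
    times <- seq(0, protocol$total_time, by = grid$time_step)
  }
  .check_time(times, protocol)
  lt_mm <- .units$cm_to_mm(geometry$tube_length)
  res <- vapply(times, function(ti) {
    ld <- .line_density(ti, protocol, geometry, grid)
    in_tube <- ld$s_mid <= lt_mm
    c(tube = sum(ld$lambda[in_tube] * ld$width[in_tube]),
      vein = sum(ld$lambda[!in_tube] * ld$width[!in_tube]))
  }, numeric(2))
  vial <- .vial_activity_num(times, protocol)
  out <- data.frame(
    time_min = times,
    vial_MBq = vial,
    tubing_MBq = res["tube", ],
    vein_MBq = res["vein", ],
    patient_MBq = protocol$initial_activity - vial - res["tube", ] -
      res["vein", ]
  )
  attr(out, "protocol") <- protocol
  attr(out, "geometry") <- geometry
  attr(out, "grid") <- grid
  class(out) <- c("infusion_sim", "data.frame")
  out
}
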