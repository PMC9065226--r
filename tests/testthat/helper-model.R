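# Shared fixtures. Unit tests run on a coarsened grid (50 radial bins, 5 mm
# axial bins) that keeps every check fast while staying inside the model's
# convergence regime; the acceptance tests use the full default resolution.

test_grid <- function() {
  simulation_grid(axial_step = 5, radial_step = 0.025)
}

default_protocol <- infusion_protocol()
default_geometry <- flow_geometry()

# memoised default-resolution simulation shared by the acceptance blocks
.acc_env <- new.env()
acceptance_sim <- function() {
  if (is.null(.acc_env$sim)) {
    .acc_env$sim <- simulate_infusion(default_protocol, default_geometry,
                                      simulation_grid())
  }
  .acc_env$sim
}

# Closed-form piston (plug-flow) bookkeeping: activity in the axial window
# [s1, s2] cm at time t when every parcel moves at the mean velocity. The
# parcel now at depth s entered the line when the pumped volume equalled
# W(t) - pi R^2 s, and the activity between two entry times is the exact
# vial-activity difference.
plug_flow_oracle <- function(t, s1_cm, s2_cm,
                             protocol = default_protocol,
                             geometry = default_geometry) {
  area <- pi * geometry$tube_radius^2 # mm2
  ends <- protocol$phase_end
  starts <- c(0, ends[-length(ends)])
  q <- protocol$flow_rate * 1000 / 60 # mm3/min
  pumped <- function(u) sum(q * pmax(0, pmin(u, ends) - starts))
  entry_time <- function(s_mm) {
    v <- pumped(t) - area * s_mm
    if (v < 0) return(NA_real_) # ahead of the front
    if (v == 0) return(0)
    stats::uniroot(function(u) pumped(u) - v, c(0, protocol$total_time),
                   tol = 1e-12)$root
  }
  a_of <- function(u) {
    if (is.na(u)) protocol$initial_activity else vial_activity(u, protocol)
  }
  a_of(entry_time(s2_cm * 10)) - a_of(entry_time(s1_cm * 10))
}

# Brute-force Cartesian quadrature of H_T over an elliptical disc (cm grid)
cartesian_ellipse_integral <- function(alpha_mm, beta_mm,
                                       curve = calibration_curve(),
                                       step_cm = 0.01) {
  a <- alpha_mm / 10
  b <- beta_mm / 10
  x <- seq(-b + step_cm / 2, b, by = step_cm)
  y <- seq(-a + step_cm / 2, a, by = step_cm)
  xx <- rep(x, times = length(y))
  yy <- rep(y, each = length(x))
  inside <- (xx / b)^2 + (yy / a)^2 <= 1
  sum(point_source_response(sqrt(xx^2 + yy^2)[inside], curve)) * step_cm^2
}
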