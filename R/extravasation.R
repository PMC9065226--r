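#' Activity accumulated in the extravasated pool
#'
#' Once the vein wall is breached at `t_E`, everything that leaves the
#' vial + tubing compartment accumulates at the injection site instead of
#' reaching the patient (the vial dynamics and the line flow rate are
#' unaffected by the leak). The pool activity is therefore the depletion of
#' the upstream compartment between the onset and the current time:
#' `A_E(t, t_E) = [A_V + A_T](t_E) - [A_V + A_T](t)`.
#'
#' @param t Evaluation time (minutes), `t >= t_E`.
#' @param t_E Extravasation onset time (minutes).
#' @param protocol An [infusion_protocol()].
#' @param geometry A [flow_geometry()].
#' @param grid A [simulation_grid()].
#' @return Extravasated activity in MBq; nonnegative and nondecreasing in
#'   `t`.
#' @export
extravasated_activity <- function(t, t_E,
                                  protocol = infusion_protocol(),
                                  geometry = flow_geometry(),
                                  grid = simulation_grid()) {
  .check_time(t_E, protocol, "t_E")
  .check_time(t, protocol)
  if (any(t < t_E)) stop("`t` must be >= `t_E`")
  n <- max(length(t), length(t_E))
  t <- rep_len(t, n)
  t_E <- rep_len(t_E, n)
  up_onset <- upstream_activity(t_E, protocol, geometry, grid)
  up_now <- upstream_activity(t, protocol, geometry, grid)
  # tiny negative excursions are quadrature noise
  pmax(0, up_onset - up_now)
}

#' Volume accumulated in the extravasated pool
#'
#' The pool volume grows at the instantaneous infusion flow rate, so it is
#' the piecewise-linear integral of the flow schedule between `t_E` and `t`
#' (continuous across phase boundaries, slope = current flow rate).
#'
#' @inheritParams extravasated_activity
#' @return Volume in mL.
#' @examples
#' extravasated_volume(25, 5) # 37.5 mL under the default schedule
#' @export
extravasated_volume <- function(t, t_E, protocol = infusion_protocol()) {
  .check_time(t_E, protocol, "t_E")
  .check_time(t, protocol)
  if (any(t < t_E)) stop("`t` must be >= `t_E`")
  ph <- .phase_table(protocol)
  n <- max(length(t), length(t_E))
  t <- rep_len(t, n)
  t_E <- rep_len(t_E, n)
  vol <- numeric(n)
  for (j in seq_along(ph$end)) {
    overlap <- pmax(0, pmin(t, ph$end[j]) - pmax(t_E, ph$start[j]))
    vol <- vol + overlap * ph$q[j] / 60 # mL
  }
  vol
}

#' Activity concentration of the extravasated pool
#'
#' `C_E = A_E / V_E`, assuming the pool is perfectly mixed. At `t = t_E`
#' the ratio is 0/0 and the function signals a distinct degenerate-pool
#' error. For onsets before the activity front reaches the arm the pool is
#' initially pure saline and the concentration is zero until arrival.
#'
#' @inheritParams extravasated_activity
#' @return Concentration in MBq/mL.
#' @export
extravasated_concentration <- function(t, t_E,
                                       protocol = infusion_protocol(),
                                       geometry = flow_geometry(),
                                       grid = simulation_grid()) {
  if (any(t == t_E)) {
    stop(structure(
      class = c("extravasim_degenerate", "error", "condition"),
      list(message = "concentration undefined at t = t_E (0/0 pool)",
           call = sys.call(-1))
    ))
  }
  extravasated_activity(t, t_E, protocol, geometry, grid) /
    extravasated_volume(t, t_E, protocol)
}

#' Trajectory of an extravasated pool
#'
#' Tabulates activity, volume and concentration of the pool from onset to
#' the end of the infusion.
#'
#' @param t_E Onset time (minutes).
#' @param protocol,geometry,grid Model components.
#' @param times Optional evaluation times (minutes, all `>= t_E`); defaults
#'   to the simulation time grid from `t_E` to the end.
#' @return `data.frame` with columns `t_min`, `t_E_min`, `A_E_MBq`,
#'   `V_E_mL`, `C_E_MBq_mL` (`C_E` is `NA` on the degenerate first row when
#'   `t = t_E`).
#' @export
extravasation_trajectory <- function(t_E,
                                     protocol = infusion_protocol(),
                                     geometry = flow_geometry(),
                                     grid = simulation_grid(),
                                     times = NULL) {
  .check_time(t_E, protocol, "t_E")
  if (is.null(times)) {
    times <- seq(t_E, protocol$total_time, by = grid$time_step)
  }
  if (any(times < t_E)) stop("`times` must all be >= t_E")
  a <- extravasated_activity(times, t_E, protocol, geometry, grid)
  v <- extravasated_volume(times, t_E, protocol)
  data.frame(
    t_min = times,
    t_E_min = t_E,
    A_E_MBq = a,
    V_E_mL = v,
    C_E_MBq_mL = ifelse(v > 0, a / v, NA_real_)
  )
}
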