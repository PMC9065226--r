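# session cache for upstream-activity interpolators (keyed on parameters)
.extravasim_cache <- new.env(parent = emptyenv())

# Linear interpolator of A_V + A_T on a fine grid aligned with the phase
# boundaries (step 0.05 min). The vial part is closed form; only the tubing
# quadrature is tabulated, so the interpolation error is far below the
# inversion tolerance. Cached per (protocol, geometry, grid).
.upstream_interp <- function(protocol, geometry, grid, step = 0.05) {
  key <- paste(
    format(c(protocol$initial_activity, protocol$vial_volume,
             protocol$phase_end, protocol$flow_rate,
             geometry$tube_radius, geometry$tube_length,
             geometry$vein_length, grid$axial_step, grid$radial_step, step),
           digits = 15),
    collapse = "|"
  )
  if (!is.null(.extravasim_cache[[key]])) return(.extravasim_cache[[key]])
  tau <- sort(unique(c(seq(0, protocol$total_time, by = step),
                       protocol$phase_end)))
  tube <- vapply(tau, function(ti) {
    segment_activity(ti, 0, geometry$tube_length, protocol, geometry, grid)
  }, numeric(1))
  tube_fun <- stats::approxfun(tau, tube, rule = 2)
  fun <- function(t) .vial_activity_num(t, protocol) + tube_fun(t)
  .extravasim_cache[[key]] <- fun
  fun
}

# pool EDR in uSv/h at (t, t_E) via the cached upstream interpolator
.pool_edr_at <- function(t, t_E, aspect_ratio, up_fun, protocol, geometry,
                         grid, curve) {
  a_e <- max(0, up_fun(t_E) - up_fun(t))
  v_e <- extravasated_volume(t, t_E, protocol)
  .pool_edr(a_e, v_e, aspect_ratio, geometry, grid, curve)
}

#' Invert a bedside EDR reading into extravasation estimates
#'
#' Given the measurement time and an EDR reading at the patient's arm,
#' scans the onset time `t_E` over `[0, t]` on the simulation time grid for
#' sign changes of `extravasation_edr(t, t_E) - edr` and refines each
#' bracketed root by bisection (interval narrowed to 2e-4 min so that every
#' solution reproduces the measured EDR to better than 0.1%). Each root is
#' reported with its extravasated activity, volume and concentration; when
#' several onsets explain the same reading, the maximum-concentration
#' solution is flagged as the precautionary one (small concentrated pools
#' are the radiologically worst case).
#'
#' @param t Measurement time (minutes), in `(0, total_time]`.
#' @param edr Measured EDR (mSv/h), > 0.
#' @param aspect_ratio Assumed pool aspect ratio; 2 is the precautionary
#'   default (it yields the highest EDR per unit activity, hence the most
#'   pessimistic concentration).
#' @param protocol,geometry,grid,curve Model components.
#' @return Object of class `characterization`: list with the measurement
#'   (`time`, `edr`, `aspect_ratio`), a `solutions` data.frame (`t_E_min`,
#'   `activity_MBq`, `volume_mL`, `concentration_MBq_mL`,
#'   `edr_residual_rel`), and `precautionary`, the row index of the
#'   max-concentration solution (NA when no onset can explain the reading).
#' @examples
#' \donttest{
#' characterize(20, 3, grid = simulation_grid(radial_step = 0.025,
#'                                            axial_step = 5))
#' }
#' @export
characterize <- function(t, edr, aspect_ratio = 2,
                         protocol = infusion_protocol(),
                         geometry = flow_geometry(),
                         grid = simulation_grid(),
                         curve = calibration_curve()) {
  if (!is.finite(t) || t <= 0 || t > protocol$total_time) {
    stop(sprintf("`t` must lie in (0, %g] minutes", protocol$total_time))
  }
  if (!is.finite(edr) || edr <= 0) stop("`edr` must be positive (mSv/h)")
  if (!is.finite(aspect_ratio) || aspect_ratio < 1) {
    stop("`aspect_ratio` must be >= 1")
  }
  target <- .units$msvh_to_usvh(edr)
  up_fun <- .upstream_interp(protocol, geometry, grid)
  f <- function(te) {
    .pool_edr_at(t, te, aspect_ratio, up_fun, protocol, geometry, grid,
                 curve) - target
  }
  te_grid <- sort(unique(c(seq(0, t, by = grid$time_step), t)))
  fg <- vapply(te_grid, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(te_grid) - 1L)) {
    if (fg[i] == 0) {
      roots <- c(roots, te_grid[i])
    } else if (fg[i] * fg[i + 1L] < 0) {
      lo <- te_grid[i]
      hi <- te_grid[i + 1L]
      flo <- fg[i]
      while (hi - lo > 2e-4) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (fm == 0) {
          lo <- hi <- mid
        } else if (sign(fm) == sign(flo)) {
          lo <- mid
          flo <- fm
        } else {
          hi <- mid
        }
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  sol <- data.frame(
    t_E_min = roots,
    activity_MBq = numeric(length(roots)),
    volume_mL = numeric(length(roots)),
    concentration_MBq_mL = numeric(length(roots)),
    edr_residual_rel = numeric(length(roots))
  )
  if (length(roots)) {
    for (k in seq_along(roots)) {
      te <- roots[k]
      a_e <- max(0, up_fun(te) - up_fun(t))
      v_e <- extravasated_volume(t, te, protocol)
      sol$activity_MBq[k] <- a_e
      sol$volume_mL[k] <- v_e
      sol$concentration_MBq_mL[k] <- if (v_e > 0) a_e / v_e else NA_real_
      sol$edr_residual_rel[k] <- abs(f(te)) / target
    }
    sol <- sol[order(sol$t_E_min), , drop = FALSE]
    row.names(sol) <- NULL
  }
  structure(
    list(time = t, edr = edr, aspect_ratio = aspect_ratio,
         solutions = sol,
         precautionary = if (nrow(sol)) {
           which.max(sol$concentration_MBq_mL)
         } else {
           NA_integer_
         }),
    class = "characterization"
  )
}

#' @export
print.characterization <- function(x, ...) {
  cat(sprintf(
    "Extravasation characterization at t = %g min, EDR = %g mSv/h (AR = %g)\n",
    x$time, x$edr, x$aspect_ratio))
  if (!nrow(x$solutions)) {
    cat("  no onset time reproduces this reading",
        "(EDR outside the achievable range at this time)\n")
    return(invisible(x))
  }
  for (k in seq_len(nrow(x$solutions))) {
    s <- x$solutions[k, ]
    tag <- if (k == x$precautionary) " [precautionary]" else ""
    cat(sprintf(
      "  onset %6.2f min: %7.1f MBq in %6.2f mL -> %7.1f MBq/mL%s\n",
      s$t_E_min, s$activity_MBq, s$volume_mL, s$concentration_MBq_mL, tag))
  }
  invisible(x)
}

#' Build iso-EDR characterization charts (abacuses)
#'
#' For every combination of EDR level, aspect ratio and measurement time on
#' the simulation time grid, finds the onset time(s) whose extravasated
#' pool reproduces the level, and tabulates the associated activity, volume
#' and concentration. Cells where the level is not achievable are omitted.
#'
#' @param levels EDR levels (mSv/h); default the reference chart levels.
#' @param aspect_ratios Pool aspect ratios; default 2 to 5.
#' @param protocol,geometry,grid,curve Model components.
#' @return `data.frame` of class `abacus_table` with columns `edr_mSv_h`,
#'   `aspect_ratio`, `t_min`, `tE_min`, `activity_MBq`, `volume_mL`,
#'   `concentration_MBq_mL`.
#' @export
build_abacus <- function(levels = c(1, 2, 3, 4, 5, 6, 8, 10),
                         aspect_ratios = c(2, 3, 4, 5),
                         protocol = infusion_protocol(),
                         geometry = flow_geometry(),
                         grid = simulation_grid(),
                         curve = calibration_curve()) {
  if (any(levels <= 0)) stop("EDR levels must be positive (mSv/h)")
  if (any(aspect_ratios < 1)) stop("aspect ratios must be >= 1")
  up_fun <- .upstream_interp(protocol, geometry, grid)
  t_grid <- seq(grid$time_step, protocol$total_time, by = grid$time_step)
  out <- vector("list", 0L)
  for (ar in aspect_ratios) {
    for (t in t_grid) {
      te_grid <- sort(unique(c(seq(0, t, by = grid$time_step), t)))
      edr_usv <- vapply(te_grid, function(te) {
        .pool_edr_at(t, te, ar, up_fun, protocol, geometry, grid, curve)
      }, numeric(1))
      for (lev in levels) {
        target <- .units$msvh_to_usvh(lev)
        fg <- edr_usv - target
        for (i in seq_len(length(te_grid) - 1L)) {
          root <- NA_real_
          if (fg[i] == 0) {
            root <- te_grid[i]
          } else if (fg[i] * fg[i + 1L] < 0) {
            lo <- te_grid[i]
            hi <- te_grid[i + 1L]
            flo <- fg[i]
            while (hi - lo > 2e-4) {
              mid <- (lo + hi) / 2
              fm <- .pool_edr_at(t, mid, ar, up_fun, protocol, geometry,
                                 grid, curve) - target
              if (fm == 0) {
                lo <- hi <- mid
              } else if (sign(fm) == sign(flo)) {
                lo <- mid
                flo <- fm
              } else {
                hi <- mid
              }
            }
            root <- (lo + hi) / 2
          }
          if (!is.na(root)) {
            a_e <- max(0, up_fun(root) - up_fun(t))
            v_e <- extravasated_volume(t, root, protocol)
            out[[length(out) + 1L]] <- data.frame(
              edr_mSv_h = lev, aspect_ratio = ar, t_min = t,
              tE_min = root, activity_MBq = a_e, volume_mL = v_e,
              concentration_MBq_mL = if (v_e > 0) a_e / v_e else NA_real_
            )
          }
        }
      }
    }
  }
  tab <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(edr_mSv_h = numeric(0), aspect_ratio = numeric(0),
               t_min = numeric(0), tE_min = numeric(0),
               activity_MBq = numeric(0), volume_mL = numeric(0),
               concentration_MBq_mL = numeric(0))
  }
  class(tab) <- c("abacus_table", "data.frame")
  tab
}

#' Monitoring series of EDR readings
#'
#' @param time Sample times (minutes), strictly increasing.
#' @param edr EDR readings (uSv/h), nonnegative.
#' @return `data.frame` of class `monitoring_series` with columns
#'   `time_min`, `edr_uSv_h`.
#' @export
monitoring_series <- function(time, edr) {
  time <- as.numeric(time)
  edr <- as.numeric(edr)
  if (!length(time) || length(time) != length(edr)) {
    stop("`time` and `edr` must be non-empty and of equal length")
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("sample times must be finite and strictly increasing")
  }
  if (any(!is.finite(edr)) || any(edr < 0)) {
    stop("EDR readings must be finite and >= 0")
  }
  structure(data.frame(time_min = time, edr_uSv_h = edr),
            class = c("monitoring_series", "data.frame"))
}

#' Screen a monitoring series against the extravasation alarm threshold
#'
#' Flags the first run of at least two consecutive samples whose reading
#' strictly exceeds the threshold (1 mSv/h by default, the empirical level
#' at which a gravity-method Lutathera infusion should be interrupted).
#' The two-sample debounce guards against single-sample operator noise; the
#' alarm time is the first triggering sample, not interpolated.
#'
#' @param series A [monitoring_series()] (or data.frame with `time_min`,
#'   `edr_uSv_h`).
#' @param threshold Alarm threshold (mSv/h), > 0.
#' @return Object of class `edr_detection`: list with `alarm` (logical),
#'   `alarm_time` (minutes or NA), `threshold` and the `triggering`
#'   samples.
#' @export
detect <- function(series, threshold = 1) {
  if (!is.data.frame(series) || !nrow(series) ||
      !all(c("time_min", "edr_uSv_h") %in% names(series))) {
    stop("`series` must be a non-empty monitoring series")
  }
  if (!is.finite(threshold) || threshold <= 0) {
    stop("`threshold` must be positive (mSv/h)")
  }
  over <- series$edr_uSv_h > .units$msvh_to_usvh(threshold)
  idx <- which(over[-length(over)] & over[-1])
  if (length(over) == 1L) idx <- integer(0)
  if (length(idx)) {
    first <- idx[1]
    res <- list(alarm = TRUE,
                alarm_time = series$time_min[first],
                threshold = threshold,
                triggering = series[first:(first + 1L), , drop = FALSE])
  } else {
    res <- list(alarm = FALSE, alarm_time = NA_real_,
                threshold = threshold, triggering = series[0, , drop = FALSE])
  }
  structure(res, class = "edr_detection")
}

#' @export
print.edr_detection <- function(x, ...) {
  if (x$alarm) {
    cat(sprintf(
      "ALARM: EDR above %g mSv/h on >= 2 consecutive samples from t = %g min\n",
      x$threshold, x$alarm_time))
  } else {
    cat(sprintf("no alarm (threshold %g mSv/h)\n", x$threshold))
  }
  invisible(x)
}

#' Synthesize a noisy EDR monitoring series
#'
#' Samples the model EDR every `sampling` minutes (2 min by default, the
#' clinical monitoring cadence) and applies multiplicative Gaussian noise
#' whose fraction mirrors the survey meter accuracy (+/- 20%). Without a
#' scenario the series follows the nonextravasated infusion EDR; with a
#' scenario the reading switches to the extravasated-pool EDR from the
#' onset onwards.
#'
#' @param scenario An [extravasation_scenario()], or NULL for a
#'   nonextravasated infusion.
#' @param protocol,geometry,grid,curve Model components.
#' @param noise_fraction Relative standard deviation of the multiplicative
#'   noise; 0 gives the exact model curve.
#' @param sampling Sampling interval (minutes), `>= grid$time_step`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   series and the caller's RNG state is left untouched.
#' @return A [monitoring_series()].
#' @export
synthesize_monitoring <- function(scenario = NULL,
                                  protocol = infusion_protocol(),
                                  geometry = flow_geometry(),
                                  grid = simulation_grid(),
                                  curve = calibration_curve(),
                                  noise_fraction = 0.2,
                                  sampling = 2,
                                  seed = NULL) {
  if (!is.finite(noise_fraction) || noise_fraction < 0) {
    stop("`noise_fraction` must be >= 0")
  }
  if (!is.finite(sampling) || sampling < grid$time_step) {
    stop("`sampling` must be >= the time grid step")
  }
  times <- seq(0, protocol$total_time, by = sampling)
  if (is.null(scenario)) {
    clean <- infusion_edr(times, protocol, geometry, grid, curve)
  } else {
    if (!inherits(scenario, "extravasation_scenario")) {
      stop("`scenario` must be an extravasation_scenario() or NULL")
    }
    clean <- numeric(length(times))
    pre <- times < scenario$onset_time
    if (any(pre)) {
      clean[pre] <- infusion_edr(times[pre], protocol, geometry, grid, curve)
    }
    if (any(!pre)) {
      clean[!pre] <- extravasation_edr(times[!pre], scenario, protocol,
                                       geometry, grid, curve)
    }
  }
  if (noise_fraction > 0) {
    if (!is.null(seed)) {
      had_seed <- exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE)
      if (had_seed) old <- get(".Random.seed", envir = globalenv())
      on.exit({
        if (had_seed) {
          assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      }, add = TRUE)
      set.seed(seed)
    }
    clean <- pmax(0, clean * (1 + noise_fraction *
                                stats::rnorm(length(clean))))
  }
  monitoring_series(times, clean)
}
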