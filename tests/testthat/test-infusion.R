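test_that("vial activity follows the chained dilution exponentials", {
  p <- default_protocol
  expect_equal(vial_activity(0, p), 7232)
  # closed form: exponent 1/3 + 2/3 + 8/3 = 11/3 over the full infusion
  expect_equal(vial_activity(40, p), 7232 * exp(-11 / 3))
  expect_equal(vial_activity(5, p), 7232 * exp(-(2 / 60) * 5))
  # strictly decreasing and continuous at the phase boundaries
  tg <- seq(0, 40, by = 0.25)
  expect_true(all(diff(vial_activity(tg, p)) < 0))
  for (tb in c(10, 20)) {
    expect_equal(vial_activity(tb - 1e-9, p), vial_activity(tb + 1e-9, p),
                 tolerance = 1e-6)
  }
  expect_error(vial_activity(-1, p), "must lie in")
  expect_error(vial_activity(41, p), "must lie in")
})

test_that("mean velocity and Reynolds number match their closed forms", {
  # Q / (pi R^2) with mL/h -> mm3/s
  expect_equal(mean_velocity(50, 1.25), 50 * 1000 / 3600 / (pi * 1.25^2))
  expect_equal(mean_velocity(100, 1.25), 2 * mean_velocity(50, 1.25))
  expect_equal(mean_velocity(50, 2.5), mean_velocity(50, 1.25) / 4)
  expect_error(mean_velocity(-50, 1.25), "positive")
  expect_error(mean_velocity(50, 0), "positive")
  # Re scales as Q/R at fixed fluid
  expect_equal(reynolds_number(100, 2.5), 2 * reynolds_number(50, 2.5))
  expect_equal(reynolds_number(50, 1.25), 2 * reynolds_number(50, 2.5))
  expect_error(reynolds_number(50, 2.5, density = -1), "positive")
})

test_that("parabolic profile has no slip, doubled centreline, exact flux", {
  expect_equal(radial_velocity(1.25, 50, 1.25), 0)
  expect_equal(radial_velocity(0, 50, 1.25), 2 * mean_velocity(50, 1.25))
  expect_error(radial_velocity(1.3, 50, 1.25), "must lie in")
  # discretised flux through the section recovers Q (relative < 1e-3)
  gr <- simulation_grid()
  r <- seq(gr$radial_step / 2, 1.25, by = gr$radial_step)
  flux_mm3_s <- sum(radial_velocity(r, 50, 1.25) * 2 * pi * r *
                      gr$radial_step)
  expect_equal(flux_mm3_s, 50 * 1000 / 3600, tolerance = 1e-3)
})

test_that("front distance accumulates phase by phase", {
  expect_equal(front_distance(1.25, 23), 0) # wall fluid never moves
  expect_equal(front_distance(0, 10), 2 * mean_velocity(50, 1.25) * 600)
  # additivity across a phase boundary
  v2 <- radial_velocity(0.5, 100, 1.25) * 60 # mm/min
  expect_equal(front_distance(0.5, 17),
               front_distance(0.5, 10) + v2 * 7)
  # monotone: nondecreasing in t, nonincreasing in r
  tg <- seq(0, 40, by = 1)
  expect_true(all(diff(front_distance(0.3, tg)) >= 0))
  rg <- seq(0, 1.25, by = 0.05)
  expect_true(all(diff(front_distance(rg, 25)) <= 0))
  expect_error(front_distance(-0.1, 5), "must lie in")
})

test_that("transit delay reproduces the piecewise phase cases", {
  p <- default_protocol
  g <- default_geometry
  expect_equal(time_delay(0, 0.4, 17), 0)
  # within phase 1 the delay is simply s / v1(r)
  v1 <- radial_velocity(0.4, 50, 1.25) * 60
  expect_equal(time_delay(30, 0.4, 8), 300 / v1)
  # phase 2, parcel entirely advected at v2
  v2 <- radial_velocity(0.4, 100, 1.25) * 60
  expect_equal(time_delay(10, 0.4, 15), 100 / v2)
  # phase 2, parcel straddling the rate change
  d2 <- v2 * 5 # distance covered since T1 at t = 15
  s_mm <- d2 + 200
  expect_equal(time_delay(s_mm / 10, 0.4, 15), 5 + 200 / v1)
  # stationary wall fluid: infinite delay, signalled as Inf
  expect_identical(time_delay(10, 1.25, 15), Inf)
  expect_error(time_delay(-1, 0.4, 15), ">= 0")
})

test_that("transit delay is self-consistent with the travelled distance", {
  # brute-force backward integration: a parcel at radius 0.6 R observed at
  # (s = 115 cm, t = 25 min) must have covered exactly s during the delay
  r <- 0.6 * 1.25
  t <- 25
  d <- time_delay(115, r, t)
  step <- 1e-4
  tt <- seq(t - d + step / 2, t, by = step)
  phase <- 1 + findInterval(tt, c(10, 20), left.open = TRUE)
  v <- radial_velocity(r, c(50, 100, 200)[phase], 1.25) * 60
  expect_equal(sum(v) * step, 1150, tolerance = 1e-3)
})

test_that("segment activity respects the advancing front", {
  gr <- test_grid()
  expect_equal(segment_activity(0, 0, 145, grid = gr), 0)
  # fastest parcel is at 34 cm after 1 min: nothing beyond 50 cm yet
  expect_equal(segment_activity(1, 50, 115, grid = gr), 0)
  expect_gt(segment_activity(1, 0, 50, grid = gr), 0)
  expect_error(segment_activity(5, 120, 100, grid = gr), "window")
  expect_error(segment_activity(5, 0, 200, grid = gr), "window")
})

test_that("plug-flow transport matches the closed-form piston solution", {
  gr <- simulation_grid(axial_step = 1, radial_step = 0.025)
  for (tt in c(15, 30)) {
    num <- segment_activity(tt, 0, 115, grid = gr, profile = "plug")
    expect_equal(num, plug_flow_oracle(tt, 0, 115), tolerance = 0.01)
  }
})

test_that("simulation conserves activity and fills the patient monotonically", {
  gr <- test_grid()
  sim <- simulate_infusion(grid = gr)
  expect_s3_class(sim, "infusion_sim")
  expect_equal(nrow(sim), 41)
  total <- sim$vial_MBq + sim$tubing_MBq + sim$vein_MBq + sim$patient_MBq
  expect_true(all(abs(total - 7232) / 7232 < 5e-3))
  expect_true(all(sim$vein_MBq >= 0))
  expect_true(all(sim$tubing_MBq >= 0))
  # patient is a quadrature remainder: at the coarse test grid the front
  # smears over one 5 mm axial bin (~1 MBq); dips stay at the 1e-4 level
  expect_true(all(diff(sim$patient_MBq) > -2))
  expect_gt(min(sim$patient_MBq), -2)
  # the line starts activity-free
  expect_equal(sim$tubing_MBq[1], 0)
  expect_equal(sim$vein_MBq[1], 0)
})

test_that("transport quadrature is grid-converged at the default steps", {
  coarse <- simulation_grid(axial_step = 2, radial_step = 0.0125)
  fine <- simulation_grid(axial_step = 1, radial_step = 0.00625)
  for (tt in c(5, 15, 40)) {
    a1 <- segment_activity(tt, 0, 145, grid = coarse)
    a2 <- segment_activity(tt, 0, 145, grid = fine)
    expect_equal(a1, a2, tolerance = 0.01)
  }
})
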