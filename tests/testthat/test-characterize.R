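test_that("characterize inverts its own forward model", {
  gr <- test_grid()
  scn <- extravasation_scenario(15, 3)
  e <- extravasation_edr(25, scn, grid = gr) # uSv/h
  res <- characterize(25, e / 1000, 3, grid = gr)
  expect_s3_class(res, "characterization")
  expect_equal(nrow(res$solutions), 1)
  sol <- res$solutions[1, ]
  expect_equal(sol$activity_MBq, extravasated_activity(25, 15, grid = gr),
               tolerance = 0.02)
  expect_equal(sol$volume_mL, extravasated_volume(25, 15), tolerance = 0.02)
  expect_equal(sol$concentration_MBq_mL,
               extravasated_concentration(25, 15, grid = gr),
               tolerance = 0.02)
  # every reported solution reproduces the measured EDR
  expect_true(all(sol$edr_residual_rel < 1e-3))
})

test_that("unreachable readings yield an explicit no-solution result", {
  gr <- test_grid()
  res <- characterize(20, 1e6, 2, grid = gr)
  expect_equal(nrow(res$solutions), 0)
  expect_true(is.na(res$precautionary))
  expect_output(print(res), "no onset")
  expect_error(characterize(0, 3, 2, grid = gr), "must lie in")
  expect_error(characterize(20, -3, 2, grid = gr), "positive")
})

test_that("early-onset multiplicity is returned with a precautionary flag", {
  gr <- test_grid()
  # at early measurement times a level can be produced both by a recent
  # concentrated pool and by an older saline-diluted one
  res <- characterize(6, 3, 2, grid = gr)
  expect_gt(nrow(res$solutions), 1)
  expect_equal(res$precautionary,
               which.max(res$solutions$concentration_MBq_mL))
  expect_true(all(res$solutions$edr_residual_rel < 1e-3))
})

test_that("abacus rows re-evaluate to their level and order by aspect ratio", {
  gr <- test_grid()
  ab <- build_abacus(levels = c(2, 4), aspect_ratios = c(2, 3, 5),
                     grid = gr)
  expect_s3_class(ab, "abacus_table")
  expect_setequal(unique(ab$edr_mSv_h), c(2, 4))
  expect_setequal(unique(ab$aspect_ratio), c(2, 3, 5))
  expect_equal(ab$concentration_MBq_mL, ab$activity_MBq / ab$volume_mL)
  # spot-check rows against the direct forward model
  idx <- seq(1, nrow(ab), length.out = 12)
  for (i in unique(round(idx))) {
    row <- ab[i, ]
    e <- extravasation_edr(row$t_min,
                           extravasation_scenario(row$tE_min,
                                                  row$aspect_ratio),
                           grid = gr)
    expect_equal(e / 1000, row$edr_mSv_h, tolerance = 2e-3)
  }
  # precautionary band structure: at fixed (level, t) the AR = 2 reading
  # is explained by the smallest pool (least volume and activity)
  sub <- ab[ab$edr_mSv_h == 2 & ab$t_min == 20, ]
  vol <- vapply(split(sub, sub$aspect_ratio),
                function(d) min(d$volume_mL), numeric(1))
  act <- vapply(split(sub, sub$aspect_ratio),
                function(d) min(d$activity_MBq), numeric(1))
  expect_equal(names(which.min(vol)), "2")
  expect_equal(names(which.min(act)), "2")
  # determinism: identical configuration, identical table
  ab2 <- build_abacus(levels = c(2, 4), aspect_ratios = c(2, 3, 5),
                      grid = gr)
  expect_identical(ab, ab2)
})

test_that("alarm screening uses a strict two-sample debounce", {
  s <- monitoring_series(seq(0, 10, by = 2),
                         c(0, 900, 1200, 900, 1200, 1100))
  d <- detect(s, threshold = 1)
  expect_true(d$alarm)
  expect_equal(d$alarm_time, 8) # first pair of consecutive exceedances
  # single-sample spikes do not trigger
  s2 <- monitoring_series(seq(0, 8, by = 2), c(0, 1500, 900, 1500, 900))
  expect_false(detect(s2)$alarm)
  # exactly at the threshold never triggers (strict exceedance)
  s3 <- monitoring_series(seq(0, 8, by = 2), rep(1000, 5))
  expect_false(detect(s3)$alarm)
  expect_error(detect(s3[0, ]), "non-empty")
  expect_error(monitoring_series(c(0, 0, 2), c(1, 2, 3)),
               "strictly increasing")
  expect_error(monitoring_series(c(0, 2), c(-1, 2)), ">= 0")
})

test_that("monitoring synthesis is deterministic and calibrated in noise", {
  gr <- test_grid()
  # no scenario, no noise: exactly the model curve at the sample times
  clean <- synthesize_monitoring(NULL, grid = gr, noise_fraction = 0)
  expect_equal(clean$time_min, seq(0, 40, by = 2))
  expect_equal(clean$edr_uSv_h, infusion_edr(clean$time_min, grid = gr))
  # a nonextravasated infusion never approaches the 1 mSv/h threshold
  expect_false(detect(clean)$alarm)
  expect_lt(max(clean$edr_uSv_h), 500)
  # an extravasated scenario alarms after onset, before the end
  scn <- extravasation_scenario(8, 2)
  ser <- synthesize_monitoring(scn, grid = gr, noise_fraction = 0)
  d <- detect(ser)
  expect_true(d$alarm)
  expect_gt(d$alarm_time, 8)
  expect_lt(d$alarm_time, 40)
  # determinism under a fixed seed
  a <- synthesize_monitoring(scn, grid = gr, noise_fraction = 0.2, seed = 11)
  b <- synthesize_monitoring(scn, grid = gr, noise_fraction = 0.2, seed = 11)
  expect_identical(a, b)
  expect_false(identical(
    a,
    synthesize_monitoring(scn, grid = gr, noise_fraction = 0.2, seed = 12)
  ))
  expect_error(synthesize_monitoring(NULL, grid = gr, noise_fraction = -1),
               ">= 0")
  expect_error(synthesize_monitoring(NULL, grid = gr, sampling = 0.5),
               "time grid step")
})

test_that("multiplicative noise has the requested relative spread", {
  gr <- test_grid()
  scn <- extravasation_scenario(8, 2)
  reps <- vapply(1:400, function(i) {
    synthesize_monitoring(scn, grid = gr, noise_fraction = 0.2,
                          sampling = 8, seed = i)$edr_uSv_h
  }, numeric(6))
  # at samples with a strong clean signal, sd/mean ~ noise fraction
  late <- 3:6 # t >= 16 min, well after onset
  ratio <- apply(reps[late, ], 1, stats::sd) / rowMeans(reps[late, ])
  expect_true(all(abs(ratio - 0.2) < 0.035))
})
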