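test_that("correction factor follows its closed form and declared units", {
  m0 <- cf_model("spring", a = 0, b = 0)
  expect_equal(correction_factor(c(10, 25, 47), m0), c(1, 1, 1))

  pub <- published_cf_models()
  # spring model at T = 1 in the model's own time unit
  expect_equal(correction_factor(1, pub$spring, units = "model"),
               exp(-0.94 + 2.36), tolerance = 1e-12)
  expect_equal(round(correction_factor(1, pub$spring, units = "model"), 4),
               4.1371)
  # with the per-47-h unit, T = 47 h is one model unit
  expect_equal(correction_factor(47, pub$spring),
               correction_factor(1, pub$spring, units = "model"))
  expect_equal(pub$fall$a, -1.10)
  expect_equal(pub$fall$b, 2.42)

  # monotone increasing in T for b > 0, and CF >= 0 always
  Ts <- seq(10, 50, 5)
  cf <- correction_factor(Ts, pub$fall)
  expect_true(all(diff(cf) > 0))
  expect_true(all(cf > 0))

  expect_error(correction_factor(0, pub$spring), "positive")
  expect_error(correction_factor(-5, pub$spring), "positive")
})

test_that("corrected distances never fall below observed distances", {
  fx <- make_crw(100, seed = 5)
  # knock out fixes to create mixed intervals
  fx <- fx[-c(5, 6, 20, 40, 41, 42), ]
  st <- corrected_steps(fx, published_cf_models()$spring)
  expect_true(all(st$corrected_m >= st$dist_m))
  # base-interval steps are left uncorrected
  expect_true(all(st$corrected_m[st$gap_h <= 5.1] ==
                  st$dist_m[st$gap_h <= 5.1]))
})

test_that("calibration measures shortfall exactly and fits the log-linear model", {
  trajs <- lapply(1:20, function(i) make_crw(150, seed = i))
  model <- calibrate_correction(trajs, season = "fall")
  tab <- attr(model, "calibration")
  expect_equal(tab$gap_h, seq(10, 50, 5))

  # independent brute-force oracle for the per-gap mean shortfall
  for (Tg in c(10, 30, 50)) {
    m <- Tg / 5
    sf <- c()
    for (tr in trajs) {
      n <- nrow(tr)
      for (s in seq(1, n - m, by = m)) {
        path <- 0
        for (k in s:(s + m - 1))
          path <- path + sqrt((tr$x[k + 1] - tr$x[k])^2 +
                              (tr$y[k + 1] - tr$y[k])^2)
        chord <- sqrt((tr$x[s + m] - tr$x[s])^2 + (tr$y[s + m] - tr$y[s])^2)
        sf <- c(sf, path - chord)
      }
    }
    expect_equal(tab$mean_shortfall_m[tab$gap_h == Tg], mean(sf),
                 tolerance = 1e-10)
  }

  # the fitted coefficients equal an independent re-fit of the same table
  fit <- stats::lm(log(tab$mean_shortfall_m) ~ I(tab$gap_h / 47))
  expect_equal(unname(model$a), unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(unname(model$b), unname(coef(fit)[2]), tolerance = 1e-10)
  expect_true(all(is.finite(model$se)))

  # held-out prediction: right order of magnitude at every gap (the
  # exponential family is an approximation, not the walk's true shortfall law)
  held <- lapply(21:40, function(i) make_crw(150, seed = i))
  htab <- migroutes:::shortfall_table(held, seq(10, 50, 5), 5)
  pred <- correction_factor(htab$gap_h, model)
  expect_true(all(pred / htab$mean_shortfall_m > 0.5 &
                  pred / htab$mean_shortfall_m < 2))
})

test_that("straight tracks make calibration degenerate", {
  trs <- lapply(1:3, function(i)
    make_straight_track(n = 200, dt_h = 5, speed_kmh = 1, id = paste0("S", i)))
  expect_error(calibrate_correction(trs), "degenerate")
})

test_that("migration summary reports durations, velocities and CIs", {
  iv <- rbind(
    data.frame(animal_id = "A", label = "spring_migration",
               t_start = utc("2003-05-01"), t_end = utc("2003-05-13"),
               migratory = TRUE),
    data.frame(animal_id = "A", label = "fall_migration",
               t_start = utc("2003-09-15"), t_end = utc("2003-09-24"),
               migratory = TRUE))
  iv <- rbind(iv,
    data.frame(animal_id = "B", label = "spring_migration",
               t_start = utc("2003-05-02"), t_end = utc("2003-05-12"),
               migratory = TRUE))
  fx <- rbind(make_straight_track(n = 80, dt_h = 5, speed_kmh = 0.8,
                                  start = utc("2003-05-01"), id = "A"),
              make_straight_track(n = 60, dt_h = 5, speed_kmh = 1.2,
                                  start = utc("2003-09-15"), id = "A"),
              make_straight_track(n = 60, dt_h = 5, speed_kmh = 1.0,
                                  start = utc("2003-05-02"), id = "B"))
  res <- migration_summary(iv, fx)
  expect_equal(res$paths$duration_days[res$paths$season == "spring"], c(12, 10))
  expect_equal(res$paths$duration_days[res$paths$season == "fall"], 9)
  # straight 0.8 and 1.0 km/h tracks: 4000 and 5000 m per 5 h, uncorrected
  expect_equal(res$paths$mean_velocity_m_per_5h[res$paths$season == "spring"],
               c(4000, 5000))
  expect_identical(names(res$summary),
                   c("parameter", "season", "n", "estimate", "sd",
                     "lower", "upper"))
  sp <- res$summary[res$summary$season == "spring", ]
  expect_true(all(sp$lower <= sp$estimate & sp$estimate <= sp$upper))
  expect_equal(sp$estimate[sp$parameter == "Duration (days)"], 11)

  # intervals with fewer than 2 fixes are excluded with a warning
  iv2 <- rbind(iv, data.frame(animal_id = "B", label = "fall_migration",
                              t_start = utc("2003-09-15"),
                              t_end = utc("2003-09-16"), migratory = TRUE))
  expect_warning(migration_summary(iv2, fx), "excluded")
})

test_that("simulated fall migrations are shorter than spring migrations", {
  cfg <- sim_config(n_animals = 8, n_years = 1, seed = 44)
  trs <- simulate_population(cfg)
  iv <- do.call(rbind, lapply(trs, function(tr) tr$intervals))
  fx <- bind_fixes(trs)
  res <- migration_summary(iv, fx)
  dur <- res$summary[res$summary$parameter == "Duration (days)", ]
  expect_lt(dur$estimate[dur$season == "fall"],
            dur$estimate[dur$season == "spring"])
})
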