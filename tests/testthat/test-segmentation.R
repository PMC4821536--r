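test_that("calving confinement is detected and sized by the MCP oracle", {
  set.seed(41)
  # 12 days of confinement in a 300-m disc starting June 3, summer cadence
  t <- utc("2003-06-01") + (0:(20 * 24 / 5)) * 5 * 3600
  conf <- t >= utc("2003-06-03") & t <= utc("2003-06-15")
  n <- length(t)
  r <- 300 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  x <- ifelse(conf, r * sin(th), (as.numeric(t) - min(as.numeric(t))) / 86400 * 5000)
  y <- ifelse(conf, r * cos(th), x)
  fx <- data.frame(animal_id = "A", t = t, x = x, y = y)
  det <- detect_calving(fx, seg_config())
  expect_false(is.null(det))
  w <- fx$t >= det$t_start & fx$t <= det$t_end
  a <- mcp_area_km2(fx$x[w], fx$y[w])
  expect_lt(a, 1.5)
  expect_lte(a, pi * 0.3^2 * 1.1)   # disc of radius 300 m
  expect_gte(as.numeric(det$t_end - det$t_start, units = "days"), 10)

  # a track moving 5 km/day throughout June confines nowhere
  mv <- make_straight_track(n = 150, dt_h = 5, speed_kmh = 5 / 24,
                            start = utc("2003-06-01"))
  expect_null(detect_calving(mv, seg_config()))
})

test_that("spring migration detection recovers simulated ground truth", {
  cfg <- sim_config(n_animals = 10, n_years = 1, seed = 11)
  trs <- simulate_population(cfg)
  sc <- seg_config()
  jac <- vapply(trs, function(tr) {
    calv <- detect_calving(tr$fixes, sc)
    sp <- detect_spring_migration(tr$fixes, sc, calving = calv)
    temporal_jaccard(sp, tr$intervals[tr$intervals$label == "spring_migration", ])
  }, 0)
  expect_true(all(jac >= 0.8))

  # detected mean start in a population with default timing is late Apr-mid May
  starts <- vapply(trs, function(tr) {
    sp <- detect_spring_migration(tr$fixes, sc,
                                  calving = detect_calving(tr$fixes, sc))
    migroutes:::doy_frac(sp$t_start)
  }, 0)
  expect_true(mean(starts) >= 118 && mean(starts) <= 140)   # Apr 28 - May 20

  # a stationary year-round track yields no migration
  cfgn <- sim_config(n_animals = 1, n_years = 1, nonmigratory_fraction = 1,
                     seed = 13)
  trn <- simulate_annual_track(cfgn, "A001", 2003)
  expect_null(detect_spring_migration(trn$fixes, sc))
})

test_that("fall migration starts outside the summer 80% isopleth", {
  cfg <- sim_config(n_animals = 6, n_years = 1, seed = 14)
  trs <- simulate_population(cfg)
  sc <- seg_config()
  # pooled summer range from ground-truth summer fixes
  sfx <- do.call(rbind, lapply(trs, function(tr)
    tr$fixes[tr$fixes$label == "summer", c("animal_id", "t", "x", "y")]))
  rng <- pooled_seasonal_range(sfx, levels = c(0.8, 0.9))
  iso80 <- rng$isopleths[["80"]]

  for (tr in trs[1:3]) {
    det <- detect_fall_migration(tr$fixes, iso80, sc)
    expect_false(is.null(det))
    start_fix <- tr$fixes[tr$fixes$t == det$t_start, ]
    expect_false(point_in_isopleth(iso80, start_fix$x, start_fix$y))
    truth <- tr$intervals[tr$intervals$label == "fall_migration", ]
    expect_gte(temporal_jaccard(det, truth), 0.8)
  }

  # missing isopleth is an instructive error
  expect_error(detect_fall_migration(trs[[1]]$fixes, NULL, sc),
               "pooled_seasonal_range")

  # a resident that never leaves the 80% polygon has no fall migration
  res <- trs[[1]]$fixes[trs[[1]]$fixes$label == "summer", ]
  expect_null(detect_fall_migration(res, iso80, sc))
})

test_that("season assembly is canonical, contiguous and validated", {
  cfg <- sim_config(n_animals = 1, n_years = 1, seed = 15)
  tr <- simulate_annual_track(cfg, "A001", 2003)
  sc <- seg_config()
  calv <- detect_calving(tr$fixes, sc)
  sp <- detect_spring_migration(tr$fixes, sc, calving = calv)
  sfx <- tr$fixes[tr$fixes$label == "summer", ]
  rng <- suppressWarnings(pooled_seasonal_range(sfx, levels = 0.8))
  fall <- detect_fall_migration(tr$fixes, rng$isopleths[["80"]], sc)
  iv <- assemble_seasons(tr$fixes, spring = sp, calving = calv, fall = fall)
  expect_identical(iv$label, c("winter", "spring_migration", "calving",
                               "summer", "fall_migration", "winter"))
  expect_true(all(iv$t_start < iv$t_end))
  expect_true(all(as.numeric(iv$t_end[-nrow(iv)]) <=
                  as.numeric(iv$t_start[-1]) + 1))
  expect_gte(label_agreement(tr, iv), 0.9)

  # without a detected calving, summer begins at the population mean date
  pce <- utc("2003-06-16")
  iv2 <- assemble_seasons(tr$fixes, spring = sp, calving = NULL, fall = fall,
                          pop_calving_end = pce)
  expect_equal(iv2$t_start[iv2$label == "summer"], pce)

  # contradictory detections error
  bad_fall <- fall; bad_fall$t_start <- sp$t_start - 86400 * 30
  expect_error(assemble_seasons(tr$fixes, spring = sp, fall = bad_fall),
               "contradictory")
})

test_that("migratory tabulation reproduces printed integer percents", {
  # counts from a published herd monitoring table, expanded to one row per
  # animal-season
  counts <- rbind(
    data.frame(year = c(2003, 2004, 2005, 2006), season = "fall",
               n_mig = c(18, 27, 23, 20), n_non = c(5, 18, 7, 9)),
    data.frame(year = c(2003, 2004, 2005, 2006), season = "spring",
               n_mig = c(19, 41, 23, 23), n_non = c(4, 6, 10, 5)))
  cls <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], data.frame(
      year = year, season = season,
      migratory = rep(c(TRUE, FALSE), c(n_mig, n_non))))
  }))
  tab <- tabulate_migratory(cls)
  get <- function(season, year, col)
    tab[tab$season == season & tab$year == year, col]
  expect_equal(get("fall", "Total", "pct_migratory"), 69)
  expect_equal(get("spring", "Total", "pct_migratory"), 81)
  expect_equal(get("fall", "2003", "pct_migratory"), 78)
  expect_equal(get("fall", "Total", "n_migratory"), 88)
  expect_equal(get("spring", "Total", "total"), 131)
  expect_equal(tab$pct_migratory[tab$season == "fall" & tab$year != "Total"],
               c(78, 60, 77, 69))
  expect_equal(tab$pct_migratory[tab$season == "spring" & tab$year != "Total"],
               c(83, 87, 70, 82))
})
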