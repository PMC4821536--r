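# Synthetic multi-animal, multi-year GPS trajectories with known ground-truth
# season labels, emulating an arctic caribou collar deployment: winter
# residency in the south, a northward spring migration ending at a calving
# site, a 10-14 day calving confinement in early June, summer residency on the
# northern range, and a southward fall migration in autumn. Fixes follow a
# seasonal schedule (5 h May-Oct, 47 h Nov-Apr), fail independently at a small
# rate, and carry isotropic GPS error.

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. Coordinates are metres
#' in a planar equal-area projection (EPSG:3338-like); no geographic
#' conversion happens inside the simulator.
#'
#' @param n_animals,n_years Number of collared animals and monitored years.
#' @param start_year First calendar year simulated.
#' @param winter_centroid,summer_centroid Population range centres (m). The
#'   default separation is 250 km along the north-south axis.
#' @param spring_start_day Mean day-of-year on which spring migration begins
#'   (default 134, mid May); `spring_start_sd` is its between-animal-year SD in
#'   days. Spring timing may be adjusted per draw so the implied travel speed
#'   stays inside `migration_speed` and arrival precedes calving onset.
#' @param fall_start_day,fall_start_sd Fall migration onset day-of-year
#'   (default 259, mid September) and jitter SD.
#' @param migration_speed Allowed range of daily displacement during spring
#'   migration, km/day.
#' @param fall_speed Range of daily displacement during fall migration, km/day.
#'   Fall defaults are faster than spring so fall migrations are shorter and
#'   more direct.
#' @param calving_duration Range (days) of the post-arrival calving
#'   confinement.
#' @param calving_radius Radius (m) of the confinement disc; the default 300 m
#'   keeps the occupied area well below 1.5 km^2.
#' @param residency_sd Stationary SD (m) of the within-range mean-reverting
#'   walk used for winter and summer residency.
#' @param residency_tau_h Correlation time (h) of the residency walk.
#' @param migration_noise Perpendicular/along-track noise of the migration
#'   walk, metres per sqrt(day).
#' @param animal_centroid_sd SD (m) of per-animal offsets of seasonal range
#'   centres (constant across years for an animal).
#' @param winter_shift_sd,summer_shift_sd SD (m) of population-level annual
#'   shifts of the winter and summer centroids. Winter defaults are larger,
#'   giving lower between-year winter fidelity than summer fidelity.
#' @param fix_interval_summer_h,fix_interval_winter_h Fix schedule: interval in
#'   hours during May-October and November-April respectively.
#' @param fix_failure_rate Probability that a scheduled fix fails.
#' @param gps_error_sd SD (m) of isotropic location error added to each fix.
#' @param nonmigratory_fraction Fraction of animals generated as residents
#'   with a single year-round range and no migration or calving labels.
#' @param seed Integer seed; identical configurations give identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 25, n_years = 4, start_year = 2003,
                       winter_centroid = c(0, 0),
                       summer_centroid = c(0, 250000),
                       spring_start_day = 134, spring_start_sd = 4,
                       fall_start_day = 259, fall_start_sd = 5,
                       migration_speed = c(7, 24),
                       fall_speed = c(15, 24),
                       calving_duration = c(10, 14),
                       calving_radius = 300,
                       residency_sd = 5000,
                       residency_tau_h = 72,
                       migration_noise = 1500,
                       animal_centroid_sd = 10000,
                       winter_shift_sd = 15000,
                       summer_shift_sd = 2000,
                       fix_interval_summer_h = 5,
                       fix_interval_winter_h = 47,
                       fix_failure_rate = 0.02,
                       gps_error_sd = 30,
                       nonmigratory_fraction = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (fix_failure_rate < 0 || fix_failure_rate > 1)
    stopf("fix_failure_rate must be in [0, 1]")
  if (nonmigratory_fraction < 0 || nonmigratory_fraction > 1)
    stopf("nonmigratory_fraction must be in [0, 1]")
  if (fix_interval_summer_h <= 0 || fix_interval_winter_h <= 0)
    stopf("fix intervals must be positive")
  if (all(winter_centroid == summer_centroid))
    stopf("winter and summer centroids must be distinct")
  if (any(migration_speed <= 0) || migration_speed[1] > migration_speed[2])
    stopf("migration_speed must be an increasing positive range")
  if (any(calving_duration < 1) || calving_duration[1] > calving_duration[2])
    stopf("calving_duration must be an increasing range of days >= 1")
  dist_km <- dist_m(winter_centroid[1], winter_centroid[2],
                    summer_centroid[1], summer_centroid[2]) / 1000
  # Calving onset is drawn in early June (day 152-155) and must be reachable:
  # even at top speed the migration may not still be under way at the latest
  # permissible onset (day 165, June 14).
  if (spring_start_day + dist_km / migration_speed[2] > 165)
    stopf(paste("invalid config: spring migration would overlap calving",
                "(start day %g + %.0f km at %g km/day ends after June 14)"),
          spring_start_day, dist_km, migration_speed[2])
  if (fall_start_day - 3 * fall_start_sd < 180)
    stopf("invalid config: fall migration would overlap calving/summer onset")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Fix schedule for one calendar year: 5-h cadence May-Oct, 47-h Nov-Apr,
# starting at Jan 1 00:00 UTC. Returns POSIXct times.
fix_schedule <- function(year, summer_h, winter_h) {
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year + 1), tz = "UTC")
  out <- numeric(0)
  t <- as.numeric(t0)
  end <- as.numeric(t1)
  while (t < end) {
    out[length(out) + 1] <- t
    mon <- as.POSIXlt(t, tz = "UTC", origin = "1970-01-01")$mon + 1
    t <- t + (if (mon %in% 5:10) summer_h else winter_h) * 3600
  }
  as.POSIXct(out, tz = "UTC", origin = "1970-01-01")
}

# Exact discrete-time mean-reverting (OU) update over a step of dt hours.
ou_step <- function(pos, mu, dt_h, sd, tau_h) {
  phi <- exp(-dt_h / tau_h)
  mu + (pos - mu) * phi + stats::rnorm(2, 0, sd * sqrt(1 - phi^2))
}

#' Simulate one animal-year trajectory with ground-truth labels
#'
#' Winter and summer are mean-reverting wander around the respective range
#' centre; migrations are biased walks toward the opposite centre at a daily
#' displacement inside the configured speed range; calving confines movement
#' to a small disc for the configured duration starting in early June. Fixes
#' are sampled on the seasonal schedule, dropped independently at the failure
#' rate, and perturbed by isotropic GPS error.
#'
#' @param config A [sim_config()].
#' @param animal_id Animal identifier (character); per-animal properties
#'   (range offsets, migratory status) are derived deterministically from it.
#' @param year Calendar year to simulate.
#' @return An object of class `labeled_trajectory`: a list with `fixes`
#'   (data.frame: animal_id, t, x, y, label), `intervals` (ground-truth season
#'   intervals), `animal_id`, `year` and `migratory`.
#' @export
simulate_annual_track <- function(config, animal_id, year) {
  stopifnot(inherits(config, "sim_config"))
  a_seed <- derive_seed(config$seed, id_hash(animal_id))
  y_seed <- derive_seed(config$seed, 999983, year)
  ay_seed <- derive_seed(config$seed, id_hash(animal_id), year)

  animal <- with_seed(a_seed, list(
    dw = stats::rnorm(2, 0, config$animal_centroid_sd),
    ds = stats::rnorm(2, 0, config$animal_centroid_sd),
    migratory = stats::runif(1) >= config$nonmigratory_fraction
  ))
  yr <- with_seed(y_seed, list(
    shift_w = stats::rnorm(2, 0, config$winter_shift_sd),
    shift_s = stats::rnorm(2, 0, config$summer_shift_sd)
  ))
  W <- config$winter_centroid + animal$dw + yr$shift_w
  S <- config$summer_centroid + animal$ds + yr$shift_s

  times <- fix_schedule(year, config$fix_interval_summer_h,
                        config$fix_interval_winter_h)
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  td <- as.numeric(times - t0, units = "days")  # days since Jan 1 00:00
  n <- length(times)

  res <- with_seed(ay_seed, {
    if (animal$migratory) {
      dist_km <- dist_m(W[1], W[2], S[1], S[2]) / 1000
      onset <- stats::runif(1, 152, 155) - 1         # calving onset, days
      settle <- stats::runif(1, 0.5, 1.5)            # arrival -> onset, days
      sp_start <- stats::rnorm(1, config$spring_start_day, config$spring_start_sd) - 1
      implied <- dist_km / (onset - settle - sp_start)
      speed_sp <- min(max(implied, config$migration_speed[1]),
                      config$migration_speed[2])
      sp_start <- onset - settle - dist_km / speed_sp
      arrive <- onset - settle
      cal_dur <- stats::runif(1, config$calving_duration[1],
                              config$calving_duration[2])
      cal_end <- onset + cal_dur
      fa_start <- stats::rnorm(1, config$fall_start_day, config$fall_start_sd) - 1
      speed_fa <- stats::runif(1, config$fall_speed[1], config$fall_speed[2])
      fa_end <- fa_start + dist_km / speed_fa
      csite <- S + stats::rnorm(2, 0, 3000)

      phase <- function(d) {
        if (d < sp_start) "winter"
        else if (d < onset) "spring_migration"
        else if (d < cal_end) "calving"
        else if (d < fa_start) "summer"
        else if (d < fa_end) "fall_migration"
        else "winter"
      }
      pos <- W + stats::rnorm(2, 0, config$residency_sd)
      xs <- ys <- numeric(n)
      for (i in seq_len(n)) {
        d <- td[i]
        dt_h <- if (i == 1) 0 else (td[i] - td[i - 1]) * 24
        if (dt_h > 0) {
          ph <- phase(d)
          if (ph == "winter") {
            pos <- ou_step(pos, W, dt_h, config$residency_sd, config$residency_tau_h)
          } else if (ph == "spring_migration") {
            if (d < arrive) {
              rem_h <- (arrive - td[i - 1]) * 24
              f <- min(1, dt_h / rem_h)
              pos <- pos + (csite - pos) * f +
                stats::rnorm(2, 0, config$migration_noise * sqrt(dt_h / 24))
            } else {
              pos <- ou_step(pos, csite, dt_h, 600, 12)
            }
          } else if (ph == "calving") {
            r <- config$calving_radius * sqrt(stats::runif(1))
            th <- stats::runif(1, 0, 2 * pi)
            pos <- csite + r * c(sin(th), cos(th))
          } else if (ph == "summer") {
            pos <- ou_step(pos, S, dt_h, config$residency_sd, config$residency_tau_h)
          } else if (ph == "fall_migration") {
            rem_h <- (fa_end - td[i - 1]) * 24
            f <- min(1, dt_h / rem_h)
            pos <- pos + (W - pos) * f +
              stats::rnorm(2, 0, config$migration_noise * sqrt(dt_h / 24))
          }
        }
        xs[i] <- pos[1]; ys[i] <- pos[2]
      }
      labels <- vapply(td, phase, "")
      ivd <- function(lab, a, b) data.frame(
        animal_id = animal_id, label = lab,
        t_start = t0 + a * 86400, t_end = t0 + b * 86400,
        migratory = lab %in% c("spring_migration", "fall_migration"),
        stringsAsFactors = FALSE)
      intervals <- rbind(
        ivd("winter", 0, sp_start),
        ivd("spring_migration", sp_start, onset),
        ivd("calving", onset, cal_end),
        ivd("summer", cal_end, fa_start),
        ivd("fall_migration", fa_start, fa_end),
        ivd("winter", fa_end, 365))
      list(xs = xs, ys = ys, labels = labels, intervals = intervals)
    } else {
      # Resident: single year-round range between the two seasonal centres.
      H <- (W + S) / 2
      pos <- H + stats::rnorm(2, 0, config$residency_sd)
      xs <- ys <- numeric(n)
      for (i in seq_len(n)) {
        dt_h <- if (i == 1) 0 else (td[i] - td[i - 1]) * 24
        if (dt_h > 0)
          pos <- ou_step(pos, H, dt_h, 1.5 * config$residency_sd,
                         config$residency_tau_h)
        xs[i] <- pos[1]; ys[i] <- pos[2]
      }
      b1 <- 152; b2 <- config$fall_start_day - 1
      labels <- ifelse(td < b1, "winter", ifelse(td < b2, "summer", "winter"))
      intervals <- data.frame(
        animal_id = animal_id,
        label = c("winter", "summer", "winter"),
        t_start = t0 + c(0, b1, b2) * 86400,
        t_end = t0 + c(b1, b2, 365) * 86400,
        migratory = FALSE, stringsAsFactors = FALSE)
      list(xs = xs, ys = ys, labels = labels, intervals = intervals)
    }
  })

  obs_seed <- derive_seed(ay_seed, 7)
  obs <- with_seed(obs_seed, {
    keep <- stats::runif(n) >= config$fix_failure_rate
    ex <- stats::rnorm(n, 0, config$gps_error_sd)
    ey <- stats::rnorm(n, 0, config$gps_error_sd)
    list(keep = keep, ex = ex, ey = ey)
  })

  fixes <- data.frame(
    animal_id = animal_id, t = times,
    x = res$xs + obs$ex, y = res$ys + obs$ey,
    label = res$labels, stringsAsFactors = FALSE)[obs$keep, ]
  rownames(fixes) <- NULL

  structure(list(fixes = fixes, intervals = res$intervals,
                 animal_id = animal_id, year = year,
                 migratory = animal$migratory),
            class = "labeled_trajectory")
}

#' Simulate a collared population over several years
#'
#' @param config A [sim_config()].
#' @return A list of [simulate_annual_track()] results, one per animal-year,
#'   named `<animal_id>_<year>`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sprintf("A%03d", seq_len(config$n_animals))
  years <- config$start_year + seq_len(config$n_years) - 1
  out <- list()
  for (id in ids) for (yr in years)
    out[[paste(id, yr, sep = "_")]] <- simulate_annual_track(config, id, yr)
  out
}

#' Combine trajectories into a single fix table
#'
#' @param trajs A list of `labeled_trajectory` objects.
#' @param labels Keep the ground-truth label column?
#' @return A data.frame with columns animal_id, t, x, y (and label).
#' @export
bind_fixes <- function(trajs, labels = FALSE) {
  if (inherits(trajs, "labeled_trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr) tr$fixes))
  rownames(df) <- NULL
  if (!labels) df$label <- NULL
  df
}

#' Inject gross outliers and movement spikes into a trajectory
#'
#' Creates the two error classes the screening filters remove: gross outliers
#' displaced >100 km laterally off the track, and single-point out-and-back
#' spikes whose implied leg speeds exceed 1.5 km/h. Spike displacements are
#' sized against the local fix interval so the implied speed criterion holds
#' by construction; spikes are only placed where both adjacent gaps are short
#' (<= 6 h), since a qualifying spike over a 47-h gap would be a gross outlier.
#'
#' @param traj A `labeled_trajectory` or a fix data.frame for one animal.
#' @param gross_rate,spike_rate Per-fix injection probabilities.
#' @param seed Seed for the injection draws.
#' @param n_gross,n_spike Optional exact counts, overriding the rates.
#' @return The input with modified coordinates and an `injected` element/
#'   attribute listing the affected row indices by class.
#' @export
inject_outliers <- function(traj, gross_rate = 0, spike_rate = 0, seed = 1,
                            n_gross = NULL, n_spike = NULL) {
  if (gross_rate < 0 || gross_rate > 1 || spike_rate < 0 || spike_rate > 1)
    stopf("injection rates must be in [0, 1]")
  is_traj <- inherits(traj, "labeled_trajectory")
  fixes <- if (is_traj) traj$fixes else traj
  n <- nrow(fixes)
  if ((gross_rate == 0 && spike_rate == 0 && is.null(n_gross) && is.null(n_spike))) {
    inj <- list(gross = integer(0), spike = integer(0))
  } else {
    inj <- with_seed(seed, {
      interior <- 2:(n - 1)
      ng <- if (!is.null(n_gross)) n_gross else stats::rbinom(1, n, gross_rate)
      gi <- if (ng > 0) sort(sample(interior, min(ng, length(interior)))) else integer(0)
      gaps_h <- diff(as.numeric(fixes$t)) / 3600
      short <- interior[gaps_h[interior - 1] <= 6 & gaps_h[interior] <= 6]
      short <- setdiff(short, c(gi - 1, gi, gi + 1))
      ns <- if (!is.null(n_spike)) n_spike else stats::rbinom(1, n, spike_rate)
      si <- integer(0)
      for (k in seq_len(ns)) {
        if (!length(short)) break
        pick <- sample(short, 1)
        si <- c(si, pick)
        short <- setdiff(short, c(pick - 1, pick, pick + 1))
      }
      si <- sort(si)
      for (i in gi) {
        mag <- stats::runif(1, 150000, 250000) * sample(c(-1, 1), 1)
        fixes$x[i] <- fixes$x[i] + mag
      }
      for (i in si) {
        dmax_h <- max(gaps_h[i - 1], gaps_h[i])
        d <- 1.5 * dmax_h * 1000 * 2       # twice the qualifying displacement
        th <- stats::runif(1, 0, 2 * pi)
        fixes$x[i] <- fixes$x[i] + d * sin(th)
        fixes$y[i] <- fixes$y[i] + d * cos(th)
      }
      list(gross = gi, spike = si, fixes = fixes)
    })
    fixes <- inj$fixes
    inj <- inj[c("gross", "spike")]
  }
  if (is_traj) {
    traj$fixes <- fixes
    traj$injected <- inj
    traj
  } else {
    attr(fixes, "injected") <- inj
    fixes
  }
}
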