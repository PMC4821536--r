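# Rule-based segmentation of an animal-year into winter, spring migration,
# calving, summer and fall migration. The field practice this replaces is
# visual interpretation of plotted trajectories; here the judgement is made
# explicit: migration starts when net displacement over a short window exceeds
# a trigger while heading along the migration axis, ends when displacement
# stays below the trigger for a quiescence period, and a candidate only counts
# as migration if it covers a substantial total distance. Calving is the
# earliest sustained confinement (rolling minimum-convex-polygon area below
# 1.5 km^2) with onset in early June.

#' Segmentation configuration
#'
#' @param window_days Directedness window over which net displacement and
#'   heading are measured (days).
#' @param min_net_displacement_km Migration trigger: net displacement over the
#'   window that marks directed movement.
#' @param heading_sector_deg Allowed deviation of the window heading from the
#'   migration axis.
#' @param end_quiescence_days Migration ends at the first time after which the
#'   rolling displacement stays below the trigger for this many days.
#' @param min_total_displacement_km A candidate migration must displace the
#'   animal by at least this much from start to end; shorter directed
#'   excursions are not migrations.
#' @param axis_deg Migration axis: heading (degrees from north) of spring
#'   migration; fall uses the opposite direction. Default 0 (due north).
#' @param calving_area_km2 Confinement threshold: rolling MCP area, km^2.
#' @param calving_min_days,calving_max_days Confinement duration bounds, days.
#' @param calving_search_doy Day-of-year window in which calving may begin
#'   (default June 1-14).
#' @param spring_search_doy,fall_search_doy Day-of-year windows in which the
#'   respective migration may begin.
#' @param fall_start_isopleth Level of the summer-range isopleth used to clip
#'   the start of the fall route (default 0.80).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(window_days = 4, min_net_displacement_km = 20,
                       heading_sector_deg = 60, end_quiescence_days = 5,
                       min_total_displacement_km = 50, axis_deg = 0,
                       calving_area_km2 = 1.5, calving_min_days = 10,
                       calving_max_days = 14,
                       calving_search_doy = c(152, 165),
                       spring_search_doy = c(60, 170),
                       fall_search_doy = c(213, 334),
                       fall_start_isopleth = 0.80) {
  cfg <- as.list(environment())
  if (any(c(window_days, min_net_displacement_km, end_quiescence_days,
            calving_area_km2, calving_min_days) <= 0))
    stopf("segmentation parameters must be positive")
  if (fall_start_isopleth <= 0 || fall_start_isopleth >= 1)
    stopf("fall_start_isopleth must be in (0, 1)")
  structure(cfg, class = "seg_config")
}

as_fixes <- function(traj) {
  if (inherits(traj, "labeled_trajectory")) traj$fixes else traj
}

# Confinement test for a window of fixes: MCP area below the threshold AND
# extent (diameter) no larger than a disc of that area, so that degenerate
# near-collinear travel (zero hull area) does not pass as confinement.
confined <- function(x, y, area_km2) {
  if (mcp_area_km2(x, y) >= area_km2) return(FALSE)
  h <- if (length(x) > 3) grDevices::chull(x, y) else seq_along(x)
  diam_km <- sqrt(max(outer(x[h], x[h], "-")^2 + outer(y[h], y[h], "-")^2)) / 1000
  diam_km <= 2 * sqrt(area_km2 / pi)
}

season_interval <- function(animal_id, label, t_start, t_end,
                            migratory = label %in% c("spring_migration",
                                                     "fall_migration")) {
  data.frame(animal_id = animal_id, label = label,
             t_start = t_start, t_end = t_end,
             migratory = migratory, stringsAsFactors = FALSE)
}

# Net displacement (km) and heading over a window of `window_days` centred on
# each fix. Centring keeps the onset/offset bias of threshold crossing
# symmetric and small (about half the time the window needs to fill with
# directed movement), unlike a forward- or backward-anchored window which
# shifts both boundaries by 1-3 days.
window_displacement <- function(fixes, window_days) {
  tt <- as.numeric(fixes$t)
  half <- window_days * 86400 / 2
  j0 <- findInterval(tt - half, tt) + 1L   # first fix inside the window
  j1 <- findInterval(tt + half, tt)        # last fix inside the window
  j0 <- pmin(j0, length(tt))
  dx <- fixes$x[j1] - fixes$x[j0]
  dy <- fixes$y[j1] - fixes$y[j0]
  list(D_km = sqrt(dx^2 + dy^2) / 1000, heading = heading_deg(dx, dy))
}

# Core directed-movement finder shared by the spring and fall detectors.
# Returns c(start_index, end_index) or NULL.
find_directed_move <- function(fixes, config, direction_deg, search_doy) {
  n <- nrow(fixes)
  if (n < 3) return(NULL)
  tt <- as.numeric(fixes$t)
  doy <- doy_frac(fixes$t)
  fd <- window_displacement(fixes, config$window_days)
  quiet <- fd$D_km < config$min_net_displacement_km
  # quiescent_from[j]: every fix in [t_j, t_j + quiescence] is quiet
  kend <- findInterval(tt + config$end_quiescence_days * 86400, tt)
  bad <- cumsum(!quiet)
  quiescent <- (bad[kend] - c(0, bad)[seq_len(n)]) == 0
  nxt <- rev(cummin(rev(ifelse(quiescent, seq_len(n), n + 1L))))
  cand <- which(doy >= search_doy[1] & doy <= search_doy[2] &
                fd$D_km >= config$min_net_displacement_km &
                ang_diff_deg(fd$heading, direction_deg) <= config$heading_sector_deg)
  for (k0 in cand) {
    j <- if (k0 + 1 <= n) nxt[k0 + 1] else n + 1L
    if (j > n) j <- n
    if (j <= k0) next
    total <- dist_m(fixes$x[k0], fixes$y[k0], fixes$x[j], fixes$y[j]) / 1000
    if (total >= config$min_total_displacement_km) return(c(k0, j))
  }
  NULL
}

#' Detect the calving confinement interval
#'
#' Finds the earliest interval of at least `calving_min_days` whose onset lies
#' in the calving search window and whose rolling occupied area (minimum
#' convex polygon of the fixes in the window) stays below
#' `calving_area_km2`. The interval is extended forward, up to
#' `calving_max_days`, while the cumulative MCP remains below the threshold.
#'
#' @param traj A `labeled_trajectory` or fix data.frame spanning early June.
#' @param config A [seg_config()].
#' @return A one-row season-interval data.frame, or NULL if no confinement.
#' @export
detect_calving <- function(traj, config = seg_config()) {
  fixes <- as_fixes(traj)
  tt <- as.numeric(fixes$t)
  doy <- doy_frac(fixes$t)
  cand <- which(doy >= config$calving_search_doy[1] &
                doy <= config$calving_search_doy[2])
  for (i in cand) {
    jmin <- findInterval(tt[i] + config$calving_min_days * 86400 - 1, tt)
    if (jmin <= i + 3) next   # too few fixes / data gap
    span_days <- (tt[jmin] - tt[i]) / 86400
    if (span_days < config$calving_min_days - 0.5) next
    if (!confined(fixes$x[i:jmin], fixes$y[i:jmin], config$calving_area_km2))
      next
    jmax <- findInterval(tt[i] + config$calving_max_days * 86400, tt)
    j <- jmin
    while (j < jmax &&
           confined(fixes$x[i:(j + 1)], fixes$y[i:(j + 1)],
                    config$calving_area_km2))
      j <- j + 1
    return(season_interval(fixes$animal_id[1], "calving",
                           fixes$t[i], fixes$t[j]))
  }
  NULL
}

#' Detect spring migration
#'
#' Start: the first fix in the spring search window whose net displacement
#' over the directedness window exceeds the trigger with heading within the
#' sector around the migration axis. End: the first subsequent time at which
#' the rolling displacement stays below the trigger for the quiescence period,
#' or the calving onset if that comes first. Candidates whose total start-end
#' displacement falls short of `min_total_displacement_km` are discarded.
#'
#' @param traj Screened `labeled_trajectory` or fix data.frame.
#' @param config A [seg_config()].
#' @param calving Optional calving interval from [detect_calving()]; if its
#'   onset precedes the detected end, the migration is clipped there.
#' @return A one-row season-interval data.frame, or NULL.
#' @export
detect_spring_migration <- function(traj, config = seg_config(), calving = NULL) {
  fixes <- as_fixes(traj)
  hit <- find_directed_move(fixes, config, config$axis_deg,
                            config$spring_search_doy)
  if (is.null(hit)) return(NULL)
  t_start <- fixes$t[hit[1]]
  t_end <- fixes$t[hit[2]]
  if (!is.null(calving) && calving$t_start < t_end && calving$t_start > t_start)
    t_end <- calving$t_start
  season_interval(fixes$animal_id[1], "spring_migration", t_start, t_end)
}

#' Detect fall migration
#'
#' Directed southward movement found with the same rules as spring; the start
#' is then clipped forward to the first fix outside the population summer
#' range's 80% isopleth, so the modelled route does not retrace the summer
#' range.
#'
#' @param traj Screened `labeled_trajectory` or fix data.frame.
#' @param summer_isopleth The summer-range isopleth (level
#'   `config$fall_start_isopleth`) from [pooled_seasonal_range()].
#' @param config A [seg_config()].
#' @return A one-row season-interval data.frame, or NULL.
#' @export
detect_fall_migration <- function(traj, summer_isopleth, config = seg_config()) {
  if (missing(summer_isopleth) || is.null(summer_isopleth))
    stopf(paste("summer 80%% isopleth is required to delineate the fall start;",
                "run pooled_seasonal_range() on the summer fixes first"))
  fixes <- as_fixes(traj)
  hit <- find_directed_move(fixes, config,
                            (config$axis_deg + 180) %% 360,
                            config$fall_search_doy)
  if (is.null(hit)) return(NULL)
  idx <- hit[1]:hit[2]
  outside <- !point_in_isopleth(summer_isopleth, fixes$x[idx], fixes$y[idx])
  if (!any(outside)) return(NULL)
  start <- idx[which(outside)[1]]
  if (start >= hit[2]) return(NULL)
  season_interval(fixes$animal_id[1], "fall_migration",
                  fixes$t[start], fixes$t[hit[2]])
}

#' Classify an animal-season as migratory
#'
#' Migratory means a migration interval was detected for that season.
#'
#' @param detection The result of a migration detector (interval or NULL).
#' @return Logical.
#' @export
classify_animal_season <- function(detection) {
  !is.null(detection) && nrow(detection) > 0
}

#' Assemble the full season sequence for one animal-year
#'
#' Winter and summer fill the gaps between the detected migrations and
#' calving: winter runs from the start of the data to the start of spring
#' migration and from the end of fall migration to the end of the data; summer
#' runs from the end of calving (or, for animals without a detected calving
#' confinement, from the population mean calving end date) to the start of
#' fall migration.
#'
#' @param traj `labeled_trajectory` or fix data.frame for one animal-year.
#' @param spring,calving,fall Detection results (possibly NULL).
#' @param pop_calving_end Population mean calving end (POSIXct), used when
#'   `calving` is NULL.
#' @return A season-interval data.frame in canonical order.
#' @export
assemble_seasons <- function(traj, spring = NULL, calving = NULL, fall = NULL,
                             pop_calving_end = NULL) {
  fixes <- as_fixes(traj)
  id <- fixes$animal_id[1]
  t_min <- min(fixes$t); t_max <- max(fixes$t)
  if (!is.null(spring) && !is.null(fall) && fall$t_start < spring$t_end)
    stopf("contradictory detections: fall migration precedes spring migration")
  summer_start <- if (!is.null(calving)) calving$t_end
                  else if (!is.null(pop_calving_end)) {
                    if (!is.null(spring)) max(pop_calving_end, spring$t_end)
                    else pop_calving_end
                  } else if (!is.null(spring)) spring$t_end
                  else NULL
  rows <- list()
  add <- function(label, a, b, migratory = label %in% c("spring_migration",
                                                        "fall_migration")) {
    if (!is.null(a) && !is.null(b) && a < b)
      rows[[length(rows) + 1]] <<- season_interval(id, label, a, b, migratory)
  }
  first_break <- if (!is.null(spring)) spring$t_start else summer_start
  add("winter", t_min, first_break)
  if (!is.null(spring))
    # with a detected calving, spring runs up to its onset so the sequence is
    # contiguous (migration ends where confinement begins)
    add("spring_migration", spring$t_start,
        if (!is.null(calving) && calving$t_start > spring$t_start)
          calving$t_start else spring$t_end)
  if (!is.null(calving)) add("calving", calving$t_start, calving$t_end)
  add("summer", summer_start,
      if (!is.null(fall)) fall$t_start else t_max)
  if (!is.null(fall)) {
    add("fall_migration", fall$t_start, fall$t_end)
    add("winter", fall$t_end, t_max)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(season_interval(id, "winter", t_min, t_max, FALSE))
  if (is.unsorted(as.numeric(out$t_start)) ||
      any(as.numeric(out$t_end[-nrow(out)]) > as.numeric(out$t_start[-1]) + 1))
    stopf("assembled seasons are not in canonical non-overlapping order")
  rownames(out) <- NULL
  out
}

#' Label fixes by season interval
#'
#' @param fixes Fix data.frame.
#' @param intervals Season intervals (one animal-year). Half-open matching:
#'   t_start <= t < t_end.
#' @return Character vector of labels (NA outside all intervals).
#' @export
label_fixes <- function(fixes, intervals) {
  out <- rep(NA_character_, nrow(fixes))
  tt <- as.numeric(fixes$t)
  last_end <- max(as.numeric(intervals$t_end))
  for (r in seq_len(nrow(intervals))) {
    hi <- as.numeric(intervals$t_end[r])
    inr <- tt >= as.numeric(intervals$t_start[r]) &
           (tt < hi | (hi == last_end & tt == hi))   # close the final interval
    out[inr] <- intervals$label[r]
  }
  out
}

#' Per-fix agreement between estimated and ground-truth labels
#'
#' @param traj A `labeled_trajectory` (carries true labels).
#' @param intervals Estimated season intervals.
#' @return Fraction of fixes whose estimated label equals the true label
#'   (unlabelled fixes count as disagreement).
#' @export
label_agreement <- function(traj, intervals) {
  est <- label_fixes(traj$fixes, intervals)
  mean(!is.na(est) & est == traj$fixes$label)
}

#' Tabulate migratory vs non-migratory animal-seasons
#'
#' Produces per-year counts and integer percents by season with a Total row,
#' in the layout of a herd monitoring summary.
#'
#' @param classifications Data.frame with columns `year`, `season`
#'   ("spring"/"fall") and `migratory` (logical).
#' @return Data.frame: season, year, n_migratory, pct_migratory,
#'   n_nonmigratory, pct_nonmigratory, total.
#' @export
tabulate_migratory <- function(classifications) {
  stopifnot(all(c("year", "season", "migratory") %in% names(classifications)))
  rows <- list()
  for (season in unique(classifications$season)) {
    sub <- classifications[classifications$season == season, ]
    for (yr in c(sort(unique(sub$year)), NA)) {
      s <- if (is.na(yr)) sub else sub[sub$year == yr, ]
      n_mig <- sum(s$migratory); n_non <- sum(!s$migratory)
      tot <- n_mig + n_non
      rows[[length(rows) + 1]] <- data.frame(
        season = season, year = if (is.na(yr)) "Total" else as.character(yr),
        n_migratory = n_mig,
        pct_migratory = ifelse(tot > 0, round(100 * n_mig / tot), NA),
        n_nonmigratory = n_non,
        pct_nonmigratory = ifelse(tot > 0, round(100 * n_non / tot), NA),
        total = tot, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
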