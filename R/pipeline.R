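# End-to-end driver: screen -> segment (with the pooled summer range's 80%
# isopleth feeding the fall-migration start) -> seasonal ranges -> movement
# metrics -> Brownian bridge routes -> overlap and fidelity summaries.
# Every artifact is written under the output directory and the run is fully
# reproducible from config + seed (the provenance record contains no
# wall-clock state, so reruns are byte-identical).

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()] to generate input data, or NULL.
#' @param input Path to a fix CSV (used when `sim` is NULL).
#' @param seg A [seg_config()].
#' @param cell_size Grid cell size for ranges and routes, metres.
#' @param range_levels Isopleth levels for seasonal ranges.
#' @param route_level Isopleth level defining a migration route.
#' @param delta Location-error SD for the bridge model, metres.
#' @param alpha_steps Bridge time-discretization steps per segment.
#' @param max_gap_h Bridge segments with longer gaps are excluded; default 8
#'   times the 5-h summer schedule.
#' @param models Correction-factor models for the movement metrics.
#' @param projection Declared projection of the planar coordinates (metadata).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, input = NULL,
                            seg = seg_config(), cell_size = 500,
                            range_levels = c(0.80, 0.90), route_level = 0.95,
                            delta = 30, alpha_steps = 10, max_gap_h = 40,
                            models = published_cf_models(),
                            projection = "EPSG:3338") {
  if (is.null(sim) && is.null(input))
    stopf("either a sim_config or an input path is required")
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with all stage results and the provenance
#'   record. Artifacts are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  fixes <- run_stage("ingest", {
    if (!is.null(config$sim)) {
      trajs <- simulate_population(config$sim)
      fx <- bind_fixes(trajs, labels = TRUE)
      write_fixes(fx, out("fixes_raw.csv"))
      truth <- fx[, c("animal_id", "t", "label")]
      truth$t <- format(truth$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      names(truth)[2] <- "timestamp"
      utils::write.csv(truth, out("truth_labels.csv"), row.names = FALSE,
                       quote = FALSE)
      fx$label <- NULL
      fx
    } else read_fixes(config$input)
  })

  scr <- run_stage("screen", screen_fixes(fixes))
  write_fixes(scr$fixes, out("fixes_screened.csv"))
  utils::write.csv(scr$report$removed, out("screening_report.csv"),
                   row.names = FALSE)

  # --- segmentation pass 1: spring, calving, provisional fall start --------
  sf <- scr$fixes
  sf$year <- as.POSIXlt(sf$t, tz = "UTC")$year + 1900
  ay <- split(sf, list(sf$animal_id, sf$year), drop = TRUE)
  seg1 <- run_stage("segment", lapply(ay, function(fx) {
    calving <- detect_calving(fx, config$seg)
    spring <- detect_spring_migration(fx, config$seg, calving = calving)
    prov <- find_directed_move(fx, config$seg,
                               (config$seg$axis_deg + 180) %% 360,
                               config$seg$fall_search_doy)
    list(fixes = fx, calving = calving, spring = spring,
         prov_fall_start = if (is.null(prov)) NULL else fx$t[prov[1]])
  }))

  years <- sort(unique(sf$year))
  mean_time <- function(ts) if (length(ts)) mean(do.call(c, ts)) else NULL
  cal_end_by_year <- lapply(years, function(yr) mean_time(
    lapply(seg1[vapply(seg1, function(s) s$fixes$year[1] == yr, TRUE)],
           function(s) if (!is.null(s$calving)) s$calving$t_end)))
  names(cal_end_by_year) <- years
  fall_start_by_year <- lapply(years, function(yr) mean_time(
    lapply(seg1[vapply(seg1, function(s) s$fixes$year[1] == yr, TRUE)],
           function(s) s$prov_fall_start)))
  names(fall_start_by_year) <- years

  # --- pooled summer ranges (needed for the fall 80% clip) -----------------
  lv <- sort(unique(c(config$range_levels, config$seg$fall_start_isopleth)))
  summer_fix_year <- function(yr) {
    do.call(rbind, lapply(seg1, function(s) {
      fx <- s$fixes
      if (fx$year[1] != yr) return(NULL)
      start <- if (!is.null(s$calving)) s$calving$t_end
               else cal_end_by_year[[as.character(yr)]]
      end <- if (!is.null(s$prov_fall_start)) s$prov_fall_start
             else fall_start_by_year[[as.character(yr)]]
      if (is.null(start)) start <- as.POSIXct(sprintf("%d-06-15", yr), tz = "UTC")
      if (is.null(end)) end <- as.POSIXct(sprintf("%d-09-16", yr), tz = "UTC")
      fx[fx$t >= start & fx$t < end, c("animal_id", "t", "x", "y")]
    }))
  }
  summer_ranges <- run_stage("ranges_summer", {
    rs <- lapply(years, function(yr)
      pooled_seasonal_range(summer_fix_year(yr), levels = lv,
                            cell_size = config$cell_size))
    names(rs) <- years
    rs
  })

  # --- segmentation pass 2: final fall detection and assembly --------------
  iso_key <- sprintf("%g", 100 * config$seg$fall_start_isopleth)
  results <- run_stage("segment", lapply(seg1, function(s) {
    yr <- as.character(s$fixes$year[1])
    fall <- detect_fall_migration(s$fixes,
                                  summer_ranges[[yr]]$isopleths[[iso_key]],
                                  config$seg)
    intervals <- assemble_seasons(s$fixes, spring = s$spring,
                                  calving = s$calving, fall = fall,
                                  pop_calving_end = cal_end_by_year[[yr]])
    list(fixes = s$fixes, spring = s$spring, calving = s$calving,
         fall = fall, intervals = intervals)
  }))
  intervals <- do.call(rbind, lapply(results, `[[`, "intervals"))
  rownames(intervals) <- NULL
  write_intervals(intervals, out("intervals.csv"))

  classifications <- do.call(rbind, lapply(results, function(r) data.frame(
    animal_id = r$fixes$animal_id[1], year = r$fixes$year[1],
    season = c("spring", "fall"),
    migratory = c(classify_animal_season(r$spring),
                  classify_animal_season(r$fall)),
    stringsAsFactors = FALSE)))
  rownames(classifications) <- NULL
  table1 <- tabulate_migratory(classifications)
  utils::write.csv(classifications, out("classifications.csv"), row.names = FALSE)
  utils::write.csv(table1, out("migratory_table.csv"), row.names = FALSE)

  # --- winter ranges --------------------------------------------------------
  winter_ranges <- run_stage("ranges_winter", {
    rs <- lapply(years, function(yr) {
      wfx <- do.call(rbind, lapply(results, function(r) {
        if (r$fixes$year[1] != yr) return(NULL)
        iv <- r$intervals[r$intervals$label == "winter", ]
        if (!nrow(iv)) return(NULL)
        keep <- rep(FALSE, nrow(r$fixes))
        for (k in seq_len(nrow(iv)))
          keep <- keep | (r$fixes$t >= iv$t_start[k] & r$fixes$t < iv$t_end[k])
        r$fixes[keep, c("animal_id", "t", "x", "y")]
      }))
      pooled_seasonal_range(wfx, levels = config$range_levels,
                            cell_size = config$cell_size)
    })
    names(rs) <- years
    rs
  })

  range_rows <- list()
  for (yr in as.character(years)) for (season in c("summer", "winter")) {
    rr <- if (season == "summer") summer_ranges[[yr]] else winter_ranges[[yr]]
    write_ud_asc(rr$ud, out(sprintf("range_%s_%s.asc", season, yr)))
    for (nm in names(rr$isopleths))
      range_rows[[length(range_rows) + 1]] <- data.frame(
        season = season, year = yr, level = as.numeric(nm) / 100,
        area_km2 = rr$isopleths[[nm]]$area_km2, h_m = rr$h,
        n_points = rr$n_points, n_animals = rr$n_animals)
  }
  range_areas <- do.call(rbind, range_rows)
  utils::write.csv(range_areas, out("range_areas.csv"), row.names = FALSE)
  for (season in c("summer", "winter")) {
    rs <- if (season == "summer") summer_ranges else winter_ranges
    isos <- lapply(rs, function(r) r$isopleths[["90"]])
    write_isopleths_geojson(isos, out(sprintf("ranges_%s.geojson", season)),
                            properties = data.frame(season = season,
                                                    year = names(isos)))
  }

  # --- movement metrics -----------------------------------------------------
  metrics <- run_stage("metrics",
                       migration_summary(intervals, scr$fixes, config$models))
  utils::write.csv(metrics$paths, out("migration_paths.csv"), row.names = FALSE)
  if (!is.null(metrics$summary))
    utils::write.csv(metrics$summary, out("migration_summary.csv"),
                     row.names = FALSE)

  # --- Brownian bridge routes ----------------------------------------------
  routes <- run_stage("routes", {
    mig <- intervals[intervals$label %in% c("spring_migration",
                                            "fall_migration"), ]
    if (!nrow(mig)) list() else {
      migfx <- list()
      for (r in seq_len(nrow(mig))) {
        fx <- scr$fixes[scr$fixes$animal_id == mig$animal_id[r] &
                        scr$fixes$t >= mig$t_start[r] &
                        scr$fixes$t <= mig$t_end[r], ]
        if (nrow(fx) >= 3) migfx[[r]] <- fx
      }
      allf <- do.call(rbind, migfx)
      route_grid <- make_grid(allf$x, allf$y, config$cell_size, margin = 25000)
      uds <- list()
      for (r in seq_len(nrow(mig))) {
        if (r > length(migfx) || is.null(migfx[[r]])) next
        season <- if (mig$label[r] == "spring_migration") "spring" else "fall"
        yr <- as.character(as.POSIXlt(mig$t_start[r], tz = "UTC")$year + 1900)
        s2 <- estimate_sigma2m(migfx[[r]], delta = config$delta)
        u <- bbmm_ud(migfx[[r]],
                     bbmm_params(as.numeric(s2), delta = config$delta,
                                 cell_size = config$cell_size,
                                 alpha_steps = config$alpha_steps,
                                 max_gap_h = config$max_gap_h),
                     grid = route_grid,
                     meta = list(animal_id = mig$animal_id[r],
                                 season = season, year = yr))
        key <- paste(season, yr, sep = "_")
        uds[[key]] <- c(uds[[key]], list(u))
      }
      pop <- lapply(names(uds), function(key) {
        parts <- strsplit(key, "_")[[1]]
        population_route(uds[[key]], season = parts[1], year = parts[2])
      })
      names(pop) <- names(uds)
      pop
    }
  })
  for (key in names(routes))
    write_ud_asc(routes[[key]], out(sprintf("route_%s.asc", key)))
  yearsofuse <- list()
  for (season in c("spring", "fall")) {
    keys <- grep(paste0("^", season, "_"), names(routes), value = TRUE)
    if (length(keys) >= 2) {
      byyr <- routes[keys]
      names(byyr) <- sub(paste0(season, "_"), "", keys)
      yo <- route_years_of_use(byyr, level = config$route_level)
      yearsofuse[[season]] <- yo
      write_ud_asc(yo, out(sprintf("route_years_of_use_%s.asc", season)))
    }
  }

  # --- overlap, fidelity, composites ---------------------------------------
  ranges90 <- list(
    summer = lapply(summer_ranges, function(r) r$isopleths[["90"]]),
    winter = lapply(winter_ranges, function(r) r$isopleths[["90"]]))
  fidelity <- run_stage("overlap", fidelity_summary(ranges90))
  utils::write.csv(fidelity$consecutive, out("fidelity_consecutive.csv"),
                   row.names = FALSE)
  if (!is.null(fidelity$season_means))
    utils::write.csv(fidelity$season_means, out("fidelity_means.csv"),
                     row.names = FALSE)
  if (!is.null(fidelity$within_year))
    utils::write.csv(fidelity$within_year, out("within_year_overlap.csv"),
                     row.names = FALSE)
  composites <- list()
  if (length(years) >= 2) {
    for (season in c("summer", "winter")) {
      comp <- composite_years_of_use(ranges90[[season]], season = season)
      composites[[season]] <- comp
      utils::write.csv(comp$table, out(sprintf("composite_%s.csv", season)),
                       row.names = FALSE)
      write_ud_asc(comp, out(sprintf("composite_%s.asc", season)))
    }
  }

  provenance <- list(
    package = "migroutes",
    version = as.character(utils::packageVersion("migroutes")),
    projection = config$projection,
    seed = if (!is.null(config$sim)) config$sim$seed else NULL,
    config = list(
      cell_size = config$cell_size, range_levels = config$range_levels,
      route_level = config$route_level, delta = config$delta,
      alpha_steps = config$alpha_steps, max_gap_h = config$max_gap_h,
      seg = unclass(config$seg),
      sim = if (!is.null(config$sim)) unclass(config$sim) else NULL),
    counts = list(
      n_input = scr$report$n_input,
      n_gross_removed = scr$report$n_gross_removed,
      n_spike_removed = scr$report$n_spike_removed,
      n_output = scr$report$n_output,
      n_animal_years = length(results),
      n_migration_paths = if (is.null(metrics$paths)) 0 else nrow(metrics$paths),
      n_routes = length(routes)))
  jsonlite::write_json(provenance, out("provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(fixes = fixes, screened = scr, intervals = intervals,
                 classifications = classifications, table1 = table1,
                 summer_ranges = summer_ranges, winter_ranges = winter_ranges,
                 range_areas = range_areas, metrics = metrics,
                 routes = routes, years_of_use = yearsofuse,
                 fidelity = fidelity, composites = composites,
                 provenance = provenance))
}
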