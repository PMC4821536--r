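# Range overlap, between-year fidelity, and years-of-use composites for
# seasonal ranges. Isopleth regions live on congruent rasters, so
# intersection and union areas are exact cell arithmetic. The overlap
# denominator is the union (combined) area: percent = 100 * |A n B| / |A u B|.

iso_masks_on_common <- function(a, b) {
  cg <- common_grid(list(a, b))
  list(a = regrid_matrix(a$cells, a, cg, fill = FALSE),
       b = regrid_matrix(b$cells, b, cg, fill = FALSE),
       cell_km2 = cg$cell_size^2 / 1e6)
}

#' Percent overlap from intersection and combined areas
#'
#' @param area_intersection,area_union Areas in the same unit.
#' @return 100 * intersection / union (unrounded; round to one decimal for
#'   reporting).
#' @export
overlap_percent <- function(area_intersection, area_union) {
  if (area_union <= 0) stopf("union area must be positive")
  100 * area_intersection / area_union
}

#' Overlap between two isopleth ranges
#'
#' @param range_a,range_b `isopleth` objects on congruent grids.
#' @param id_a,id_b Identifiers for the report.
#' @return One-row data.frame: ids, areas of each range, of the intersection
#'   and of the union (km^2), and `percent_overlap` = 100 * intersection /
#'   union.
#' @export
percent_overlap <- function(range_a, range_b, id_a = "A", id_b = "B") {
  if (!any(range_a$cells) || !any(range_b$cells))
    stopf("empty isopleth region; cannot compute overlap")
  m <- iso_masks_on_common(range_a, range_b)
  ai <- sum(m$a & m$b) * m$cell_km2
  au <- sum(m$a | m$b) * m$cell_km2
  data.frame(id_a = id_a, id_b = id_b,
             area_a = sum(m$a) * m$cell_km2,
             area_b = sum(m$b) * m$cell_km2,
             area_intersection = ai, area_union = au,
             percent_overlap = overlap_percent(ai, au),
             stringsAsFactors = FALSE)
}

#' Years-of-use composite of annual seasonal ranges
#'
#' Overlays the annual ranges on their common grid, counts the years of use
#' per cell, and reports the percent of the composite (union) area used in
#' exactly 1..n years.
#'
#' @param ranges Named list (by year) of `isopleth` objects (>= 2).
#' @param season Optional season tag for the table.
#' @return List with `counts` raster (plus grid geometry) and `table`
#'   (years_used, area_km2, percent of the composite area).
#' @export
composite_years_of_use <- function(ranges, season = NULL) {
  if (length(ranges) < 2) stopf("need at least 2 annual ranges")
  cg <- common_grid(ranges)
  counts <- matrix(0L, cg$n_rows, cg$n_cols)
  for (iso in ranges)
    counts <- counts + regrid_matrix(iso$cells, iso, cg, fill = FALSE)
  cell_km2 <- cg$cell_size^2 / 1e6
  total <- sum(counts > 0) * cell_km2
  ks <- seq_along(ranges)
  tab <- data.frame(
    season = if (is.null(season)) NA_character_ else season,
    years_used = ks,
    area_km2 = vapply(ks, function(k) sum(counts == k) * cell_km2, 0))
  tab$percent <- 100 * tab$area_km2 / total
  list(x0 = cg$x0, y0 = cg$y0, cell_size = cg$cell_size,
       n_rows = cg$n_rows, n_cols = cg$n_cols,
       counts = counts, total_area_km2 = total, table = tab)
}

#' Site-fidelity and seasonal-separation summary
#'
#' Percent overlap between ranges used in the same season during consecutive
#' years (site fidelity), per-season means and ranges, and the within-year
#' overlap between the summer and winter ranges (seasonal separation).
#'
#' @param ranges Nested list: `ranges[[season]][[year]]` is the season-year
#'   90% `isopleth`. Seasons are typically "summer" and "winter".
#' @return List of data.frames: `consecutive` (per season-year pair),
#'   `season_means`, and `within_year` (summer vs winter per year). Seasons
#'   with fewer than 2 years yield an empty `consecutive` table with a
#'   warning.
#' @export
fidelity_summary <- function(ranges) {
  cons <- list(); means <- list(); within <- list()
  for (season in names(ranges)) {
    yrs <- sort(names(ranges[[season]]))
    if (length(yrs) < 2) {
      warnf("season %s has fewer than 2 years; no fidelity estimate", season)
      next
    }
    for (i in seq_len(length(yrs) - 1)) {
      ov <- percent_overlap(ranges[[season]][[yrs[i]]],
                            ranges[[season]][[yrs[i + 1]]],
                            id_a = paste(season, yrs[i]),
                            id_b = paste(season, yrs[i + 1]))
      cons[[length(cons) + 1]] <- cbind(season = season,
                                        year_a = yrs[i], year_b = yrs[i + 1], ov)
    }
  }
  cons <- if (length(cons)) do.call(rbind, cons) else
    data.frame(season = character(0), year_a = character(0),
               year_b = character(0), percent_overlap = numeric(0))
  for (season in unique(cons$season)) {
    v <- cons$percent_overlap[cons$season == season]
    means[[length(means) + 1]] <- data.frame(
      season = season, n_pairs = length(v), mean_percent = mean(v),
      min_percent = min(v), max_percent = max(v), stringsAsFactors = FALSE)
  }
  if (all(c("summer", "winter") %in% names(ranges))) {
    yrs <- intersect(names(ranges$summer), names(ranges$winter))
    for (yr in sort(yrs)) {
      ov <- percent_overlap(ranges$summer[[yr]], ranges$winter[[yr]],
                            id_a = paste("summer", yr),
                            id_b = paste("winter", yr))
      within[[length(within) + 1]] <- cbind(year = yr, ov)
    }
  }
  list(consecutive = cons,
       season_means = if (length(means)) do.call(rbind, means) else NULL,
       within_year = if (length(within)) do.call(rbind, within) else NULL)
}
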