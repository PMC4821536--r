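# Readers and writers. Fix tables are CSV with header
# animal_id,timestamp,x,y (ISO-8601 UTC timestamps; x/y metres in a declared
# planar equal-area projection). UDs and years-of-use rasters are ESRI ASCII
# grids; isopleths are GeoJSON (cell rectangles merged into row runs).

#' Read a fix table
#'
#' @param path CSV with columns animal_id, timestamp (ISO-8601 UTC), x, y.
#' @return Data.frame (animal_id, t, x, y) sorted per animal by time.
#'   Duplicate (animal, timestamp) rows keep the first occurrence, with a
#'   warning. Malformed rows raise errors naming the row.
#' @export
read_fixes <- function(path) {
  if (!file.exists(path)) stopf("fix file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  t <- as.POSIXct(rep(NA_real_, nrow(raw)), tz = "UTC",
                  origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M:%S")) {
    p <- strptime(raw$timestamp, fmt, tz = "UTC")
    fill <- is.na(t) & !is.na(p)
    t[fill] <- as.POSIXct(p[fill], tz = "UTC")
  }
  if (anyNA(t))
    stopf("unparseable timestamp at row %d: '%s'",
          which(is.na(t))[1], raw$timestamp[which(is.na(t))[1]])
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) stopf("non-finite coordinate at row %d", bad[1])
  df <- data.frame(animal_id = as.character(raw$animal_id), t = t, x = x, y = y,
                   stringsAsFactors = FALSE)
  df <- df[order(df$animal_id, df$t), ]
  dup <- duplicated(df[, c("animal_id", "t")])
  if (any(dup)) {
    warnf("%d duplicate timestamp row(s) dropped (first kept)", sum(dup))
    df <- df[!dup, ]
  }
  rownames(df) <- NULL
  df
}

#' Write a fix table
#'
#' Coordinates are written with 17 significant digits so a write/read
#' round-trip reproduces them exactly.
#'
#' @param fixes Data.frame with animal_id, t, x, y (label column, if present,
#'   is written too).
#' @param path Output CSV path.
#' @export
write_fixes <- function(fixes, path) {
  out <- data.frame(animal_id = fixes$animal_id,
                    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    x = sprintf("%.17g", fixes$x),
                    y = sprintf("%.17g", fixes$y),
                    stringsAsFactors = FALSE)
  if (!is.null(fixes$label)) out$label <- fixes$label
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write season intervals as CSV
#' @param intervals Season-interval data.frame.
#' @param path Output path.
#' @export
write_intervals <- function(intervals, path) {
  out <- intervals
  out$t_start <- format(out$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$t_end <- format(out$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a UD (or years-of-use raster) as an ESRI ASCII grid
#'
#' @param ud A `ud_grid`, or any list with grid geometry and a `p` or `counts`
#'   matrix.
#' @param path Output path (.asc).
#' @export
write_ud_asc <- function(ud, path) {
  m <- if (!is.null(ud$p)) ud$p else ud$counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("NCOLS %d", ud$n_cols),
               sprintf("NROWS %d", ud$n_rows),
               sprintf("XLLCORNER %.6f", ud$x0),
               sprintf("YLLCORNER %.6f", ud$y0),
               sprintf("CELLSIZE %.6f", ud$cell_size),
               "NODATA_VALUE -9999"), con)
  for (i in rev(seq_len(ud$n_rows)))   # ASCII grids run north to south
    writeLines(paste(sprintf("%.10g", m[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a `ud_grid`
#' @param path Path to a .asc file.
#' @return A `ud_grid` (mass matrix as stored, not renormalized).
#' @export
read_ud_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  val <- vapply(hdr, function(h) as.numeric(h[2]), 0)
  names(val) <- toupper(vapply(hdr, `[`, "", 1))
  n_rows <- as.integer(val[["NROWS"]]); n_cols <- as.integer(val[["NCOLS"]])
  m <- matrix(NA_real_, n_rows, n_cols)
  for (k in seq_len(n_rows)) {
    m[n_rows - k + 1, ] <- as.numeric(strsplit(trimws(lines[6 + k]), "\\s+")[[1]])
  }
  ud_grid(val[["XLLCORNER"]], val[["YLLCORNER"]], val[["CELLSIZE"]],
          n_rows, n_cols, p = m)
}

# Merge a logical mask row into x-interval runs; returns a list of rectangle
# rings (closed, counter-clockwise).
mask_rectangles <- function(iso) {
  rects <- list()
  cs <- iso$cell_size
  for (i in seq_len(iso$n_rows)) {
    rr <- rle(as.vector(iso$cells[i, ]))
    pos <- cumsum(c(1, rr$lengths))
    for (k in seq_along(rr$values)) {
      if (!rr$values[k]) next
      j1 <- pos[k]; j2 <- pos[k] + rr$lengths[k] - 1
      x1 <- iso$x0 + (j1 - 1) * cs; x2 <- iso$x0 + j2 * cs
      y1 <- iso$y0 + (i - 1) * cs; y2 <- iso$y0 + i * cs
      rects[[length(rects) + 1]] <-
        list(list(c(x1, y1), c(x2, y1), c(x2, y2), c(x1, y2), c(x1, y1)))
    }
  }
  rects
}

#' Write isopleths as GeoJSON
#'
#' Each isopleth becomes a Feature whose geometry is a MultiPolygon of its
#' grid-cell row runs, with level and area properties.
#'
#' @param isos A named list of `isopleth` objects (or a single one).
#' @param path Output path (.geojson).
#' @param properties Optional data.frame of extra per-feature properties
#'   (season, year, ...).
#' @export
write_isopleths_geojson <- function(isos, path, properties = NULL) {
  if (inherits(isos, "isopleth")) isos <- list(isos)
  feats <- lapply(seq_along(isos), function(k) {
    iso <- isos[[k]]
    props <- list(level = iso$level, area_km2 = iso$area_km2)
    if (!is.null(properties))
      props <- c(props, as.list(properties[k, , drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon",
                         coordinates = mask_rectangles(iso)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
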