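# Internal helpers shared across modules.

# Deterministic 32-bit seed derived from a base seed and integer keys.
# Values stay below 2^31 so set.seed() never overflows.
derive_seed <- function(...) {
  ks <- as.numeric(c(...))
  s <- 0
  for (k in ks) s <- (s * 48271 + (abs(k) %% 2147483647)) %% 2147483563
  as.integer(s) + 1L
}

# Stable integer hash for identifier strings (order-sensitive).
id_hash <- function(id) {
  v <- utf8ToInt(as.character(id)[1])
  sum(v * seq_along(v)) %% 1000003
}

# Evaluate `code` under a fixed seed, then restore the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  code
}

# Euclidean distance in metres between planar points.
dist_m <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

# Heading in degrees clockwise from north (grid north = +y).
heading_deg <- function(dx, dy) (atan2(dx, dy) * 180 / pi) %% 360

# Smallest absolute angular difference between two headings, in degrees.
ang_diff_deg <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# Fractional day of year (Jan 1 00:00 UTC -> 1.0).
doy_frac <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$yday + 1 + (lt$hour + (lt$min + lt$sec / 60) / 60) / 24
}

#' Minimum convex polygon area
#'
#' Area of the convex hull of a planar point set, in square kilometres.
#' Used as the occupied-area measure when testing for calving confinement.
#'
#' @param x,y Coordinates in metres.
#' @return Area in km^2 (0 if fewer than 3 non-collinear points).
#' @export
mcp_area_km2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  xs <- x[h]; ys <- y[h]
  n <- length(h)
  j <- c(2:n, 1)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2 / 1e6
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
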