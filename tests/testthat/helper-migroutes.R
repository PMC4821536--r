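# Fixture builders used across the suite. Everything is generated in code at
# test time; no stored data.

utc <- function(s) as.POSIXct(s, tz = "UTC")

# Straight constant-speed track heading `heading_deg` (degrees from north).
make_straight_track <- function(n = 20, dt_h = 5, speed_kmh = 1,
                                heading = 0, start = utc("2003-05-01"),
                                id = "S1") {
  t <- start + (0:(n - 1)) * dt_h * 3600
  d <- (0:(n - 1)) * speed_kmh * dt_h * 1000
  data.frame(animal_id = id, t = t,
             x = d * sin(heading * pi / 180),
             y = d * cos(heading * pi / 180), stringsAsFactors = FALSE)
}

# Correlated random walk sampled at the 5-h base interval.
make_crw <- function(n_steps = 200, step_m = 1000, rho = 0.7, seed = 1,
                     id = sprintf("C%d", seed)) {
  set.seed(seed)
  th <- cumsum(c(stats::runif(1, 0, 2 * pi),
                 stats::rnorm(n_steps - 1, 0, (1 - rho) * pi)))
  data.frame(animal_id = id,
             t = utc("2003-06-20") + (0:n_steps) * 5 * 3600,
             x = cumsum(c(0, step_m * sin(th))),
             y = cumsum(c(0, step_m * cos(th))), stringsAsFactors = FALSE)
}

# Exact Brownian motion segment (a bridge conditioned on its own endpoints).
make_bb_segment <- function(n_fix = 5, dt_s = 18000, sigma2 = 0.5, id = "B") {
  data.frame(animal_id = id,
             t = utc("2003-05-01") + (0:(n_fix - 1)) * dt_s,
             x = cumsum(c(0, stats::rnorm(n_fix - 1, 0, sqrt(sigma2 * dt_s)))),
             y = cumsum(c(0, stats::rnorm(n_fix - 1, 0, sqrt(sigma2 * dt_s)))),
             stringsAsFactors = FALSE)
}

# Analytic isotropic-Gaussian UD discretized on a fine grid.
make_gaussian_ud <- function(sd = 1000, cell = 50, extent = 6 * sd) {
  g <- make_grid(c(-extent, extent), c(-extent, extent), cell, margin = 0)
  cx <- g$x0 + (seq_len(g$n_cols) - 0.5) * cell
  cy <- g$y0 + (seq_len(g$n_rows) - 0.5) * cell
  dens <- stats::dnorm(cy, 0, sd) %o% stats::dnorm(cx, 0, sd)
  g$p <- dens * cell^2 / sum(dens * cell^2)
  g
}

# Rectangular isopleth region: cells [r1..r2] x [c1..c2] on a given grid.
make_rect_iso <- function(x0 = 0, y0 = 0, cell = 500, n_rows = 40, n_cols = 40,
                          rows = 1:20, cols = 1:20, level = 0.9) {
  mask <- matrix(FALSE, n_rows, n_cols)
  mask[rows, cols] <- TRUE
  structure(list(x0 = x0, y0 = y0, cell_size = cell, n_rows = n_rows,
                 n_cols = n_cols, level = level, cells = mask,
                 area_km2 = sum(mask) * cell^2 / 1e6, mass = level,
                 meta = list()),
            class = "isopleth")
}

# Temporal Jaccard between a detected interval and a truth interval.
temporal_jaccard <- function(det, truth) {
  if (is.null(det)) return(0)
  a <- max(as.numeric(det$t_start), as.numeric(truth$t_start))
  b <- min(as.numeric(det$t_end), as.numeric(truth$t_end))
  u <- max(as.numeric(det$t_end), as.numeric(truth$t_end)) -
       min(as.numeric(det$t_start), as.numeric(truth$t_start))
  max(0, b - a) / u
}
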