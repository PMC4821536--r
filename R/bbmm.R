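# Brownian bridge movement models for migration routes. Conditional on two
# consecutive fixes z_start, z_end separated by time T, the bridge position at
# fractional time a has mean (1-a) z_start + a z_end and variance
# T a (1-a) sigma2_m + (1-a)^2 delta^2 + a^2 delta^2, where sigma2_m is the
# Brownian motion variance (m^2/s) and delta the location-error SD (m).
# sigma2_m is estimated by maximizing the likelihood of every second fix under
# the bridge between its temporal neighbours; the route UD is the
# time-weighted average of the bridge densities over all segments.

#' BBMM parameters
#'
#' @param sigma2_m Brownian motion variance, m^2/s (>= 0).
#' @param delta Location-error SD, metres (default 30; collar accuracy was
#'   field-verified only as within 100 m, so this is configuration).
#' @param cell_size Grid cell size, metres (default 500).
#' @param alpha_steps Time-discretization steps per segment (midpoint rule,
#'   >= 5; default 10).
#' @param max_gap_h Segments with fix gaps longer than this are excluded from
#'   bridging (long gaps make bridges uninformative). Default Inf.
#' @return An object of class `bbmm_params`.
#' @export
bbmm_params <- function(sigma2_m, delta = 30, cell_size = 500,
                        alpha_steps = 10, max_gap_h = Inf) {
  if (sigma2_m < 0 || delta < 0) stopf("sigma2_m and delta must be >= 0")
  if (cell_size <= 0) stopf("cell_size must be positive")
  if (alpha_steps < 5) stopf("alpha_steps must be at least 5")
  structure(list(sigma2_m = sigma2_m, delta = delta, cell_size = cell_size,
                 alpha_steps = alpha_steps, max_gap_h = max_gap_h),
            class = "bbmm_params")
}

# Assemble the leave-one-out bridge terms (every second interior fix) from one
# or more segments.
bridge_terms <- function(segments) {
  if (inherits(segments, "data.frame")) segments <- list(segments)
  segments <- lapply(segments, as_fixes)
  acc <- list(x = c(), y = c(), mx = c(), my = c(), a = c(), Tt = c())
  for (seg in segments) {
    n <- nrow(seg)
    if (n < 3) next
    tt <- as.numeric(seg$t)
    i <- seq(2, n - 1, by = 2)
    a <- (tt[i] - tt[i - 1]) / (tt[i + 1] - tt[i - 1])
    acc$x <- c(acc$x, seg$x[i]); acc$y <- c(acc$y, seg$y[i])
    acc$mx <- c(acc$mx, (1 - a) * seg$x[i - 1] + a * seg$x[i + 1])
    acc$my <- c(acc$my, (1 - a) * seg$y[i - 1] + a * seg$y[i + 1])
    acc$a <- c(acc$a, a)
    acc$Tt <- c(acc$Tt, tt[i + 1] - tt[i - 1])
  }
  acc
}

#' Estimate the Brownian motion variance
#'
#' Maximizes the likelihood of each even-indexed fix under the Brownian bridge
#' between its temporal neighbours (bounded scalar search over log sigma2_m
#' refined by golden section).
#'
#' @param segments A fix data.frame (one migration segment, >= 3 fixes) or a
#'   list of them; the likelihood pools all segments.
#' @param delta Location-error SD, metres.
#' @param s2_range Search range for sigma2_m, m^2/s.
#' @return Estimated sigma2_m (m^2/s), with the log-likelihood attached as
#'   attribute `"loglik"`.
#' @export
estimate_sigma2m <- function(segments, delta = 30, s2_range = c(1e-6, 1e5)) {
  bt <- bridge_terms(segments)
  if (length(bt$x) < 1)
    stopf("need at least one segment with >= 3 fixes to estimate sigma2_m")
  ll <- function(s2) {
    v <- bt$Tt * bt$a * (1 - bt$a) * s2 +
      ((1 - bt$a)^2 + bt$a^2) * delta^2
    v <- pmax(v, 1e-12)
    sum(stats::dnorm(bt$x, bt$mx, sqrt(v), log = TRUE) +
        stats::dnorm(bt$y, bt$my, sqrt(v), log = TRUE))
  }
  lg <- seq(log(s2_range[1]), log(s2_range[2]), length.out = 80)
  vals <- vapply(lg, function(l) ll(exp(l)), 0)
  i <- which.max(vals)
  lo <- lg[max(i - 1, 1)]; hi <- lg[min(i + 1, length(lg))]
  opt <- stats::optimize(function(l) ll(exp(l)), c(lo, hi),
                         maximum = TRUE, tol = 1e-8)
  s2 <- exp(opt$maximum)
  attr(s2, "loglik") <- opt$objective
  s2
}

# Add the per-cell mass of a weighted isotropic Gaussian to an accumulator
# matrix. The Gaussian is separable, so the cell integral is exact:
# mass(i,j) = w * (Phi(x_j+1) - Phi(x_j)) * (Phi(y_i+1) - Phi(y_i)).
# Only cells within +/- 7 SD are touched.
add_gaussian_local <- function(P, grid, mux, muy, sd, w) {
  sd <- max(sd, 1e-9)
  r <- 7 * sd + grid$cell_size
  j1 <- max(1L, floor((mux - r - grid$x0) / grid$cell_size) + 1L)
  j2 <- min(grid$n_cols, ceiling((mux + r - grid$x0) / grid$cell_size))
  i1 <- max(1L, floor((muy - r - grid$y0) / grid$cell_size) + 1L)
  i2 <- min(grid$n_rows, ceiling((muy + r - grid$y0) / grid$cell_size))
  if (j1 > j2 || i1 > i2) return(P)
  ex <- grid$x0 + (j1 - 1):j2 * grid$cell_size   # cell edges
  ey <- grid$y0 + (i1 - 1):i2 * grid$cell_size
  mx <- diff(stats::pnorm(ex, mux, sd))
  my <- diff(stats::pnorm(ey, muy, sd))
  P[i1:i2, j1:j2] <- P[i1:i2, j1:j2] + w * (my %o% mx)
  P
}

#' Brownian bridge utilization distribution of a trajectory segment
#'
#' Time-weighted average over all inter-fix segments and alpha steps of the
#' bridge's Gaussian density integrated over each cell (exactly, via the
#' separable normal CDF), normalized to one.
#'
#' @param fixes Time-ordered fixes of one migration segment (>= 2 fixes).
#' @param params A [bbmm_params()] (carries sigma2_m, delta, cell size, alpha
#'   steps and the gap-exclusion rule).
#' @param grid Optional `ud_grid`; built over the fixes with a margin when
#'   omitted.
#' @param meta Metadata list stored on the result (animal id, season, year).
#' @return A `ud_grid` route UD.
#' @export
bbmm_ud <- function(fixes, params, grid = NULL, meta = list()) {
  fixes <- as_fixes(fixes)
  n <- nrow(fixes)
  if (n < 2) stopf("need at least 2 fixes for a bridge")
  tt <- as.numeric(fixes$t)
  Tt <- diff(tt)
  use <- Tt / 3600 <= params$max_gap_h & Tt > 0
  if (!any(use)) stopf("no usable segments (all gaps exceed max_gap_h)")
  maxvar <- max(Tt[use]) / 4 * params$sigma2_m + params$delta^2
  if (is.null(grid))
    grid <- make_grid(fixes$x, fixes$y, params$cell_size,
                      margin = 5 * sqrt(maxvar) + 3 * params$cell_size)
  P <- matrix(0, grid$n_rows, grid$n_cols)
  alphas <- (seq_len(params$alpha_steps) - 0.5) / params$alpha_steps
  total_w <- 0
  for (k in which(use)) {
    w_seg <- Tt[k] / params$alpha_steps
    for (a in alphas) {
      mux <- (1 - a) * fixes$x[k] + a * fixes$x[k + 1]
      muy <- (1 - a) * fixes$y[k] + a * fixes$y[k + 1]
      v <- Tt[k] * a * (1 - a) * params$sigma2_m +
        ((1 - a)^2 + a^2) * params$delta^2
      P <- add_gaussian_local(P, grid, mux, muy, sqrt(v), w_seg)
    }
    total_w <- total_w + Tt[k]
  }
  mass <- P / total_w
  captured <- sum(mass)
  if (captured < 0.999)
    warnf("route grid captures only %.2f%% of the bridge mass", 100 * captured)
  grid$p <- mass / captured
  grid$captured <- captured
  grid$meta <- meta
  grid
}

#' Population-level migration route
#'
#' Cell-wise arithmetic (unweighted) mean of individual route UDs,
#' renormalized. UDs on congruent but different extents are embedded in their
#' common grid first.
#'
#' @param uds List of individual route `ud_grid`s.
#' @param season,year Metadata for the result.
#' @return A `ud_grid` with meta `animal_id = "population"`.
#' @export
population_route <- function(uds, season = NULL, year = NULL) {
  if (!length(uds)) stopf("no individual route UDs supplied")
  cg <- common_grid(uds)
  acc <- matrix(0, cg$n_rows, cg$n_cols)
  for (u in uds) acc <- acc + regrid_matrix(u$p, u, cg)
  p <- acc / length(uds)
  cg$p <- p / sum(p)
  cg$meta <- list(animal_id = "population", season = season, year = year,
                  n_individuals = length(uds))
  cg
}

#' Years-of-use raster for migration routes
#'
#' For each cell, counts the years whose route (the `level` isopleth of that
#' year's population UD) contains the cell.
#'
#' @param uds_by_year Named list (by year) of population route `ud_grid`s
#'   (>= 2 years).
#' @param level Isopleth level defining a route (default 0.95).
#' @return A list: grid geometry, integer `counts` matrix, `years`, `level`.
#' @export
route_years_of_use <- function(uds_by_year, level = 0.95) {
  if (length(uds_by_year) < 2) stopf("need at least 2 years of routes")
  isos <- lapply(uds_by_year, isopleth, level = level)
  cg <- common_grid(isos)
  counts <- matrix(0L, cg$n_rows, cg$n_cols)
  for (iso in isos)
    counts <- counts + regrid_matrix(iso$cells, iso, cg, fill = FALSE)
  list(x0 = cg$x0, y0 = cg$y0, cell_size = cg$cell_size,
       n_rows = cg$n_rows, n_cols = cg$n_cols,
       counts = counts, years = names(uds_by_year), level = level)
}
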