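# Fixed-kernel utilization distributions. The kernel is an isotropic
# bivariate Gaussian with a single scalar bandwidth h chosen by likelihood
# cross-validation: h maximizes the leave-one-out log-likelihood
# sum_i log f_{-i}(x_i; h). UDs are discretized on a regular grid
# (cell mass = mean kernel density at the cell centre times cell area,
# renormalized), and isopleths are highest-density cell sets.

#' Likelihood cross-validation bandwidth
#'
#' Maximizes the leave-one-out log-likelihood of an isotropic bivariate
#' Gaussian kernel density over a bounded range of bandwidths (coarse
#' log-spaced scan followed by golden-section refinement within the
#' bracketing interval).
#'
#' @param x,y Point coordinates in metres (>= 5 points, not all coincident).
#' @param h_range Optional search range c(h_min, h_max), metres. Defaults span
#'   a tenth of the median nearest-neighbour distance to the point-set
#'   diameter.
#' @param max_points Bandwidth selection uses at most this many points
#'   (systematic subsample) to bound the pairwise-distance cost.
#' @return Bandwidth h in metres, with the attained log-likelihood as
#'   attribute `"loglik"`.
#' @export
cvh_bandwidth <- function(x, y, h_range = NULL, max_points = 2000) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stopf("need at least 5 points to cross-validate a bandwidth")
  if (n > max_points) {
    idx <- unique(round(seq(1, n, length.out = max_points)))
    x <- x[idx]; y <- y[idx]; n <- length(x)
  }
  d2 <- as.matrix(stats::dist(cbind(x, y)))^2
  diam <- sqrt(max(d2))
  if (diam == 0) stopf("all points are coincident; CV likelihood is unbounded")
  if (is.null(h_range)) {
    nn <- apply(d2 + diag(Inf, n), 1, min)
    nnd <- sqrt(stats::median(nn[nn > 0]))
    if (!is.finite(nnd) || nnd == 0) nnd <- diam / n
    h_range <- c(max(nnd / 10, diam * 1e-6), diam)
  }
  loo_ll <- function(h) {
    s <- rowSums(exp(-d2 / (2 * h^2))) - 1    # subtract the self term
    if (any(s <= 0)) return(-1e300)
    sum(log(s)) - n * log((n - 1) * 2 * pi * h^2)
  }
  lg <- seq(log(h_range[1]), log(h_range[2]), length.out = 50)
  vals <- vapply(lg, function(l) loo_ll(exp(l)), 0)
  i <- which.max(vals)
  lo <- lg[max(i - 1, 1)]; hi <- lg[min(i + 1, length(lg))]
  opt <- stats::optimize(function(l) loo_ll(exp(l)), c(lo, hi),
                         maximum = TRUE, tol = 1e-7)
  h <- exp(opt$maximum)
  attr(h, "loglik") <- opt$objective
  h
}

#' Kernel utilization distribution on a grid
#'
#' Cell mass is the average over points of the isotropic Gaussian kernel
#' density evaluated at the cell centre, times the cell area, renormalized to
#' sum to one. Warns when the grid captures less than 99.9% of the kernel
#' mass.
#'
#' @param x,y Point coordinates, metres.
#' @param h Bandwidth, metres.
#' @param grid Optional `ud_grid` to evaluate on; built from the points with
#'   `cell_size` and a 3h margin when omitted.
#' @param cell_size Cell size used when `grid` is NULL (default 500 m).
#' @return A `ud_grid` with probability mass `p`.
#' @export
kde_ud <- function(x, y, h, grid = NULL, cell_size = 500) {
  if (is.null(grid)) grid <- make_grid(x, y, cell_size, margin = 4 * h)
  n <- length(x)
  cx <- grid_centers_x(grid)
  cy <- grid_centers_y(grid)
  gx <- exp(-outer(x, cx, "-")^2 / (2 * h^2))   # n x n_cols
  gy <- exp(-outer(y, cy, "-")^2 / (2 * h^2))   # n x n_rows
  dens <- crossprod(gy, gx) / (n * 2 * pi * h^2)  # n_rows x n_cols
  p <- dens * grid$cell_size^2
  captured <- sum(p)
  if (captured < 0.999)
    warnf("grid captures only %.2f%% of the kernel mass; enlarge the grid",
          100 * captured)
  grid$p <- p / captured
  grid$captured <- captured
  grid
}

#' Highest-density isopleth of a UD
#'
#' Selects the smallest set of highest-density cells whose cumulative mass
#' reaches `level` (cells sorted by mass, ties broken deterministically by
#' row-major index) and reports its area.
#'
#' @param ud A `ud_grid`.
#' @param level Mass fraction in (0, 1].
#' @return An object of class `isopleth`: grid geometry, logical cell mask,
#'   `level`, `area_km2` and the mass actually enclosed.
#' @export
isopleth <- function(ud, level) {
  if (level <= 0 || level > 1) stopf("isopleth level must be in (0, 1]")
  p <- ud$p
  rm_idx <- (row(p) - 1) * ncol(p) + col(p)     # row-major tie-break
  ord <- order(-as.vector(p), as.vector(rm_idx))
  if (level >= 1) {
    sel <- which(p > 0)
  } else {
    cum <- cumsum(p[ord])
    k <- which(cum >= level - 1e-9)[1]
    if (is.na(k)) k <- length(ord)
    sel <- ord[seq_len(k)]
    sel <- sel[p[sel] > 0]
  }
  mask <- matrix(FALSE, nrow(p), ncol(p))
  mask[sel] <- TRUE
  structure(list(x0 = ud$x0, y0 = ud$y0, cell_size = ud$cell_size,
                 n_rows = ud$n_rows, n_cols = ud$n_cols,
                 level = level, cells = mask,
                 area_km2 = length(sel) * cell_area_km2(ud),
                 mass = sum(p[sel]), meta = ud$meta),
            class = "isopleth")
}

#' Test whether points fall inside an isopleth region
#'
#' @param iso An `isopleth`.
#' @param x,y Point coordinates, metres.
#' @return Logical vector (FALSE outside the grid).
#' @export
point_in_isopleth <- function(iso, x, y) {
  rc <- cell_of(iso, x, y)
  out <- logical(length(x))
  ok <- !is.na(rc$row)
  out[ok] <- iso$cells[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' @export
print.isopleth <- function(x, ...) {
  cat(sprintf("isopleth: level %.2f, area %.1f km^2 (%d cells of %g m)\n",
              x$level, x$area_km2, sum(x$cells), x$cell_size))
  invisible(x)
}

#' Pooled population seasonal range
#'
#' Pools per-season fixes across individuals (after thinning each animal's
#' fixes to at least `min_gap_h` apart so high-frequency summer sampling does
#' not under-smooth the kernel), fits a single fixed-kernel UD with CVh
#' bandwidth, and extracts isopleths. The 90% isopleth is the seasonal range;
#' the 80% isopleth delineates the beginning of fall migration routes.
#'
#' @param fixes Fix data.frame (one season, one year, >= 1 animal).
#' @param levels Isopleth levels (default 0.80 and 0.90).
#' @param cell_size Grid cell size, metres (default 500, commensurate with the
#'   migration-route grid).
#' @param min_gap_h Thinning interval, hours (default 47).
#' @param h Optional fixed bandwidth; CVh-selected when NULL.
#' @return List with `ud`, `h`, named `isopleths`, `n_animals`, `n_points`,
#'   and `notes` (provenance warnings).
#' @export
pooled_seasonal_range <- function(fixes, levels = c(0.80, 0.90),
                                  cell_size = 500, min_gap_h = 47, h = NULL) {
  thinned <- thin_by_interval(fixes, min_gap_h)
  n_animals <- length(unique(thinned$animal_id))
  notes <- character(0)
  if (n_animals < 2) {
    notes <- "fewer than 2 animals contribute to the pooled range"
    warnf(notes)
  }
  if (is.null(h)) h <- cvh_bandwidth(thinned$x, thinned$y)
  ud <- kde_ud(thinned$x, thinned$y, h, cell_size = cell_size)
  isos <- lapply(levels, function(l) isopleth(ud, l))
  names(isos) <- sprintf("%g", 100 * levels)
  list(ud = ud, h = as.numeric(h), isopleths = isos,
       n_animals = n_animals, n_points = nrow(thinned), notes = notes)
}
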