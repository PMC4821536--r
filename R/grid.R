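# Regular planar grids holding discretized utilization distributions.
#
# Convention: origin (x0, y0) at the lower-left corner, row 1 is the
# southernmost row, column 1 the westernmost column, half-open cells
# [x0 + (j-1)c, x0 + j*c) x [y0 + (i-1)c, y0 + i*c). Origins are snapped to
# multiples of the cell size so grids built independently with the same cell
# size are congruent and can be compared cell-by-cell.

#' Create a utilization-distribution grid
#'
#' @param x0,y0 Lower-left origin in metres.
#' @param cell_size Cell edge length in metres.
#' @param n_rows,n_cols Grid dimensions.
#' @param p Optional `n_rows x n_cols` matrix of per-cell probability mass
#'   (row 1 = southernmost row).
#' @param meta Optional named list of metadata (animal id, season, year).
#' @return An object of class `ud_grid`.
#' @export
ud_grid <- function(x0, y0, cell_size, n_rows, n_cols, p = NULL, meta = list()) {
  if (cell_size <= 0) stopf("cell_size must be positive")
  if (is.null(p)) p <- matrix(0, n_rows, n_cols)
  stopifnot(nrow(p) == n_rows, ncol(p) == n_cols)
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size,
                 n_rows = n_rows, n_cols = n_cols, p = p, meta = meta),
            class = "ud_grid")
}

#' Build an empty grid covering a point set with a margin
#'
#' The origin is snapped down to a multiple of `cell_size`, so all grids with
#' the same cell size share cell boundaries.
#'
#' @param x,y Point coordinates in metres.
#' @param cell_size Cell edge length in metres.
#' @param margin Margin added on every side, metres.
#' @return An empty `ud_grid`.
#' @export
make_grid <- function(x, y, cell_size, margin) {
  x0 <- floor((min(x) - margin) / cell_size) * cell_size
  y0 <- floor((min(y) - margin) / cell_size) * cell_size
  n_cols <- ceiling((max(x) + margin - x0) / cell_size)
  n_rows <- ceiling((max(y) + margin - y0) / cell_size)
  ud_grid(x0, y0, cell_size, max(n_rows, 1L), max(n_cols, 1L))
}

grid_centers_x <- function(g) g$x0 + (seq_len(g$n_cols) - 0.5) * g$cell_size
grid_centers_y <- function(g) g$y0 + (seq_len(g$n_rows) - 0.5) * g$cell_size

cell_area_km2 <- function(g) g$cell_size^2 / 1e6

# Row/column of the cells containing (x, y); NA outside the grid.
cell_of <- function(g, x, y) {
  col <- floor((x - g$x0) / g$cell_size) + 1
  row <- floor((y - g$y0) / g$cell_size) + 1
  bad <- col < 1 | col > g$n_cols | row < 1 | row > g$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(c(a$x0, a$y0, a$cell_size, a$n_rows, a$n_cols),
                   c(b$x0, b$y0, b$cell_size, b$n_rows, b$n_cols)))
}

congruent_grids <- function(a, b, tol = 1e-6) {
  a$cell_size == b$cell_size &&
    abs((a$x0 - b$x0) / a$cell_size - round((a$x0 - b$x0) / a$cell_size)) < tol &&
    abs((a$y0 - b$y0) / a$cell_size - round((a$y0 - b$y0) / a$cell_size)) < tol
}

# Smallest grid covering all input grids (equal, congruent cell sizes only).
common_grid <- function(grids) {
  cs <- unique(vapply(grids, function(g) g$cell_size, 0))
  if (length(cs) != 1) stopf("grids have different cell sizes; cannot align")
  for (g in grids[-1]) if (!congruent_grids(grids[[1]], g))
    stopf("grid origins are not congruent modulo the cell size")
  x0 <- min(vapply(grids, function(g) g$x0, 0))
  y0 <- min(vapply(grids, function(g) g$y0, 0))
  xmax <- max(vapply(grids, function(g) g$x0 + g$n_cols * cs, 0))
  ymax <- max(vapply(grids, function(g) g$y0 + g$n_rows * cs, 0))
  ud_grid(x0, y0, cs, round((ymax - y0) / cs), round((xmax - x0) / cs))
}

# Place the mass (or mask) matrix of `g` into target grid `tg` (congruent).
regrid_matrix <- function(m, g, tg, fill = 0) {
  out <- matrix(fill, tg$n_rows, tg$n_cols)
  dr <- round((g$y0 - tg$y0) / g$cell_size)
  dc <- round((g$x0 - tg$x0) / g$cell_size)
  out[dr + seq_len(g$n_rows), dc + seq_len(g$n_cols)] <- m
  out
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("ud_grid: %d x %d cells of %g m, origin (%g, %g), total mass %.6f\n",
              x$n_rows, x$n_cols, x$cell_size, x$x0, x$y0, sum(x$p)))
  invisible(x)
}
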