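#' Uniform finite-volume grid on the opinion interval [0, 1]
#'
#' Cells are half-open `[a, b)` with the final cell closed, so that a score
#' of exactly 1 is kept. Cell centers sit at midpoints; `dw = 1/n`.
#'
#' @param n Number of cells (>= 2).
#' @return An object of class `opinion_grid1d` with fields `n`, `dw`,
#'   `edges` (length `n + 1`) and `centers` (length `n`).
#' @export
opinion_grid1d <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("grid needs at least 2 cells")
  dw <- 1 / n
  structure(
    list(n = n, dw = dw,
         edges = seq(0, 1, length.out = n + 1L),
         centers = (seq_len(n) - 0.5) * dw),
    class = "opinion_grid1d")
}

#' Uniform tensor grid on the opinion square [0, 1]^2
#'
#' The product of two [opinion_grid1d()] grids: axis 1 is the positive
#' score `w+`, axis 2 the negative score `w-`. Cell `(i, j)` covers
#' `[(i-1) dw+, i dw+) x [(j-1) dw-, j dw-)`, with the last cell on each
#' axis right-closed.
#'
#' @param n_plus,n_minus Cell counts per axis (default 20, the binning used
#'   throughout the sentiment-data pipeline).
#' @return An object of class `opinion_grid2d` with the two 1-D grids in
#'   `$plus` and `$minus` and the cell area in `$cell_area`.
#' @export
opinion_grid2d <- function(n_plus = 20, n_minus = 20) {
  gp <- opinion_grid1d(n_plus)
  gm <- opinion_grid1d(n_minus)
  structure(
    list(plus = gp, minus = gm, cell_area = gp$dw * gm$dw),
    class = "opinion_grid2d")
}

#' @export
print.opinion_grid1d <- function(x, ...) {
  cat(sprintf("<opinion_grid1d> %d cells on [0,1], dw = %g\n", x$n, x$dw))
  invisible(x)
}

#' @export
print.opinion_grid2d <- function(x, ...) {
  cat(sprintf("<opinion_grid2d> %d x %d cells on [0,1]^2\n",
              x$plus$n, x$minus$n))
  invisible(x)
}

# Map scores in [0,1] to cell indices; 1.0 goes to the last cell.
.cell_index <- function(w, grid) {
  i <- findInterval(w, grid$edges, rightmost.closed = TRUE)
  pmin.int(pmax.int(i, 1L), grid$n)
}

#' Construct a cell-averaged density field on the opinion square
#'
#' @param grid An [opinion_grid2d()].
#' @param values `n_plus x n_minus` matrix of nonnegative cell-averaged
#'   density values (row i = positive-score cell i).
#' @param n_records Optional count of raw records behind the field.
#' @return Object of class `density_field2d` with `grid`, `values`, `mass`.
#' @export
density_field2d <- function(grid, values, n_records = NA_integer_) {
  stopifnot(inherits(grid, "opinion_grid2d"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$plus$n, grid$minus$n)))
    stop("values must be n_plus x n_minus")
  if (any(values < 0)) stop("density values must be nonnegative")
  structure(
    list(grid = grid, values = values,
         mass = sum(values) * grid$cell_area,
         n_records = n_records),
    class = "density_field2d")
}

#' @export
print.density_field2d <- function(x, ...) {
  cat(sprintf("<density_field2d> %d x %d cells, mass = %.6g\n",
              x$grid$plus$n, x$grid$minus$n, x$mass))
  invisible(x)
}
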