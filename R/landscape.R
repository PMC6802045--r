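#' Raster landscapes of prey biomass production
#'
#' A `landscape_grid` holds a raster of monthly prey biomass production
#' (kg/month/cell) over a protected area, together with an inside-area mask
#' and the Euclidean distance of every inside cell to the area border. Cells
#' are 250 m squares by default (62,500 m^2 each), matching the resolution of
#' ungulate prey data for the Nepal lowlands. Cells are stored as row-major
#' vectors: cell `k` sits at row `(k - 1) %/% ncol + 1`, column
#' `(k - 1) %% ncol + 1`.
#'
#' The border distance of an inside cell is the distance from its centre to
#' the nearest outside cell centre (a one-cell virtual ring beyond the grid
#' edge counts as outside, so masks touching the edge still have a border).
#'
#' @param prey numeric vector (row-major) or matrix of prey biomass
#'   production, kg/month/cell; non-negative.
#' @param mask logical vector or matrix: `TRUE` for cells inside the
#'   protected area.
#' @param nrow,ncol grid dimensions (taken from `prey` when it is a matrix).
#' @param cell_side cell side length in metres.
#' @param xll,yll lower-left corner coordinates carried through raster I/O.
#' @return An object of class `landscape_grid`: a list with elements `nrow`,
#'   `ncol`, `cell_side`, `mask`, `prey`, `dist_border` (metres; 0 outside),
#'   `inside` (integer cell indices), `xll`, `yll`.
#' @export
landscape_grid <- function(prey, mask, nrow = NULL, ncol = NULL,
                           cell_side = 250, xll = 0, yll = 0) {
  if (is.matrix(prey)) {
    nrow <- dim(prey)[1]
    ncol <- dim(prey)[2]
    prey <- as.vector(t(prey))
  }
  if (is.matrix(mask)) mask <- as.vector(t(mask))
  if (is.null(nrow) || is.null(ncol))
    stop("supply matrices or explicit nrow/ncol")
  if (cell_side <= 0) stop("cell_side must be positive")
  prey <- as.numeric(prey)
  mask <- as.logical(mask)
  if (length(prey) != nrow * ncol || length(mask) != nrow * ncol)
    stop("prey and mask must have nrow * ncol cells")
  if (anyNA(mask)) stop("mask must not contain NA")
  if (any(prey[mask] < 0, na.rm = TRUE)) stop("prey must be non-negative")
  prey[!mask] <- 0
  if (!any(mask)) stop("empty landscape: no cells inside the mask")
  grid <- structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         cell_side = cell_side, mask = mask, prey = prey,
         dist_border = NULL, inside = which(mask),
         xll = xll, yll = yll),
    class = "landscape_grid")
  compute_distance_to_border(grid)
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid: %d x %d cells (%g m side), %d inside (%.1f km2)\n",
              x$nrow, x$ncol, x$cell_side, length(x$inside),
              length(x$inside) * cell_area_km2(x)))
  pr <- x$prey[x$inside]
  cat(sprintf("prey kg/month/cell: min %.3g  mean %.3g  max %.3g  total %.4g\n",
              min(pr), mean(pr), max(pr), sum(pr)))
  cat(sprintf("border distance: max %.0f m\n", max(x$dist_border)))
  invisible(x)
}

#' @export
as.matrix.landscape_grid <- function(x, field = c("prey", "mask", "dist_border"),
                                     ...) {
  field <- match.arg(field)
  matrix(x[[field]], nrow = x$nrow, ncol = x$ncol, byrow = TRUE)
}

cell_area_km2 <- function(grid) (grid$cell_side / 1000)^2

#' Total prey biomass production inside a landscape
#' @param grid a [landscape_grid()].
#' @return kg/month summed over inside cells.
#' @export
total_prey <- function(grid) sum(grid$prey[grid$inside])

#' Row/column coordinates of cell indices
#' @param grid a [landscape_grid()].
#' @param cells integer cell indices (1-based, row-major).
#' @return two-column matrix of 1-based (row, col).
#' @export
cell_rowcol <- function(grid, cells) {
  cbind(row = (cells - 1L) %/% grid$ncol + 1L,
        col = (cells - 1L) %% grid$ncol + 1L)
}

#' Centre-to-centre distance between cells, in metres
#' @inheritParams cell_rowcol
#' @param from single cell index.
#' @export
cell_distance <- function(grid, from, cells) {
  a <- cell_rowcol(grid, from)
  b <- cell_rowcol(grid, cells)
  sqrt((b[, 1] - a[1])^2 + (b[, 2] - a[2])^2) * grid$cell_side
}

#' Stylized circular protected area with uniform prey
#'
#' Rasterizes a disc of the given area: a cell is inside iff its centre lies
#' within the analytic disc of radius `sqrt(area / pi)`. Every inside cell
#' receives the same prey biomass production, by default the Chitwan mean of
#' 4.84 kg/month/cell.
#'
#' @param area area of the protected area in km^2.
#' @param prey_per_cell prey biomass production assigned to every inside
#'   cell, kg/month.
#' @param cell_side cell side in metres.
#' @return a [landscape_grid()].
#' @examples
#' circ <- make_circle_landscape(1000, 4.84)
#' length(circ$inside) # about 16,000 cells
#' @export
make_circle_landscape <- function(area = 1000, prey_per_cell = 4.84,
                                  cell_side = 250) {
  if (area <= 0 || cell_side <= 0) stop("area and cell_side must be positive")
  if (prey_per_cell < 0) stop("prey_per_cell must be non-negative")
  r_m <- sqrt(area / pi) * 1000
  r_cells <- r_m / cell_side
  half <- ceiling(r_cells) + 1L
  n <- 2L * half + 1L
  ctr <- half + 1L
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  mask <- (rows - ctr)^2 + (cols - ctr)^2 <= r_cells^2
  landscape_grid(prey = ifelse(mask, prey_per_cell, 0), mask = mask,
                 cell_side = cell_side)
}

#' Distance of every inside cell to the landscape border
#'
#' Fills the `dist_border` field: for each inside cell, the minimum Euclidean
#' distance from its centre to the nearest outside cell centre (metres). A
#' virtual one-cell outside ring beyond the grid edge is included so the field
#' is defined even for masks that fill the whole grid.
#'
#' @param grid a [landscape_grid()].
#' @return the grid with `dist_border` populated.
#' @export
compute_distance_to_border <- function(grid) {
  if (!any(grid$mask)) stop("empty landscape: no cells inside the mask")
  grid$dist_border <- cpp_dist_border(grid$mask, grid$nrow, grid$ncol,
                                      grid$cell_side)
  grid
}

#' Maximum border distance over inside cells
#' @param grid a [landscape_grid()].
#' @export
d_max <- function(grid) max(grid$dist_border[grid$inside])

# separable Gaussian blur of a matrix, edges padded by replication
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Synthetic spatially autocorrelated prey landscape
#'
#' Generates a heterogeneous prey surface with a controlled value envelope, as
#' a synthetic stand-in emulating the statistical envelope of a real
#' protected-area prey raster (minimum 2.05, maximum 10.46, mean 4.84
#' kg/month/cell for Chitwan National Park). The surface is Gaussian-smoothed
#' uniform noise rescaled to `[prey_min, prey_max]`; a monotone power
#' transform is solved so the realized mean matches `prey_mean`.
#'
#' @param area area of the (circular) protected area in km^2.
#' @param prey_min,prey_max,prey_mean target envelope, kg/month/cell;
#'   requires `prey_min < prey_mean < prey_max`.
#' @param correlation_range smoothing scale in metres (Gaussian sigma is
#'   `correlation_range / (2 * cell_side)` cells).
#' @param seed integer seed; the surface is deterministic given the seed.
#' @param cell_side cell side in metres.
#' @return a [landscape_grid()].
#' @export
make_synthetic_heterogeneous_landscape <- function(area = 1239,
                                                   prey_min = 2.05,
                                                   prey_max = 10.46,
                                                   prey_mean = 4.84,
                                                   correlation_range = 2000,
                                                   seed = 1,
                                                   cell_side = 250) {
  if (!(prey_min < prey_mean && prey_mean < prey_max))
    stop("infeasible envelope: need prey_min < prey_mean < prey_max")
  base <- make_circle_landscape(area, prey_per_cell = 1, cell_side = cell_side)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noise <- matrix(runif(base$nrow * base$ncol), base$nrow, base$ncol)
  sm <- gaussian_blur(noise, sigma = correlation_range / (2 * cell_side))
  v <- as.vector(t(sm))[base$inside]
  t01 <- (v - min(v)) / (max(v) - min(v))
  mean_at <- function(g) mean(prey_min + (prey_max - prey_min) * t01^g)
  gamma <- uniroot(function(g) mean_at(g) - prey_mean,
                   lower = 1e-3, upper = 50, tol = 1e-10)$root
  prey <- numeric(base$nrow * base$ncol)
  prey[base$inside] <- prey_min + (prey_max - prey_min) * t01^gamma
  landscape_grid(prey = prey, mask = base$mask, nrow = base$nrow,
                 ncol = base$ncol, cell_side = cell_side)
}

#' Per-cell table of a landscape
#'
#' @param grid a [landscape_grid()].
#' @param inside_only drop outside cells.
#' @return data.frame with `row`, `col`, `prey`, `dist_border`.
#' @export
landscape_table <- function(grid, inside_only = TRUE) {
  cells <- if (inside_only) grid$inside else seq_len(grid$nrow * grid$ncol)
  rc <- cell_rowcol(grid, cells)
  data.frame(row = rc[, 1], col = rc[, 2], prey = grid$prey[cells],
             dist_border = grid$dist_border[cells])
}
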