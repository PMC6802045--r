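#' Read an ESRI ASCII grid as a landscape
#'
#' Parses the `.asc` dialect with a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' whitespace-separated cell values, top row first. `NODATA` cells become
#' outside-mask cells with prey 0.
#'
#' @param path file path.
#' @return a [landscape_grid()].
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || !(tolower(parts[1]) %in% keys))
      stop(sprintf("malformed header at line %d: '%s'", i, lines[i]))
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val))
      stop(sprintf("malformed header at line %d: non-numeric value '%s'",
                   i, parts[2]))
    hdr[[tolower(parts[1])]] <- val
  }
  for (k in keys) if (is.null(hdr[[k]]))
    stop(sprintf("malformed header: missing '%s'", k))
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("expected %d data rows, found %d", nr, length(body)))
  vals <- numeric(0)
  for (i in seq_along(body)) {
    row <- strsplit(trimws(body[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(row))
    if (anyNA(v))
      stop(sprintf("parse error at line %d: non-numeric cell '%s'",
                   i + 6L, row[which(is.na(v))[1]]))
    if (length(v) != nc)
      stop(sprintf("parse error at line %d: expected %d columns, found %d",
                   i + 6L, nc, length(v)))
    vals <- c(vals, v)
  }
  mask <- vals != hdr$nodata_value
  prey <- ifelse(mask, vals, 0)
  landscape_grid(prey = prey, mask = mask, nrow = nr, ncol = nc,
                 cell_side = hdr$cellsize, xll = hdr$xllcorner,
                 yll = hdr$yllcorner)
}

#' Write a landscape (or any per-cell field) as an ESRI ASCII grid
#'
#' Values are printed at full precision (`%.17g`) so a write/read round trip
#' is bit-faithful. Outside cells are written as the NODATA value.
#'
#' @param grid a [landscape_grid()].
#' @param path output file path.
#' @param field per-cell vector to write; defaults to prey.
#' @param nodata NODATA value for outside cells.
#' @export
write_raster <- function(grid, path, field = grid$prey, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncol),
               sprintf("nrows %d", grid$nrow),
               sprintf("xllcorner %.17g", grid$xll),
               sprintf("yllcorner %.17g", grid$yll),
               sprintf("cellsize %.17g", grid$cell_side),
               sprintf("NODATA_value %g", nodata)), con)
  m <- matrix(ifelse(grid$mask, field, nodata), grid$nrow, grid$ncol,
              byrow = TRUE)
  for (r in seq_len(grid$nrow))
    writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
  invisible(path)
}
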