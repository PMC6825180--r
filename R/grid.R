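#' Predictor grid container
#'
#' A stack of named predictor rasters on a common regular lon/lat lattice,
#' with a shared validity mask. Cells are indexed row-major from the
#' north-west corner; matrix row 1 is the northernmost row. Cell-edge
#' intervals are half-open: a point on the eastern/southern edge of a cell
#' belongs to the next cell, except on the outermost grid edge.
#'
#' @param xmin,ymin coordinates (decimal degrees) of the south-west corner
#'   of the grid (cell edges, not centers).
#' @param cell_size cell edge length in degrees (> 0).
#' @param nx,ny number of columns / rows (each >= 2).
#' @param layers named list of `ny x nx` numeric matrices, row 1 = north.
#' @param mask logical `ny x nx` matrix, `TRUE` where data are valid.
#'   Defaults to all valid.
#' @return An object of class `predictor_grid`.
#' @export
predictor_grid <- function(xmin, ymin, cell_size, nx, ny, layers = list(),
                           mask = NULL) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L)
    stop("grid extent must span at least 2x2 cells", call. = FALSE)
  if (length(layers)) {
    if (is.null(names(layers)) || any(!nzchar(names(layers))))
      stop("all layers must be named", call. = FALSE)
    for (nm in names(layers)) {
      d <- dim(layers[[nm]])
      if (is.null(d) || d[1] != ny || d[2] != nx)
        stop("layer '", nm, "' is not a ", ny, "x", nx, " matrix",
             call. = FALSE)
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, ny, nx)
  stopifnot(is.logical(mask), all(dim(mask) == c(ny, nx)))
  structure(
    list(xmin = xmin, ymin = ymin, cell_size = cell_size,
         nx = nx, ny = ny, layers = layers, mask = mask),
    class = "predictor_grid")
}

#' @method print predictor_grid
#' @export
print.predictor_grid <- function(x, ...) {
  cat("predictor_grid:", x$ny, "rows x", x$nx, "cols, cell",
      format(x$cell_size), "deg\n")
  cat("  extent: lon [", x$xmin, ",", x$xmin + x$nx * x$cell_size,
      "] lat [", x$ymin, ",", x$ymin + x$ny * x$cell_size, "]\n")
  cat("  layers:", if (length(x$layers)) paste(names(x$layers),
      collapse = ", ") else "(none)", "\n")
  cat("  valid cells:", sum(x$mask), "/", length(x$mask), "\n")
  invisible(x)
}

#' Cell-center coordinates
#'
#' @param grid a `predictor_grid`.
#' @return `grid_cell_centers`: a data frame of all cell centers with
#'   columns `row`, `col`, `lon`, `lat`.
#' @export
grid_cell_centers <- function(grid) {
  rc <- expand.grid(row = seq_len(grid$ny), col = seq_len(grid$nx))
  data.frame(row = rc$row, col = rc$col,
             lon = grid$xmin + (rc$col - 0.5) * grid$cell_size,
             lat = grid$ymin + (grid$ny - rc$row + 0.5) * grid$cell_size)
}

#' Locate points on the grid
#'
#' Maps lon/lat points to (row, col) cell indices. Points on interior cell
#' edges go to the cell to the east/south (half-open convention); points
#' outside the extent get `NA`.
#'
#' @param grid a `predictor_grid`.
#' @param lon,lat numeric vectors of coordinates.
#' @return data frame with columns `row`, `col`.
#' @export
grid_locate <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$cell_size) + 1
  ymax <- grid$ymin + grid$ny * grid$cell_size
  row <- floor((ymax - lat) / grid$cell_size) + 1
  # points exactly on the outer east/north edge belong to the last cell
  col[lon == grid$xmin + grid$nx * grid$cell_size] <- grid$nx
  row[lat == grid$ymin] <- grid$ny
  bad <- col < 1 | col > grid$nx | row < 1 | row > grid$ny |
    is.na(lon) | is.na(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Write / read a grid layer as an ESRI ASCII raster
#'
#' Plain-text single-band georeferenced grid (`.asc`): a 6-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values from north to south. Masked cells are written as the
#' no-data value. Values are written with full precision (`format = "%.17g"`)
#' so a write/read round trip is bit-exact.
#'
#' @param grid a `predictor_grid`.
#' @param layer layer name to write.
#' @param path output file path.
#' @param nodata no-data sentinel value.
#' @export
write_ascii_grid <- function(grid, layer, path, nodata = -9999) {
  if (!layer %in% names(grid$layers))
    stop("no layer named '", layer, "'", call. = FALSE)
  m <- grid$layers[[layer]]
  m[!grid$mask] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$nx),
    paste("nrows", grid$ny),
    paste("xllcorner", sprintf("%.17g", grid$xmin)),
    paste("yllcorner", sprintf("%.17g", grid$ymin)),
    paste("cellsize", sprintf("%.17g", grid$cell_size)),
    paste("NODATA_value", sprintf("%.17g", nodata))), con)
  for (i in seq_len(grid$ny))
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param paths named character vector of `.asc` files (names become layer
#'   names).
#' @return `read_ascii_grids`: a `predictor_grid` with one layer per file;
#'   the mask marks cells that are no-data in any layer.
#' @export
read_ascii_grids <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("`paths` must be a named vector (names become layer names)",
         call. = FALSE)
  layers <- list(); hdr0 <- NULL; mask <- NULL; nodata <- NULL
  for (nm in names(paths)) {
    lines <- readLines(paths[[nm]])
    hdr <- list()
    for (k in 1:6) {
      parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    }
    vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
                 quiet = TRUE)
    m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
    if (is.null(hdr0)) {
      hdr0 <- hdr
      mask <- matrix(TRUE, hdr$nrows, hdr$ncols)
    } else if (!isTRUE(all.equal(unlist(hdr0), unlist(hdr)))) {
      stop("layer '", nm, "' is not on the common lattice", call. = FALSE)
    }
    nd <- m == hdr$nodata_value
    m[nd] <- NA_real_
    mask <- mask & !nd
    layers[[nm]] <- m
  }
  predictor_grid(hdr0$xllcorner, hdr0$yllcorner, hdr0$cellsize,
                 hdr0$ncols, hdr0$nrows, layers = layers, mask = mask)
}
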