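#' Lightweight single-band raster
#'
#' `fever_raster()` wraps a numeric matrix together with its georeferencing:
#' cell size in metres and the coordinate of the lower-left corner of the
#' grid. Rows are stored north-to-south (row 1 is the northernmost row) and
#' coordinates refer to cell centres. `NA` cells are nodata.
#'
#' @param values numeric matrix (row 1 = north).
#' @param cell_size cell edge length in metres.
#' @param xll,yll coordinates of the lower-left grid corner in metres.
#' @param layer optional character label (e.g. `"travel_time_min"`).
#' @return An object of class `fever_raster`.
#' @export
fever_raster <- function(values, cell_size, xll = 0, yll = 0, layer = NULL) {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll), layer = layer),
    class = "fever_raster"
  )
}

#' @export
print.fever_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<fever_raster%s> %d x %d cells, %.0f m resolution\n",
              if (is.null(x$layer)) "" else paste0(": ", x$layer),
              nrow(v), ncol(v), x$cell_size))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.fever_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  d <- dim(r$values)
  c(xmin = r$xll, xmax = r$xll + d[2] * r$cell_size,
    ymin = r$yll, ymax = r$yll + d[1] * r$cell_size)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$cell_size, a$xll, a$yll),
                     c(b$cell_size, b$xll, b$yll)))
}

#' Map point coordinates to raster cells and back
#'
#' `cell_at()` returns the (row, col) of the cell containing each point;
#' `cell_centre()` returns the centre coordinate of given cells. Points on a
#' cell boundary belong to the cell to the north-east of the boundary,
#' consistent with a half-open cell footprint.
#'
#' @param r a [fever_raster()].
#' @param x,y point coordinates in metres.
#' @return `cell_at()`: a two-column integer matrix (row, col).
#' @keywords internal
cell_at <- function(r, x, y) {
  ext <- raster_extent(r)
  d <- dim(r$values)
  if (any(x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"])) {
    bad <- which(x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"])
    stop("coordinates outside raster extent (point ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  col <- pmin(d[2], floor((x - r$xll) / r$cell_size) + 1L)
  row <- pmin(d[1], floor((ext["ymax"] - y) / r$cell_size) + 1L)
  cbind(row = pmax(1L, as.integer(row)), col = pmax(1L, as.integer(col)))
}

cell_centre <- function(r, row, col) {
  ext <- raster_extent(r)
  cbind(x = r$xll + (col - 0.5) * r$cell_size,
        y = ext["ymax"] - (row - 0.5) * r$cell_size)
}

#' Convert a raster to a tidy tibble
#'
#' One row per cell with cell-centre coordinates, useful for ggplot2.
#'
#' @param x a [fever_raster()].
#' @param ... unused.
#' @return A tibble with columns `x`, `y`, `row`, `col`, `value`.
#' @method as_tibble fever_raster
#' @export
as_tibble.fever_raster <- function(x, ...) {
  d <- dim(x$values)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  ctr <- cell_centre(x, grid$row, grid$col)
  tibble::tibble(x = ctr[, "x"], y = ctr[, "y"],
                 row = grid$row, col = grid$col,
                 value = x$values[cbind(grid$row, grid$col)])
}

#' Read and write rasters as ESRI ASCII grids
#'
#' A plain-text interchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' whitespace-separated values, north row first — the layout this package
#' uses internally.
#'
#' @param r a [fever_raster()].
#' @param path file path (conventionally `.asc`).
#' @return `read_ascii_grid()` returns a [fever_raster()]; `write_ascii_grid()`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  d <- dim(r$values)
  hdr <- c(paste("ncols", d[2]), paste("nrows", d[1]),
           paste("xllcorner", format(r$xll, digits = 15)),
           paste("yllcorner", format(r$yll, digits = 15)),
           paste("cellsize", format(r$cell_size, digits = 15)),
           "NODATA_value -9999")
  v <- r$values
  v[is.na(v)] <- -9999
  rows <- apply(v, 1, function(z) paste(format(z, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param layer optional layer label attached to the result.
#' @export
read_ascii_grid <- function(path, layer = NULL) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  body <- lines[-(1:6)]
  v <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(nrow(v) == val["nrows"], ncol(v) == val["ncols"])
  v[v == val["nodata_value"]] <- NA_real_
  fever_raster(v, cell_size = val["cellsize"],
               xll = val["xllcorner"], yll = val["yllcorner"], layer = layer)
}
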