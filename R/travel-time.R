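#' Default land-class travel speeds
#'
#' Walking speeds (km/h) on flat ground per land class, used when building a
#' friction surface. Values follow the conventions of accessibility
#' modelling practice: open grassland and cropland are walked at a typical
#' flat-ground pace, forest more slowly, wetland slowest. Roads override the
#' land class with motorised travel.
#'
#' @return Named numeric vector of km/h.
#' @export
default_speed_table <- function() {
  c(grassland = 5, cropland = 4.5, forest = 3, wetland = 1.5)
}

# Tobler hiking factor, normalised to 1 on flat ground: speed multiplier
# exp(-3.5 * |s + 0.05|) / exp(-3.5 * 0.05) for slope magnitude s (rise/run).
tobler_factor <- function(slope) {
  exp(-3.5 * abs(slope + 0.05)) / exp(-3.5 * 0.05)
}

# Steepest slope magnitude (rise/run) per cell over the 8 neighbours.
steepest_slope <- function(elev, cell_size) {
  nr <- nrow(elev); nc <- ncol(elev)
  s <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    run <- cell_size * sqrt(dr^2 + dc^2)
    s <- pmax(s, abs(elev[rs, cs, drop = FALSE] - elev) / run)
  }
  s
}

#' Build a friction (traversal-speed) surface
#'
#' Combines land class, road network and elevation into a per-cell travel
#' speed in km/h. Road cells take the motorised `road_speed`, independent of
#' slope. Off-road cells take their land-class walking speed scaled by the
#' Tobler hiking factor evaluated at the cell's steepest slope, so steep
#' terrain is traversed more slowly. Classes flagged non-walking in
#' `walking` skip the slope correction.
#'
#' @param land_class [fever_raster()] of integer class codes.
#' @param roads [fever_raster()] road mask (1 = road).
#' @param elevation [fever_raster()] of elevation in metres.
#' @param speed_table named km/h per land-class name (see
#'   [default_speed_table()]).
#' @param road_speed motorised speed on road cells, km/h.
#' @param walking named logical per class; `TRUE` (default for every class)
#'   applies the slope correction.
#' @param class_names character vector mapping class code `i` to
#'   `class_names[i]`; defaults to `names(speed_table)`.
#' @return A [fever_raster()] of speeds (km/h), layer `"speed_kmh"`.
#' @export
build_friction <- function(land_class, roads, elevation, speed_table = default_speed_table(),
                           road_speed = 60, walking = NULL, class_names = NULL) {
  stopifnot(inherits(land_class, "fever_raster"))
  if (!same_grid(land_class, roads) || !same_grid(land_class, elevation))
    stop("land class, road and elevation rasters must be co-registered", call. = FALSE)
  class_names <- class_names %||% names(speed_table)
  codes <- sort(unique(stats::na.omit(as.vector(land_class$values))))
  if (any(codes < 1 | codes > length(class_names)))
    stop("unmapped land class code(s): ",
         paste(setdiff(codes, seq_along(class_names)), collapse = ", "), call. = FALSE)
  used <- class_names[codes]
  missing_cls <- setdiff(used, names(speed_table))
  if (length(missing_cls) > 0)
    stop("land class(es) missing from speed table: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  walking <- walking %||% stats::setNames(rep(TRUE, length(class_names)), class_names)

  v <- land_class$values
  speed <- matrix(speed_table[class_names[v]], nrow(v), ncol(v))
  walk <- matrix(walking[class_names[v]], nrow(v), ncol(v))
  walk[is.na(walk)] <- FALSE
  slope <- steepest_slope(elevation$values, land_class$cell_size)
  speed[walk] <- speed[walk] * tobler_factor(slope[walk])
  speed[roads$values == 1] <- road_speed
  speed[is.na(v)] <- NA_real_
  fever_raster(speed, land_class$cell_size, land_class$xll, land_class$yll,
               layer = "speed_kmh")
}

# 8-connected grid edges over traversable cells; cost in minutes uses the
# harmonic-mean speed of the two cells (time-additive across the boundary).
grid_edges <- function(speed, cell_size) {
  nr <- nrow(speed); nc <- ncol(speed)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  ok <- !is.na(speed) & speed > 0
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- as.vector(idx[r1, c1, drop = FALSE])
    b <- as.vector(idx[r1 + dr, c1 + dc, drop = FALSE])
    keep <- ok[a] & ok[b]
    if (!any(keep)) next
    a <- a[keep]; b <- b[keep]
    dist_km <- cell_size / 1000 * sqrt(dr^2 + dc^2)
    # minutes = dist / harmonic-mean speed * 60 = dist/2 * (1/v1 + 1/v2) * 60
    w_new <- dist_km / 2 * (1 / speed[a] + 1 / speed[b]) * 60
    from <- c(from, a); to <- c(to, b); w <- c(w, w_new)
  }
  list(from = from, to = to, weight = w)
}

#' Minutes-to-nearest-facility raster by least-cost search
#'
#' Multi-source shortest-path travel time over the 8-connected grid graph of
#' a friction surface. The cost of stepping between two adjacent cells is
#' the centre-to-centre distance (diagonals scaled by sqrt(2)) divided by
#' the harmonic mean of the two cells' speeds, in minutes; the output at
#' each cell is the exact minimum total cost over all paths to any source.
#' Facilities are snapped to the centre of their containing cell; facilities
#' sharing a cell collapse to one source; facilities outside the raster
#' extent are ignored.
#'
#' @param friction a speed [fever_raster()] from [build_friction()].
#' @param sources data frame of facility coordinates with columns `x`, `y`
#'   (extra columns such as `tier` are allowed).
#' @param tier optional label stored on the output raster.
#' @return A [fever_raster()] of minutes, 0 at source cells, `NA` where
#'   unreachable or nodata.
#' @export
cost_distance <- function(friction, sources, tier = NULL) {
  stopifnot(inherits(friction, "fever_raster"))
  if (nrow(sources) == 0) stop("no sources for cost distance", call. = FALSE)
  ext <- raster_extent(friction)
  inside <- sources$x >= ext["xmin"] & sources$x <= ext["xmax"] &
    sources$y >= ext["ymin"] & sources$y <= ext["ymax"]
  if (!any(inside)) stop("no source inside the raster extent", call. = FALSE)
  sources <- sources[inside, , drop = FALSE]
  cells <- cell_at(friction, sources$x, sources$y)
  nr <- nrow(friction$values)
  src_idx <- unique((cells[, "col"] - 1L) * nr + cells[, "row"])
  speed <- friction$values
  live <- !is.na(speed[src_idx]) & speed[src_idx] > 0
  if (!any(live)) stop("all sources lie on nodata cells", call. = FALSE)
  src_idx <- src_idx[live]

  e <- grid_edges(speed, friction$cell_size)
  g <- igraph::make_empty_graph(n = length(speed), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(rbind(e$from, e$to)), weight = e$weight)
  d <- igraph::distances(g, v = src_idx, weights = igraph::E(g)$weight)
  tt <- if (nrow(d) == 1) as.vector(d) else do.call(pmin, asplit(d, 1))
  tt[!is.finite(tt)] <- NA_real_
  tt[is.na(speed) | speed <= 0] <- NA_real_
  out <- matrix(tt, nrow = nr)
  fever_raster(out, friction$cell_size, friction$xll, friction$yll,
               layer = paste0("travel_time_min",
                              if (!is.null(tier)) paste0(":", tier) else ""))
}

#' Read travel time at point locations
#'
#' Nearest-cell lookup: each point takes the value of the cell containing
#' it. Nodata cells yield `NA`; points outside the raster extent are an
#' error.
#'
#' @param raster a travel-time [fever_raster()].
#' @param x,y point coordinates in metres.
#' @return Numeric vector of minutes (`NA` where nodata).
#' @export
extract_travel_time <- function(raster, x, y) {
  cells <- cell_at(raster, x, y)
  raster$values[cells]
}
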