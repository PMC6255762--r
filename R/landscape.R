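#' Configure a synthetic study landscape
#'
#' Describes the gridded world the generator builds: land classes, elevation
#' relief, a road network, an under-5 population surface, public health
#' facilities in three tiers and a regular partition into administrative
#' units. All downstream stages (travel time, survey simulation, aggregation)
#' run against these layers, so a complete study can be produced without any
#' external data.
#'
#' @param grid_width,grid_height grid dimensions in cells.
#' @param cell_size cell edge length in metres.
#' @param land_class_fractions named proportions per land class; must sum to 1.
#' @param road_density target fraction of cells carrying a road.
#' @param elevation_relief total elevation range in metres.
#' @param n_facilities_per_tier named integer counts for tiers
#'   `hospital`, `health_centre`, `dispensary`.
#' @param n_admin_units number of administrative units in the block tiling.
#' @param mean_u5_per_cell average under-5 population per cell; the surface
#'   is strongly clustered around a few towns.
#' @param seed integer seed making the landscape reproducible.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(grid_width = 60, grid_height = 60,
                             cell_size = 1000,
                             land_class_fractions = c(grassland = 0.45,
                                                      cropland = 0.30,
                                                      forest = 0.20,
                                                      wetland = 0.05),
                             road_density = 0.08,
                             elevation_relief = 800,
                             n_facilities_per_tier = c(hospital = 2,
                                                      health_centre = 6,
                                                      dispensary = 16),
                             n_admin_units = 6,
                             mean_u5_per_cell = 25,
                             seed = 1L) {
  if (abs(sum(land_class_fractions) - 1) > 1e-9)
    stop("land_class_fractions must sum to 1", call. = FALSE)
  if (is.null(names(land_class_fractions)) || any(!nzchar(names(land_class_fractions))))
    stop("land_class_fractions must be named", call. = FALSE)
  if (any(land_class_fractions < 0)) stop("land_class_fractions must be >= 0", call. = FALSE)
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (any(n_facilities_per_tier < 0)) stop("facility counts must be >= 0", call. = FALSE)
  stopifnot(grid_width >= 2, grid_height >= 2, n_admin_units >= 1)
  structure(
    list(grid_width = as.integer(grid_width),
         grid_height = as.integer(grid_height),
         cell_size = cell_size,
         land_class_fractions = land_class_fractions,
         road_density = road_density,
         elevation_relief = elevation_relief,
         n_facilities_per_tier = n_facilities_per_tier,
         n_admin_units = as.integer(n_admin_units),
         mean_u5_per_cell = mean_u5_per_cell,
         seed = as.integer(seed)),
    class = "landscape_config"
  )
}

# Smooth random field as a sum of Gaussian bumps; used for elevation,
# land-class patchiness and population clustering.
bump_field <- function(nr, nc, n_bumps, bandwidth) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- matrix(0, nr, nc)
  for (i in seq_len(n_bumps)) {
    cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
    amp <- stats::runif(1, 0.5, 1) * sample(c(-1, 1), 1)
    f <- f + amp * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * bandwidth^2))
  }
  f
}

#' Generate the synthetic landscape
#'
#' Builds co-registered rasters (land class, elevation, road mask, under-5
#' population, administrative partition) and a facility list from a
#' [landscape_config()]. Land classes form spatially coherent patches whose
#' areas match the configured fractions exactly (to cell rounding); the road
#' network is a set of straight transects; population is concentrated around
#' a few towns; facilities are placed preferentially in high-population
#' cells; the administrative partition is a regular block tiling.
#'
#' @param config a [landscape_config()].
#' @return A list of class `fever_landscape` with elements `land_class`,
#'   `elevation`, `roads`, `population`, `admin` (all [fever_raster()]s),
#'   `facilities` (tibble: `facility_id`, `tier`, `x`, `y`), `class_names`,
#'   and the `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  if (sum(config$n_facilities_per_tier) == 0)
    stop("no sources for cost distance: all facility tiers have zero count",
         call. = FALSE)
  nr <- config$grid_height; nc <- config$grid_width
  with_seed(config$seed, {
    # elevation: smooth field scaled to the configured relief
    elev <- bump_field(nr, nc, n_bumps = 8, bandwidth = max(nr, nc) / 4)
    elev <- (elev - min(elev)) / max(diff(range(elev)), 1e-12) * config$elevation_relief

    # land class: quantile-slice a second smooth field so patch areas match
    # the configured fractions
    patch <- bump_field(nr, nc, n_bumps = 25, bandwidth = max(nr, nc) / 8)
    patch <- patch + stats::rnorm(nr * nc, sd = 0.05)  # break ties
    fr <- config$land_class_fractions
    brk <- stats::quantile(patch, probs = cumsum(fr) / sum(fr), names = FALSE)
    land <- matrix(findInterval(patch, c(-Inf, brk[-length(brk)])), nr, nc)

    # roads: straight transects until the target density is met
    roads <- matrix(0, nr, nc)
    target <- config$road_density * nr * nc
    guard <- 0
    while (sum(roads) < target && guard < 200) {
      guard <- guard + 1
      if (stats::runif(1) < 0.5) roads[sample.int(nr, 1), ] <- 1
      else roads[, sample.int(nc, 1)] <- 1
    }

    # under-5 population: a few towns plus sparse rural background
    n_towns <- 3
    pop <- matrix(0, nr, nc)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(n_towns)) {
      cr <- stats::runif(1, nr * 0.15, nr * 0.85)
      cc <- stats::runif(1, nc * 0.15, nc * 0.85)
      sigma <- stats::runif(1, 2, max(nr, nc) / 10)
      pop <- pop + stats::runif(1, 0.5, 1) *
        exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sigma^2))
    }
    pop <- pop + 0.02 * matrix(stats::rexp(nr * nc), nr, nc)
    pop <- pop / mean(pop) * config$mean_u5_per_cell
    pop[land == which(names(fr) == "wetland")] <- pop[land == which(names(fr) == "wetland")] * 0.2

    # facilities: weighted towards dense cells (weight = population^2)
    fac <- purrr::imap_dfr(as.list(config$n_facilities_per_tier), function(n, tier) {
      if (n == 0) return(tibble::tibble())
      idx <- sample.int(nr * nc, n, prob = as.vector(pop)^2)
      tibble::tibble(tier = tier,
                     row = (idx - 1L) %% nr + 1L,
                     col = (idx - 1L) %/% nr + 1L)
    })

    # admin units: kr x kc block tiling with kr * kc = n_admin_units
    K <- config$n_admin_units
    kr <- max(1L, as.integer(floor(sqrt(K))))
    while (K %% kr != 0) kr <- kr - 1L
    kc <- K %/% kr
    block_r <- pmin(kr, ceiling(seq_len(nr) / (nr / kr)))
    block_c <- pmin(kc, ceiling(seq_len(nc) / (nc / kc)))
    admin <- outer(block_r, block_c, function(r, c) (r - 1L) * kc + c)

    mk <- function(v, layer) fever_raster(v, config$cell_size, layer = layer)
    land_r <- mk(land, "land_class")
    ctr <- cell_centre(land_r, fac$row, fac$col)
    facilities <- tibble::tibble(
      facility_id = sprintf("fac_%03d", seq_len(nrow(fac))),
      tier = fac$tier, x = ctr[, "x"], y = ctr[, "y"])

    structure(
      list(land_class = land_r,
           elevation = mk(elev, "elevation_m"),
           roads = mk(roads, "road_mask"),
           population = mk(pop, "u5_population"),
           admin = mk(admin, "admin_unit"),
           facilities = facilities,
           class_names = names(fr),
           config = config),
      class = "fever_landscape")
  })
}

#' @export
print.fever_landscape <- function(x, ...) {
  cat(sprintf("<fever_landscape> %d x %d cells (%.0f m), %d facilities, %d admin units\n",
              dim(x$land_class$values)[1], dim(x$land_class$values)[2],
              x$config$cell_size, nrow(x$facilities), x$config$n_admin_units))
  invisible(x)
}
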