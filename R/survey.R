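#' Ground-truth parameters for the response generator
#'
#' Collects the generative parameters of the treatment-seeking model: the
#' three-parameter logistic item parameters per facility-type item
#' (discrimination `a > 0`, difficulty `b`, floor `c` in (0, 1]), the
#' ability regression (intercept `alpha`, travel-time slope `beta_time`
#' per minute, urban shift `beta_urban`), the two-week fever recall
#' prevalence and the rate at which fever-case treatment responses are
#' missing ("don't know").
#'
#' @param items tibble with columns `item`, `a`, `b`, `c`; one row per
#'   survey item. The default is the single public-sector item.
#' @param alpha ability intercept.
#' @param beta_time ability change per minute of travel time (negative for
#'   distance decay).
#' @param beta_urban ability shift for urban residence.
#' @param fever_prevalence probability of a fever episode in the two-week
#'   recall window.
#' @param missing_rate probability a fever case's treatment response is
#'   recorded as missing.
#' @return A list of class `true_parameters`.
#' @export
true_parameters <- function(items = tibble::tibble(item = "any_public",
                                                   a = 1, b = 0, c = 0.2),
                            alpha = 0.5, beta_time = -0.01, beta_urban = 0.4,
                            fever_prevalence = 0.25, missing_rate = 0.03) {
  stopifnot(all(c("item", "a", "b", "c") %in% names(items)))
  if (any(items$a <= 0)) stop("discrimination a must be > 0", call. = FALSE)
  if (any(items$c <= 0 | items$c > 1)) stop("floor c must be in (0, 1]", call. = FALSE)
  if (fever_prevalence < 0 || fever_prevalence > 1)
    stop("fever_prevalence must be in [0, 1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  structure(list(items = items, alpha = alpha, beta_time = beta_time,
                 beta_urban = beta_urban, fever_prevalence = fever_prevalence,
                 missing_rate = missing_rate),
            class = "true_parameters")
}

#' Sample survey clusters proportional to population size
#'
#' First stage of the two-stage cluster design: cells are selected with
#' probability proportional to their under-5 population, without
#' replacement, so cluster locations are distinct. Each cluster receives a
#' uniformly drawn household count in 15--30 and an urban/rural residence
#' flag from a population-density threshold. The cluster point is placed
#' uniformly within its cell.
#'
#' @param population a [fever_raster()] of under-5 population per cell.
#' @param n_clusters number of clusters to draw.
#' @param urban_threshold people-per-cell at or above which a cell counts
#'   as urban.
#' @param seed integer seed.
#' @return A tibble with one row per cluster: `cluster_id`, `row`, `col`,
#'   `x_true`, `y_true`, `residence`, `n_households`, `cell_population`.
#' @export
sample_clusters <- function(population, n_clusters, urban_threshold = 100,
                            seed = 1L) {
  stopifnot(inherits(population, "fever_raster"))
  pop <- as.vector(population$values)
  pop[is.na(pop)] <- 0
  if (any(pop < 0) || sum(pop) <= 0)
    stop("population raster must be non-negative with positive total", call. = FALSE)
  populated <- which(pop > 0)
  if (n_clusters > length(populated))
    stop("n_clusters exceeds the number of populated cells", call. = FALSE)
  if (n_clusters == 0)
    return(tibble::tibble(cluster_id = character(), row = integer(),
                          col = integer(), x_true = numeric(), y_true = numeric(),
                          residence = character(), n_households = integer(),
                          cell_population = numeric()))
  nr <- dim(population$values)[1]
  with_seed(seed, {
    idx <- populated[sample.int(length(populated), n_clusters,
                                prob = pop[populated])]
    row <- (idx - 1L) %% nr + 1L
    col <- (idx - 1L) %/% nr + 1L
    ctr <- cell_centre(population, row, col)
    half <- population$cell_size / 2
    tibble::tibble(
      cluster_id = sprintf("cl_%04d", seq_len(n_clusters)),
      row = row, col = col,
      x_true = ctr[, "x"] + stats::runif(n_clusters, -half, half),
      y_true = ctr[, "y"] + stats::runif(n_clusters, -half, half),
      residence = ifelse(pop[idx] >= urban_threshold, "urban", "rural"),
      n_households = sample(15:30, n_clusters, replace = TRUE),
      cell_population = pop[idx])
  })
}

#' Displace cluster coordinates for disclosure protection
#'
#' Adds the anonymisation jitter used by georeferenced household surveys:
#' each cluster is moved by a uniformly random angle and a uniform distance
#' up to 2 km (urban) or 5 km (rural), with a small share of rural clusters
#' displaced up to 10 km. True coordinates are retained (they exist only in
#' the synthetic world) so displacement effects can be studied.
#'
#' @param clusters tibble from [sample_clusters()].
#' @param seed integer seed.
#' @param urban_max_km,rural_max_km maximum displacement per residence class.
#' @param rural_far_fraction share of rural clusters eligible for the larger
#'   displacement.
#' @param rural_far_km maximum displacement for that share.
#' @param extent optional [fever_raster()]; published coordinates are clamped
#'   into its extent (a non-expansive projection, so displacement bounds
#'   still hold).
#' @return `clusters` with columns `x_pub`, `y_pub` added.
#' @export
displace_clusters <- function(clusters, seed = 1L, urban_max_km = 2,
                              rural_max_km = 5, rural_far_fraction = 0.01,
                              rural_far_km = 10, extent = NULL) {
  n <- nrow(clusters)
  if (n == 0) return(dplyr::mutate(clusters, x_pub = numeric(), y_pub = numeric()))
  with_seed(seed, {
    max_km <- ifelse(clusters$residence == "urban", urban_max_km, rural_max_km)
    far <- clusters$residence == "rural" &
      stats::runif(n) < rural_far_fraction
    max_km[far] <- rural_far_km
    ang <- stats::runif(n, 0, 2 * pi)
    dist <- stats::runif(n, 0, max_km * 1000)
    out <- dplyr::mutate(clusters,
                         x_pub = .data$x_true + dist * cos(ang),
                         y_pub = .data$y_true + dist * sin(ang))
    if (!is.null(extent)) {
      ext <- raster_extent(extent)
      eps <- extent$cell_size * 1e-6
      out$x_pub <- pmin(pmax(out$x_pub, ext["xmin"] + eps), ext["xmax"] - eps)
      out$y_pub <- pmin(pmax(out$y_pub, ext["ymin"] + eps), ext["ymax"] - eps)
    }
    out
  })
}

# Vectorised generative core: one Bernoulli treatment response per fever
# case from the 3PL model at the given covariates.
draw_responses <- function(t_min, urban, params, item = 1L) {
  it <- params$items[item, ]
  theta <- params$alpha + params$beta_time * t_min + params$beta_urban * urban
  p <- item_probability(theta, a = it$a, b = it$b, c = it$c)
  stats::rbinom(length(p), 1L, p)
}

#' Simulate child-level fever and treatment responses
#'
#' Second stage of the survey generator. Each sampled household contributes
#' one under-5 child; fever follows the configured two-week recall
#' prevalence; for fever cases the treatment response is drawn from the
#' three-parameter logistic model at the cluster's travel time (extracted
#' from the travel-time raster at the published coordinates) and residence,
#' and a configured share of responses is then set missing. Children
#' without fever carry no treatment response.
#'
#' With a single travel-time raster all responses belong to the first
#' (public-sector) item. With a named list of rasters (one per facility
#' tier matching `params$items$item`), each cluster is assigned the item of
#' its nearest tier and that tier's travel time.
#'
#' @param clusters tibble from [displace_clusters()] (must have `x_pub`,
#'   `y_pub`).
#' @param travel_time a `travel_time_min` [fever_raster()], or a named list
#'   of them keyed by item.
#' @param params a [true_parameters()].
#' @param seed integer seed.
#' @return A tibble with one row per child: `child_id`, `cluster_id`,
#'   `fever`, `item`, `response`, `travel_time_min`, `urban`.
#' @export
simulate_responses <- function(clusters, travel_time, params, seed = 1L) {
  stopifnot(inherits(params, "true_parameters"))
  if (!all(c("x_pub", "y_pub") %in% names(clusters)))
    stop("clusters must carry published coordinates; run displace_clusters()",
         call. = FALSE)
  rasters <- if (inherits(travel_time, "fever_raster"))
    stats::setNames(list(travel_time), params$items$item[1]) else travel_time
  if (!all(names(rasters) %in% params$items$item))
    stop("travel-time raster names must match item labels", call. = FALSE)

  # per-cluster travel time (and item, for the multi-tier configuration)
  tt <- vapply(rasters, function(r) {
    vapply(seq_len(nrow(clusters)), function(i) {
      tryCatch(extract_travel_time(r, clusters$x_pub[i], clusters$y_pub[i]),
               error = function(e) stop("cluster ", clusters$cluster_id[i],
                                        " lies outside the travel-time raster",
                                        call. = FALSE))
    }, numeric(1))
  }, numeric(nrow(clusters)))
  tt <- matrix(tt, nrow = nrow(clusters))
  if (anyNA(tt)) {
    bad <- clusters$cluster_id[which(rowSums(is.na(tt)) > 0)]
    stop("no travel time (nodata) at cluster ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pick <- apply(tt, 1, which.min)
  cl_item <- names(rasters)[pick]
  cl_time <- tt[cbind(seq_len(nrow(clusters)), pick)]

  with_seed(seed, {
    children <- tidyr::uncount(
      dplyr::transmute(clusters, cluster_id = .data$cluster_id,
                       urban = as.integer(.data$residence == "urban"),
                       travel_time_min = cl_time, item = cl_item,
                       n = .data$n_households),
      .data$n)
    n <- nrow(children)
    children$child_id <- sprintf("ch_%05d", seq_len(n))
    children$fever <- stats::rbinom(n, 1L, params$fever_prevalence)
    children$response <- NA_integer_
    fev <- which(children$fever == 1L)
    for (it in unique(children$item[fev])) {
      sel <- fev[children$item[fev] == it]
      children$response[sel] <- draw_responses(
        children$travel_time_min[sel], children$urban[sel], params,
        item = match(it, params$items$item))
    }
    if (length(fev) > 0 && params$missing_rate > 0) {
      drop <- fev[stats::runif(length(fev)) < params$missing_rate]
      children$response[drop] <- NA_integer_
    }
    children$item[children$fever == 0L] <- NA_character_
    dplyr::select(children, "child_id", "cluster_id", "fever", "item",
                  "response", "travel_time_min", "urban")
  })
}
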