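#' Treated-fever rates by administrative unit
#'
#' Descriptive aggregation of the raw survey counts: clusters are assigned
#' to administrative units through their published coordinates, and each
#' unit reports its sampled fever count, treated count, the unit's under-5
#' population and the treated rate per 1,000 under-5 children. The rate is
#' the survey-estimated treated fraction among fever cases with an
#' observed response, scaled to per-1,000; units with no sampled fever
#' cases (or no observed responses) are flagged missing. An optional
#' per-child `weight` column supplies survey design weights (default 1).
#'
#' @param children tibble from [simulate_responses()] (or ingested data)
#'   with `cluster_id`, `fever`, `response`.
#' @param clusters tibble with `cluster_id`, `x_pub`, `y_pub`.
#' @param admin a [fever_raster()] of administrative-unit labels.
#' @param population a co-registered under-5 population [fever_raster()].
#' @return A tibble with one row per admin unit: `admin_unit`, `fever_n`,
#'   `responded_n`, `treated_n`, `pop_u5`, `rate_per_1000`.
#' @export
admin_rates <- function(children, clusters, admin, population) {
  if (!same_grid(admin, population))
    stop("admin and population rasters must share the same grid", call. = FALSE)
  cells <- tryCatch(cell_at(admin, clusters$x_pub, clusters$y_pub),
                    error = function(e)
                      stop("cluster outside every admin unit: ",
                           conditionMessage(e), call. = FALSE))
  unit <- admin$values[cells]
  if (anyNA(unit))
    stop("cluster outside every admin unit: ",
         paste(clusters$cluster_id[is.na(unit)], collapse = ", "), call. = FALSE)
  lookup <- stats::setNames(unit, clusters$cluster_id)

  pop_by_unit <- tapply(as.vector(population$values),
                        as.vector(admin$values), sum, na.rm = TRUE)

  if (!"weight" %in% names(children)) children$weight <- 1
  counts <- children |>
    dplyr::mutate(admin_unit = lookup[.data$cluster_id]) |>
    dplyr::group_by(.data$admin_unit) |>
    dplyr::summarise(
      fever_n = sum(.data$weight * (.data$fever == 1)),
      responded_n = sum(.data$weight * (!is.na(.data$response))),
      treated_n = sum(.data$weight * (!is.na(.data$response) & .data$response == 1)),
      .groups = "drop")

  tibble::tibble(admin_unit = as.integer(names(pop_by_unit)),
                 pop_u5 = as.numeric(pop_by_unit)) |>
    dplyr::left_join(counts, by = "admin_unit") |>
    dplyr::mutate(dplyr::across(c("fever_n", "responded_n", "treated_n"),
                                ~tidyr::replace_na(.x, 0)),
                  rate_per_1000 = ifelse(.data$responded_n > 0,
                                         .data$treated_n / .data$responded_n * 1000,
                                         NA_real_)) |>
    dplyr::select("admin_unit", "fever_n", "responded_n", "treated_n",
                  "pop_u5", "rate_per_1000")
}

#' Population-weighted national treated-fever rate
#'
#' Weighted mean of the unit rates with the units' under-5 populations as
#' weights; units with no sampled fever cases are excluded.
#'
#' @param aggregates tibble from [admin_rates()].
#' @return A single rate per 1,000 under-5 children.
#' @export
national_summary <- function(aggregates) {
  ok <- !is.na(aggregates$rate_per_1000)
  if (!any(ok)) stop("all admin units are missing", call. = FALSE)
  stats::weighted.mean(aggregates$rate_per_1000[ok], aggregates$pop_u5[ok])
}
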