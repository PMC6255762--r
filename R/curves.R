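# per-draw parameter matrix for one item: alpha, beta_time, beta_urban, a, b, c
item_draw_matrix <- function(samples, item = 1L) {
  if (inherits(samples, "fever_irt_fit")) samples <- samples$draws
  stopifnot(inherits(samples, "fever_draws"))
  items <- samples$items
  i <- if (is.character(item)) match(item, items) else as.integer(item)
  if (is.na(i) || i < 1 || i > length(items))
    stop("unknown item: ", item, call. = FALSE)
  suffix <- if (length(items) == 1) c("a", "b", "c")
  else paste0(c("a", "b", "c"), "[", items[i], "]")
  m <- pooled_draws(samples, c("alpha", "beta_time", "beta_urban", suffix))
  colnames(m) <- c("alpha", "beta_time", "beta_urban", "a", "b", "c")
  m
}

# 3PL probability for every draw (rows) at each covariate point (cols)
draw_probabilities <- function(m, t_min, urban) {
  theta <- m[, "alpha"] + outer(m[, "beta_time"], t_min) + m[, "beta_urban"] * urban
  m[, "c"] + (1 - m[, "c"]) * stats::plogis(m[, "a"] * theta - m[, "b"])
}

#' Back-calculated probability of seeking treatment by travel time
#'
#' Evaluates the three-parameter logistic response probability at
#' `theta = alpha + beta_time * t + beta_urban * urban` for every retained
#' posterior draw and every grid point, then summarises each grid point by
#' the posterior median and central 95% credible interval across draws.
#' Draw-wise evaluation (the default) produces valid credible bands; the
#' `"plugin"` mode instead evaluates the curve once at the posterior
#' medians of the parameters, for comparison, and reports no interval.
#'
#' @param samples a `fever_draws` or `fever_irt_fit`.
#' @param time_grid travel times in minutes (non-empty).
#' @param residence `"rural"` or `"urban"`.
#' @param item item label or index (default first).
#' @param mode `"draws"` (default) or `"plugin"`.
#' @return A tibble of class `treatment_curve` with columns `t_min`,
#'   `median`, `lo95`, `hi95`, `residence`, `item`.
#' @export
treatment_curve <- function(samples, time_grid = seq(0, 240, by = 5),
                            residence = c("rural", "urban"), item = 1L,
                            mode = c("draws", "plugin")) {
  if (length(time_grid) == 0) stop("time_grid must be non-empty", call. = FALSE)
  residence <- match.arg(residence)
  mode <- match.arg(mode)
  m <- item_draw_matrix(samples, item)
  urban <- as.integer(residence == "urban")
  if (mode == "plugin") {
    med <- apply(m, 2, stats::median)
    theta <- med["alpha"] + med["beta_time"] * time_grid + med["beta_urban"] * urban
    p <- unname(item_probability(theta, med["a"], med["b"], med["c"]))
    out <- tibble::tibble(t_min = time_grid, median = p,
                          lo95 = NA_real_, hi95 = NA_real_)
  } else {
    pm <- draw_probabilities(m, time_grid, urban)
    qs <- apply(pm, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
    out <- tibble::tibble(t_min = time_grid, median = unname(qs[1, ]),
                          lo95 = unname(qs[2, ]), hi95 = unname(qs[3, ]))
  }
  out$residence <- residence
  out$item <- if (inherits(samples, "fever_irt_fit")) {
    items <- samples$items
    if (is.character(item)) item else items[item]
  } else if (is.character(item)) item else samples$items[item]
  class(out) <- c("treatment_curve", class(out))
  out
}

#' Posterior summaries at fixed travel-time thresholds
#'
#' Reads a [treatment_curve()] at the requested thresholds (linear
#' interpolation between grid points) and formats each as
#' `median (lower-upper)` to two decimals, the layout used for
#' national-level reporting.
#'
#' @param curve a [treatment_curve()].
#' @param thresholds travel times in minutes; must lie within the curve's
#'   grid range. The default is 10 min, 30 min, 1 h and 2 h.
#' @return A tibble with columns `t_min`, `median`, `lo95`, `hi95`,
#'   `formatted`.
#' @export
summarize_at_thresholds <- function(curve, thresholds = c(10, 30, 60, 120)) {
  if (length(thresholds) == 0)
    return(tibble::tibble(t_min = numeric(), median = numeric(),
                          lo95 = numeric(), hi95 = numeric(),
                          formatted = character()))
  rng <- range(curve$t_min)
  if (any(thresholds < rng[1] | thresholds > rng[2]))
    stop("threshold outside the curve's travel-time grid", call. = FALSE)
  interp <- function(y) {
    if (all(is.na(y))) return(rep(NA_real_, length(thresholds)))
    stats::approx(curve$t_min, y, xout = thresholds)$y
  }
  med <- interp(curve$median); lo <- interp(curve$lo95); hi <- interp(curve$hi95)
  tibble::tibble(
    t_min = thresholds, median = med, lo95 = lo, hi95 = hi,
    formatted = sprintf("%.2f (%.2f-%.2f)", med, lo, hi))
}

#' Posterior summary of the floor probability
#'
#' The floor parameter `c` is the asymptotic minimum probability of seeking
#' treatment, approached at very large travel times; its posterior summary
#' bounds the treatment curve from below.
#'
#' @param samples a `fever_draws` or `fever_irt_fit`.
#' @param item item label or index.
#' @return A tibble with `item`, `median`, `lo95`, `hi95`.
#' @export
threshold_floor <- function(samples, item = 1L) {
  m <- item_draw_matrix(samples, item)
  q <- stats::quantile(m[, "c"], c(0.5, 0.025, 0.975), names = FALSE)
  items <- if (inherits(samples, "fever_irt_fit")) samples$items else samples$items
  items <- items %||% as.character(item)
  tibble::tibble(item = if (is.character(item)) item else items[item],
                 median = q[1], lo95 = q[2], hi95 = q[3])
}

#' Gridded posterior-median probability map
#'
#' Evaluates the treatment-seeking probability draw-wise at every raster
#' cell's travel time and residence and stores the per-cell posterior
#' median. Nodata in either input propagates to the output.
#'
#' @param samples a `fever_draws` or `fever_irt_fit`.
#' @param travel_time a travel-time [fever_raster()] (minutes).
#' @param urban a co-registered 0/1 urban-mask [fever_raster()].
#' @param item item label or index.
#' @return A [fever_raster()] of probabilities, layer `"p_treat"`.
#' @export
probability_raster <- function(samples, travel_time, urban, item = 1L) {
  if (!same_grid(travel_time, urban))
    stop("travel-time and urban rasters must share the same grid", call. = FALSE)
  m <- item_draw_matrix(samples, item)
  t_vec <- as.vector(travel_time$values)
  u_vec <- as.vector(urban$values)
  out <- rep(NA_real_, length(t_vec))
  ok <- which(!is.na(t_vec) & !is.na(u_vec))
  for (start in seq(1, length(ok), by = 512)) {
    sel <- ok[start:min(start + 511, length(ok))]
    theta <- m[, "alpha"] + outer(m[, "beta_time"], t_vec[sel]) +
      outer(m[, "beta_urban"], u_vec[sel])
    pm <- m[, "c"] + (1 - m[, "c"]) * stats::plogis(m[, "a"] * theta - m[, "b"])
    out[sel] <- apply(pm, 2, stats::median)
  }
  fever_raster(matrix(out, nrow(travel_time$values)), travel_time$cell_size,
               travel_time$xll, travel_time$yll, layer = "p_treat")
}

#' Plot a treatment curve with its credible band
#'
#' @param object a [treatment_curve()].
#' @param thresholds optional vertical reference lines (minutes).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot treatment_curve
#' @export
autoplot.treatment_curve <- function(object, thresholds = c(10, 30, 60, 120),
                                     ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$t_min, .data$median))
  if (!all(is.na(object$lo95)))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95,
                                               ymax = .data$hi95),
                                  fill = "firebrick", alpha = 0.2)
  p +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "travel time to nearest facility (minutes)",
                  y = "probability of seeking treatment") +
    ggplot2::theme_minimal()
}
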