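# Internal sampling-scale state layout
# ability block: alpha, bt_hr (per-hour slope), bu
# per item i:    ua_i = log a_i, b_i, uc_i = qlogis(c_i)

# Aggregate child records to binomial sufficient statistics per unique
# (item, travel time, urban) covariate row; exact and much faster.
aggregate_responses <- function(children, item_levels) {
  keep <- !is.na(children$response)
  dd <- children[keep, , drop = FALSE]
  if (nrow(dd) == 0) stop("all responses are missing", call. = FALSE)
  if (!all(dd$response %in% c(0L, 1L)))
    stop("responses must be 0, 1 or missing", call. = FALSE)
  if (!"item" %in% names(dd)) dd$item <- item_levels[1]
  dd |>
    dplyr::group_by(.data$item, .data$travel_time_min, .data$urban) |>
    dplyr::summarise(trials = dplyr::n(), successes = sum(.data$response),
                     .groups = "drop") |>
    dplyr::mutate(item_idx = match(.data$item, item_levels),
                  t_hr = .data$travel_time_min / 60)
}

binom_loglik <- function(p, trials, successes) {
  ll <- sum(successes * log(p))
  fail <- trials - successes
  has_fail <- fail > 0
  if (any(has_fail)) {
    q <- log1p(-p[has_fail])
    ll <- ll + sum(fail[has_fail] * q)
  }
  ll
}

# log posterior on the sampling scale (includes Jacobians of the
# transforms for free parameters)
make_logpost <- function(agg, priors, free) {
  n_items <- max(agg$item_idx)
  force(free)
  function(st) {
    a <- exp(st[paste0("ua_", seq_len(n_items))])
    b <- st[paste0("b_", seq_len(n_items))]
    cc <- stats::plogis(st[paste0("uc_", seq_len(n_items))])
    theta <- st[["alpha"]] + st[["bt_hr"]] * agg$t_hr + st[["bu"]] * agg$urban
    eta <- a[agg$item_idx] * theta - b[agg$item_idx]
    p <- cc[agg$item_idx] + (1 - cc[agg$item_idx]) * stats::plogis(eta)
    ll <- binom_loglik(p, agg$trials, agg$successes)
    lp <- 0
    if ("alpha" %in% free)
      lp <- lp + stats::dnorm(st[["alpha"]], priors$alpha_mean, priors$alpha_sd, log = TRUE)
    if ("bt_hr" %in% free)
      lp <- lp + stats::dnorm(st[["bt_hr"]], priors$beta_mean, priors$beta_sd, log = TRUE)
    if ("bu" %in% free)
      lp <- lp + stats::dnorm(st[["bu"]], priors$beta_mean, priors$beta_sd, log = TRUE)
    for (i in seq_len(n_items)) {
      if (paste0("ua_", i) %in% free)
        lp <- lp + log_dtnorm_pos(a[i], priors$mu_a, priors$sigma_a) + log(a[i])
      if (paste0("b_", i) %in% free)
        lp <- lp + stats::dnorm(b[i], priors$b_mean, priors$b_sd, log = TRUE)
      if (paste0("uc_", i) %in% free)
        lp <- lp + stats::dbeta(cc[i], priors$c_shape1, priors$c_shape2, log = TRUE) +
          log(cc[i]) + log1p(-cc[i])
    }
    if (!is.finite(ll) || !is.finite(lp)) return(-Inf)
    ll + lp
  }
}

run_chain <- function(logpost, init, free, blocks, config, chain_seed) {
  n_keep <- retained_draws(config)
  kept <- matrix(NA_real_, n_keep, length(init),
                 dimnames = list(NULL, names(init)))
  with_seed(chain_seed, {
    st <- init
    lp <- logpost(st)
    if (!is.finite(lp)) {          # fall back to a safe start
      st[free] <- 0
      lp <- logpost(st)
    }
    scales <- lapply(blocks, function(b) rep(0.2, length(b)))
    acc <- n_try <- rep(0, length(blocks))
    k <- 0L
    for (iter in seq_len(config$n_iterations)) {
      for (bi in seq_along(blocks)) {
        blk <- blocks[[bi]]
        prop <- st
        prop[blk] <- prop[blk] + stats::rnorm(length(blk)) * scales[[bi]]
        lp_new <- logpost(prop)
        n_try[bi] <- n_try[bi] + 1
        if (log(stats::runif(1)) < lp_new - lp) {
          st <- prop; lp <- lp_new; acc[bi] <- acc[bi] + 1
        }
      }
      if (config$adapt && iter <= config$burn_in && iter %% 50 == 0) {
        for (bi in seq_along(blocks)) {
          rate <- acc[bi] / n_try[bi]
          scales[[bi]] <- pmin(10, pmax(1e-3,
            scales[[bi]] * exp(0.6 * (rate - 0.3))))
          acc[bi] <- 0; n_try[bi] <- 0
        }
      }
      if (iter > config$burn_in &&
          (iter - config$burn_in) %% config$thinning == 0) {
        k <- k + 1L
        kept[k, ] <- st
      }
    }
    list(draws = kept[seq_len(k), , drop = FALSE],
         acceptance = ifelse(n_try > 0, acc / n_try, NA_real_))
  })
}

#' Fit the treatment-seeking item-response model by MCMC
#'
#' Posterior sampling for the three-parameter logistic model with
#' covariate-structured ability, by Metropolis-within-Gibbs: a joint
#' random-walk block for the free ability coefficients, a per-item block
#' for (log a, b) and a per-item block for logit c. Proposal scales adapt
#' during burn-in towards 20--50% acceptance and are then frozen, so the
#' retained chains target the exact posterior. Chains start from
#' over-dispersed jittered positions.
#'
#' With a single item the discrimination and difficulty are not separately
#' identifiable from the ability scale and location, so they are fixed at
#' `a = 1`, `b = 0` by default; with several items the first item is the
#' anchor. Any parameter can be fixed explicitly through `fix`.
#'
#' @param children tibble with columns `response` (0/1/NA),
#'   `travel_time_min`, `urban`, optionally `item`; missing responses are
#'   dropped from the likelihood.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param fix named list of parameters to hold fixed, e.g.
#'   `list(beta_urban = 0)` or `list(a = 1, b = 0, c = 0.3)` (item
#'   parameters given as scalars apply to every item; vectors apply per
#'   item). `NULL` entries are ignored.
#' @param init optional named list of natural-scale starting values
#'   (`alpha`, `beta_time`, `beta_urban`, `a`, `b`, `c`).
#' @return An object of class `fever_irt_fit` with elements `draws` (a
#'   `fever_draws` array of natural-scale retained draws), `items`,
#'   `fixed`, `priors`, `config`, `acceptance` and `n_obs`.
#' @export
fit_treatment_irt <- function(children, priors = prior_spec(),
                              config = mcmc_config(), fix = NULL,
                              init = NULL) {
  stopifnot(inherits(config, "mcmc_config"), inherits(priors, "prior_spec"))
  item_levels <- if ("item" %in% names(children))
    unique(stats::na.omit(children$item)) else "any_public"
  if (length(item_levels) == 0) item_levels <- "any_public"
  agg <- aggregate_responses(children, item_levels)
  n_items <- length(item_levels)

  # default identifiability constraints
  fix <- fix %||% list()
  fix_ab_items <- if (n_items == 1) 1L else 1L  # anchor first item
  fixed <- list()
  for (nm in c("alpha", "beta_time", "beta_urban"))
    if (!is.null(fix[[nm]])) fixed[[nm]] <- fix[[nm]]
  expand_item <- function(v) if (length(v) == 1) rep(v, n_items) else v
  a_fix <- if (!is.null(fix$a)) expand_item(fix$a) else {
    v <- rep(NA_real_, n_items); v[fix_ab_items] <- 1; v
  }
  b_fix <- if (!is.null(fix$b)) expand_item(fix$b) else {
    v <- rep(NA_real_, n_items); v[fix_ab_items] <- 0; v
  }
  c_fix <- if (!is.null(fix$c)) expand_item(fix$c) else rep(NA_real_, n_items)

  # sampling-scale state template and free-parameter registry
  init <- init %||% list()
  st0 <- c(alpha = init$alpha %||% 0,
           bt_hr = (init$beta_time %||% 0) * 60,
           bu = init$beta_urban %||% 0)
  for (i in seq_len(n_items)) {
    st0[paste0("ua_", i)] <- log(if (!is.na(a_fix[i])) a_fix[i] else (init$a %||% 1))
    st0[paste0("b_", i)]  <- if (!is.na(b_fix[i])) b_fix[i] else (init$b %||% 0)
    st0[paste0("uc_", i)] <- stats::qlogis(if (!is.na(c_fix[i])) c_fix[i]
                                           else (init$c %||% 0.2))
  }
  if (!is.null(fixed$alpha)) st0["alpha"] <- fixed$alpha
  if (!is.null(fixed$beta_time)) st0["bt_hr"] <- fixed$beta_time * 60
  if (!is.null(fixed$beta_urban)) st0["bu"] <- fixed$beta_urban

  free <- character(0)
  if (is.null(fixed$alpha)) free <- c(free, "alpha")
  if (is.null(fixed$beta_time)) free <- c(free, "bt_hr")
  if (is.null(fixed$beta_urban) && any(agg$urban != agg$urban[1]))
    free <- c(free, "bu")
  for (i in seq_len(n_items)) {
    if (is.na(a_fix[i])) free <- c(free, paste0("ua_", i))
    if (is.na(b_fix[i])) free <- c(free, paste0("b_", i))
    if (is.na(c_fix[i])) free <- c(free, paste0("uc_", i))
  }
  if (length(free) == 0) stop("no free parameters to sample", call. = FALSE)

  blocks <- list()
  abl <- intersect(c("alpha", "bt_hr", "bu"), free)
  if (length(abl) > 0) blocks <- c(blocks, list(abl))
  for (i in seq_len(n_items)) {
    ab <- intersect(paste0(c("ua_", "b_"), i), free)
    if (length(ab) > 0) blocks <- c(blocks, list(ab))
    if (paste0("uc_", i) %in% free) blocks <- c(blocks, list(paste0("uc_", i)))
  }

  logpost <- make_logpost(agg, priors, free)
  n_keep <- retained_draws(config)

  chains <- lapply(seq_len(config$n_chains), function(ch) {
    chain_seed <- substream_seed(config$seed, "fit") + 7919L * ch
    st <- st0
    with_seed(chain_seed - 1L, {  # over-dispersed start
      st[free] <- st[free] + stats::rnorm(length(free), 0, 0.7)
    })
    run_chain(logpost, st, free, blocks, config, chain_seed)
  })

  # natural-scale draw array: chain x draw x parameter
  par_names <- c("alpha", "beta_time", "beta_urban",
                 as.vector(t(outer(c("a", "b", "c"), seq_len(n_items),
                                   function(p, i) {
                                     if (n_items == 1) p
                                     else paste0(p, "[", item_levels[i], "]")
                                   }))))
  draws <- array(NA_real_, c(config$n_chains, n_keep, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(config$n_chains)) {
    kc <- chains[[ch]]$draws
    nat <- cbind(alpha = kc[, "alpha"], beta_time = kc[, "bt_hr"] / 60,
                 beta_urban = kc[, "bu"])
    for (i in seq_len(n_items)) {
      nat <- cbind(nat, exp(kc[, paste0("ua_", i)]),
                   kc[, paste0("b_", i)],
                   stats::plogis(kc[, paste0("uc_", i)]))
    }
    draws[ch, , ] <- nat
  }

  samples <- structure(list(draws = draws, parameters = par_names,
                            items = item_levels, config = config),
                       class = "fever_draws")
  structure(list(draws = samples, items = item_levels,
                 fixed = list(alpha = fixed$alpha, beta_time = fixed$beta_time,
                              beta_urban = if (!is.null(fixed$beta_urban))
                                fixed$beta_urban
                              else if (!("bu" %in% free)) st0[["bu"]] else NULL,
                              a = a_fix, b = b_fix, c = c_fix),
                 free = free, priors = priors, config = config,
                 acceptance = lapply(chains, `[[`, "acceptance"),
                 n_obs = sum(agg$trials)),
            class = "fever_irt_fit")
}

#' @export
print.fever_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<fever_draws> %d chain(s) x %d draws x %d parameters\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.fever_irt_fit <- function(x, ...) {
  cat("Treatment-seeking 3PL item-response fit\n")
  cat(sprintf("  %d observations, %d chain(s), %d retained draws/chain\n",
              x$n_obs, x$config$n_chains, dim(x$draws$draws)[2]))
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  print(tidy(x))
  invisible(x)
}

#' Posterior draws as a tidy tibble
#'
#' @param x a `fever_draws` object.
#' @param ... unused.
#' @return Long tibble with columns `chain`, `draw`, `parameter`, `value`.
#' @method as_tibble fever_draws
#' @export
as_tibble.fever_draws <- function(x, ...) {
  d <- dim(x$draws)
  tibble::tibble(
    chain = rep(seq_len(d[1]), times = d[2] * d[3]),
    draw = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    parameter = rep(x$parameters, each = d[1] * d[2]),
    value = as.vector(x$draws))
}

# draws matrix (all chains pooled) for one or more parameters
pooled_draws <- function(samples, parameters = NULL) {
  parameters <- parameters %||% samples$parameters
  d <- samples$draws
  m <- sapply(parameters, function(p) as.vector(d[, , p]))
  matrix(m, ncol = length(parameters),
         dimnames = list(NULL, parameters))
}

free_parameter_names <- function(fit) {
  map <- c(alpha = "alpha", bt_hr = "beta_time", bu = "beta_urban")
  vapply(fit$free, function(f) {
    if (f %in% names(map)) return(unname(map[f]))
    i <- as.integer(sub("^(ua|b|uc)_", "", f))
    p <- c(ua = "a", b = "b", uc = "c")[sub("_.*$", "", f)]
    if (length(fit$items) == 1) unname(p)
    else paste0(p, "[", fit$items[i], "]")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname fit_treatment_irt
#' @param x a `fever_irt_fit`.
#' @param ... unused.
#' @method tidy fever_irt_fit
#' @export
tidy.fever_irt_fit <- function(x, ...) {
  pars <- free_parameter_names(x)
  m <- pooled_draws(x$draws, pars)
  tibble::tibble(
    term = pars,
    estimate = apply(m, 2, stats::median),
    mean = colMeans(m),
    std.error = apply(m, 2, stats::sd),
    conf.low = apply(m, 2, stats::quantile, 0.025),
    conf.high = apply(m, 2, stats::quantile, 0.975))
}

#' @rdname fit_treatment_irt
#' @method glance fever_irt_fit
#' @export
glance.fever_irt_fit <- function(x, ...) {
  psrf <- if (x$config$n_chains >= 2)
    max(vapply(free_parameter_names(x),
               function(p) gelman_rubin(x$draws, p), numeric(1)))
  else NA_real_
  tibble::tibble(n_obs = x$n_obs, n_chains = x$config$n_chains,
                 n_draws = dim(x$draws$draws)[2] * x$config$n_chains,
                 max_psrf = psrf,
                 mean_acceptance = mean(unlist(x$acceptance), na.rm = TRUE))
}

#' Trace plot of posterior draws
#'
#' @param object a `fever_irt_fit`.
#' @param parameters parameters to show (default: all free).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fever_irt_fit
#' @export
autoplot.fever_irt_fit <- function(object, parameters = NULL, ...) {
  parameters <- parameters %||% free_parameter_names(object)
  df <- as_tibble(object$draws) |>
    dplyr::filter(.data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(.data$draw, .data$value,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = "value", colour = "chain") +
    ggplot2::theme_minimal()
}
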