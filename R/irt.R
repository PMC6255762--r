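#' Three-parameter logistic response probability
#'
#' The probability that a child with latent ability `theta` yields a
#' positive treatment response on an item with discrimination `a`,
#' difficulty `b` and floor `c`:
#' \deqn{P = c + (1 - c) \frac{e^{a\theta - b}}{1 + e^{a\theta - b}}.}
#' The floor `c` is the minimum probability, approached as ability falls
#' (here: as travel time grows); `a` scales how sharply the curve rises and
#' `b` shifts it. Vectorised over all arguments; numerically stable for
#' extreme linear predictors.
#'
#' @param theta latent ability (any real).
#' @param a discrimination, `> 0`.
#' @param b difficulty.
#' @param c floor probability in `[0, 1]` (the generative model uses
#'   `(0, 1]`; `c = 0` gives the plain two-parameter logistic).
#' @return Probabilities in `[c, 1]`.
#' @export
item_probability <- function(theta, a = 1, b = 0, c = 0) {
  if (any(a <= 0)) stop("discrimination a must be > 0", call. = FALSE)
  if (any(c < 0 | c > 1)) stop("floor c must lie in [0, 1]", call. = FALSE)
  c + (1 - c) * stats::plogis(a * theta - b)
}

#' Ability regression coefficients
#'
#' The latent ability is a deterministic linear function of each child's
#' covariates: `theta = alpha + beta_time * travel_time_min + beta_urban *
#' urban`. `beta_time` is expressed per minute of travel time.
#'
#' @param alpha intercept.
#' @param beta_time slope per minute of travel time.
#' @param beta_urban shift for urban residence.
#' @return A list of class `ability_model`.
#' @export
ability_model <- function(alpha = 0, beta_time = 0, beta_urban = 0) {
  out <- list(alpha = alpha, beta_time = beta_time, beta_urban = beta_urban)
  if (any(!is.finite(unlist(out)))) stop("coefficients must be finite", call. = FALSE)
  structure(out, class = "ability_model")
}

#' Prior specification for the Bayesian fit
#'
#' Priors follow the model's constraints: a half-normal (normal truncated to
#' the positive line) on each discrimination `a`, a beta prior on each floor
#' `c`, and normal priors on difficulties, the ability intercept and the
#' ability slopes. Slope priors are stated on the per-hour scale (travel
#' time is divided by 60 inside the sampler) so that a unit-variance normal
#' is weakly informative for realistic distance-decay strengths.
#'
#' @param mu_a,sigma_a location and scale of the truncated normal on `a`.
#' @param c_shape1,c_shape2 beta shapes for `c`; the default `Beta(2, 5)`
#'   mildly favours small floors.
#' @param b_mean,b_sd normal prior on difficulties.
#' @param alpha_mean,alpha_sd normal prior on the ability intercept.
#' @param beta_mean,beta_sd normal prior on the ability slopes
#'   (per-hour travel-time coefficient and the urban shift).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(mu_a = 0, sigma_a = 2.5, c_shape1 = 2, c_shape2 = 5,
                       b_mean = 0, b_sd = 5, alpha_mean = 0, alpha_sd = 5,
                       beta_mean = 0, beta_sd = 1) {
  if (sigma_a <= 0 || c_shape1 <= 0 || c_shape2 <= 0 ||
      b_sd <= 0 || alpha_sd <= 0 || beta_sd <= 0)
    stop("prior scales and shapes must be positive", call. = FALSE)
  structure(list(mu_a = mu_a, sigma_a = sigma_a,
                 c_shape1 = c_shape1, c_shape2 = c_shape2,
                 b_mean = b_mean, b_sd = b_sd,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_mean = beta_mean, beta_sd = beta_sd),
            class = "prior_spec")
}

#' MCMC schedule
#'
#' Chain length bookkeeping for the Metropolis-within-Gibbs sampler. The
#' number of retained draws per chain is
#' `floor((n_iterations - burn_in) / thinning)`. The default desk-scale
#' schedule (22,000 iterations, 2,000 burn-in, thinning 10, three chains)
#' retains 2,000 draws per chain; a production schedule of 550,000
#' iterations with 50,000 burn-in and thinning 500 retains exactly 1,000.
#'
#' @param n_iterations total iterations per chain.
#' @param burn_in iterations discarded before retention (proposal scales
#'   adapt only here).
#' @param thinning keep every `thinning`-th post-burn-in iteration.
#' @param n_chains number of independent chains (at least 2 for the
#'   Gelman-Rubin diagnostic).
#' @param seed integer seed; each chain derives its own substream.
#' @param adapt adapt proposal scales during burn-in (target acceptance
#'   20--50%).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 22000, burn_in = 2000, thinning = 10,
                        n_chains = 3, seed = 1L, adapt = TRUE) {
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations", call. = FALSE)
  if (thinning < 1) stop("thinning must be >= 1", call. = FALSE)
  if (n_chains < 1) stop("n_chains must be >= 1", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "mcmc_config")
}

#' Retained draws implied by an MCMC schedule
#'
#' @param config an [mcmc_config()].
#' @return `floor((n_iterations - burn_in) / thinning)`, an integer.
#' @export
retained_draws <- function(config) {
  as.integer(floor((config$n_iterations - config$burn_in) / config$thinning))
}

#' Bernoulli log-likelihood of the treatment responses
#'
#' Sums `Y log P + (1 - Y) log(1 - P)` over all non-missing responses, with
#' `P` from [item_probability()] at each child's ability. Missing responses
#' contribute nothing (missing-at-random).
#'
#' @param children tibble with columns `response` (0/1/NA),
#'   `travel_time_min`, `urban` and optionally `item` (defaults to the
#'   first item).
#' @param items tibble with columns `item`, `a`, `b`, `c`.
#' @param ability an [ability_model()] (or a bare list with the same
#'   elements).
#' @return The log-likelihood (0 for an empty response set).
#' @export
log_likelihood <- function(children, items, ability) {
  y <- children$response
  keep <- !is.na(y)
  y <- y[keep]
  if (length(y) == 0) return(0)
  if (!all(y %in% c(0L, 1L)))
    stop("responses must be 0, 1 or missing", call. = FALSE)
  it <- if ("item" %in% names(children)) children$item[keep] else items$item[1]
  ii <- match(it, items$item)
  if (anyNA(ii)) stop("response maps to unregistered item", call. = FALSE)
  theta <- ability$alpha + ability$beta_time * children$travel_time_min[keep] +
    ability$beta_urban * children$urban[keep]
  p <- item_probability(theta, items$a[ii], items$b[ii], items$c[ii])
  sum(ifelse(y == 1, log(p), log1p(-p)))
}

# log density of N(mu, sd) truncated to (0, Inf)
log_dtnorm_pos <- function(x, mu, sd) {
  ifelse(x > 0,
         stats::dnorm(x, mu, sd, log = TRUE) -
           stats::pnorm(0, mu, sd, lower.tail = FALSE, log.p = TRUE),
         -Inf)
}

#' Joint log prior density
#'
#' Sum of the log prior densities of [prior_spec()] over item and ability
#' parameters, on the natural scale. Returns `-Inf` outside the support
#' (non-positive `a`, `c` outside `(0, 1)`). The travel-time slope prior is
#' evaluated on the per-hour coefficient `beta_time * 60`.
#'
#' @inheritParams log_likelihood
#' @param priors a [prior_spec()].
#' @return The log prior density.
#' @export
log_prior <- function(items, ability, priors) {
  lp <- sum(log_dtnorm_pos(items$a, priors$mu_a, priors$sigma_a)) +
    sum(stats::dbeta(items$c, priors$c_shape1, priors$c_shape2, log = TRUE)) +
    sum(stats::dnorm(items$b, priors$b_mean, priors$b_sd, log = TRUE)) +
    stats::dnorm(ability$alpha, priors$alpha_mean, priors$alpha_sd, log = TRUE) +
    stats::dnorm(ability$beta_time * 60, priors$beta_mean, priors$beta_sd, log = TRUE) +
    stats::dnorm(ability$beta_urban, priors$beta_mean, priors$beta_sd, log = TRUE)
  if (is.nan(lp)) -Inf else lp
}
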