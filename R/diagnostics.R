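#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance diagnostic,
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}},}
#' where `W` is the mean within-chain variance and `B` the between-chain
#' variance of the chain means, over `n` retained draws per chain. Values
#' near 1 indicate the chains have mixed.
#'
#' @param samples a `fever_draws` object (at least two chains), or a
#'   numeric matrix with one column per chain.
#' @param parameter parameter name when `samples` is a `fever_draws`.
#' @return The PSRF, a single number.
#' @export
gelman_rubin <- function(samples, parameter = NULL) {
  m <- if (inherits(samples, "fever_draws")) {
    stopifnot(!is.null(parameter))
    d <- dim(samples$draws)
    t(matrix(samples$draws[, , parameter], d[1], d[2]))
  } else as.matrix(samples)
  if (ncol(m) < 2) stop("Gelman-Rubin requires at least two chains", call. = FALSE)
  n <- nrow(m)
  if (n < 10) stop("need at least 10 retained draws per chain", call. = FALSE)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Raftery-Lewis run-length diagnostic
#'
#' Estimates how many MCMC iterations are needed to estimate the posterior
#' quantile `q` to within `+/- r` with probability `s`. The chain is
#' binarised at its `q`-quantile, a thinning interval `k` is chosen as the
#' smallest at which the binary chain passes a first-order Markov test
#' (BIC comparison against second order), and the required burn-in and run
#' length follow from the fitted two-state transition probabilities. The
#' independent-chain minimum is `N_min = ceiling(z^2 q (1-q) / r^2)` with
#' `z` the `(1+s)/2` normal quantile; the dependence factor is the ratio of
#' the required run length to `N_min`.
#'
#' @param chain numeric vector of draws (length at least 100).
#' @param q posterior quantile of interest.
#' @param r required precision of the quantile estimate.
#' @param s probability of achieving that precision.
#' @param eps convergence tolerance used for the burn-in bound.
#' @return A list: `N` (required iterations), `burn_in`, `thin_k`,
#'   `N_min`, `dependence_factor`.
#' @export
raftery_lewis <- function(chain, q = 0.025, r = 0.005, s = 0.95,
                          eps = 0.001) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100) stop("chain must have at least 100 draws", call. = FALSE)
  if (stats::sd(chain) == 0)
    stop("degenerate chain: all values identical", call. = FALSE)
  phi <- stats::qnorm(0.5 * (1 + s))
  n_min <- ceiling(phi^2 * q * (1 - q) / r^2)

  cutoff <- stats::quantile(chain, q, names = FALSE)
  z <- as.integer(chain <= cutoff)

  k <- 0
  repeat {
    k <- k + 1
    zt <- z[seq(1, n, by = k)]
    if (length(zt) < 3 || length(unique(zt)) < 2)
      stop("binarised chain is degenerate at the chosen quantile", call. = FALSE)
    tri <- table(factor(zt[1:(length(zt) - 2)], 0:1),
                 factor(zt[2:(length(zt) - 1)], 0:1),
                 factor(zt[3:length(zt)], 0:1))
    g2 <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
      if (tri[i1, i2, i3] == 0) next
      fitted <- sum(tri[i1, i2, ]) * sum(tri[, i2, i3]) / sum(tri[, i2, ])
      g2 <- g2 + 2 * tri[i1, i2, i3] * log(tri[i1, i2, i3] / fitted)
    }
    bic <- g2 - 2 * log(length(zt) - 2)
    if (bic < 0 || k > n / 100) break
  }

  zt <- z[seq(1, n, by = k)]
  tr <- table(factor(zt[-length(zt)], 0:1), factor(zt[-1], 0:1))
  alpha <- tr["0", "1"] / sum(tr["0", ])   # 0 -> 1
  beta <- tr["1", "0"] / sum(tr["1", ])    # 1 -> 0
  ab <- alpha + beta
  burn <- if (ab > 0 && abs(1 - ab) > 0 && abs(1 - ab) < 1) {
    ceiling(log(eps * ab / max(alpha, beta)) / log(abs(1 - ab))) * k
  } else 0
  n_prec <- ceiling(alpha * beta * (2 - ab) / ab^3 * (phi / r)^2) * k
  list(N = burn + n_prec, burn_in = burn, thin_k = k,
       N_min = as.integer(n_min),
       dependence_factor = (burn + n_prec) / n_min)
}

#' Convergence report for a fitted model
#'
#' Per-parameter Gelman-Rubin PSRF together with the Raftery-Lewis
#' run-length requirement (computed per chain; the worst chain is
#' reported), and a pass flag.
#'
#' @param fit a `fever_irt_fit`.
#' @param q,r,s Raftery-Lewis settings.
#' @param psrf_threshold pass threshold on the PSRF (1.1 is the usual rule
#'   of thumb).
#' @return A tibble with one row per free parameter: `parameter`, `psrf`,
#'   `rl_N`, `rl_N_min`, `rl_dependence`, `pass`.
#' @export
convergence_report <- function(fit, q = 0.025, r = 0.005, s = 0.95,
                               psrf_threshold = 1.1) {
  pars <- free_parameter_names(fit)
  purrr::map_dfr(pars, function(p) {
    psrf <- if (fit$config$n_chains >= 2) gelman_rubin(fit$draws, p) else NA_real_
    rl <- lapply(seq_len(fit$config$n_chains), function(ch) {
      tryCatch(raftery_lewis(fit$draws$draws[ch, , p], q, r, s),
               error = function(e) NULL)
    })
    rl <- rl[!vapply(rl, is.null, logical(1))]
    worst <- if (length(rl) > 0) rl[[which.max(vapply(rl, `[[`, 0, "N"))]] else NULL
    tibble::tibble(parameter = p, psrf = psrf,
                   rl_N = worst$N %||% NA_real_,
                   rl_N_min = worst$N_min %||% NA_integer_,
                   rl_dependence = worst$dependence_factor %||% NA_real_,
                   pass = !is.na(psrf) && psrf < psrf_threshold)
  })
}
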