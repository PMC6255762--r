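# Shared fixtures and independent oracles; everything is generated in code.

tiny_config <- function(seed = 1L, ...) {
  args <- list(grid_width = 24, grid_height = 24, cell_size = 1000,
               n_facilities_per_tier = c(hospital = 1, health_centre = 2,
                                         dispensary = 4),
               n_admin_units = 4, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(landscape_config, args)
}

# batch-means Monte-Carlo standard errors of the mean and sd of draws
# (per-chain batches, so between-chain disagreement is counted)
batch_mcse <- function(chain_matrix, batch = 100) {
  bm <- c(); bs <- c()
  for (ch in seq_len(nrow(chain_matrix))) {
    x <- chain_matrix[ch, ]
    nb <- floor(length(x) / batch)
    m <- matrix(x[seq_len(nb * batch)], batch)
    bm <- c(bm, colMeans(m))
    bs <- c(bs, apply(m, 2, sd))
  }
  list(mean = sd(bm) / sqrt(length(bm)), sd = sd(bs) / sqrt(length(bs)))
}

# a flat raster with one value everywhere
flat_raster <- function(value, nr = 10, nc = 10, cell = 1000) {
  fever_raster(matrix(value, nr, nc), cell)
}

# child table simulated straight from the 3PL model at given covariates
make_children <- function(t_min, urban, alpha = 0.5, beta_time = -0.01,
                          beta_urban = 0, a = 1, b = 0, c = 0.2, seed = 1) {
  withr::with_seed(seed, {
    p <- item_probability(alpha + beta_time * t_min + beta_urban * urban,
                          a, b, c)
    tibble::tibble(response = stats::rbinom(length(t_min), 1L, p),
                   travel_time_min = t_min, urban = as.integer(urban))
  })
}

# hand-built posterior draws container (single chain)
make_draws <- function(alpha, beta_time = 0, beta_urban = 0,
                       a = 1, b = 0, c = 0.2) {
  n <- max(lengths(list(alpha, beta_time, beta_urban, a, b, c)))
  m <- cbind(alpha = rep_len(alpha, n), beta_time = rep_len(beta_time, n),
             beta_urban = rep_len(beta_urban, n), a = rep_len(a, n),
             b = rep_len(b, n), c = rep_len(c, n))
  arr <- array(NA_real_, c(1, n, 6),
               dimnames = list(NULL, NULL, colnames(m)))
  arr[1, , ] <- m
  structure(list(draws = arr, parameters = colnames(m),
                 items = "any_public", config = NULL),
            class = "fever_draws")
}

# Exhaustive least-cost oracle: depth-first search over all simple paths
# from every source, with branch-and-bound pruning (prunes only paths that
# provably cannot improve, so the result equals full enumeration).
brute_force_times <- function(speed, cell_size, sources) {
  nr <- nrow(speed); nc <- ncol(speed)
  best <- matrix(Inf, nr, nc)
  ok <- !is.na(speed) & speed > 0
  edge_min <- function(r1, c1, r2, c2) {
    d_km <- cell_size / 1000 * sqrt((r1 - r2)^2 + (c1 - c2)^2)
    d_km / 2 * (1 / speed[r1, c1] + 1 / speed[r2, c2]) * 60
  }
  dfs <- function(r, c, t, visited) {
    # prune only when the current prefix provably cannot improve any cell:
    # with non-negative edge costs a dearer prefix to (r, c) cannot beat
    # continuations of the cheaper one
    if (t >= best[r, c]) return(invisible())
    best[r, c] <<- t
    visited[r, c] <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!ok[r2, c2] || visited[r2, c2]) next
      dfs(r2, c2, t + edge_min(r, c, r2, c2), visited)
    }
  }
  for (s in seq_len(nrow(sources))) {
    r <- sources[s, 1]; c <- sources[s, 2]
    if (ok[r, c]) dfs(r, c, 0, matrix(FALSE, nr, nc))
  }
  best[!ok] <- NA_real_
  best[is.infinite(best)] <- NA_real_
  best
}

# Mann-Whitney pair-count AUC oracle, O(n^2)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
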