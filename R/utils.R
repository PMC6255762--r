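#' @importFrom tibble as_tibble
#' @importFrom generics tidy glance
NULL

#' @export
tibble::as_tibble

# Evaluate code under a temporary RNG state so package functions never
# disturb the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-stage substream of a master seed, so adding or removing
# one stage never perturbs another stage's draws.
substream_seed <- function(master, stage) {
  offsets <- c(landscape = 11L, clusters = 23L, displace = 37L,
               responses = 51L, holdout = 67L, fit = 83L,
               validate = 101L, acceptance = 113L)
  off <- offsets[[stage]] %||% (1000L + nchar(stage))
  as.integer((as.double(master) * 1009 + off * 9973) %% 2147483629)
}

#' @export
generics::tidy

#' @export
generics::glance
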