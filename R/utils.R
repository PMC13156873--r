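#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used wherever a printed statistic in the
#' package is defined to one decimal, and for the sample-extrapolation
#' estimator. Base R's `round()` rounds halves to even, which would make
#' e.g. `round(0.5) == 0`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(0.25, 1)    # 0.3
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic package code funnels through
# this so simulations never disturb (nor depend on) the global stream.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed
#'
#' Mixes a base seed with one or more non-negative integer indices through a
#' multiplicative-congruential hash so that every cell of a simulation grid
#' (dataset i, prior fraction j, replicate k) owns an independently
#' reproducible seed. The result is always in `[1, 2^31 - 2]`.
#'
#' @param base_seed Integer base seed.
#' @param ... Non-negative integer indices identifying the cell.
#' @return A single integer seed.
#' @export
mix_seed <- function(base_seed, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; products stay exact in doubles
  h <- as.numeric(base_seed) %% m
  for (x in c(...)) {
    h <- (h * 48271 + as.numeric(x) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
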