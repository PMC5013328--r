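#' Round half away from zero
#'
#' Nearest-integer rounding with .5 always rounded up, used wherever a real
#' centroid coordinate is snapped to a pixel. Base `round()` rounds half to
#' even, which would make patch windows depend on parity.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# clip numeric values into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# validate a (min, max) range
check_range <- function(x, name) {
  if (length(x) != 2 || !is.numeric(x) || any(!is.finite(x)) || x[1] > x[2] ||
      any(x <= 0)) {
    abort(sprintf("`%s` must be a positive (min, max) pair with min <= max", name))
  }
  invisible(x)
}

# draw uniformly from a (min, max) range
runif_range <- function(n, range) runif(n, range[1], range[2])

# stable seed stream: draw n child seeds reproducibly from the current RNG
draw_seeds <- function(n) sample.int(.Machine$integer.max, n)
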