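# RNG hygiene: seed the generator for a reproducible block and hand back a
# restorer for the caller's RNG state (used via on.exit).
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Back-derive a standard error from a printed confidence interval
#'
#' For a symmetric normal-theory interval, `SE = (high - low) / (2 * z)`
#' with `z` the two-sided normal quantile of the stated level (1.96 at
#' 95%). Useful for consuming published tables that print CIs but not SEs.
#'
#' @param low,high interval bounds, `low < high`.
#' @param level confidence level (default 0.95).
#' @return the implied standard error.
#' @export
#' @examples
#' se_from_ci(0.041, 0.136)  # 0.0242
se_from_ci <- function(low, high, level = 0.95) {
  stopifnot(all(low < high), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  (high - low) / (2 * z)
}

# round half away from zero (journal-table convention; base round() is
# half-to-even)
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
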