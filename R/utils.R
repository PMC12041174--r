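# internal condition helper: all package errors carry a machine-readable class
hf_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "hepaflow_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' `base::round()` rounds halves to even; printed clinical tables round
#' halves up, so exact reproduction of reported percentages needs this
#' variant (e.g. 6.25 -> 6 at 0 digits is wrong for such tables: half-up
#' gives 6 only because 6.25 < 6.5; 21.305 -> 21.3 at one digit).
#'
#' @param x numeric vector.
#' @param digits integer; decimal places kept.
#' @return `x` rounded with ties going away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package randomness goes through
# this so no global state leaks.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
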