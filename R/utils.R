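#' @useDynLib eodcoding, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Derive a child seed from a master seed
#'
#' Counter-based fan-out of independent RNG streams: each named stage of the
#' pipeline (scene noise for fish n, per-unit intrinsic noise, calibration)
#' draws its seed as `child_seed(master, stream)` with a fixed stream index,
#' so adding a unit never perturbs the scene realization.
#'
#' @param master master seed (integer-valued).
#' @param stream non-negative stream index (integer-valued, < 2^20).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, stream) {
  m <- as.double(master) %% 2147483647
  s <- as.double(stream) %% 1048576
  # multiplicative hash; all intermediates stay below 2^53 so doubles are exact
  x <- (m * 48271 + s * 69621 + 11) %% 2147483629
  as.integer(x + 1)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the global stream.
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
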