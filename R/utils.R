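# Small shared helpers.

#' Round half away from zero
#'
#' Decimal rounding where exact halves go up (away from zero), as used in
#' all reported statistics in this package. Base R's `round()` rounds
#' half-to-even, which disagrees with conventional report rounding at
#' values such as 0.5 at the last printed digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Reverse-complement of an IUPAC DNA string (plain character, any length).
rev_comp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# stopifnot with a custom message
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
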