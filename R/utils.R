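# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero (the rendering convention for percentage tables;
# base round() is half-to-even).
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Format a rate as a whole-number percentage with its spread
#'
#' Renders `mean` and `sd` (both fractions in \[0, 1\]) in the
#' `"84 ± 3%"` convention used for performance tables: percentages
#' rounded half-away-from-zero to integers.
#'
#' @param mean,sd Numeric fractions in \[0, 1\].
#' @return A character scalar, e.g. `"84 ± 3%"`.
#' @examples
#' formatPct(0.842, 0.031)
#' @export
formatPct <- function(mean, sd) {
  if (is.na(mean)) return(NA_character_)
  sprintf("%d ± %d%%", roundHalfUp(100 * mean), roundHalfUp(100 * sd))
}

# Re-raise any error from `expr` with the pipeline stage named, so failures
# deep in a repeated run say which stage broke.
stageCall <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s stage: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

# Largest-remainder apportionment of n units to fractions f (sums to n).
# Ties in the fractional remainders go to the earlier entry of f.
largestRemainder <- function(n, f) {
  target <- n * f
  base <- floor(target)
  rem <- as.integer(round(n - sum(base)))
  frac <- target - base
  if (rem > 0) {
    ord <- order(-frac, seq_along(f))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
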