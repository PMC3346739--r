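# small shared helpers

#' Round half away from zero
#'
#' Integer-style rounding where .5 always rounds up in magnitude (2.5 -> 3),
#' unlike [base::round()]'s round-half-even. Used for the printed percentages
#' in cluster composition tables (e.g. 4/13 -> 31%).
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(100 * 4 / 13)  # 31
#' roundHalfUp(2.5)           # 3
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit seed derived from a string label and a base seed.
# Gives each synthetic population its own stream independent of list order.
stringSeed <- function(label, base) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(base) %% 1000003 * 1009 + h * 97) %% 2147483647L)
}

# stop() with a stage prefix so pipeline failures name the failing stage
stopStage <- function(stage, fmt, ...) {
  stop(sprintf("stage '%s': %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

fmtNum <- function(x) {
  out <- rep("NA", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}
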