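# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards; makes simulation output a pure function of
# (configuration, seed).
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoidal integral of y over x (x need not be sorted; integrates on the
# ascending ordering so the result is orientation-independent).
trapz <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @importFrom utils head tail
NULL

degToRad <- function(deg) deg * pi / 180

# ppm axis of a scheme, descending (downfield left), DFT convention:
# n points of spacing bandwidth/n starting at center + bandwidth/2.
schemeAxisPpm <- function(scheme) {
  n <- scheme@spectralPoints
  d <- scheme@bandwidthPpm / n
  scheme@centerPpm + scheme@bandwidthPpm / 2 - (seq_len(n) - 1) * d
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
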