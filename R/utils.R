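# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals, the convention used when
# comparing derived quantities with values printed at fixed precision.
#' Round half-up to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed-value comparisons in this
#' package use the conventional half-up rule instead (2.35 -> 2.4 at one
#' decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage child seed from a global seed; keeps results < 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(phantom = 101L, scan = 211L, recon = 307L, metrics = 401L,
               trace = 503L, misc = 601L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.double(seed) * 7919 + off) %% 2147483647)
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(class, "axotomo_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
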