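#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic generators in the package funnel through this so that a
## fixed seed gives bit-identical output regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministic 31-bit sub-seed derived from a global seed and a stage name.
## FNV-style string hash; stage-level reproducibility does not depend on the
## order stages execute in.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 17
  for (b in utf8ToInt(stage)) {
    h <- (h * 69069 + b) %% 2147483647   # stays well inside double precision
  }
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

## Linear interpolation that returns NA outside the support (no rule-2
## extrapolation surprises).
interp_na <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 1)$y
}
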