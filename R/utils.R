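#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream sub-seed below 2^31, so that each generator stage
# draws from its own reproducible stream.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 1009 + h * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Day of year as used by the seasonal harmonics.
day_of_year <- function(dates) as.integer(format(dates, "%j"))

# Elapsed time in decades (1 decade = 3652.5 days) since `origin`.
elapsed_decades <- function(dates, origin = dates[1]) {
  as.numeric(dates - origin) / 3652.5
}

stars_for_p <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("field '%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
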