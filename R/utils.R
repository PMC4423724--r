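# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All exported stochastic entry points funnel
# their randomness through this so a fixed seed is bit-reproducible regardless
# of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a per-task child seed from a master seed; keeps results independent of
# how many RNG draws the surrounding code performs. Stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647L)
}

# Shortest decimal representation that round-trips through as.numeric().
# Values in sparse SVM data are overwhelmingly repeated (mostly 1), so format
# unique values once.
format_shortest <- function(x) {
  ux <- unique(x)
  fu <- vapply(ux, function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
  fu[match(x, ux)]
}

stss_log <- function(level = "info", ..., .level = getOption("stss.log_level", "info")) {
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L, quiet = 5L)
  if (ranks[[level]] >= ranks[[.level %||% "info"]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
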