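# Internal helpers: error conditions, seed handling, numeric formatting.

abort_axismr <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "axismr_error"), call = call))
}

input_error      <- function(msg) abort_axismr(msg, "axismr_input_error")
config_error     <- function(msg) abort_axismr(msg, "axismr_config_error")
io_error         <- function(msg) abort_axismr(msg, "axismr_io_error")
estimation_error <- function(msg) abort_axismr(msg, "axismr_estimation_error")
screening_error  <- function(msg) abort_axismr(msg, "axismr_screening_error")

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards,
# so seeded internals (bootstraps, simulations) never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Repr-faithful numeric formatting: 17 significant digits survive a
# write/read round trip exactly for doubles.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
  out
}

z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# 95% normal CI half-width multiplier, fixed so CIs are reproducible digit
# for digit across platforms.
Z975 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ensure a list of datasets is named and that each element's trait_id
# matches its list name (list names take precedence in orchestration).
name_datasets <- function(l) {
  nm <- names(l)
  if (is.null(nm)) {
    nm <- vapply(l, function(d) attr(d, "trait_id") %||% "trait", character(1))
    names(l) <- nm
  }
  for (i in seq_along(l)) attr(l[[i]], "trait_id") <- nm[i]
  l
}
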