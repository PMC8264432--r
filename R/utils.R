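# Internal helpers: structured errors, RNG scoping, small numeric utilities.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "autoplan_error", "error")))
}

abort_argument <- function(msg) abort(msg, "autoplan_argument_error")
abort_geometry <- function(msg) abort(msg, "autoplan_geometry_error")
abort_format   <- function(msg) abort(msg, "autoplan_format_error")
abort_shape    <- function(msg) abort(msg, "autoplan_shape_error")
abort_training <- function(msg) abort(msg, "autoplan_training_error")

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_argument(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort_argument(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}

same_dim <- function(a, b) identical(dim(a), dim(b))

as_mask <- function(x) {
  storage.mode(x) <- "logical"
  x
}
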