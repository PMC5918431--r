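# Typed conditions used across the package.  Every user-facing error carries a
# subclass so callers (and the command-line wrapper) can map failures to exit
# codes without string matching.

abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mutembed_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_format     <- function(message) abort(message, "mutembed_format_error")
abort_empty      <- function(message) abort(message, c("mutembed_empty_input_error", "mutembed_data_error"))
abort_validation <- function(message) abort(message, "mutembed_validation_error")
abort_config     <- function(message) abort(message, "mutembed_config_error")
abort_degenerate <- function(message) abort(message, c("mutembed_degenerate_input_error", "mutembed_data_error"))

# Run an expression with R's RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.  All stochastic operations in the package route through
# this so a single integer seed makes a whole analysis reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
  }
  expr
}
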