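# internal helpers shared across modules

# classed errors so callers/tests can distinguish failure modes
stop_ionspike <- function(msg, class, call = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "ionspike_error", "error", "condition"),
    list(message = msg, call = call))
  stop(cnd)
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# half-up rounding used for the one-decimal reporting view of scaling factors
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_ionspike(sprintf("`%s` must be a finite scalar in [%g, %g]",
                          name, lower, upper), "ionspike_domain_error")
  invisible(x)
}
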