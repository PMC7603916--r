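# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "mbfpet_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

# Error subclasses used for CLI exit-code mapping
stop_invalid  <- function(fmt, ...) stopf(fmt, ..., class = "mbfpet_invalid_parameter")
stop_domain   <- function(fmt, ...) stopf(fmt, ..., class = "mbfpet_domain_error")
stop_state    <- function(fmt, ...) stopf(fmt, ..., class = "mbfpet_state_error")
stop_validate <- function(fmt, ...) stopf(fmt, ..., class = "mbfpet_validation_error")
stop_io       <- function(fmt, ...) stopf(fmt, ..., class = "mbfpet_io_error")

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_invalid("'%s' = %g outside allowed range [%g, %g]%s",
                 name, x, lower, upper,
                 if (strict_lower) " (strict lower bound)" else "")
  invisible(x)
}

# Trapezoidal integral of y over x (both numeric, same length)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Cumulative trapezoidal integral, same length as x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  c(0, cumsum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2))
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
# Keeps simulation seeding explicit without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
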