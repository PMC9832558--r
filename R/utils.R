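# Internal numerical and error helpers.

# Numerically stable log(1 + exp(x)); linear for large x, exp(x) for very
# negative x (log1p(exp(x)) already underflows correctly there).
log1pexp <- function(x) {
  r <- x
  small <- x <= 33
  r[small] <- log1p(exp(x[small]))
  r
}

# Validation failures carry a dedicated condition class so callers (and the
# command-line wrapper) can distinguish bad input (exit 2) from internal errors.
stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pike_validation_error", "validationError")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Laplace (double-exponential) log-density with rate parameterization:
# f(x) = rate/2 * exp(-rate * |x|).
dlaplace_log <- function(x, rate) log(rate / 2) - rate * abs(x)
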