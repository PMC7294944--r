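# internal helpers shared across modules

# fail with a classed condition so callers/tests can distinguish
# user-input problems from bugs
stop_input <- function(msg, class = "lrx_input_error") {
  rlang::abort(msg, class = c(class, "lrx_error"))
}

stop_format <- function(msg) {
  stop_input(msg, class = "lrx_format_error")
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_input(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_input(sprintf("`%s` must be a number in [%g, %g]", name, lo, hi))
  }
  as.numeric(x)
}

# derive a reproducible child seed from a run seed; keeps results
# independent of the order in which stages consume randomness.
# result stays below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
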