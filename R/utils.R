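#' @keywords internal
"_PACKAGE"

# Deterministic child-seed splitting: one master seed, children indexed by
# (participant, sample) or (cohort). Coefficients are coprime and the index
# ranges used in practice (<= 1e3 participants, <= 1e2 samples) cannot collide.
# Result stays inside the 32-bit integer range R requires of set.seed().
child_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 10007 +
                as.numeric(j) * 101) %% 2147483647)
}

clip <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_invalid(what, " must lie in [0, 1]")
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_invalid(what, " must be a single integer >= ", min)
  }
  invisible(as.integer(x))
}
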