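# internal helpers shared across modules

# deterministic child seed: keep below 2^31 even for large base seeds
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset) %% 2147483647
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

# nearest sample index of time `t` on an axis starting at t0 with rate fs
time_index <- function(t, t0, fs) as.integer(round((t - t0) * fs)) + 1L

# inclusive index range for a [lo, hi] window on a numeric axis.
# half-sample tolerance so grid round-off never drops an endpoint pixel.
axis_window <- function(axis, lo, hi) {
  step <- if (length(axis) > 1L) min(diff(axis)) else 1
  which(axis >= lo - step / 2 & axis <= hi + step / 2)
}
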