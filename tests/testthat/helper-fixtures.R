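# Shared fixtures, generated once per test run and memoized. Sizes are scaled
# to keep the suite fast; the full-scale study conditions are exercised in
# test-acceptance.R.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_params <- function(...) {
  generator_params(n_neurons = 50L, n_frames_baseline = 1500L,
                   n_frames_ts = 2500L, ...)
}

small_session <- function() {
  fixture("small_session", generate_session(small_params(), day = 1, seed = 11))
}

# the study-scale session: 200 neurons, 12,000 TS frames, seed 1
default_session <- function() {
  fixture("default_session", generate_session(generator_params(), day = 1, seed = 1))
}

manifold_params <- function(...) {
  generator_params(n_neurons = 100L, n_frames_baseline = 2000L,
                   n_frames_ts = 4000L, ...)
}

manifold_config <- function(...) {
  analysis_config(isomap_neighbors = 100, ...)
}

expect_within <- function(x, center, tol) {
  expect_true(abs(x - center) <= tol,
              label = sprintf("%.4f within %g +/- %g", x, center, tol))
}
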