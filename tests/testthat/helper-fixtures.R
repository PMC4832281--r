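# Shared fixtures. The default model and its control steady state are
# memoised because several files need them and settling is the slow part.

default_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- cam_model()
    m
  }
})

control_state <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- steady_state(default_model())
    s
  }
})

# the square-wave oscillatory reference signature (average 0.16 uM,
# 0.52/0.10 uM levels, period 40 s, 400 s duration)
reference_piecewise <- function(period = 40, duration = 400, ...) {
  piecewise_signature(0.16, 0.52, 0.10, period = period,
                      duration = duration, ...)
}

# a short, cheap signature for pipeline tests (two spikes, 1200 s readout)
short_piecewise <- function() reference_piecewise(duration = 80)

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)),
            rel_tol)
}
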