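# Shared fixtures: the full synthetic model is built once, and the settled
# model (expensive) is created lazily and cached for the protocol and
# acceptance tests.
.fixtures <- new.env(parent = emptyenv())

get_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_synthetic_lss()
  .fixtures$model
}

get_settled <- function() {
  if (is.null(.fixtures$settled)) .fixtures$settled <- settle(get_model())
  .fixtures$settled
}

# small two-endplate disc for FE tests
get_disc <- function(gauss_order = 2L) {
  build_disc(new_frame(), new_frame(c(0, 0, 0.011)),
             gauss_order = gauss_order)
}

expect_vec_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
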