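# Shared fixtures. Heavy objects (the synthetic channel, the generated
# open-state model, its IV curve) are built once per test session and
# memoised here; everything is deterministic, so caching does not hide
# state.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_bundle <- function(len = 12, ...) {
  build_bundle(bundle_spec(helix_length = len, ...))
}

cached_channel <- function() {
  memo("channel", function() synthetic_closed_channel())
}

cached_channel_axis <- function() {
  memo("channel_axis", function() compute_pore_axis(cached_channel()))
}

cached_open_state <- function() {
  memo("open_state", function() generate_open_state(cached_channel()))
}

cached_iv <- function() {
  memo("iv", function() {
    sys <- pnp_from_structure(cached_open_state()$open)
    iv_curve(sys)
  })
}

# mean theta over chains for one residue from a helix_rotation table
rot_mean <- function(rot, rs) {
  unique(rot$theta_mean[rot$resseq == rs])
}

expect_equal_xyz <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as.matrix(a[, c("x", "y", "z")]) -
                      as.matrix(b[, c("x", "y", "z")]))), tol)
}
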