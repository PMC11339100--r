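# shared fixtures: small scenes and series built in code at test time

small_scene <- function(seed = 1, ...) {
  make_default_scene(seed = seed, shape = c(48, 48, 16),
                     spacing = c(2, 2, 4), ...)
}

# tiny hand-built series: values are a deterministic ramp so subtraction and
# filtering results can be computed by hand
ramp_series <- function(nx = 6, ny = 5, nz = 4, nt = 6, n_mask = 2) {
  data <- array(seq_len(nx * ny * nz * nt) %% 7, dim = c(nx, ny, nz, nt))
  ct_series(data, times = seq(0, by = 6, length.out = nt),
            integration = 5, n_mask = n_mask, spacing = c(2, 2, 4))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

expect_equal_array <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
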