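# Shared fixtures, all generated in code.

# A small smooth wood-like profile used by hand-built matrices.
fixture_profile <- function(n = 120) {
  ch <- seq_len(n)
  200 + 150 * exp(-ch / 60) + 80 * exp(-(ch - 60)^2 / 72) +
    50 * exp(-(ch - 100)^2 / 50)
}

# Adversarial coincident-spike matrix: rows 1 and 2 are affine copies
# sharing a spike at the same channel (invisible to their mutual reference
# in pass 1); row 1 carries a second, unique spike whose pass-1 replacement
# shifts row 1 in score space so that in pass 2 both rows pair with clean
# neighbours and the shared spike is exposed.
coincident_spike_fixture <- function() {
  n <- 120
  ch <- seq_len(n)
  base <- fixture_profile(n)
  c_spk <- 90
  prof_c <- rep(0, n)
  prof_c[(c_spk - 1):(c_spk + 1)] <- c(150, 300, 150)
  a_spk <- 25
  prof_a <- rep(0, n)
  prof_a[(a_spk - 1):(a_spk + 1)] <- 40 * c(0.5, 1, 0.5)
  scales <- c(1, 1.0005, 1.003, 0.999, seq(1.05, 1.23, by = 0.03))
  m <- length(scales)
  X <- matrix(0, m, n)
  set.seed(7)
  for (i in seq_len(m)) {
    jit <- if (i >= 5)
      0.05 * sin(2 * pi * ch / runif(1, 15, 40) + runif(1, 0, 6)) else 0
    X[i, ] <- scales[i] * base + jit
  }
  X[1, ] <- base + prof_c + prof_a
  X[2, ] <- 1.0005 * (base + prof_c)
  list(X = X, coincident_channels = (c_spk - 1):(c_spk + 1),
       unique_channels = (a_spk - 1):(a_spk + 1))
}

# Dense brute-force Whittaker oracle: solves (W + lambda D'D) z = W x with
# base R dense linear algebra, independent of the sparse path.
dense_whittaker <- function(x, w, lambda, order) {
  n <- length(x)
  D <- diff(diag(n), differences = order)
  solve(diag(w, n) + lambda * crossprod(D), w * x)
}

expect_rel_equal <- function(got, want, tol) {
  expect_lt(max(abs(got - want)) / max(abs(want), 1e-12), tol)
}
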