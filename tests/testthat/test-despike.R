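test_that("channel correlation matches the definition and handles degeneracy", {
  set.seed(20)
  X <- matrix(rnorm(8 * 6), 8, 6)
  R <- spectral_correlation(X)
  expect_equal(R, stats::cor(X), tolerance = 1e-12)
  expect_equal(diag(R), rep(1, 6))
  expect_true(all(abs(R) <= 1 + 1e-12))
  # perfect anticorrelation
  Y <- cbind(X[, 1], -2 * X[, 1], X[, 2])
  expect_equal(spectral_correlation(Y)[1, 2], -1, tolerance = 1e-12)
  # definition-sum oracle on a small integer matrix
  Z <- matrix(c(1, 2, 4, 7, 0, 3, 5, 2, 6, 1, 8, 3), 4, 3)
  R2 <- spectral_correlation(Z)
  for (j in 1:3) for (l in 1:3) {
    cj <- Z[, j] - mean(Z[, j]); cl <- Z[, l] - mean(Z[, l])
    expect_equal(R2[j, l],
                 sum(cj * cl) / sqrt(sum(cj^2) * sum(cl^2)),
                 tolerance = 1e-12)
  }
  # zero-variance channel: correlations zeroed, warning raised
  Z0 <- cbind(Z, 5)
  expect_warning(R3 <- spectral_correlation(Z0), "zero-variance")
  expect_equal(R3[4, 1:3], rep(0, 3))
  expect_equal(R3[4, 4], 1)
})

test_that("principal-component features match an independent SVD route", {
  set.seed(21)
  for (i in 1:5) {
    m <- sample(5:50, 1); n <- sample(3:40, 1)
    X <- matrix(rnorm(m * n), m, n) + outer(rnorm(m), rnorm(n))
    pf <- pca_features(X, variance_threshold = 0.85)
    expect_equal(sum(pf$proportions), 1, tolerance = 1e-12)
    expect_true(all(diff(pf$eigenvalues) <= 1e-10))
    # orthonormal eigenvectors
    G <- crossprod(pf$eigenvectors)
    expect_equal(G, diag(n), tolerance = 1e-8)
    # q is minimal for the cumulative threshold
    cum <- cumsum(pf$proportions)
    expect_gte(cum[pf$q], 0.85 - 1e-12)
    if (pf$q > 1) expect_lt(cum[pf$q - 1], 0.85)
    # SVD on standardized columns as the independent oracle
    Z <- scale(X)
    sv <- svd(Z)
    ev_svd <- sv$d^2 / (m - 1)
    k <- min(m - 1, n)
    expect_equal(pf$eigenvalues[seq_len(k)], ev_svd[seq_len(k)],
                 tolerance = 1e-8)
    # compare score columns only where the eigenvalue is well separated
    # (degenerate eigenspaces are defined only up to rotation)
    scores_svd <- Z %*% sv$v[, seq_len(pf$q), drop = FALSE]
    gaps <- abs(diff(c(Inf, pf$eigenvalues)))
    for (c_ in seq_len(pf$q)) {
      sep <- min(gaps[c_], if (c_ < n) gaps[c_ + 1] else Inf)
      if (sep < 1e-4 * pf$eigenvalues[1]) next
      sgn <- sign(sum(pf$scores[, c_] * scores_svd[, c_]))
      if (sgn == 0) sgn <- 1
      expect_equal(pf$scores[, c_], sgn * scores_svd[, c_], tolerance = 1e-6)
    }
  }
})

test_that("rank-one data collapse to a single component", {
  set.seed(22)
  pattern <- rnorm(30)
  X <- outer(c(1, 2, 3.5, 5), pattern) + 2
  pf <- pca_features(X, variance_threshold = 1)
  expect_identical(pf$q, 1L)
  expect_equal(pf$proportions[1], 1, tolerance = 1e-10)
})

test_that("eigenvalues solve the characteristic polynomial of R", {
  set.seed(23)
  X <- matrix(rnorm(5 * 3), 5, 3)
  pf <- pca_features(X, 0.85)
  R <- spectral_correlation(X)
  for (lam in pf$eigenvalues) {
    expect_lt(abs(det(R - lam * diag(3))), 1e-8)
  }
})

test_that("pairwise squared distances match the definition", {
  expect_equal(pairwise_sq_distances(rbind(c(0, 0), c(3, 4)))[1, 2], 25)
  set.seed(24)
  S <- matrix(rnorm(6 * 3), 6, 3)
  D <- pairwise_sq_distances(S)
  loop <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) loop[i, j] <- sum((S[i, ] - S[j, ])^2)
  expect_equal(D, loop, tolerance = 1e-12)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 6))
  expect_true(all(D >= 0))
})

test_that("most-similar-spectrum search excludes self and breaks ties low", {
  D2 <- pairwise_sq_distances(rbind(1, 2))
  expect_identical(find_mss(D2, 1), 2L)
  D <- rbind(c(0, 5, 2, 2), c(5, 0, 1, 9), c(2, 1, 0, 4), c(2, 9, 4, 0))
  expect_identical(find_mss(D, 1), 3L) # tie between 3 and 4 broken low
  set.seed(25)
  S <- matrix(rnorm(8 * 2), 8, 2)
  Dr <- pairwise_sq_distances(S)
  for (i in 1:8) {
    ord <- setdiff(order(Dr[i, ]), i)
    expect_identical(find_mss(Dr, i), ord[1])
    expect_identical(find_mss(Dr, i, excluded = ord[1]), ord[2])
  }
  expect_error(find_mss(D2, 1, excluded = 2), "No reference spectrum")
})

test_that("linear fit matches the normal equations", {
  y_star <- c(1, 2, 3)
  f <- linear_fit(y_star, y_star)
  expect_equal(c(f$a, f$b, f$S), c(1, 0, 0), tolerance = 1e-12)
  f2 <- linear_fit(y_star, 2 * y_star + 3)
  expect_equal(c(f2$a, f2$b, f2$S), c(2, 3, 0), tolerance = 1e-12)
  # independent normal-equation solve
  y <- c(1, 2, 2)
  f3 <- linear_fit(y_star, y)
  A <- rbind(c(sum(y_star^2), sum(y_star)), c(sum(y_star), 3))
  ab <- solve(A, c(sum(y_star * y), sum(y)))
  expect_equal(c(f3$a, f3$b), unname(ab), tolerance = 1e-12)
  set.seed(26)
  for (i in 1:10) {
    ys <- rnorm(20); yy <- rnorm(20)
    f4 <- linear_fit(ys, yy)
    A4 <- rbind(c(sum(ys^2), sum(ys)), c(sum(ys), 20))
    ab4 <- solve(A4, c(sum(ys * yy), sum(yy)))
    expect_equal(c(f4$a, f4$b), unname(ab4), tolerance = 1e-10)
  }
  expect_warning(fc <- linear_fit(rep(2, 5), 1:5), "Constant reference")
  expect_equal(c(fc$a, fc$b), c(0, 3))
})

test_that("residual standardization divides by the population sd only", {
  e <- c(0, 2, 4)
  got <- standardize_residual(e)
  expect_equal(got, e / sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(got[2], 1.224745, tolerance = 1e-6)
  set.seed(27)
  r <- rnorm(100, 5, 3)
  out <- standardize_residual(r)
  expect_equal(sqrt(mean((out - mean(out))^2)), 1, tolerance = 1e-12)
  expect_equal(standardize_residual(1000 * r), out, tolerance = 1e-12)
  expect_equal(standardize_residual(rep(4, 10)), rep(0, 10))
})

test_that("threshold vector flags only abrupt drops among positive residuals", {
  # hand case: one dominant value, drop of -11.5 at rank 1
  E0 <- rbind(c(12, -1), c(0.5, -2), c(0.3, -0.5), c(0.1, -4))
  t_ <- threshold_vector(E0, -1)
  expect_equal(t_[1], 12)
  expect_identical(t_[2], Inf) # all-negative column: nothing to flag
  # small i.i.d. residuals with no steep gap
  set.seed(28)
  E1 <- matrix(runif(40 * 3, 0, 0.5), 40, 3)
  expect_identical(threshold_vector(E1, -1), c(Inf, Inf, Inf))
  # deepest qualifying rank wins so all larger residuals are flagged
  E2 <- cbind(c(9, 7, 0.4, 0.2, 0.1))
  expect_equal(threshold_vector(E2, -1)[1], 7)
  expect_error(threshold_vector(E0[1:2, , drop = FALSE]), "at least 3")
})

test_that("spike zones are centred, clipped and merged", {
  n <- 977
  y <- rnorm(n)
  y_re <- rep(0, n)
  e <- rep(0, n); t_ <- rep(Inf, n)
  none <- locate_and_replace(y, y_re, e, t_, 41L)
  expect_identical(none$corrected, y)
  expect_false(any(none$mask))

  e1 <- rep(0, n); e1[500] <- 10; t1 <- rep(5, n)
  got <- locate_and_replace(y, y_re, e1, t1, 41L)
  expect_identical(which(got$mask), 480:520)
  expect_true(all(got$corrected[480:520] == 0))
  expect_identical(got$corrected[-(480:520)], y[-(480:520)])

  e2 <- rep(0, n); e2[5] <- 10
  got2 <- locate_and_replace(y, y_re, e2, t1, 41L)
  expect_identical(which(got2$mask), 1:25)

  # overlapping centres merge into one run
  e3 <- rep(0, n); e3[c(100, 110)] <- 10
  got3 <- locate_and_replace(y, y_re, e3, t1, 41L)
  expect_identical(which(got3$mask), 80:130)
})

test_that("despiking repairs an injected spike using a near-duplicate pool", {
  set.seed(29)
  n <- 300
  base <- fixture_profile(n)
  m <- 15
  X <- matrix(0, m, n)
  for (i in seq_len(m)) X[i, ] <- base * runif(1, 0.95, 1.05) + rnorm(n, 0, 2)
  spike_chans <- 140:142
  X[4, spike_chans] <- X[4, spike_chans] + c(20, 40, 20) * 2 # 20 sigma spike
  res <- despike(X, apri_config())
  expect_true(all(res$spike_mask[4, spike_chans]))
  expect_true(all(abs(res$corrected[4, spike_chans] -
                        base[spike_chans] * X[4, 200] / base[200]) < 3 * 2 * 3))
  # untouched channels are bit-identical
  expect_identical(res$corrected[!res$spike_mask], X[!res$spike_mask])
  expect_true(all(res$mss_index != seq_len(m)))
})

test_that("regression collapses to identity for same-scale spectra", {
  set.seed(30)
  base <- fixture_profile(200)
  X <- matrix(rep(base, 12), 12, byrow = TRUE) + rnorm(12 * 200, 0, 1)
  res <- despike(X, apri_config())
  expect_true(all(abs(res$reg_a - 1) < 0.05))
  expect_true(all(abs(res$reg_b) < 0.05 * mean(base)))
})

test_that("detection is invariant under rescaling of the data set", {
  sim <- simulate_raman_image(5, 8, n_channels = 250, baseline = "none",
                              spike_rate = 0.3, seed = 31)
  X <- sim$dataset$intensities
  r1 <- despike(X)
  r2 <- despike(1000 * X)
  expect_identical(r1$spike_mask, r2$spike_mask)
  expect_identical(r1$mss_index, r2$mss_index)
})

test_that("small pools are refused or warned about", {
  X <- matrix(rnorm(2 * 20), 2, 20)
  expect_error(despike(X), "at least 3")
  set.seed(32)
  X5 <- matrix(rep(fixture_profile(60), 5), 5, byrow = TRUE) + rnorm(300)
  expect_warning(despike(X5), "pool is thin")
})
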