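test_that("whittaker smoother honours its limiting cases", {
  set.seed(10)
  x <- rnorm(50)
  expect_equal(whittaker_smooth(x, lambda = 0), x, tolerance = 1e-12)
  # constants lie in the null space of both difference operators
  for (ord in 1:2) {
    expect_equal(whittaker_smooth(rep(3.7, 40), lambda = 1e8, diff_order = ord),
                 rep(3.7, 40), tolerance = 1e-6)
  }
  # a straight line survives the second-order penalty untouched
  line <- 2 + 0.5 * (1:60)
  expect_equal(whittaker_smooth(line, lambda = 1e9, diff_order = 2), line,
               tolerance = 1e-7)
  expect_error(whittaker_smooth(c(1, NA, 3)), "finite")
  expect_error(whittaker_smooth(1:5, w = rep(0, 5), lambda = 0), "Singular")
})

test_that("sparse solve agrees with a dense brute-force solve", {
  # frozen small case first: x = [1,3,2,5], w = 1, lambda = 1, order 1
  x0 <- c(1, 3, 2, 5)
  want <- dense_whittaker(x0, rep(1, 4), 1, 1)
  expect_rel_equal(whittaker_smooth(x0, rep(1, 4), 1, 1), want, 1e-10)

  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    ord <- sample(1:2, 1)
    x <- rnorm(n, sd = 10)
    w <- runif(n)
    lam <- 10^runif(1, -2, 7)
    expect_rel_equal(whittaker_smooth(x, w, lam, ord),
                     dense_whittaker(x, w, lam, ord), 1e-8)
  }
})

test_that("roughness of the fit is non-increasing in lambda", {
  set.seed(12)
  x <- cumsum(rnorm(120))
  w <- runif(120, 0.2, 1)
  for (ord in 1:2) {
    rough <- vapply(10^seq(-2, 8, by = 1), function(lam) {
      z <- whittaker_smooth(x, w, lam, ord)
      sum(diff(z, differences = ord)^2)
    }, numeric(1))
    expect_true(all(diff(rough) <= 1e-8 * rough[-length(rough)] + 1e-12))
  }
})

test_that("airPLS reconstructs exactly and flags peak points", {
  set.seed(13)
  ch <- 1:400
  x <- 100 + 0.2 * ch + 300 * exp(-(ch - 150)^2 / 50) + rnorm(400, 0, 2)
  fit <- airpls_baseline(x, lambda = 1e6)
  expect_identical(fit$corrected + fit$baseline, x)
  expect_lte(fit$iterations, 20L)
  # zero-weight channels sat on or above the final candidate baseline
  zw <- fit$weights == 0
  expect_true(any(zw))
  expect_true(all(x[zw] >= fit$baseline[zw] - 1e-8))
  expect_true(all(fit$weights >= 0))
})

test_that("a pure straight-line spectrum is flattened almost completely", {
  x <- 50 + 0.3 * (1:500)
  fit <- airpls_baseline(x)
  expect_lt(max(abs(fit$corrected)), 1e-3 * max(abs(x)))
})

test_that("airPLS recovers a known baseline away from the peaks", {
  # quadratic and exponential fluorescence shapes at realistic noise
  covs <- vapply(1:4, function(s) {
    kind <- if (s %% 2 == 1) "quadratic" else "exponential"
    sim <- simulate_spectrum(
      seq(250, 3200, length.out = 977),
      bands = tibble::tibble(center = c(700, 1600, 2500),
                             fwhm = c(40, 60, 50),
                             amplitude = c(1, 0.7, 1.2),
                             shape = "gaussian", component = "x"),
      band_scale = 180, baseline = kind, baseline_scale = 500,
      noise_sigma = 10, spike_rate = 0, seed = 100 + s)
    fit <- airpls_baseline(sim$spectrum)
    wn <- seq(250, 3200, length.out = 977)
    peak_free <- abs(wn - 700) > 160 & abs(wn - 1600) > 240 &
      abs(wn - 2500) > 200
    mean(abs(fit$baseline - sim$truth$baseline)[peak_free] < 30)
  }, numeric(1))
  expect_gt(mean(covs), 0.95)
})

test_that("dataset baseline correction is row-wise and order preserving", {
  set.seed(14)
  X <- matrix(rnorm(5 * 80, 100, 5), 5, 80) + outer(1:5, (1:80) * 0.1)
  cfg <- apri_config(lambda = 1e5)
  res <- correct_baseline(X, cfg)
  one <- airpls_baseline(X[3, ], lambda = 1e5)
  expect_equal(as_spectra_matrix(res$corrected)[3, ], one$corrected)
  # permuting rows permutes the result identically
  perm <- c(4, 1, 5, 2, 3)
  res_p <- correct_baseline(X[perm, ], cfg)
  expect_equal(as_spectra_matrix(res_p$corrected),
               as_spectra_matrix(res$corrected)[perm, ])
  expect_identical(tidy(res)$spectrum, 1:5)
  expect_identical(nrow(glance(res)), 1L)
})
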