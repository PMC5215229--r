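test_that("poplar band table carries the expected bands", {
  bands <- poplar_bands()
  expect_identical(nrow(bands), 12L)
  expect_true(all(c(1095, 1123, 1163, 1275, 1331, 1378, 1460, 1603, 1656,
                    2889, 2940, 2490) %in% bands$center))
  expect_match(bands$component[bands$center == 1603], "lignin")
  expect_identical(bands$component[bands$center == 2490], "D2O")
  expect_true(all(bands$fwhm > 0))
  expect_true(all(bands$amplitude > 0))
  expect_true(all(bands$shape %in% c("gaussian", "lorentzian")))
})

test_that("the noiseless limit equals the analytic band sum", {
  wn <- seq(250, 3200, by = 5)
  s <- simulate_spectrum(wn, baseline = "none", noise_sigma = 0,
                         spike_rate = 0, band_scale = 100, seed = 40)
  bands <- poplar_bands()
  manual <- rep(0, length(wn))
  for (k in seq_len(nrow(bands))) {
    hw <- bands$fwhm[k] / 2
    manual <- manual + if (bands$shape[k] == "lorentzian") {
      bands$amplitude[k] * hw^2 / ((wn - bands$center[k])^2 + hw^2)
    } else {
      sg <- bands$fwhm[k] / (2 * sqrt(2 * log(2)))
      bands$amplitude[k] * exp(-(wn - bands$center[k])^2 / (2 * sg^2))
    }
  }
  expect_equal(s$spectrum, 100 * manual, tolerance = 1e-12)
  expect_equal(s$truth$noise, rep(0, length(wn)))
  expect_identical(nrow(s$truth$spike_table), 0L)
})

test_that("forced spike injection has the configured geometry", {
  wn <- seq(400, 1800, length.out = 200)
  s <- simulate_spectrum(wn, baseline = "none", noise_sigma = 0,
                         spike_rate = 1, max_spikes = 1L,
                         spike_amplitude = c(500, 500),
                         spike_width = c(3L, 3L), seed = 41)
  st <- s$truth$spike_table
  expect_identical(nrow(st), 1L)
  expect_identical(st$width, 3L)
  expect_equal(st$amplitude, 500)
  expect_equal(max(s$truth$spikes), 500, tolerance = 1e-12)
  expect_true(all(s$truth$spikes >= 0))
  expect_lte(sum(s$truth$spikes > 0), 3)
})

test_that("spike occurrence frequency matches the configured rate", {
  sim <- simulate_raman_image(20, 20, n_channels = 60, baseline = "none",
                              noise_sigma = 0, spike_rate = 0.05, seed = 42)
  hit <- length(unique(sim$truth$spike_table$spectrum))
  ci <- qbinom(c(0.005, 0.995), 400, 0.05)
  expect_gte(hit, ci[1])
  expect_lte(hit, ci[2])
})

test_that("generation is deterministic and exactly additive", {
  a <- simulate_raman_image(3, 4, n_channels = 100, spike_rate = 0.5, seed = 43)
  b <- simulate_raman_image(3, 4, n_channels = 100, spike_rate = 0.5, seed = 43)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$truth$spike_table, b$truth$spike_table)
  tr <- a$truth
  expect_identical(a$dataset$intensities,
                   tr$clean + tr$baselines + tr$noise + tr$spikes)
  expect_true(all(tr$spike_table$amplitude > 0))
  expect_identical(tr$seed, 43L)
  # a different seed gives different data
  c_ <- simulate_raman_image(3, 4, n_channels = 100, spike_rate = 0.5, seed = 44)
  expect_false(identical(a$dataset$intensities, c_$dataset$intensities))
})

test_that("spatial patterns modulate composition across the grid", {
  sim <- simulate_raman_image(6, 10, n_channels = 300, pattern = "two_region",
                              region_contrast = 0.6, baseline = "none",
                              noise_sigma = 0, spike_rate = 0,
                              intensity_spread = 0, seed = 45)
  wn <- seq(250, 3200, length.out = 300)
  lignin_ch <- which.min(abs(wn - 1603))
  m_grid <- matrix(seq_len(60), nrow = 6, ncol = 10, byrow = TRUE)
  left_idx <- as.vector(m_grid[, 1:5])
  right_idx <- as.vector(m_grid[, 6:10])
  left_mean <- mean(sim$dataset$intensities[left_idx, lignin_ch])
  right_mean <- mean(sim$dataset$intensities[right_idx, lignin_ch])
  expect_gt(left_mean, right_mean * 1.3)

  # degenerate 1x1 grid still produces a valid single-spectrum data set
  tiny <- simulate_raman_image(1, 1, n_channels = 50, seed = 46)
  expect_identical(dim(tiny$dataset$intensities), c(1L, 50L))
})

test_that("invalid contamination parameters are rejected", {
  wn <- seq_len(50)
  expect_error(simulate_spectrum(wn, spike_amplitude = c(5, 1)), "hi >= lo")
  expect_error(simulate_spectrum(wn, spike_rate = 1.2), "0, 1")
  expect_error(simulate_spectrum(wn, noise_sigma = -1), ">= 0")
  expect_error(simulate_spectrum(wn, spike_width = c(0L, 3L)), "positive integer")
})
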