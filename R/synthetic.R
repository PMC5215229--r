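#' Raman band templates of poplar cell walls
#'
#' The characteristic bands of the major poplar cell-wall polymers —
#' cellulose, hemicellulose and lignin — between 1000 and 3000 reciprocal
#' centimetres, plus the deuterium-oxide band at 2490 (sections are mounted
#' in D2O, which suppresses lignin fluorescence and adds a broad marker
#' band there). Default widths and relative amplitudes are chosen to give a
#' plausible wood spectrum: sharp aromatic lignin bands (Lorentzian), the
#' dominant CH-stretch envelope near 2889/2940, and the broad D2O band.
#'
#' @return A tibble with one row per band: `center` and `fwhm` (reciprocal
#'   centimetres), relative `amplitude`, `shape` (`"gaussian"` or
#'   `"lorentzian"`) and `component` label.
#' @examples
#' poplar_bands()
#' @export
poplar_bands <- function() {
  tibble::tribble(
    ~center, ~fwhm, ~amplitude, ~shape,       ~component,
    1095,    18,    0.55,       "gaussian",   "cellulose/hemicellulose",
    1123,    16,    0.40,       "gaussian",   "cellulose/hemicellulose",
    1163,    18,    0.18,       "gaussian",   "cellulose/hemicellulose",
    1275,    22,    0.20,       "lorentzian", "lignin",
    1331,    24,    0.30,       "gaussian",   "lignin/cellulose/hemicellulose",
    1378,    20,    0.28,       "gaussian",   "cellulose/hemicellulose",
    1460,    26,    0.32,       "gaussian",   "lignin/cellulose/hemicellulose",
    1603,    20,    0.60,       "lorentzian", "lignin",
    1656,    24,    0.25,       "lorentzian", "lignin",
    2490,    180,   0.30,       "gaussian",   "D2O",
    2889,    60,    1.00,       "gaussian",   "cellulose/hemicellulose",
    2940,    55,    0.85,       "gaussian",   "lignin/cellulose/hemicellulose"
  )
}

band_profile <- function(wavenumber, center, fwhm, amplitude, shape) {
  if (shape == "lorentzian") {
    hw <- fwhm / 2
    amplitude * hw^2 / ((wavenumber - center)^2 + hw^2)
  } else {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    amplitude * exp(-(wavenumber - center)^2 / (2 * s^2))
  }
}

baseline_shape <- function(kind, n) {
  u <- seq(0, 1, length.out = n)
  switch(kind,
         none = rep(0, n),
         linear = 0.3 + 0.7 * u,
         quadratic = 1 - 0.9 * (u - 0.25)^2,
         exponential = exp(-u / 0.7),
         sigmoid = 1 / (1 + exp(-8 * (u - 0.45))),
         stop("Unknown baseline kind: ", kind, call. = FALSE))
}

#' Simulate one Raman spectrum with known ground truth
#'
#' Builds a spectrum as the sum of four stored components: the clean band
#' signal (Gaussian/Lorentzian profiles from `bands` times `band_scale`), a
#' smooth fluorescence-like baseline, i.i.d. Gaussian channel noise, and
#' sparse narrow positive cosmic-ray spikes. With probability `spike_rate`
#' the spectrum carries spikes (`1` up to `max_spikes` of them); each spike
#' is triangular, 1 to 5 channels wide by default — far narrower than the
#' 41-channel replacement window the despiker uses — with a peak amplitude
#' drawn from `spike_amplitude`. Identical arguments and `seed` give a
#' bit-identical spectrum.
#'
#' @param wavenumber Wavenumber axis (channel positions).
#' @param bands Band table as from [poplar_bands()].
#' @param band_scale Multiplier taking relative band amplitudes to counts.
#' @param baseline Baseline family: `"exponential"` (default — broad
#'   fluorescence decay), `"none"`, `"linear"`, `"quadratic"`, `"sigmoid"`.
#' @param baseline_scale Peak height of the baseline, counts.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param spike_rate Probability that the spectrum carries spikes.
#' @param max_spikes Maximum spikes per contaminated spectrum.
#' @param spike_amplitude Length-2 range of spike peak amplitudes, counts.
#' @param spike_width Length-2 integer range of spike widths, channels.
#' @param seed Optional integer seed (uses and restores the RNG stream).
#' @return List with `spectrum` (numeric vector) and `truth`: a list of
#'   `clean`, `baseline`, `noise`, `spikes` (all vectors summing exactly to
#'   `spectrum`) and a `spike_table` tibble (`center`, `width`,
#'   `amplitude`, `from`, `to` channel span).
#' @examples
#' s <- simulate_spectrum(seq(300, 3100, by = 3), seed = 1)
#' all.equal(s$spectrum,
#'           s$truth$clean + s$truth$baseline + s$truth$noise + s$truth$spikes)
#' @export
simulate_spectrum <- function(wavenumber,
                              bands = poplar_bands(),
                              band_scale = 200,
                              baseline = c("exponential", "none", "linear",
                                           "quadratic", "sigmoid"),
                              baseline_scale = 500,
                              noise_sigma = 10,
                              spike_rate = 0.05,
                              max_spikes = 2L,
                              spike_amplitude = c(150, 1500),
                              spike_width = c(1L, 5L),
                              seed = NULL) {
  baseline <- match.arg(baseline)
  check_spike_params(spike_rate, spike_amplitude, spike_width, noise_sigma)
  if (!is.null(seed)) {
    return(with_local_seed(seed, simulate_spectrum(
      wavenumber, bands, band_scale, baseline, baseline_scale, noise_sigma,
      spike_rate, max_spikes, spike_amplitude, spike_width, seed = NULL)))
  }
  n <- length(wavenumber)
  clean <- band_sum(wavenumber, bands) * band_scale
  base <- baseline_scale * baseline_shape(baseline, n)
  noise <- if (noise_sigma > 0) rnorm(n, 0, noise_sigma) else rep(0, n)
  sp <- draw_spikes(n, spike_rate, max_spikes, spike_amplitude, spike_width)
  list(
    spectrum = clean + base + noise + sp$spikes,
    truth = list(clean = clean, baseline = base, noise = noise,
                 spikes = sp$spikes, spike_table = sp$table)
  )
}

band_sum <- function(wavenumber, bands) {
  out <- rep(0, length(wavenumber))
  for (k in seq_len(nrow(bands))) {
    out <- out + band_profile(wavenumber, bands$center[k], bands$fwhm[k],
                              bands$amplitude[k], bands$shape[k])
  }
  out
}

check_spike_params <- function(spike_rate, spike_amplitude, spike_width,
                               noise_sigma) {
  if (!(is.numeric(spike_rate) && spike_rate >= 0 && spike_rate <= 1)) {
    stop("`spike_rate` must be in [0, 1].", call. = FALSE)
  }
  if (length(spike_amplitude) != 2L || spike_amplitude[1] <= 0 ||
      spike_amplitude[2] < spike_amplitude[1]) {
    stop("`spike_amplitude` must be (lo, hi) with hi >= lo > 0.", call. = FALSE)
  }
  if (length(spike_width) != 2L || spike_width[1] < 1 ||
      spike_width[2] < spike_width[1]) {
    stop("`spike_width` must be an increasing positive integer range.",
         call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0.", call. = FALSE)
}

draw_spikes <- function(n, spike_rate, max_spikes, spike_amplitude,
                        spike_width) {
  spikes <- rep(0, n)
  table <- tibble::tibble(center = integer(), width = integer(),
                          amplitude = numeric(), from = integer(),
                          to = integer())
  if (spike_rate > 0 && runif(1) < spike_rate) {
    k <- if (max_spikes > 1L) sample.int(max_spikes, 1L) else 1L
    for (s in seq_len(k)) {
      width <- if (spike_width[2] > spike_width[1])
        sample(spike_width[1]:spike_width[2], 1L) else spike_width[1]
      center <- sample.int(n, 1L)
      amp <- runif(1, spike_amplitude[1], spike_amplitude[2])
      half <- (width - 1L) %/% 2L
      from <- max(1L, center - half)
      to <- min(n, center + half)
      # triangular profile peaking at the centre, strictly positive
      prof <- amp * pmax(0, 1 - abs(seq(from, to) - center) / (half + 1))
      spikes[from:to] <- spikes[from:to] + prof
      table <- dplyr::bind_rows(table, tibble::tibble(
        center = as.integer(center), width = as.integer(width),
        amplitude = amp, from = as.integer(from), to = as.integer(to)))
    }
  }
  list(spikes = spikes, table = table)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a Raman imaging data set with ground truth
#'
#' Generates `rows x cols` spectra on a mapping grid. Band amplitudes are
#' modulated across the grid by `pattern`:
#' * `"uniform"` — identical mean composition everywhere,
#' * `"two_region"` — lignin bands stronger in the left half, carbohydrate
#'   bands stronger in the right (contrast `region_contrast`), emulating a
#'   lignified cell corner next to a carbohydrate-rich wall,
#' * `"gradient"` — lignin fraction ramps linearly left to right.
#' Per-pixel intensity additionally varies by a random factor
#' (`intensity_spread`) around 1, and each pixel gets its own baseline
#' amplitude jitter — fluorescence varies spatially in real tissue.
#'
#' All contamination parameters are as in [simulate_spectrum()]; the
#' emitted matrix is exactly `clean + baselines + noise + spikes` from the
#' returned truth object, and the same `seed` reproduces everything.
#'
#' @param rows,cols Grid dimensions (pixels).
#' @param n_channels Number of wavenumber channels.
#' @param wavenumber Axis; default spans 250 to 3200 over `n_channels`.
#' @param bands Band table, as [poplar_bands()].
#' @param pattern Spatial composition pattern (see above).
#' @param region_contrast Relative amplitude contrast of `"two_region"` /
#'   `"gradient"`.
#' @param intensity_spread Half-width of the per-pixel uniform intensity
#'   factor around 1.
#' @param band_scale,baseline,baseline_scale,noise_sigma,spike_rate,max_spikes,spike_amplitude,spike_width
#'   Passed to the per-spectrum generator (see [simulate_spectrum()]).
#' @param step_um Stage step recorded in the grid metadata.
#' @param seed Optional integer seed.
#' @return List with `dataset` (a [raman_dataset()] with grid metadata) and
#'   `truth`, an object of class `"synthetic_truth"`: matrices `clean`,
#'   `baselines`, `noise`, `spikes`, the scalar `noise_sigma`, a
#'   `spike_table` tibble (`spectrum`, `center`, `width`, `amplitude`,
#'   `from`, `to`) and the `seed`.
#' @examples
#' sim <- simulate_raman_image(4, 5, n_channels = 200, seed = 1)
#' range(sim$dataset$intensities -
#'   (sim$truth$clean + sim$truth$baselines + sim$truth$noise + sim$truth$spikes))
#' @export
simulate_raman_image <- function(rows, cols,
                                 n_channels = 300L,
                                 wavenumber = seq(250, 3200,
                                                  length.out = n_channels),
                                 bands = poplar_bands(),
                                 pattern = c("uniform", "two_region",
                                             "gradient"),
                                 region_contrast = 0.6,
                                 intensity_spread = 0.15,
                                 band_scale = 200,
                                 baseline = c("exponential", "none", "linear",
                                              "quadratic", "sigmoid"),
                                 baseline_scale = 500,
                                 noise_sigma = 10,
                                 spike_rate = 0.05,
                                 max_spikes = 2L,
                                 spike_amplitude = c(150, 1500),
                                 spike_width = c(1L, 5L),
                                 step_um = 0.5,
                                 seed = NULL) {
  pattern <- match.arg(pattern)
  baseline <- match.arg(baseline)
  stopifnot(rows >= 1, cols >= 1)
  check_spike_params(spike_rate, spike_amplitude, spike_width, noise_sigma)
  if (!is.null(seed)) {
    return(with_local_seed(seed, {
      out <- simulate_raman_image(
        rows, cols, n_channels, wavenumber, bands, pattern, region_contrast,
        intensity_spread, band_scale, baseline, baseline_scale, noise_sigma,
        spike_rate, max_spikes, spike_amplitude, spike_width, step_um,
        seed = NULL)
      out$truth$seed <- as.integer(seed)
      out
    }))
  }
  m <- rows * cols
  n <- length(wavenumber)
  lignin <- grepl("lignin", bands$component)
  d2o <- bands$component == "D2O"
  clean <- matrix(0, m, n)
  baselines <- matrix(0, m, n)
  noise <- matrix(0, m, n)
  spikes <- matrix(0, m, n)
  spike_table <- tibble::tibble(spectrum = integer(), center = integer(),
                                width = integer(), amplitude = numeric(),
                                from = integer(), to = integer())
  base_unit <- baseline_shape(baseline, n)
  for (i in seq_len(m)) {
    col_i <- grid_col_of(i, list(rows = rows, cols = cols))
    frac <- if (cols > 1) (col_i - 1) / (cols - 1) else 0.5
    lignin_factor <- switch(pattern,
      uniform = 1,
      two_region = 1 + region_contrast * (frac < 0.5) -
        region_contrast * (frac >= 0.5),
      gradient = 1 + region_contrast * (0.5 - frac) * 2)
    carb_factor <- 2 - lignin_factor
    amp <- bands$amplitude *
      ifelse(lignin, lignin_factor, ifelse(d2o, 1, carb_factor))
    intensity <- runif(1, 1 - intensity_spread, 1 + intensity_spread)
    b <- bands
    b$amplitude <- amp
    clean[i, ] <- band_sum(wavenumber, b) * band_scale * intensity
    baselines[i, ] <- baseline_scale * base_unit *
      runif(1, 1 - intensity_spread, 1 + intensity_spread)
    if (noise_sigma > 0) noise[i, ] <- rnorm(n, 0, noise_sigma)
    sp <- draw_spikes(n, spike_rate, max_spikes, spike_amplitude, spike_width)
    spikes[i, ] <- sp$spikes
    if (nrow(sp$table)) {
      sp$table$spectrum <- i
      spike_table <- dplyr::bind_rows(spike_table,
                                      sp$table[, c("spectrum", "center",
                                                   "width", "amplitude",
                                                   "from", "to")])
    }
  }
  dataset <- raman_dataset(clean + baselines + noise + spikes,
                           wavenumber = wavenumber,
                           grid = list(rows = rows, cols = cols,
                                       step_um = step_um))
  truth <- structure(
    list(clean = clean, baselines = baselines, noise = noise, spikes = spikes,
         noise_sigma = noise_sigma, spike_table = spike_table, seed = NULL),
    class = "synthetic_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d x %d; noise sigma = %g; %d spike(s) in %d spectrum/spectra\n",
    nrow(x$clean), ncol(x$clean), x$noise_sigma, nrow(x$spike_table),
    length(unique(x$spike_table$spectrum))))
  invisible(x)
}
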