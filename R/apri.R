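#' Automatic pre-processing of a Raman imaging data set
#'
#' The full pipeline: per-spectrum airPLS baseline correction
#' ([correct_baseline()]) followed by PCA most-similar-spectrum despiking
#' ([despike()]), repeated for `config$passes` passes (default 2). A single
#' pass can miss a spike that sits at the same channels in a spectrum and
#' its reference; after the first pass has cleaned the rest of the data
#' set the similarity structure changes, references are re-chosen, and a
#' second pass resolves such coincidences.
#'
#' @param x A [raman_dataset()], matrix or data frame (rows = spectra).
#' @param config An [apri_config()] (or argument list).
#' @return An object of class `"apri_result"`: list with
#'   * `clean` — corrected data in the same container as the input,
#'   * `baselines` — the pass-1 baseline estimates (`m x n`),
#'   * `spike_mask` — union of the spike masks over all passes,
#'   * `passes` — per-pass list of `baseline` ([correct_baseline()] result)
#'     and `despike` ([despike()] result).
#'   `glance()` summarises the run; `tidy()` gives the per-spectrum table
#'   of the final pass.
#' @examples
#' sim <- simulate_raman_image(3, 4, n_channels = 150, seed = 2)
#' res <- apri(sim$dataset, apri_config(lambda = 1e5, spike_window = 5))
#' glance(res)
#' @export
apri <- function(x, config = apri_config()) {
  config <- as_apri_config(config)
  X <- as_spectra_matrix(x)
  passes <- vector("list", config$passes)
  mask_union <- matrix(FALSE, nrow(X), ncol(X))
  current <- X
  for (p in seq_len(config$passes)) {
    bl <- correct_baseline(current, config)
    corrected_mat <- as_spectra_matrix(bl$corrected)
    dsp <- despike(corrected_mat, config)
    passes[[p]] <- list(baseline = bl, despike = dsp)
    mask_union <- mask_union | dsp$spike_mask
    current <- dsp$corrected
  }
  clean <- if (inherits(x, "raman_dataset")) {
    raman_dataset(current, wavenumber = x$wavenumber, grid = x$grid)
  } else {
    current
  }
  structure(
    list(clean = clean,
         baselines = passes[[1]]$baseline$baselines,
         spike_mask = mask_union,
         passes = passes,
         config = config),
    class = "apri_result"
  )
}

#' @export
print.apri_result <- function(x, ...) {
  d <- dim(as_spectra_matrix(x$clean))
  cat(sprintf("<apri_result> %d spectra x %d channels, %d pass(es)\n",
              d[1], d[2], length(x$passes)))
  for (p in seq_along(x$passes)) {
    cat(sprintf("  pass %d: %d channel(s) replaced, q = %d components\n",
                p, sum(x$passes[[p]]$despike$spike_mask),
                x$passes[[p]]$despike$pca$q))
  }
  invisible(x)
}
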