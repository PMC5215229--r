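#' Evaluate a correction against synthetic ground truth
#'
#' Quantifies how well a pre-processing run recovered the known components
#' of a simulated data set:
#' * `baseline_rmse` — root-mean-square error between the estimated
#'   baselines and the true ones (mean over spectra; `NA` when no baseline
#'   estimate is supplied);
#' * `spike_recall` — fraction of injected spikes with at least half of
#'   their channels masked;
#' * `spike_precision` — fraction of masked channels attributable to a
#'   recalled spike, i.e. lying within half a replacement window of its
#'   channels (masking a window around a real spike is the intended
#'   behaviour, not an error);
#' * `channel_fpr` — fraction of masked channels among channels farther
#'   than half a window from any injected spike (the channels where masking
#'   is genuinely wrong);
#' * `residual_rmse` — RMSE between the corrected matrix and the true
#'   clean signal.
#'
#' @param corrected Corrected data ([raman_dataset()] or matrix), or an
#'   `"apri_result"` (its `clean`, `spike_mask` and `baselines` are used).
#' @param truth A `"synthetic_truth"` object from [simulate_raman_image()].
#' @param mask Logical `m x n` spike mask (ignored when `corrected` is an
#'   `"apri_result"`).
#' @param baselines Optional `m x n` estimated-baseline matrix.
#' @param window Replacement-window width used for attribution (channels).
#' @return A one-row tibble with the five metrics plus `n_spikes_true` and
#'   `n_masked_channels`.
#' @examples
#' sim <- simulate_raman_image(3, 4, n_channels = 150, seed = 3)
#' res <- apri(sim$dataset, apri_config(lambda = 1e5))
#' evaluate_correction(res, sim$truth)
#' @export
evaluate_correction <- function(corrected, truth, mask = NULL,
                                baselines = NULL, window = 41L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (inherits(corrected, "apri_result")) {
    if (is.null(mask)) mask <- corrected$spike_mask
    if (is.null(baselines)) baselines <- corrected$baselines
    corrected <- corrected$clean
  }
  X <- as_spectra_matrix(corrected)
  m <- nrow(X)
  n <- ncol(X)
  if (!all(dim(truth$clean) == c(m, n))) {
    stop("Corrected data is ", m, " x ", n, " but the truth is ",
         nrow(truth$clean), " x ", ncol(truth$clean), ".", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(FALSE, m, n)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == c(m, n))) stop("`mask` shape mismatch.", call. = FALSE)

  st <- truth$spike_table
  half <- (window - 1L) %/% 2L
  recalled <- logical(nrow(st))
  attributable <- matrix(FALSE, m, n)
  near_any_spike <- matrix(FALSE, m, n)
  if (nrow(st)) {
    for (k in seq_len(nrow(st))) {
      i <- st$spectrum[k]
      chans <- st$from[k]:st$to[k]
      recalled[k] <- mean(mask[i, chans]) >= 0.5
      zone <- max(1L, st$from[k] - half):min(n, st$to[k] + half)
      near_any_spike[i, zone] <- TRUE
      if (recalled[k]) attributable[i, zone] <- TRUE
    }
  }
  n_masked <- sum(mask)
  free <- !near_any_spike
  baseline_rmse <- if (is.null(baselines)) NA_real_ else {
    stopifnot(all(dim(baselines) == c(m, n)))
    mean(sqrt(rowMeans((baselines - truth$baselines)^2)))
  }
  tibble::tibble(
    baseline_rmse = baseline_rmse,
    spike_recall = if (nrow(st)) mean(recalled) else NA_real_,
    spike_precision = if (n_masked) sum(mask & attributable) / n_masked
    else NA_real_,
    channel_fpr = if (sum(free)) sum(mask & free) / sum(free) else NA_real_,
    residual_rmse = sqrt(mean((X - truth$clean)^2)),
    n_spikes_true = nrow(st),
    n_masked_channels = as.integer(n_masked)
  )
}

#' Principal-component score maps of an imaging data set
#'
#' Projects each pixel's spectrum on the first `k` principal components
#' (of the channel correlation matrix, standardized columns) and reshapes
#' the scores to the mapping grid — the standard visual diagnostic of
#' correction quality: contaminated data put baseline drift and spikes
#' into the leading components, clean data put chemistry there.
#'
#' @param ds A [raman_dataset()] with grid metadata.
#' @param k Number of components to map (`k = 0` returns an empty tibble).
#' @return A tibble of class `"pca_score_maps"` with columns `component`,
#'   `row`, `col`, `score`, plus a `proportions` attribute (variance share
#'   per mapped component). Degenerate input (every channel constant)
#'   raises an error naming the condition.
#' @examples
#' sim <- simulate_raman_image(4, 6, n_channels = 150, pattern = "two_region",
#'                             baseline = "none", spike_rate = 0, seed = 4)
#' maps <- pca_score_maps(sim$dataset, 2)
#' @export
pca_score_maps <- function(ds, k) {
  if (!inherits(ds, "raman_dataset") || is.null(ds$grid)) {
    stop("`ds` must be a raman_dataset with grid metadata.", call. = FALSE)
  }
  X <- ds$intensities
  stopifnot(k >= 0, k <= min(dim(X)))
  empty <- tibble::tibble(component = integer(), row = integer(),
                          col = integer(), score = numeric())
  if (k == 0) {
    return(structure(empty, proportions = numeric(),
                     class = c("pca_score_maps", class(empty))))
  }
  if (all(apply(X, 2L, sd) == 0)) {
    stop("Degenerate input: every channel is constant, components are ",
         "undefined.", call. = FALSE)
  }
  pf <- suppressWarnings(pca_features(X, variance_threshold = 1))
  sds <- apply(X, 2L, sd)
  scale <- ifelse(sds == 0, 1, sds)
  Z <- sweep(sweep(X, 2L, colMeans(X), "-"), 2L, scale, "/")
  scores <- Z %*% pf$eigenvectors[, seq_len(k), drop = FALSE]
  spectra <- seq_len(nrow(X))
  out <- tibble::tibble(
    component = rep(seq_len(k), each = nrow(X)),
    row = rep(grid_row_of(spectra, ds$grid), times = k),
    col = rep(grid_col_of(spectra, ds$grid), times = k),
    score = as.vector(scores)
  )
  structure(out, proportions = pf$proportions[seq_len(k)],
            class = c("pca_score_maps", class(out)))
}
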