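#' Tidy an airPLS fit
#'
#' @param x An `"airpls_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per channel: `channel`, `baseline`,
#'   `corrected`, `weight`.
#' @method tidy airpls_fit
#' @export
tidy.airpls_fit <- function(x, ...) {
  tibble::tibble(
    channel = seq_along(x$baseline),
    baseline = x$baseline,
    corrected = x$corrected,
    weight = x$weights
  )
}

#' @rdname tidy.airpls_fit
#' @return `glance()` returns a one-row tibble: `iterations`, `converged`,
#'   `lambda`, `diff_order`.
#' @method glance airpls_fit
#' @export
glance.airpls_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 lambda = x$lambda, diff_order = x$diff_order)
}

#' Tidy a data-set baseline correction
#'
#' @param x A `"baseline_result"` from [correct_baseline()].
#' @param ... Unused.
#' @return The per-spectrum tibble (`spectrum`, `iterations`, `converged`).
#' @method tidy baseline_result
#' @export
tidy.baseline_result <- function(x, ...) x$fits

#' @rdname tidy.baseline_result
#' @method glance baseline_result
#' @export
glance.baseline_result <- function(x, ...) {
  tibble::tibble(
    n_spectra = nrow(x$fits),
    n_converged = sum(x$fits$converged),
    mean_iterations = mean(x$fits$iterations),
    lambda = x$config$lambda,
    diff_order = x$config$diff_order
  )
}

#' Tidy a principal-component feature model
#'
#' @param x A `"pca_features"` object.
#' @param ... Unused.
#' @return One row per component: `component`, `eigenvalue`, `proportion`,
#'   `cumulative`, `retained`.
#' @method tidy pca_features
#' @export
tidy.pca_features <- function(x, ...) {
  k <- seq_along(x$eigenvalues)
  tibble::tibble(
    component = k,
    eigenvalue = x$eigenvalues,
    proportion = x$proportions,
    cumulative = cumsum(x$proportions),
    retained = k <= x$q
  )
}

#' @rdname tidy.pca_features
#' @method glance pca_features
#' @export
glance.pca_features <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$eigenvalues),
    q = x$q,
    cumulative_retained = sum(x$proportions[seq_len(x$q)]),
    variance_threshold = x$variance_threshold
  )
}

#' Tidy a despiking result
#'
#' @param x A `"despike_result"` from [despike()].
#' @param ... Unused.
#' @return One row per spectrum: `spectrum`, `mss_index`, regression
#'   coefficients `a` and `b`, and `n_masked` channels replaced.
#' @method tidy despike_result
#' @export
tidy.despike_result <- function(x, ...) {
  tibble::tibble(
    spectrum = seq_along(x$mss_index),
    mss_index = x$mss_index,
    a = x$reg_a,
    b = x$reg_b,
    n_masked = rowSums(x$spike_mask)
  )
}

#' @rdname tidy.despike_result
#' @method glance despike_result
#' @export
glance.despike_result <- function(x, ...) {
  tibble::tibble(
    n_spectra = nrow(x$corrected),
    q = x$pca$q,
    n_masked_channels = sum(x$spike_mask),
    n_spectra_with_spikes = sum(rowSums(x$spike_mask) > 0),
    mask_density = mean(x$spike_mask)
  )
}

#' Tidy a full pipeline run
#'
#' @param x An `"apri_result"` from [apri()].
#' @param ... Unused.
#' @return `tidy()`: the per-spectrum table of the final despiking pass.
#'   `glance()`: one row per pass (`pass`, `q`, `n_masked_channels`,
#'   `mean_baseline_iterations`, `mask_density`).
#' @method tidy apri_result
#' @export
tidy.apri_result <- function(x, ...) {
  tidy(x$passes[[length(x$passes)]]$despike)
}

#' @rdname tidy.apri_result
#' @method glance apri_result
#' @export
glance.apri_result <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$passes), function(p) {
    ps <- x$passes[[p]]
    tibble::tibble(
      pass = p,
      q = ps$despike$pca$q,
      n_masked_channels = sum(ps$despike$spike_mask),
      mean_baseline_iterations = mean(ps$baseline$fits$iterations),
      mask_density = mean(ps$despike$spike_mask)
    )
  }))
}
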