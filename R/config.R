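#' Pipeline configuration
#'
#' Bundles every tunable of the pre-processing pipeline in one validated
#' list. The defaults are the published operating point of the method:
#' `lambda = 1e7` and `max_iter = 20` for the airPLS baseline fit, an 85%
#' cumulative-variance cut for the number of retained principal components,
#' a 41-channel replacement window around each detected spike, a sorted
#' residual-derivative threshold of -1, and two full passes of the pipeline
#' so spikes coincident between a spectrum and its reference are caught on
#' the second pass.
#'
#' @param lambda Positive smoothing penalty of the Whittaker/airPLS fit.
#'   Larger values give smoother (stiffer) baselines. For second-order
#'   differences the effective smoothing length is about `lambda^(1/4)`
#'   channels, so the default 1e7 corresponds to roughly 56 channels.
#' @param max_iter Maximum airPLS reweighting iterations.
#' @param term_ratio Convergence ratio: iteration stops when the L1 norm of
#'   the negative residuals falls below `term_ratio * sum(abs(x))`.
#' @param diff_order Order of the finite-difference roughness penalty, 1 or
#'   2. Default 2: with the default `lambda` an order-1 penalty has a
#'   smoothing length far beyond the length of a typical spectrum and
#'   flattens genuine baseline curvature.
#' @param variance_threshold Cumulative proportion of variance (in `(0, 1]`)
#'   that the retained principal components must explain.
#' @param spike_window Odd width, in channels, of the replacement zone
#'   centred on each detected spike channel.
#' @param deriv_threshold Negative cut on the discrete derivative of each
#'   column of the descending-sorted standardized-residual matrix; a drop
#'   steeper than this marks the boundary between spikes and normal
#'   residuals.
#' @param passes Number of full baseline-plus-despike passes.
#' @param seed Optional integer seed recorded in the configuration (used by
#'   callers that simulate data; the correction itself is deterministic).
#'
#' @return A list of class `"apri_config"`.
#' @examples
#' cfg <- apri_config(lambda = 1e6, passes = 1)
#' cfg$spike_window
#' @export
apri_config <- function(lambda = 1e7,
                        max_iter = 20L,
                        term_ratio = 0.001,
                        diff_order = 2L,
                        variance_threshold = 0.85,
                        spike_window = 41L,
                        deriv_threshold = -1,
                        passes = 2L,
                        seed = NULL) {
  stopifnot(
    is.numeric(lambda), length(lambda) == 1L, lambda > 0,
    is.numeric(max_iter), length(max_iter) == 1L, max_iter >= 1,
    is.numeric(term_ratio), length(term_ratio) == 1L, term_ratio > 0,
    length(diff_order) == 1L, diff_order %in% c(1L, 2L),
    is.numeric(variance_threshold), length(variance_threshold) == 1L,
    variance_threshold > 0, variance_threshold <= 1,
    is.numeric(spike_window), length(spike_window) == 1L, spike_window >= 1,
    is.numeric(deriv_threshold), length(deriv_threshold) == 1L,
    deriv_threshold < 0,
    is.numeric(passes), length(passes) == 1L, passes >= 1
  )
  if (spike_window %% 2 == 0) {
    stop("`spike_window` must be odd so the zone can be centred on a channel.",
         call. = FALSE)
  }
  structure(
    list(
      lambda = as.numeric(lambda),
      max_iter = as.integer(max_iter),
      term_ratio = as.numeric(term_ratio),
      diff_order = as.integer(diff_order),
      variance_threshold = as.numeric(variance_threshold),
      spike_window = as.integer(spike_window),
      deriv_threshold = as.numeric(deriv_threshold),
      passes = as.integer(passes),
      seed = if (!is.null(seed)) as.integer(seed) else NULL
    ),
    class = "apri_config"
  )
}

#' @export
print.apri_config <- function(x, ...) {
  cat("<apri_config>\n")
  cat(sprintf("  airPLS : lambda = %g, max_iter = %d, term_ratio = %g, diff_order = %d\n",
              x$lambda, x$max_iter, x$term_ratio, x$diff_order))
  cat(sprintf("  despike: variance_threshold = %g, spike_window = %d, deriv_threshold = %g\n",
              x$variance_threshold, x$spike_window, x$deriv_threshold))
  cat(sprintf("  passes : %d\n", x$passes))
  invisible(x)
}

as_apri_config <- function(config) {
  if (inherits(config, "apri_config")) return(config)
  if (is.list(config)) return(do.call(apri_config, config))
  stop("`config` must be an `apri_config` or a list of its arguments.",
       call. = FALSE)
}
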