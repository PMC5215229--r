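#' Channel correlation matrix
#'
#' Pearson correlation between every pair of wavenumber channels (columns)
#' of a baseline-corrected matrix. A channel with zero variance carries no
#' information for the decomposition; its correlations are set to 0 (the
#' diagonal stays 1) with a warning rather than propagating `NaN`.
#'
#' @param X `m x n` matrix, rows are spectra.
#' @return `n x n` symmetric correlation matrix, unit diagonal.
#' @export
spectral_correlation <- function(X) {
  X <- as_spectra_matrix(X)
  if (nrow(X) < 2L) stop("Need at least 2 spectra to correlate channels.",
                         call. = FALSE)
  sds <- apply(X, 2L, sd)
  zero <- sds == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance channel(s); their correlations are set to 0.",
            call. = FALSE)
  }
  Xc <- sweep(X, 2L, colMeans(X), "-")
  scale <- ifelse(zero, 1, sds)
  Z <- sweep(Xc, 2L, scale, "/")
  R <- crossprod(Z) / (nrow(X) - 1L)
  R[zero, ] <- 0
  R[, zero] <- 0
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Principal-component features of a spectral matrix
#'
#' Eigendecomposition of the channel correlation matrix. Components are
#' ordered by decreasing eigenvalue; the proportion of variance of
#' component `k` is `PR_k = lambda_k / sum(lambda)` and the smallest `q`
#' with cumulative `PR >= variance_threshold` components are retained.
#' Scores are the standardized columns (centred, scaled by the sample
#' standard deviation — the same standardization the correlation matrix
#' implies) projected on the retained eigenvectors; each row of the score
#' matrix is the low-dimensional feature of one spectrum.
#'
#' @param X `m x n` matrix, rows are spectra.
#' @param variance_threshold Cumulative variance cut in `(0, 1]`.
#' @return An object of class `"pca_features"`: list with `eigenvalues`
#'   (length `n`, descending), `eigenvectors` (`n x n`, columns), and
#'   `proportions`, `q`, `scores` (`m x q`). `tidy()` gives the
#'   per-component table.
#' @export
pca_features <- function(X, variance_threshold = 0.85) {
  X <- as_spectra_matrix(X)
  if (nrow(X) < 2L || ncol(X) < 2L) {
    stop("Need at least 2 spectra and 2 channels.", call. = FALSE)
  }
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  R <- suppressWarnings(spectral_correlation(X))
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  proportions <- lambda / sum(lambda)
  cum <- cumsum(proportions)
  q <- which(cum >= variance_threshold - 1e-12)[1]
  if (is.na(q)) q <- length(lambda)
  sds <- apply(X, 2L, sd)
  scale <- ifelse(sds == 0, 1, sds)
  Z <- sweep(sweep(X, 2L, colMeans(X), "-"), 2L, scale, "/")
  scores <- Z %*% eig$vectors[, seq_len(q), drop = FALSE]
  structure(
    list(eigenvalues = lambda, eigenvectors = eig$vectors,
         proportions = proportions, q = as.integer(q), scores = scores,
         variance_threshold = variance_threshold),
    class = "pca_features"
  )
}

#' @export
print.pca_features <- function(x, ...) {
  cat(sprintf("<pca_features> %d components; q = %d retained (%.1f%% of variance)\n",
              length(x$eigenvalues), x$q,
              100 * sum(x$proportions[seq_len(x$q)])))
  invisible(x)
}

#' Squared Euclidean distances between score rows
#'
#' @param scores `m x q` score matrix.
#' @return `m x m` symmetric matrix of squared Euclidean distances, zero
#'   diagonal.
#' @export
pairwise_sq_distances <- function(scores) {
  scores <- as.matrix(scores)
  r <- rowSums(scores^2)
  D <- outer(r, r, "+") - 2 * tcrossprod(scores)
  D[D < 0] <- 0
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Most similar spectrum by score distance
#'
#' Index of the reference spectrum closest (squared Euclidean distance in
#' score space) to spectrum `i`, never `i` itself. Ties break to the
#' smallest index.
#'
#' @param D `m x m` distance matrix.
#' @param i Query row.
#' @param excluded Integer indices that may not be chosen (on top of `i`).
#' @return The chosen row index.
#' @export
find_mss <- function(D, i, excluded = integer()) {
  m <- nrow(D)
  candidates <- setdiff(seq_len(m), c(i, excluded))
  if (!length(candidates)) {
    stop("No reference spectrum left for spectrum ", i,
         "; fall back to single-spectrum filtering.", call. = FALSE)
  }
  candidates[which.min(D[i, candidates])]
}

#' Least-squares fit of a spectrum on its reference
#'
#' Closed-form simple linear regression `y ~ a * y_star + b` minimizing the
#' sum of squared errors `S`. The scale `a` absorbs intensity differences
#' between a spectrum and its reference; `b` absorbs a residual offset.
#' If `y_star` is constant the slope is undefined: `a = 0`,
#' `b = mean(y)` are returned with a warning.
#'
#' @param y_star Reference spectrum (regressor).
#' @param y Spectrum to model (response).
#' @return List with `a`, `b`, `y_re` (fitted spectrum `a*y_star + b`) and
#'   `S` (residual sum of squares).
#' @export
linear_fit <- function(y_star, y) {
  stopifnot(length(y_star) == length(y), length(y) >= 2L)
  mx <- mean(y_star)
  my <- mean(y)
  sxx <- sum((y_star - mx)^2)
  if (sxx == 0) {
    warning("Constant reference spectrum: slope undefined, using a = 0.",
            call. = FALSE)
    a <- 0
    b <- my
  } else {
    a <- sum((y_star - mx) * (y - my)) / sxx
    b <- my - a * mx
  }
  y_re <- a * y_star + b
  list(a = a, b = b, y_re = y_re, S = sum((y - y_re)^2))
}

#' Standardize a residual vector
#'
#' Divides by the population standard deviation (denominator `n`), making
#' the residual scale-free: multiplying the input spectra by any positive
#' constant leaves the standardized residuals unchanged. The vector is not
#' mean-centred. An all-equal residual returns zeros.
#'
#' @param e Residual vector.
#' @return `e / sigma_e`.
#' @export
standardize_residual <- function(e) {
  stopifnot(length(e) >= 2L)
  sigma <- sqrt(mean((e - mean(e))^2))
  if (sigma == 0) return(rep(0, length(e)))
  e / sigma
}

#' Per-channel spike thresholds from sorted residuals
#'
#' For each channel, the positive standardized residuals across all spectra
#' are sorted in descending order; spikes — rare, strictly positive and far
#' above normal residuals — show up as an abrupt drop in that sorted
#' column. The threshold is set at the deepest rank whose discrete
#' derivative (next value minus current) falls below `deriv_threshold`, so
#' every entry ranked at or above the drop counts as a spike candidate. A
#' channel with no qualifying drop gets `Inf` (nothing flagged there).
#'
#' @param E0 `m x n` matrix of standardized residuals (rows = spectra).
#' @param deriv_threshold Negative cut on the sorted-column derivative.
#' @return Numeric threshold vector of length `n`.
#' @export
threshold_vector <- function(E0, deriv_threshold = -1) {
  E0 <- as.matrix(E0)
  if (nrow(E0) < 3L) stop("Need at least 3 spectra to set thresholds.",
                          call. = FALSE)
  stopifnot(deriv_threshold < 0)
  apply(E0, 2L, function(col) {
    v <- sort(col[col > 0], decreasing = TRUE)
    if (length(v) < 2L) return(Inf)
    drops <- which(diff(v) < deriv_threshold)
    if (!length(drops)) Inf else v[max(drops)]
  })
}

#' Replace spike zones with the fitted reference
#'
#' Channels whose standardized residual meets or exceeds the channel
#' threshold are spike centres. Each centre is expanded to a window of
#' `spike_window` channels centred on it (clipped at the spectrum edges);
#' overlapping windows merge. Inside the mask the spectrum is replaced by
#' the fitted reference `y_re`; outside it is returned bit-identical.
#'
#' @param y Spectrum.
#' @param y_re Fitted reference spectrum.
#' @param e_std Standardized residual of `y` against `y_re`.
#' @param t Per-channel threshold vector.
#' @param spike_window Odd window width in channels.
#' @return List with `corrected` and logical `mask`.
#' @export
locate_and_replace <- function(y, y_re, e_std, t, spike_window = 41L) {
  n <- length(y)
  stopifnot(length(y_re) == n, length(e_std) == n, length(t) == n,
            spike_window >= 1, spike_window %% 2 == 1)
  centers <- which(e_std >= t)
  mask <- rep(FALSE, n)
  if (length(centers)) {
    half <- (spike_window - 1L) %/% 2L
    for (c in centers) {
      mask[max(1L, c - half):min(n, c + half)] <- TRUE
    }
  }
  corrected <- y
  corrected[mask] <- y_re[mask]
  list(corrected = corrected, mask = mask)
}

#' PCA most-similar-spectrum despiking
#'
#' Removes cosmic-ray spikes from a baseline-corrected matrix. Each
#' spectrum is summarized by its retained principal-component scores and
#' paired with its most similar spectrum (MSS) — the nearest other spectrum
#' in score space. The spectrum is regressed on its MSS; the standardized
#' residuals of all spectra are stacked into a matrix from which a
#' per-channel threshold is derived ([threshold_vector()]); channels above
#' threshold are replaced, along with a surrounding window, by the fitted
#' MSS ([locate_and_replace()]).
#'
#' A reference that carries a spike at the very channels it should repair
#' would copy its own spike in. A provisional detection round therefore
#' flags candidate zones for every spectrum first; an MSS whose candidate
#' zones overlap the query's candidate zones is demoted to the next-nearest
#' spectrum, up to `min(m - 1, 5)` demotions, after which the nearest is
#' accepted as-is.
#'
#' Despiking needs a pool of similar spectra: fewer than 3 is an error and
#' fewer than 10 draws a warning (with so few references, single-spectrum
#' filters are more appropriate).
#'
#' @param X `m x n` baseline-corrected matrix (or data frame /
#'   [raman_dataset()]).
#' @param config An [apri_config()] (or argument list).
#' @return An object of class `"despike_result"`: list with `corrected`
#'   matrix, logical `spike_mask`, `mss_index`, `reg_a`, `reg_b`,
#'   `residual_matrix` (standardized residuals), `threshold`, `pca`
#'   (the [pca_features()] model) and, for `m <= 500`, `distances`.
#'   `tidy()` gives the per-spectrum table.
#' @examples
#' sim <- simulate_raman_image(3, 4, n_channels = 150, baseline = "none",
#'                             spike_rate = 0.3, seed = 7)
#' dsr <- despike(sim$dataset, apri_config(spike_window = 5))
#' sum(dsr$spike_mask)
#' @export
despike <- function(X, config = apri_config()) {
  config <- as_apri_config(config)
  X <- as_spectra_matrix(X)
  m <- nrow(X)
  n <- ncol(X)
  if (m < 3L) {
    stop("Despiking needs at least 3 spectra; with fewer, use a ",
         "single-spectrum filter instead.", call. = FALSE)
  }
  if (m < 10L) {
    warning("Only ", m, " spectra: the most-similar-spectrum pool is thin; ",
            "results may be unreliable below ~10 spectra.", call. = FALSE)
  }
  pca <- pca_features(X, config$variance_threshold)
  D <- pairwise_sq_distances(pca$scores)

  # Residuals that are pure floating-point noise (an affine-exact reference)
  # count as a perfect fit: standardizing them would inflate rounding error
  # to unit scale. This extends the sigma = 0 convention of
  # standardize_residual() to sigma below 1e-8 of the spectrum's RMS.
  fit_against <- function(i, j) {
    fit <- linear_fit(X[j, ], X[i, ])
    e <- X[i, ] - fit$y_re
    sigma <- sqrt(mean((e - mean(e))^2))
    tol <- 1e-8 * max(sqrt(mean(X[i, ]^2)), .Machine$double.eps)
    e_std <- if (sigma <= tol) rep(0, n) else e / sigma
    list(fit = fit, e_std = e_std)
  }

  # provisional round: nearest MSS for everyone, candidate zones only
  prov_mss <- vapply(seq_len(m), function(i) find_mss(D, i), integer(1))
  E0_prov <- matrix(0, m, n)
  for (i in seq_len(m)) {
    E0_prov[i, ] <- fit_against(i, prov_mss[i])$e_std
  }
  t_prov <- threshold_vector(E0_prov, config$deriv_threshold)
  prov_zone <- matrix(FALSE, m, n)
  for (i in seq_len(m)) {
    prov_zone[i, ] <- locate_and_replace(X[i, ], X[i, ], E0_prov[i, ], t_prov,
                                         config$spike_window)$mask
  }

  # final round: demote references whose own candidate zones collide
  mss_index <- integer(m)
  max_fallbacks <- min(m - 1L, 5L)
  for (i in seq_len(m)) {
    excluded <- integer()
    chosen <- find_mss(D, i)
    for (k in seq_len(max_fallbacks)) {
      j <- find_mss(D, i, excluded)
      if (!any(prov_zone[j, ] & prov_zone[i, ])) {
        chosen <- j
        break
      }
      excluded <- c(excluded, j)
      if (length(excluded) >= max_fallbacks) break
    }
    mss_index[i] <- chosen
  }

  reg_a <- numeric(m)
  reg_b <- numeric(m)
  E0 <- matrix(0, m, n)
  y_re_mat <- matrix(0, m, n)
  for (i in seq_len(m)) {
    f <- fit_against(i, mss_index[i])
    reg_a[i] <- f$fit$a
    reg_b[i] <- f$fit$b
    y_re_mat[i, ] <- f$fit$y_re
    E0[i, ] <- f$e_std
  }
  threshold <- threshold_vector(E0, config$deriv_threshold)
  corrected <- X
  spike_mask <- matrix(FALSE, m, n)
  for (i in seq_len(m)) {
    rep_i <- locate_and_replace(X[i, ], y_re_mat[i, ], E0[i, ], threshold,
                                config$spike_window)
    corrected[i, ] <- rep_i$corrected
    spike_mask[i, ] <- rep_i$mask
  }
  structure(
    list(corrected = corrected, spike_mask = spike_mask,
         mss_index = mss_index, reg_a = reg_a, reg_b = reg_b,
         residual_matrix = E0, threshold = threshold, pca = pca,
         distances = if (m <= 500L) D else NULL,
         config = config),
    class = "despike_result"
  )
}

#' @export
print.despike_result <- function(x, ...) {
  cat(sprintf(
    "<despike_result> %d spectra x %d channels; q = %d; %d channel(s) replaced in %d spectrum/spectra\n",
    nrow(x$corrected), ncol(x$corrected), x$pca$q, sum(x$spike_mask),
    sum(rowSums(x$spike_mask) > 0)))
  invisible(x)
}
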