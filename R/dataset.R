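#' Raman imaging data set
#'
#' A spectral image is stored as an `m x n` matrix: one row per recorded
#' position (spectrum), one column per wavenumber channel. An optional
#' wavenumber axis labels the columns and optional grid metadata
#' (`rows`, `cols`, `step_um`) records the mapping geometry, with
#' `rows * cols == m`.
#'
#' The wavenumber axis, when given, must be strictly monotonic; a
#' decreasing axis is normalized to increasing order and the intensity
#' columns are reordered with it. All algorithms operate on the channel
#' index — the axis is only used for labelling and plotting.
#'
#' @param intensities Numeric matrix (or data frame of numeric columns),
#'   rows are spectra. All entries must be finite.
#' @param wavenumber Optional numeric vector of length `ncol(intensities)`,
#'   in reciprocal centimetres.
#' @param grid Optional list with elements `rows`, `cols` and optionally
#'   `step_um`.
#'
#' @return An object of class `"raman_dataset"`: a list with elements
#'   `intensities`, `wavenumber` and `grid`.
#' @examples
#' ds <- raman_dataset(matrix(rnorm(20), 4, 5), wavenumber = seq(1000, 1400, 100))
#' dim(ds)
#' @export
raman_dataset <- function(intensities, wavenumber = NULL, grid = NULL) {
  x <- as_spectra_matrix(intensities)
  m <- nrow(x)
  n <- ncol(x)
  if (m < 1L || n < 2L) {
    stop("A data set needs at least 1 spectrum and 2 channels; got ",
         m, " x ", n, ".", call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% m) + 1L
    j <- ((bad[1] - 1L) %/% m) + 1L
    stop(sprintf(
      "Non-finite intensity at spectrum %d, channel %d (%d offending cell%s in total). Complete spectra are required.",
      i, j, length(bad), if (length(bad) > 1) "s" else ""), call. = FALSE)
  }
  if (!is.null(wavenumber)) {
    wavenumber <- as.numeric(wavenumber)
    if (length(wavenumber) != n) {
      stop("`wavenumber` has length ", length(wavenumber),
           " but the matrix has ", n, " channels.", call. = FALSE)
    }
    d <- diff(wavenumber)
    if (any(!is.finite(wavenumber)) || !(all(d > 0) || all(d < 0))) {
      stop("`wavenumber` must be finite and strictly monotonic.", call. = FALSE)
    }
    if (all(d < 0)) {
      wavenumber <- rev(wavenumber)
      x <- x[, rev(seq_len(n)), drop = FALSE]
    }
  }
  if (!is.null(grid)) {
    grid <- validate_grid(grid, m)
  }
  structure(
    list(intensities = x, wavenumber = wavenumber, grid = grid),
    class = "raman_dataset"
  )
}

validate_grid <- function(grid, m) {
  if (!is.list(grid) || is.null(grid$rows) || is.null(grid$cols)) {
    stop("`grid` must be a list with `rows` and `cols`.", call. = FALSE)
  }
  rows <- as.integer(grid$rows)
  cols <- as.integer(grid$cols)
  if (rows < 1L || cols < 1L) stop("Grid dimensions must be positive.", call. = FALSE)
  if (rows * cols != m) {
    stop("Grid ", rows, " x ", cols, " does not match the ", m,
         " spectra in the data set.", call. = FALSE)
  }
  step <- grid$step_um
  if (!is.null(step)) {
    step <- as.numeric(step)
    if (!is.finite(step) || step <= 0) stop("`step_um` must be positive.", call. = FALSE)
  }
  list(rows = rows, cols = cols, step_um = step)
}

as_spectra_matrix <- function(x) {
  if (inherits(x, "raman_dataset")) return(x$intensities)
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    if (!all(num)) {
      stop("All columns must be numeric; column(s) ",
           paste(names(x)[!num], collapse = ", "), " are not.", call. = FALSE)
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) {
    if (is.numeric(x)) x <- matrix(x, nrow = 1L) else
      stop("Expected a matrix, data frame or raman_dataset.", call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
dim.raman_dataset <- function(x) dim(x$intensities)

#' @export
print.raman_dataset <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<raman_dataset> %d spectra x %d channels\n", d[1], d[2]))
  if (!is.null(x$wavenumber)) {
    cat(sprintf("  wavenumber: %.1f .. %.1f cm^-1\n",
                min(x$wavenumber), max(x$wavenumber)))
  }
  if (!is.null(x$grid)) {
    cat(sprintf("  grid: %d rows x %d cols%s\n", x$grid$rows, x$grid$cols,
                if (!is.null(x$grid$step_um))
                  sprintf(" at %g um/pixel", x$grid$step_um) else ""))
  }
  invisible(x)
}

#' Long-format view of a data set
#'
#' @param x A `raman_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per (spectrum, channel) cell: columns
#'   `spectrum`, `channel`, `wavenumber` (if the axis is present), `row`
#'   and `col` (if a grid is present), and `intensity`.
#' @method as_tibble raman_dataset
#' @export
as_tibble.raman_dataset <- function(x, ...) {
  d <- dim(x$intensities)
  out <- tibble::tibble(
    spectrum = rep(seq_len(d[1]), times = d[2]),
    channel = rep(seq_len(d[2]), each = d[1]),
    intensity = as.vector(x$intensities)
  )
  if (!is.null(x$wavenumber)) {
    out$wavenumber <- x$wavenumber[out$channel]
  }
  if (!is.null(x$grid)) {
    out$row <- grid_row_of(out$spectrum, x$grid)
    out$col <- grid_col_of(out$spectrum, x$grid)
  }
  out[order(out$spectrum, out$channel), , drop = FALSE]
}

# Row-major scan order: spectrum 1 is the top-left pixel, filling each image
# row left to right.
grid_row_of <- function(spectrum, grid) ((spectrum - 1L) %/% grid$cols) + 1L
grid_col_of <- function(spectrum, grid) ((spectrum - 1L) %% grid$cols) + 1L
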