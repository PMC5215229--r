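#' Read a spectral matrix from disk
#'
#' Reads a Raman imaging data set stored either as a delimited text matrix
#' (comma or tab separated, auto-detected; one spectrum per row) or as a
#' MATLAB MAT v5 container holding a 2-D numeric array and, optionally, a
#' wavenumber vector.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension: `.mat` is MAT v5, anything else
#'   delimited), `"delimited"` or `"mat"`.
#' @param header For delimited input, skip one header row.
#' @param grid Optional grid metadata passed on to [raman_dataset()].
#' @return A [raman_dataset()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, format = c("auto", "delimited", "mat"),
                         header = FALSE, grid = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "mat" else "delimited"
  }
  if (format == "mat") {
    vars <- read_mat5(path)
    mats <- Filter(function(v) is.matrix(v) && min(dim(v)) > 1L, vars)
    if (!length(mats)) {
      # fall back: any 2-D array, even a single row/column
      mats <- Filter(is.matrix, vars)
    }
    if (!length(mats)) stop("MAT file holds no 2-D numeric array: ", path,
                            call. = FALSE)
    x <- mats[[1]]
    axis <- NULL
    vecs <- Filter(function(v) is.numeric(v) && !is.matrix(v), vars)
    axis_named <- vars[intersect(c("wavenumber", "axis", "wn"), names(vars))]
    if (length(axis_named)) {
      axis <- as.numeric(axis_named[[1]])
    } else {
      hit <- Filter(function(v) length(v) == ncol(x), vecs)
      if (length(hit)) axis <- as.numeric(hit[[1]])
    }
    if (!is.null(axis) && length(axis) != ncol(x)) axis <- NULL
    return(raman_dataset(x, wavenumber = axis, grid = grid))
  }
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("Empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("Ragged delimited file: row %d has %d fields, row 1 has %d.",
                 bad, widths[bad], widths[1]), call. = FALSE)
  }
  x <- matrix(NA_real_, nrow = length(parts), ncol = widths[1])
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("Non-numeric value %s at row %d, column %d.",
                   dQuote(trimws(parts[[i]][j])), i, j), call. = FALSE)
    }
    x[i, ] <- v
  }
  raman_dataset(x, grid = grid)
}

#' Write a spectral matrix to disk
#'
#' Delimited output stores the intensity matrix alone at full precision
#' (17 significant digits, one spectrum per row); grid metadata belongs in a
#' sidecar configuration file ([write_apri_sidecar()]). MAT output stores
#' the matrix as variable `spectra` plus, when present, the axis as
#' `wavenumber`, and round-trips bit-exactly.
#'
#' @param x A [raman_dataset()], matrix or data frame.
#' @param path Output file.
#' @param format `"auto"`, `"delimited"` or `"mat"` (see [read_spectra()]).
#' @param sep Field separator for delimited output.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, format = c("auto", "delimited", "mat"),
                          sep = ",") {
  format <- match.arg(format)
  ds <- if (inherits(x, "raman_dataset")) x else raman_dataset(x)
  if (format == "auto") {
    format <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "mat" else "delimited"
  }
  if (format == "mat") {
    vars <- list(spectra = ds$intensities)
    if (!is.null(ds$wavenumber)) vars$wavenumber <- ds$wavenumber
    write_mat5(vars, path)
  } else {
    lines <- apply(ds$intensities, 1L, function(r)
      paste(formatC(r, digits = 17, format = "g"), collapse = sep))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("Cannot write to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Mapping-grid geometry
#'
#' Converts the physical extent of a rectangular mapping region and the
#' stage step into pixel counts: `cols = floor(width_um / step_um)`,
#' `rows = floor(height_um / step_um)`, and `n_spectra = cols * rows` —
#' one recorded spectrum per pixel. A 65 x 49.5 micrometre region mapped at
#' 0.5 micrometre per pixel therefore yields 130 x 99 = 12,870 spectra.
#'
#' @param width_um,height_um Extent of the mapped region, micrometres.
#' @param step_um Stage step (pixel pitch), micrometres.
#' @return A one-row tibble with `cols`, `rows` and `n_spectra`.
#' @examples
#' grid_dimensions(65, 49.5, 0.5)
#' @export
grid_dimensions <- function(width_um, height_um, step_um) {
  stopifnot(is.numeric(width_um), is.numeric(height_um), is.numeric(step_um),
            width_um > 0, height_um > 0, step_um > 0)
  if (step_um > width_um && step_um > height_um) {
    stop("`step_um` exceeds both extents; the grid would be empty.",
         call. = FALSE)
  }
  cols <- as.integer(floor(width_um / step_um))
  rows <- as.integer(floor(height_um / step_um))
  tibble::tibble(cols = cols, rows = rows, n_spectra = cols * rows)
}

#' Sidecar configuration files
#'
#' A plain `key = value` text file carrying an [apri_config()] and optional
#' grid metadata alongside a delimited matrix, which stores numbers only.
#'
#' @param config An [apri_config()].
#' @param path File to write / read.
#' @param grid Optional grid list (`rows`, `cols`, `step_um`).
#' @return `write_apri_sidecar()` returns `path` invisibly;
#'   `read_apri_sidecar()` returns a list with elements `config` and `grid`.
#' @export
write_apri_sidecar <- function(config, path, grid = NULL) {
  config <- as_apri_config(config)
  kv <- c(
    lambda = format(config$lambda, digits = 17),
    max_iter = config$max_iter,
    term_ratio = format(config$term_ratio, digits = 17),
    diff_order = config$diff_order,
    variance_threshold = format(config$variance_threshold, digits = 17),
    spike_window = config$spike_window,
    deriv_threshold = format(config$deriv_threshold, digits = 17),
    passes = config$passes
  )
  if (!is.null(config$seed)) kv <- c(kv, seed = config$seed)
  if (!is.null(grid)) {
    kv <- c(kv, grid_rows = grid$rows, grid_cols = grid$cols)
    if (!is.null(grid$step_um)) kv <- c(kv, grid_step_um = grid$step_um)
  }
  writeLines(paste(names(kv), "=", kv), path)
  invisible(path)
}

#' @rdname write_apri_sidecar
#' @export
read_apri_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
  kv <- setNames(
    vapply(m, function(p) trimws(p[3]), character(1)),
    vapply(m, function(p) p[2], character(1))
  )
  num <- function(k) if (k %in% names(kv)) as.numeric(kv[[k]]) else NULL
  cfg_args <- list(
    lambda = num("lambda"), max_iter = num("max_iter"),
    term_ratio = num("term_ratio"), diff_order = num("diff_order"),
    variance_threshold = num("variance_threshold"),
    spike_window = num("spike_window"),
    deriv_threshold = num("deriv_threshold"), passes = num("passes"),
    seed = num("seed")
  )
  cfg_args <- cfg_args[!vapply(cfg_args, is.null, logical(1))]
  grid <- NULL
  if (!is.null(num("grid_rows")) && !is.null(num("grid_cols"))) {
    grid <- list(rows = num("grid_rows"), cols = num("grid_cols"),
                 step_um = num("grid_step_um"))
  }
  list(config = do.call(apri_config, cfg_args), grid = grid)
}
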