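# Minimal MAT-file (level 5) reader/writer for numeric arrays.
# Scope: uncompressed little-endian files; real full numeric matrices and
# vectors (the containers instrument exports of Raman maps use). Compressed
# elements, cells, structs, complex and sparse arrays are out of scope and
# rejected with a clear error.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE_CLASS <- 6L

mi_size <- function(type) {
  switch(as.character(type),
         "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
         "7" = 4L, "9" = 8L,
         stop("Unsupported MAT data type ", type, call. = FALSE))
}

mi_read_numeric <- function(raw, type) {
  n <- length(raw) %/% mi_size(type)
  switch(as.character(type),
    "1" = as.numeric(readBin(raw, "integer", n, size = 1L, signed = TRUE)),
    "2" = as.numeric(readBin(raw, "integer", n, size = 1L, signed = FALSE)),
    "3" = as.numeric(readBin(raw, "integer", n, size = 2L, signed = TRUE,
                             endian = "little")),
    "4" = as.numeric(readBin(raw, "integer", n, size = 2L, signed = FALSE,
                             endian = "little")),
    "5" = as.numeric(readBin(raw, "integer", n, size = 4L, endian = "little")),
    "6" = {
      v <- as.numeric(readBin(raw, "integer", n, size = 4L, endian = "little"))
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    "7" = readBin(raw, "double", n, size = 4L, endian = "little"),
    "9" = readBin(raw, "double", n, size = 8L, endian = "little"),
    stop("Unsupported MAT data type ", type, call. = FALSE))
}

#' Read numeric variables from a MAT v5 file
#'
#' Supports uncompressed little-endian files containing real numeric
#' arrays (written e.g. by `scipy.io.savemat(..., do_compression=False)` or
#' MATLAB `save -v6`). 1 x n and n x 1 arrays are returned as plain
#' vectors, everything else as a double matrix.
#'
#' @param path MAT file.
#' @return Named list of numeric vectors/matrices.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 136L) stop("Not a MAT v5 file (too short): ", path, call. = FALSE)
  endian <- rawToChar(raw[127:128])
  if (endian == "MI") {
    stop("Big-endian MAT files are not supported.", call. = FALSE)
  }
  if (endian != "IM") stop("Not a MAT v5 file: ", path, call. = FALSE)
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(raw)) {
    tag <- parse_tag(raw, pos)
    if (tag$type == MI_COMPRESSED) {
      stop("Compressed MAT elements are not supported; write the file ",
           "uncompressed (scipy: do_compression=False; MATLAB: save -v6).",
           call. = FALSE)
    }
    if (tag$type == MI_MATRIX) {
      var <- parse_matrix(raw, tag$data_pos, tag$nbytes)
      if (!is.null(var)) out[[var$name]] <- var$value
    }
    pos <- tag$next_pos
  }
  out
}

parse_tag <- function(raw, pos) {
  type <- readBin(raw[pos:(pos + 3L)], "integer", 1L, size = 4L,
                  endian = "little")
  small_nbytes <- bitwShiftR(bitwAnd(type, -65536L), 16L) # upper 16 bits
  if (small_nbytes != 0L) {
    # small data element: count in the upper half of the type word,
    # data packed into the second word of the tag
    list(type = bitwAnd(type, 65535L), nbytes = small_nbytes,
         data_pos = pos + 4L, next_pos = pos + 8L)
  } else {
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L,
                      endian = "little")
    pad <- (8L - nbytes %% 8L) %% 8L
    list(type = type, nbytes = nbytes, data_pos = pos + 8L,
         next_pos = pos + 8L + nbytes + pad)
  }
}

parse_matrix <- function(raw, pos, nbytes) {
  end <- pos + nbytes - 1L
  flags_tag <- parse_tag(raw, pos)
  flags <- readBin(raw[flags_tag$data_pos:(flags_tag$data_pos + 3L)],
                   "integer", 1L, size = 4L, endian = "little")
  class_id <- bitwAnd(flags, 255L)
  complex_flag <- bitwAnd(flags, 2048L) != 0L
  dims_tag <- parse_tag(raw, flags_tag$next_pos)
  dims <- readBin(raw[dims_tag$data_pos:(dims_tag$data_pos + dims_tag$nbytes - 1L)],
                  "integer", dims_tag$nbytes %/% 4L, size = 4L, endian = "little")
  name_tag <- parse_tag(raw, dims_tag$next_pos)
  name <- if (name_tag$nbytes > 0L)
    rawToChar(raw[name_tag$data_pos:(name_tag$data_pos + name_tag$nbytes - 1L)])
  else ""
  if (!(class_id %in% 6:15) || complex_flag || length(dims) != 2L) {
    return(NULL) # not a real 2-D numeric array; skip
  }
  data_tag <- parse_tag(raw, name_tag$next_pos)
  if (data_tag$data_pos + data_tag$nbytes - 1L > end + 8L) {
    stop("Corrupt MAT element: data runs past the variable.", call. = FALSE)
  }
  vals <- mi_read_numeric(
    raw[data_tag$data_pos:(data_tag$data_pos + data_tag$nbytes - 1L)],
    data_tag$type)
  if (length(vals) != prod(dims)) {
    stop("Corrupt MAT element: ", length(vals), " values for dimensions ",
         paste(dims, collapse = " x "), ".", call. = FALSE)
  }
  value <- if (any(dims == 1L)) as.numeric(vals)
  else matrix(vals, nrow = dims[1], ncol = dims[2]) # MAT data is column-major
  list(name = name, value = value)
}

#' Write numeric variables to a MAT v5 file
#'
#' Writes each element of `vars` as an uncompressed little-endian double
#' array. Vectors are stored as 1 x n row vectors. Round-trips bit-exactly
#' through [read_mat5()] and is readable by `scipy.io.loadmat` and MATLAB.
#'
#' @param vars Named list of numeric vectors/matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by apri on %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  header <- charToRaw(substr(sprintf("%-116s", desc), 1L, 116L))
  writeBin(header, con)
  writeBin(raw(8L), con)                                   # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                     # version 0x0100
  writeBin(charToRaw("IM"), con)                           # endian marker
  for (nm in names(vars)) {
    writeBin(mat5_matrix_element(nm, vars[[nm]]), con)
  }
  invisible(path)
}

mat5_matrix_element <- function(name, x) {
  if (is.matrix(x)) {
    dims <- dim(x)
    vals <- as.numeric(x)           # column-major, matching MAT layout
  } else {
    vals <- as.numeric(x)
    dims <- c(1L, length(vals))
  }
  body <- c(
    mat5_element(MI_UINT32, writeBin(c(MX_DOUBLE_CLASS, 0L), raw(),
                                     size = 4L, endian = "little")),
    mat5_element(MI_INT32, writeBin(as.integer(dims), raw(), size = 4L,
                                    endian = "little")),
    mat5_element(MI_INT8, charToRaw(name)),
    mat5_element(MI_DOUBLE, writeBin(vals, raw(), size = 8L, endian = "little"))
  )
  c(writeBin(c(MI_MATRIX, length(body)), raw(), size = 4L, endian = "little"),
    body)
}

mat5_element <- function(type, data) {
  nbytes <- length(data)
  pad <- (8L - nbytes %% 8L) %% 8L
  c(writeBin(c(as.integer(type), nbytes), raw(), size = 4L, endian = "little"),
    data, raw(pad))
}
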