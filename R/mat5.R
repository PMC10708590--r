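## Minimal MAT-file (level 5) reader.
##
## Covers what per-trial inertial recordings need: numeric arrays (double,
## single, 8/16/32-bit integers), character vectors, and zlib-compressed
## elements. Cell arrays, structs, sparse and complex data are skipped with
## a warning. Both endiannesses are handled via the header flag.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L

MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

#' Read a MAT-file (format level 5)
#'
#' Reads the named variables of a binary MAT v5 container into a list.
#' Numeric arrays come back as vectors/matrices/arrays of doubles,
#' character arrays as strings. Unsupported variable classes (cells,
#' structs, sparse, complex) are skipped with a warning.
#'
#' @param path path to the `.mat` file.
#' @return named list of variables.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128) stop("not a MAT v5 file: truncated header")
  endian_tag <- rawToChar(raw[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI")
    "big" else stop("not a MAT v5 file: bad endian indicator")
  pos <- 129L
  out <- list()
  while (pos + 8L <= length(raw) + 1L) {
    el <- mat5_read_element(raw, pos, endian)
    pos <- el$next_pos
    if (is.null(el$value)) next
    if (!is.null(el$name)) out[[el$name]] <- el$value
  }
  out
}

mat5_read_tag <- function(raw, pos, endian) {
  t32 <- readBin(raw[pos:(pos + 3L)], "integer", 1, size = 4, endian = endian)
  small_bytes <- bitwAnd(bitwShiftR(t32, 16L), 0xffffL)
  if (small_bytes > 0L) {
    list(type = bitwAnd(t32, 0xffffL), nbytes = small_bytes,
         data_pos = pos + 4L, small = TRUE,
         next_pos = pos + 8L)
  } else {
    nb <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1, size = 4,
                  endian = endian)
    padded <- 8L * ((nb + 7L) %/% 8L)
    list(type = t32, nbytes = nb, data_pos = pos + 8L, small = FALSE,
         next_pos = pos + 8L + padded)
  }
}

mat5_decode_numeric <- function(raw, pos, nbytes, type, endian) {
  bytes <- raw[pos:(pos + nbytes - 1L)]
  switch(as.character(type),
    "1" = readBin(bytes, "integer", nbytes, size = 1, signed = TRUE, endian = endian),
    "2" = readBin(bytes, "integer", nbytes, size = 1, signed = FALSE, endian = endian),
    "3" = readBin(bytes, "integer", nbytes / 2, size = 2, signed = TRUE, endian = endian),
    "4" = readBin(bytes, "integer", nbytes / 2, size = 2, signed = FALSE, endian = endian),
    "5" = readBin(bytes, "integer", nbytes / 4, size = 4, endian = endian),
    "6" = {
      v <- readBin(bytes, "integer", nbytes / 4, size = 4, endian = endian)
      ifelse(v < 0, v + 2^32, v)
    },
    "7" = readBin(bytes, "numeric", nbytes / 4, size = 4, endian = endian),
    "9" = readBin(bytes, "numeric", nbytes / 8, size = 8, endian = endian),
    "16" = bytes,
    stop(sprintf("unsupported MAT data type %d", type)))
}

mat5_read_element <- function(raw, pos, endian) {
  tag <- mat5_read_tag(raw, pos, endian)
  if (tag$type == MI_COMPRESSED) {
    inner <- memDecompress(raw[tag$data_pos:(tag$data_pos + tag$nbytes - 1L)],
                           type = "gzip")
    el <- mat5_read_element(inner, 1L, endian)
    el$next_pos <- tag$next_pos
    return(el)
  }
  if (tag$type != MI_MATRIX) {
    # non-matrix top-level element: skip
    return(list(value = NULL, name = NULL, next_pos = tag$next_pos))
  }
  p <- tag$data_pos
  # array flags
  ftag <- mat5_read_tag(raw, p, endian)
  flags <- readBin(raw[ftag$data_pos:(ftag$data_pos + 3L)], "integer", 1,
                   size = 4, endian = endian)
  klass <- bitwAnd(flags, 0xffL)
  complex_flag <- bitwAnd(bitwShiftR(flags, 8L), 8L) > 0L
  p <- ftag$next_pos
  # dimensions
  dtag <- mat5_read_tag(raw, p, endian)
  dims <- readBin(raw[dtag$data_pos:(dtag$data_pos + dtag$nbytes - 1L)],
                  "integer", dtag$nbytes / 4, size = 4, endian = endian)
  p <- dtag$next_pos
  # name
  ntag <- mat5_read_tag(raw, p, endian)
  nm <- if (ntag$nbytes > 0)
    rawToChar(raw[ntag$data_pos:(ntag$data_pos + ntag$nbytes - 1L)]) else ""
  p <- ntag$next_pos
  supported <- klass %in% c(MX_CHAR, MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8,
                            MX_INT16, MX_UINT16, MX_INT32, MX_UINT32)
  if (!supported || complex_flag) {
    warning(sprintf("skipping MAT variable '%s': unsupported class %d", nm, klass))
    return(list(value = NULL, name = NULL, next_pos = tag$next_pos))
  }
  vtag <- mat5_read_tag(raw, p, endian)
  vals <- if (vtag$nbytes > 0)
    mat5_decode_numeric(raw, vtag$data_pos, vtag$nbytes, vtag$type, endian)
  else numeric(0)
  if (klass == MX_CHAR) {
    chars <- if (is.raw(vals)) rawToChar(vals) else
      intToUtf8(as.integer(vals), multiple = FALSE)
    value <- chars
  } else {
    value <- as.numeric(vals)
    if (length(dims) == 2 && dims[2] == 1) dims <- dims[1]
    if (length(dims) == 2) value <- matrix(value, dims[1], dims[2])
    else if (length(dims) > 2) value <- array(value, dims)
  }
  list(value = value, name = nm, next_pos = tag$next_pos)
}
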