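# Minimal MATLAB level-5 MAT-file support, enough for Ninapro-style subject
# files: little-endian files, numeric (real) matrices, zlib-compressed
# (v7 / miCOMPRESSED) or plain elements. Unsupported variable classes
# (cell, struct, char, ...) are skipped with a warning.

mi_sizes <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 2, `5` = 4, `6` = 4,
              `7` = 4, `9` = 8, `12` = 8, `13` = 8)

decode_numeric <- function(type, dat) {
  n <- length(dat) / mi_sizes[[as.character(type)]]
  switch(as.character(type),
    `1` = as.numeric(readBin(dat, "integer", n, 1, signed = TRUE)),
    `2` = as.numeric(readBin(dat, "integer", n, 1, signed = FALSE)),
    `3` = as.numeric(readBin(dat, "integer", n, 2, signed = TRUE,
                             endian = "little")),
    `4` = as.numeric(readBin(dat, "integer", n, 2, signed = FALSE,
                             endian = "little")),
    `5` = as.numeric(readBin(dat, "integer", n, 4, endian = "little")),
    `6` = {
      v <- readBin(dat, "integer", n, 4, endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    `7` = readBin(dat, "double", n, 4, endian = "little"),
    `9` = readBin(dat, "double", n, 8, endian = "little"),
    stopf("unsupported MAT data type %d", type))
}

# Parse the data element starting at 0-based offset `pos`; returns type, the
# raw payload, and the offset of the next element.
parse_tag <- function(raw, pos, pad = TRUE) {
  t16 <- readBin(raw[pos + 1:2], "integer", 1, 2, signed = FALSE,
                 endian = "little")
  n16 <- readBin(raw[pos + 3:4], "integer", 1, 2, signed = FALSE,
                 endian = "little")
  if (n16 != 0) {                                  # small data element
    list(type = t16, data = raw[pos + 4 + seq_len(n16)], next_pos = pos + 8)
  } else {
    nb <- readBin(raw[pos + 5:8], "integer", 1, 4, endian = "little")
    data <- if (nb > 0) raw[pos + 8 + seq_len(nb)] else raw(0)
    adv <- if (pad) 8 * ceiling(nb / 8) else nb
    list(type = t16, data = data, next_pos = pos + 8 + adv)
  }
}

parse_matrix_element <- function(content) {
  pos <- 0
  flags <- parse_tag(content, pos); pos <- flags$next_pos
  cls <- as.integer(flags$data[1])
  dims_el <- parse_tag(content, pos); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4, 4,
                  endian = "little")
  name_el <- parse_tag(content, pos); pos <- name_el$next_pos
  name <- rawToChar(name_el$data)
  if (!(cls %in% 6:15)) {
    warnf("skipping variable '%s': unsupported class %d", name, cls)
    return(list(name = name, value = NULL))
  }
  data_el <- parse_tag(content, pos)
  vals <- decode_numeric(data_el$type, data_el$data)
  value <- if (length(dims) == 2) matrix(vals, dims[1], dims[2])
           else array(vals, dims)
  list(name = name, value = value)
}

#' Read a MATLAB v5/v7 MAT-file of numeric matrices
#'
#' Supports little-endian files with real numeric variables, stored plainly
#' (v5) or zlib-compressed (v7). Non-numeric variables are skipped with a
#' warning.
#'
#' @param path file path.
#' @return named list of numeric matrices/arrays.
#' @export
read_mat <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128 || rawToChar(raw[1:4]) != "MATL")
    stopf("'%s' is not a MATLAB level-5 MAT-file", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") stopf("big-endian MAT-files are not supported")
  out <- list()
  pos <- 128
  while (pos + 8 <= length(raw)) {
    el <- parse_tag(raw, pos, pad = (readBin(raw[pos + 1:2], "integer", 1, 2,
                                             signed = FALSE,
                                             endian = "little") != 15))
    content <- el$data
    if (el$type == 15) {                           # miCOMPRESSED
      content <- memDecompress(content, type = "gzip")
      inner <- parse_tag(content, 0)
      content <- inner$data
    } else if (el$type != 14) {
      pos <- el$next_pos
      next
    }
    v <- parse_matrix_element(content)
    if (!is.null(v$value)) out[[v$name]] <- v$value
    pos <- el$next_pos
  }
  out
}

u32_raw <- function(x) writeBin(as.integer(x), raw(), 4, endian = "little")

mat_element_raw <- function(type, payload) {
  n <- length(payload)
  pad <- raw((8 - n %% 8) %% 8)
  c(u32_raw(type), u32_raw(n), payload, pad)
}

#' Write numeric matrices as a MATLAB v5 MAT-file
#'
#' Companion to [read_mat()]: every variable is stored as a real double
#' matrix, optionally compressed.
#'
#' @param path file path.
#' @param vars named list of numeric vectors/matrices.
#' @param compress store each variable as a zlib-compressed element (v7
#'   style).
#' @export
write_mat <- function(path, vars, compress = FALSE) {
  stopifnot(length(names(vars)) == length(vars))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by fitnet on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  header <- c(charToRaw(formatC(desc, width = -116)), raw(8),
              as.raw(c(0x00, 0x01)), charToRaw("IM"))
  stopifnot(length(header) == 128)
  body <- lapply(names(vars), function(nm) {
    m <- as.matrix(vars[[nm]])
    content <- c(
      mat_element_raw(6, c(u32_raw(6), u32_raw(0))),           # flags: double
      mat_element_raw(5, c(u32_raw(nrow(m)), u32_raw(ncol(m)))),
      mat_element_raw(1, charToRaw(nm)),
      mat_element_raw(9, writeBin(as.numeric(m), raw(), 8, endian = "little")))
    el <- mat_element_raw(14, content)
    if (compress) {
      z <- memCompress(el, type = "gzip")
      c(u32_raw(15), u32_raw(length(z)), z)
    } else el
  })
  writeBin(c(header, do.call(c, body)), path)
  invisible(path)
}
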