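#' Bit streams
#'
#' A `bitstream` is an ordered sequence of 0/1 integers with byte packing
#' defined MSB-first: the first bit of the stream is the most significant
#' bit of the first byte, and the last byte is zero-padded. The exact bit
#' length always travels alongside the packed bytes (archive members store
#' it in their headers), so padding bits are never interpreted as data.
#'
#' @param bits integer vector of 0s and 1s, or a character string such as
#'   `"11010"`.
#' @return An integer vector of class `bitstream`.
#' @examples
#' bitstream("11010")
#' pack_bits(bitstream(c(1, 1, 0, 1, 0)))
#' @export
bitstream <- function(bits = integer()) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1L)
    bits <- if (nzchar(bits)) as.integer(strsplit(bits, "")[[1L]]) else integer()
  }
  bits <- as.integer(bits)
  if (length(bits) && !all(bits %in% c(0L, 1L))) {
    stop("a bitstream may only contain 0s and 1s")
  }
  structure(bits, class = "bitstream")
}

#' @rdname bitstream
#' @param x a `bitstream`.
#' @param ... unused.
#' @export
print.bitstream <- function(x, ...) {
  cat("<bitstream: ", length(x), " bits> ", bit_string(x), "\n", sep = "")
  invisible(x)
}

#' @rdname bitstream
#' @export
bit_string <- function(x) paste(unclass(x), collapse = "")

#' Concatenate bitstreams
#' @param ... bitstreams (or 0/1 vectors).
#' @return A single `bitstream`.
#' @export
bs_concat <- function(...) {
  bitstream(unlist(lapply(list(...), unclass), use.names = FALSE))
}

#' Pack a bitstream into bytes (MSB-first)
#'
#' @param bits a `bitstream` or 0/1 integer vector.
#' @return A list with `bytes` (raw vector, final byte zero-padded) and
#'   `nbits` (exact bit count).
#' @export
pack_bits <- function(bits) {
  bits <- unclass(bitstream(bits))
  nbits <- length(bits)
  if (nbits == 0L) {
    return(list(bytes = raw(0), nbits = 0L))
  }
  pad <- (8L - nbits %% 8L) %% 8L
  padded <- c(bits, rep(0L, pad))
  # packBits() is little-endian within bytes; reverse each octet for
  # MSB-first order
  idx <- as.vector(matrix(seq_along(padded), nrow = 8L)[8:1, ])
  list(bytes = packBits(as.logical(padded[idx]), type = "raw"), nbits = nbits)
}

#' Unpack bytes into a bitstream (MSB-first)
#'
#' @param bytes raw vector.
#' @param nbits exact number of data bits (padding is discarded).
#' @return A `bitstream`.
#' @export
unpack_bits <- function(bytes, nbits) {
  if (nbits == 0L) {
    return(bitstream())
  }
  bits <- as.integer(rawToBits(bytes))
  idx <- as.vector(matrix(seq_along(bits), nrow = 8L)[8:1, ])
  bitstream(bits[idx][seq_len(nbits)])
}
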