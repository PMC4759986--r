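#' Integer stream coding with a configurable codec
#'
#' The archive encodes every integer field (start-position deltas,
#' variation counts and offsets, read lengths, flags, zigzagged template
#' offsets, read-ID deltas) with one of three codecs: canonical Huffman,
#' Golomb, or extended Golomb. One codec id applies to all streams of a
#' run.
#'
#' @param values non-negative integer vector (may be empty).
#' @param codec one of `"huffman"`, `"golomb"`, `"extended_golomb"`.
#' @param m divisor for the Golomb family (default 3; ignored by
#'   Huffman).
#' @return An encoded stream: list with `codec`, `m`, `n`, `bytes`,
#'   `nbits`, and for Huffman `symbols`/`lengths`.
#' @examples
#' s <- encode_integers(c(7, 0, 12), "golomb", m = 3)
#' decode_integers(s)
#' @export
encode_integers <- function(values, codec = c("huffman", "golomb", "extended_golomb"),
                            m = 3L) {
  codec <- match.arg(codec)
  values <- as.integer(values)
  if (any(is.na(values) | values < 0L)) stop("stream values must be non-negative integers")
  out <- list(codec = codec, m = as.integer(m), n = length(values))
  if (length(values) == 0L) {
    out$bytes <- raw(0)
    out$nbits <- 0
    if (codec == "huffman") {
      out$symbols <- integer()
      out$lengths <- integer()
    }
    return(out)
  }
  enc <- switch(codec,
    golomb = cpp_golomb_encode(values, out$m),
    extended_golomb = cpp_egolomb_encode(values, out$m),
    huffman = {
      h <- huffman_stream_encode(values)
      out$symbols <- h$symbols
      out$lengths <- h$lengths
      h
    }
  )
  out$bytes <- enc$bytes
  out$nbits <- enc$nbits
  out
}

#' @rdname encode_integers
#' @param stream an encoded stream as returned by `encode_integers`.
#' @export
decode_integers <- function(stream) {
  if (stream$n == 0L) {
    return(integer())
  }
  switch(stream$codec,
    golomb = cpp_golomb_decode(stream$bytes, stream$nbits, stream$m, stream$n)$values,
    extended_golomb = cpp_egolomb_decode(stream$bytes, stream$nbits, stream$m, stream$n)$values,
    huffman = cpp_huffman_decode(
      stream$bytes, stream$nbits, stream$symbols,
      stream$lengths, stream$n
    )$values,
    stop("unknown codec id in stream")
  )
}

CODEC_IDS <- c(huffman = 1L, golomb = 2L, extended_golomb = 3L)

#' Serialize an encoded integer stream
#'
#' Wire format: codec id (1 byte), divisor m (2 bytes), value count
#' (4 bytes), bit length (8 bytes), then for Huffman the length table
#' (symbol count as 4 bytes, then per symbol a 4-byte symbol value and a
#' 1-byte length), then the packed payload bytes. All integers
#' little-endian.
#'
#' @param stream an encoded stream from [encode_integers()].
#' @return A raw vector.
#' @keywords internal
#' @export
serialize_stream <- function(stream) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(CODEC_IDS[[stream$codec]]), con)
  writeBin(packBits(intToBits(stream$m)[1:16], type = "raw"), con)
  writeBin(as.integer(stream$n), con, size = 4L, endian = "little")
  writeBin(as.numeric(stream$nbits), con, size = 8L, endian = "little")
  if (stream$codec == "huffman") {
    writeBin(length(stream$symbols), con, size = 4L, endian = "little")
    if (length(stream$symbols)) {
      writeBin(as.integer(stream$symbols), con, size = 4L, endian = "little")
      writeBin(as.raw(stream$lengths), con)
    }
  }
  writeBin(stream$bytes, con)
  rawConnectionValue(con)
}

#' @rdname serialize_stream
#' @param bytes raw vector produced by `serialize_stream` (possibly with
#'   trailing data).
#' @param pos 1-based read offset into `bytes`.
#' @return For the reader, a list with the decoded `stream` and `pos`
#'   advanced past it.
#' @keywords internal
#' @export
read_stream <- function(bytes, pos = 1L) {
  con <- rawConnection(bytes[pos:length(bytes)], "rb")
  on.exit(close(con))
  id <- as.integer(readBin(con, "raw", 1L))
  codec <- names(CODEC_IDS)[match(id, CODEC_IDS)]
  if (is.na(codec)) stop("unknown codec id in stream header: ", id)
  m <- sum(as.integer(readBin(con, "raw", 2L)) * c(1L, 256L))
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  nbits <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  stream <- list(codec = codec, m = m, n = n, nbits = nbits)
  consumed <- 15L
  if (codec == "huffman") {
    nsym <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    stream$symbols <- readBin(con, "integer", nsym, size = 4L, endian = "little")
    stream$lengths <- as.integer(readBin(con, "raw", nsym))
    consumed <- consumed + 4L + 5L * nsym
  }
  nbytes <- as.integer(ceiling(nbits / 8))
  stream$bytes <- readBin(con, "raw", nbytes)
  consumed <- consumed + nbytes
  list(stream = stream, pos = pos + consumed)
}
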