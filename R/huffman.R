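#' Optimal prefix-code lengths (Huffman)
#'
#' Computes the codeword lengths of an optimal binary prefix code for the
#' given symbol frequencies, by Huffman merging with a deterministic
#' tie-break (ties between equal weights are resolved in favour of the
#' earlier-created node, so the length table is reproducible). A
#' single-symbol alphabet gets length 1.
#'
#' @param counts non-negative frequencies, one per symbol; at least one
#'   must be positive.
#' @return Integer vector of codeword lengths, parallel to `counts`.
#' @examples
#' huffman_code_lengths(c(0.25, 0.25, 0.2, 0.15, 0.15))
#' @export
huffman_code_lengths <- function(counts) {
  cpp_huffman_lengths(as.numeric(counts))
}

#' Canonical Huffman codebook
#'
#' Assigns canonical codewords to a length table: symbols are sorted by
#' `(length, symbol order)` and codewords are assigned sequentially, so
#' the whole codebook is determined by the lengths alone — this is what
#' lets an archive store the length table instead of a code tree.
#'
#' @param lengths positive integer codeword lengths satisfying the Kraft
#'   inequality `sum(2^-lengths) <= 1`.
#' @param symbols optional symbol labels (defaults to `0:(n-1)`).
#' @return A data.frame with columns `symbol`, `length`, `code` (bit
#'   string), in canonical order.
#' @examples
#' canonical_codebook(c(2, 2, 2, 3, 3), letters[1:5])
#' @export
canonical_codebook <- function(lengths, symbols = seq_along(lengths) - 1L) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) stop("empty length table")
  if (any(is.na(lengths) | lengths < 1L)) stop("lengths must be positive integers")
  if (sum(2^-lengths) > 1 + 1e-12) stop("length table violates the Kraft inequality")
  ord <- order(lengths, seq_along(lengths))
  code <- 0
  prev <- 0L
  out <- character(length(lengths))
  for (i in seq_along(ord)) {
    s <- ord[i]
    code <- code * 2^(lengths[s] - prev)
    out[i] <- bit_string(int_to_bits(code, lengths[s]))
    code <- code + 1
    prev <- lengths[s]
  }
  data.frame(
    symbol = symbols[ord], length = lengths[ord], code = out,
    stringsAsFactors = FALSE
  )
}

#' Huffman-code an integer stream
#'
#' Builds the empirical symbol table of `values`, derives optimal lengths,
#' and emits the canonical-coded bit stream. The returned table (symbols
#' and lengths) is all a decoder needs.
#'
#' @param values non-empty integer vector.
#' @return A list with `bytes`, `nbits`, `symbols`, `lengths`, `n`.
#' @examples
#' enc <- huffman_stream_encode(c(1, 1, 2, 3))
#' huffman_stream_decode(enc)
#' @export
huffman_stream_encode <- function(values) {
  values <- as.integer(values)
  if (length(values) == 0L) stop("cannot Huffman-code an empty stream")
  tab <- sort(unique(values))
  counts <- tabulate(match(values, tab), nbins = length(tab))
  lengths <- cpp_huffman_lengths(as.numeric(counts))
  enc <- cpp_huffman_encode(values, tab, lengths)
  list(
    bytes = enc$bytes, nbits = enc$nbits,
    symbols = tab, lengths = lengths, n = length(values)
  )
}

#' @rdname huffman_stream_encode
#' @param enc a list as returned by `huffman_stream_encode` (or with the
#'   same fields read back from an archive member).
#' @param count number of values to decode (defaults to `enc$n`).
#' @return For the decoder, the integer vector of decoded values.
#' @export
huffman_stream_decode <- function(enc, count = enc$n) {
  if (count == 0L) {
    return(integer())
  }
  cpp_huffman_decode(enc$bytes, enc$nbits, enc$symbols, enc$lengths, count)$values
}
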