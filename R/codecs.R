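#' Unary code
#'
#' Encodes a non-negative integer `i` as `i` ones followed by a single
#' terminating zero; `unary_encode(4)` is `11110`.
#'
#' @param n non-negative integer.
#' @return A `bitstream` of `n + 1` bits.
#' @examples
#' bit_string(unary_encode(4))
#' @export
unary_encode <- function(n) {
  n <- check_scalar_nonneg(n)
  bitstream(c(rep(1L, n), 0L))
}

#' @rdname unary_encode
#' @param bits a `bitstream` (or `"0110..."` string) starting with a unary
#'   codeword.
#' @param offset 1-based position at which to start reading.
#' @return For the decoder, a list with `value` and `bits_consumed`.
#' @export
unary_decode <- function(bits, offset = 1L) {
  bits <- bitstream(bits)
  zero <- which(unclass(bits)[offset:length(bits)] == 0L)
  if (length(zero) == 0L) stop("bit stream exhausted mid-codeword (unary)")
  list(value = zero[1L] - 1L, bits_consumed = zero[1L])
}

#' Truncated binary code
#'
#' Prefix-free code for an alphabet of size `m`: with `k = floor(log2(m))`
#' the first `2^(k+1) - m` symbols get `k`-bit codewords and the remaining
#' symbols get `k + 1` bits. The singleton alphabet (`m = 1`) needs zero
#' bits.
#'
#' @param r symbol in `[0, m)`.
#' @param m alphabet size, `m >= 1`.
#' @return A `bitstream`.
#' @examples
#' bit_string(truncbin_encode(1, 3))
#' @export
truncbin_encode <- function(r, m) {
  m <- check_scalar_pos(m, "alphabet size m")
  r <- check_scalar_nonneg(r)
  if (r >= m) stop("symbol out of range [0, m)")
  if (m == 1L) {
    return(bitstream())
  }
  k <- floor(log2(m))
  t <- 2^(k + 1) - m
  if (r < t) int_to_bits(r, k) else int_to_bits(r + t, k + 1)
}

#' @rdname truncbin_encode
#' @param bits a `bitstream`.
#' @param offset 1-based read position.
#' @export
truncbin_decode <- function(bits, m, offset = 1L) {
  m <- check_scalar_pos(m, "alphabet size m")
  bits <- unclass(bitstream(bits))
  if (m == 1L) {
    return(list(value = 0L, bits_consumed = 0L))
  }
  k <- as.integer(floor(log2(m)))
  t <- 2^(k + 1) - m
  if (offset + k - 1L > length(bits)) stop("bit stream exhausted mid-codeword (truncated binary)")
  v <- bits_to_int(bits[offset + seq_len(k) - 1L])
  if (v < t) {
    return(list(value = as.integer(v), bits_consumed = k))
  }
  if (offset + k > length(bits)) stop("bit stream exhausted mid-codeword (truncated binary)")
  v <- v * 2 + bits[offset + k]
  list(value = as.integer(v - t), bits_consumed = k + 1L)
}

#' Golomb code
#'
#' Splits `n` into quotient `q = n %/% m` and remainder `r = n %% m`,
#' encodes `q` in unary and `r` in truncated binary, and concatenates the
#' two. `m = 1` degenerates to pure unary coding. Golomb codes are optimal
#' prefix codes for geometrically distributed integers.
#'
#' @param n non-negative integer.
#' @param m positive divisor (default 3).
#' @return A `bitstream`.
#' @examples
#' bit_string(golomb_encode(7, 3)) # "11010"
#' golomb_decode("11010", 3)$value # 7
#' @export
golomb_encode <- function(n, m = 3L) {
  m <- check_scalar_pos(m, "divisor m")
  n <- check_scalar_nonneg(n)
  bs_concat(unary_encode(n %/% m), truncbin_encode(n %% m, m))
}

#' @rdname golomb_encode
#' @param bits a `bitstream` or bit string beginning with a Golomb
#'   codeword.
#' @param offset 1-based read position, for composable decoding of
#'   concatenated codewords.
#' @return For the decoder, a list with `value` (`q * m + r`) and
#'   `bits_consumed`.
#' @export
golomb_decode <- function(bits, m = 3L, offset = 1L) {
  m <- check_scalar_pos(m, "divisor m")
  bits <- bitstream(bits)
  q <- unary_decode(bits, offset)
  r <- truncbin_decode(bits, m, offset + q$bits_consumed)
  list(
    value = q$value * m + r$value,
    bits_consumed = q$bits_consumed + r$bits_consumed
  )
}

#' Golomb-Rice parameter from a sample mean
#'
#' For a geometric source with mean `mu`, the Rice variant restricts the
#' Golomb divisor to powers of two, `m = 2^k`. The optimal exponent is
#' `k* = max(0, 1 + floor(log2(log(phi - 1) / log(mu / (mu + 1)))))`, with
#' `phi = (sqrt(5) + 1) / 2` the golden ratio. The inner ratio of
#' logarithms is base-invariant; natural logs are used.
#'
#' @param mu positive sample mean.
#' @return Non-negative integer `k*`.
#' @examples
#' rice_parameter(100)
#' @export
rice_parameter <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0) {
    stop("mu must be a positive number")
  }
  phi <- (sqrt(5) + 1) / 2
  ratio <- log(phi - 1) / log(mu / (mu + 1))
  as.integer(max(0, 1 + floor(log2(ratio))))
}

#' Extended Golomb code
#'
#' Iterated-division code for power-law distributed integers: divide `n`
#' by `m` until the quotient reaches 0, collecting remainders `r_1..r_M`;
#' emit the iteration count `M` in unary followed by the remainders
#' most-recent-first. The final remainder `r_M` is never 0, so it is coded
#' on the reduced alphabet `{1..m-1}` (as `r_M - 1` in truncated binary of
#' size `m - 1`); earlier remainders use truncated binary of size `m`.
#' The integer 0, which no `M >= 1` codeword can produce, takes the
#' reserved `M = 0` codeword, a single `0` bit.
#'
#' @param n non-negative integer.
#' @param m divisor, `m >= 2` (division never terminates for `m = 1`).
#' @return A `bitstream`.
#' @examples
#' bit_string(extended_golomb_encode(7, 3)) # "110110"
#' extended_golomb_decode("110110", 3)$value # 7
#' @export
extended_golomb_encode <- function(n, m = 3L) {
  m <- check_scalar_pos(m, "divisor m")
  if (m < 2L) stop("extended Golomb requires divisor m >= 2")
  n <- check_scalar_nonneg(n)
  if (n == 0) {
    return(unary_encode(0L))
  }
  rs <- integer()
  while (n > 0) {
    rs <- c(rs, n %% m)
    n <- n %/% m
  }
  M <- length(rs)
  parts <- list(unary_encode(M), truncbin_encode(rs[M] - 1L, m - 1L))
  for (i in rev(seq_len(M - 1L))) parts <- c(parts, list(truncbin_encode(rs[i], m)))
  do.call(bs_concat, parts)
}

#' @rdname extended_golomb_encode
#' @param bits a `bitstream` or bit string beginning with a codeword.
#' @param offset 1-based read position.
#' @return For the decoder, a list with `value` (the fold
#'   `((r_M * m + r_{M-1}) * m + ...) * m + r_1`) and `bits_consumed`.
#' @export
extended_golomb_decode <- function(bits, m = 3L, offset = 1L) {
  m <- check_scalar_pos(m, "divisor m")
  if (m < 2L) stop("extended Golomb requires divisor m >= 2")
  bits <- bitstream(bits)
  u <- unary_decode(bits, offset)
  used <- u$bits_consumed
  if (u$value == 0L) {
    return(list(value = 0L, bits_consumed = used))
  }
  fin <- truncbin_decode(bits, m - 1L, offset + used)
  used <- used + fin$bits_consumed
  n <- fin$value + 1
  for (i in seq_len(u$value - 1L)) {
    r <- truncbin_decode(bits, m, offset + used)
    used <- used + r$bits_consumed
    n <- n * m + r$value
  }
  list(value = n, bits_consumed = used)
}

#' Zigzag mapping for signed integers
#'
#' All integer codecs here are defined on non-negative integers; signed
#' fields (template offsets) are mapped `0, -1, 1, -2, 2, ... ->
#' 0, 1, 2, 3, 4, ...` before encoding.
#'
#' @param x integer vector (signed for encode, non-negative for decode).
#' @return Integer vector.
#' @export
zigzag_encode <- function(x) {
  x <- as.integer(x)
  ifelse(x >= 0L, 2L * x, -2L * x - 1L)
}

#' @rdname zigzag_encode
#' @export
zigzag_decode <- function(x) {
  x <- as.integer(x)
  ifelse(x %% 2L == 0L, x %/% 2L, -((x + 1L) %/% 2L))
}

# ---- internal helpers -------------------------------------------------

check_scalar_nonneg <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("expected a single non-negative integer")
  }
  as.integer(n)
}

check_scalar_pos <- function(m, what = "m") {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != floor(m)) {
    stop(what, " must be a positive integer")
  }
  as.integer(m)
}

int_to_bits <- function(v, width) {
  if (width == 0L) {
    return(bitstream())
  }
  bitstream(as.integer((v %/% 2^((width - 1):0)) %% 2))
}

bits_to_int <- function(bits) {
  if (length(bits) == 0L) {
    return(0)
  }
  sum(bits * 2^((length(bits) - 1):0))
}
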