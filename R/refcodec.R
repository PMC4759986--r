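#' Codec configuration
#'
#' One codec id applies to every integer stream of a compression run.
#'
#' @param codec `"huffman"`, `"golomb"` or `"extended_golomb"`.
#' @param m Golomb-family divisor (default 3).
#' @return A list of class `codec_config`.
#' @export
codec_config <- function(codec = c("huffman", "golomb", "extended_golomb"), m = 3L) {
  codec <- match.arg(codec)
  m <- check_scalar_pos(m, "divisor m")
  if (codec == "extended_golomb" && m < 2L) stop("extended Golomb requires m >= 2")
  structure(list(codec = codec, m = m), class = "codec_config")
}

VAR_KINDS <- c(sub = 0L, ins = 1L, del = 2L, soft = 3L)
BASE_ALPHA <- c("A", "C", "G", "T", "N")

#' Aligned read container
#'
#' Aligned reads are kept in two parallel tables: `reads` (one row per
#' read: `id`, `mate`, `ref_id`, `start` (1-based leftmost reference
#' position), `reverse`, `read_len`, `tlen`) and `variations` (one row per
#' difference from the reference: `read` index into `reads`, `ref_offset`
#' 0-based from `start`, `kind` in sub/ins/del/soft, `len`, `bases`).
#' Variations are stored in reference orientation carrying the read's
#' base; the reverse-complement is applied last on decode.
#'
#' @param reads data.frame as described above.
#' @param variations data.frame as described above (zero rows allowed).
#' @return An object of class `aligned_reads`.
#' @export
aligned_reads <- function(reads, variations = empty_variations()) {
  stopifnot(all(c("id", "mate", "ref_id", "start", "reverse", "read_len", "tlen")
  %in% names(reads)))
  if (nrow(reads) && any(reads$start < 1L)) stop("SAM positions are 1-based: start must be >= 1")
  structure(list(reads = reads, variations = variations), class = "aligned_reads")
}

empty_variations <- function() {
  data.frame(
    read = integer(), ref_offset = integer(), kind = character(),
    len = integer(), bases = character(), stringsAsFactors = FALSE
  )
}

empty_aligned <- function() {
  aligned_reads(data.frame(
    id = character(), mate = integer(), ref_id = character(),
    start = integer(), reverse = logical(), read_len = integer(),
    tlen = integer(), stringsAsFactors = FALSE
  ))
}

empty_unaligned <- function() {
  data.frame(id = character(), mate = integer(), seq = character(), stringsAsFactors = FALSE)
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(
    "<aligned_reads: ", nrow(x$reads), " reads, ", nrow(x$variations),
    " variations over ", length(unique(x$reads$ref_id)), " reference(s)>\n",
    sep = ""
  )
  invisible(x)
}

ref_chars <- function(references) {
  if (methods::is(references, "DNAStringSet")) {
    out <- as.character(references)
  } else {
    out <- unlist(references)
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("references must be named sequences")
  }
  # FASTA headers may carry descriptions; the reference id is the first token
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

strip_mate_suffix <- function(qname) {
  has <- grepl("_[12]$", qname)
  mate <- integer(length(qname))
  mate[has] <- as.integer(substring(qname[has], nchar(qname[has])))
  id <- ifelse(has, substr(qname, 1L, nchar(qname) - 2L), qname)
  list(id = id, mate = mate)
}

#' Parse SAM alignments into differential records
#'
#' Reads SAM text (1-based coordinates, as produced by standard aligners;
#' `"*"` accepted in QUAL) and splits records into aligned reads — primary
#' mapped records whose CIGAR uses only M/I/D/S, with variations derived
#' by comparing the stored sequence to the reference slice — and
#' unaligned reads (unmapped records and unsupported CIGARs; routing
#' whole reads to the reference-free fallback keeps the scheme lossless).
#' Secondary alignments (flag 0x100) are skipped: the read is carried by
#' its primary record. The quality column is ignored. Read names ending
#' in `_1`/`_2` are interpreted as mate labels from pre-processing.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @param references named character vector or `DNAStringSet` containing
#'   every reference named by a mapped record.
#' @return A list with `aligned` (an [aligned_reads()] object) and
#'   `unaligned` (data.frame `id`, `mate`, `seq`).
#' @export
parse_sam <- function(sam, references) {
  lines <- if (length(sam) == 1L && !grepl("\t", sam) && file.exists(sam)) {
    readLines(sam)
  } else {
    as.character(sam)
  }
  refs <- ref_chars(references)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  if (length(body) == 0L) {
    return(list(aligned = empty_aligned(), unaligned = empty_unaligned()))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1L]
    stop("malformed SAM line ", body[bad], ": fewer than 11 fields")
  }
  pick <- function(i) vapply(fields, `[[`, character(1), i)
  qname <- pick(1L)
  flag <- suppressWarnings(as.integer(pick(2L)))
  rname <- pick(3L)
  pos <- suppressWarnings(as.integer(pick(4L)))
  cigar <- pick(6L)
  tlen <- suppressWarnings(as.integer(pick(9L)))
  seqs <- pick(10L)
  if (any(is.na(flag))) {
    stop("malformed SAM line ", body[which(is.na(flag))[1L]], ": non-numeric FLAG")
  }
  keep <- bitwAnd(flag, 0x100L) == 0L # drop secondary alignments
  qname <- qname[keep]
  flag <- flag[keep]
  rname <- rname[keep]
  pos <- pos[keep]
  cigar <- cigar[keep]
  tlen <- tlen[keep]
  seqs <- seqs[keep]
  body <- body[keep]

  ms <- strip_mate_suffix(qname)
  flag_mate <- ifelse(bitwAnd(flag, 0x40L) > 0L, 1L, ifelse(bitwAnd(flag, 0x80L) > 0L, 2L, 0L))
  mate <- ifelse(ms$mate > 0L, ms$mate, flag_mate)
  id <- ms$id

  unmapped <- bitwAnd(flag, 0x4L) > 0L | rname == "*" | cigar == "*"
  unsupported <- !unmapped & grepl("[^0-9MIDS]", cigar)
  to_ref <- !unmapped & !unsupported
  if (any(to_ref & is.na(pos))) {
    stop("malformed SAM line ", body[which(to_ref & is.na(pos))[1L]], ": non-numeric POS")
  }

  una <- data.frame(
    id = id[!to_ref], mate = mate[!to_ref],
    seq = ifelse(bitwAnd(flag[!to_ref], 0x10L) > 0L,
      revcomp(seqs[!to_ref]), seqs[!to_ref]
    ),
    stringsAsFactors = FALSE
  )

  if (!any(to_ref)) {
    return(list(aligned = empty_aligned(), unaligned = una))
  }
  i <- which(to_ref)
  missing_ref <- setdiff(unique(rname[i]), names(refs))
  if (length(missing_ref)) {
    stop("reference '", missing_ref[1L], "' not found among the supplied references")
  }
  tl <- tlen[i]
  tl[is.na(tl)] <- 0L
  reads <- data.frame(
    id = id[i], mate = mate[i], ref_id = rname[i], start = pos[i],
    reverse = bitwAnd(flag[i], 0x10L) > 0L,
    read_len = nchar(seqs[i]), tlen = tl, stringsAsFactors = FALSE
  )

  simple <- grepl("^[0-9]+M$", cigar[i])
  vtabs <- vector("list", 2L)

  if (any(simple)) {
    si <- which(simple)
    rl <- reads$read_len[si]
    refseq <- refs[reads$ref_id[si]]
    ends <- reads$start[si] + rl - 1L
    over <- ends > nchar(refseq)
    if (any(over)) {
      stop(
        "alignment at line ", body[i[si[which(over)[1L]]]],
        " extends past the end of reference ", reads$ref_id[si[which(over)[1L]]]
      )
    }
    slices <- substr(refseq, reads$start[si], ends)
    offs <- cpp_mismatch_offsets(seqs[i][si], slices)
    nvar <- lengths(offs)
    if (sum(nvar) > 0L) {
      read_idx <- rep(si, nvar)
      ref_off <- unlist(offs, use.names = FALSE)
      vtabs[[1L]] <- data.frame(
        read = read_idx, ref_offset = ref_off, kind = "sub", len = 1L,
        bases = substring(seqs[i][read_idx], ref_off + 1L, ref_off + 1L),
        stringsAsFactors = FALSE
      )
    }
  }

  if (any(!simple)) {
    parts <- lapply(which(!simple), function(j) {
      walk_cigar(
        seqs[i][j], cigar[i][j], refs[[reads$ref_id[j]]],
        reads$start[j], j, body[i[j]]
      )
    })
    vtabs[[2L]] <- do.call(rbind, parts)
  }

  vt <- do.call(rbind, vtabs[!vapply(vtabs, is.null, logical(1))])
  if (is.null(vt)) vt <- empty_variations()
  vt <- vt[order(vt$read, seq_len(nrow(vt))), , drop = FALSE]
  rownames(vt) <- NULL
  list(aligned = aligned_reads(reads, vt), unaligned = una)
}

# CIGAR walk for records with indels or soft clips; returns the variation
# rows for one read (read-order, non-decreasing ref_offset).
walk_cigar <- function(seq, cigar, ref, start, read_idx, line_no) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1L]]
  if (length(lens) != length(ops)) stop("malformed CIGAR at SAM line ", line_no)
  rp <- 0L # reference bases consumed (0-based offset from start)
  qp <- 0L # read bases consumed
  rows <- list()
  for (k in seq_along(ops)) {
    L <- lens[k]
    op <- ops[k]
    if (op == "M") {
      if (start + rp + L - 1L > nchar(ref)) {
        stop("alignment at line ", line_no, " extends past the reference end")
      }
      refseg <- substr(ref, start + rp, start + rp + L - 1L)
      readseg <- substr(seq, qp + 1L, qp + L)
      off <- cpp_mismatch_offsets(readseg, refseg)[[1L]]
      if (length(off)) {
        rows[[length(rows) + 1L]] <- data.frame(
          read = read_idx, ref_offset = rp + off, kind = "sub", len = 1L,
          bases = substring(readseg, off + 1L, off + 1L), stringsAsFactors = FALSE
        )
      }
      rp <- rp + L
      qp <- qp + L
    } else if (op == "I" || op == "S") {
      rows[[length(rows) + 1L]] <- data.frame(
        read = read_idx, ref_offset = rp, kind = if (op == "I") "ins" else "soft",
        len = L, bases = substr(seq, qp + 1L, qp + L), stringsAsFactors = FALSE
      )
      qp <- qp + L
    } else if (op == "D") {
      rows[[length(rows) + 1L]] <- data.frame(
        read = read_idx, ref_offset = rp, kind = "del", len = L, bases = "",
        stringsAsFactors = FALSE
      )
      rp <- rp + L
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

revcomp <- function(x) {
  if (length(x) == 0L) {
    return(character())
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Reconstruct a read from its reference and differential record
#'
#' Applies the stored variations to the reference slice in reference
#' orientation, then reverse-complements if the strand flag is set. The
#' result is byte-for-byte the original read sequence.
#'
#' @param reference reference sequence (single character string).
#' @param rec a list with `start`, `reverse`, `read_len` and a
#'   `variations` data.frame (`ref_offset`, `kind`, `len`, `bases`).
#' @return The reconstructed read sequence.
#' @export
reconstruct_read <- function(reference, rec) {
  vt <- rec$variations
  if (is.null(vt)) vt <- empty_variations()
  ins_len <- sum(vt$len[vt$kind %in% c("ins", "soft")])
  del_len <- sum(vt$len[vt$kind == "del"])
  span <- rec$read_len - ins_len + del_len
  if (rec$start + span - 1L > nchar(reference)) {
    stop("reference too short for the recorded alignment span")
  }
  slice <- substr(reference, rec$start, rec$start + span - 1L)
  out <- patch_slice(slice, vt, span)
  if (nchar(out) != rec$read_len) {
    stop("corrupt record: reconstructed length ", nchar(out), " != ", rec$read_len)
  }
  if (isTRUE(rec$reverse)) revcomp(out) else out
}

patch_slice <- function(slice, vt, span) {
  if (nrow(vt) == 0L) {
    return(slice)
  }
  if (any(vt$ref_offset > span)) stop("corrupt record: variation offset beyond alignment span")
  pieces <- character(0)
  rpos <- 1L # next unconsumed 1-based index into slice
  for (k in seq_len(nrow(vt))) {
    ro1 <- vt$ref_offset[k] + 1L
    if (ro1 > rpos) pieces <- c(pieces, substr(slice, rpos, ro1 - 1L))
    kind <- vt$kind[k]
    if (kind == "sub") {
      pieces <- c(pieces, vt$bases[k])
      rpos <- ro1 + 1L
    } else if (kind == "ins" || kind == "soft") {
      pieces <- c(pieces, vt$bases[k])
      rpos <- ro1
    } else if (kind == "del") {
      rpos <- ro1 + vt$len[k]
    } else {
      stop("unknown variation kind: ", kind)
    }
  }
  if (rpos <= nchar(slice)) pieces <- c(pieces, substr(slice, rpos, nchar(slice)))
  paste(pieces, collapse = "")
}

# Batch reconstruction for decompression: vectorized slice extraction and
# substitution patching, per-read rebuild only where indels are present.
reconstruct_all <- function(aligned, references) {
  reads <- aligned$reads
  vt <- aligned$variations
  refs <- ref_chars(references)
  n <- nrow(reads)
  if (n == 0L) {
    return(character())
  }
  missing_ref <- setdiff(unique(reads$ref_id), names(refs))
  if (length(missing_ref)) {
    stop("reference '", missing_ref[1L], "' is required for decompression but was not found")
  }
  indel <- vt$kind != "sub"
  extra <- integer(n) # span - read_len
  if (any(indel)) {
    d <- vt$len[indel] * ifelse(vt$kind[indel] == "del", 1L, -1L)
    agg <- rowsum(d, vt$read[indel])
    extra[as.integer(rownames(agg))] <- agg[, 1L]
  }
  span <- reads$read_len + extra
  refseq <- refs[reads$ref_id]
  if (any(reads$start + span - 1L > nchar(refseq))) {
    stop("corrupt archive: alignment span exceeds reference length")
  }
  out <- substr(refseq, reads$start, reads$start + span - 1L)
  names(out) <- NULL

  indel_reads <- unique(vt$read[indel])
  sub_rows <- which(!indel & !(vt$read %in% indel_reads))
  for (k in sub_rows) { # sequential: several substitutions may hit one read
    r <- vt$read[k]
    substr(out[r], vt$ref_offset[k] + 1L, vt$ref_offset[k] + 1L) <- vt$bases[k]
  }
  for (r in indel_reads) {
    rows <- vt[vt$read == r, , drop = FALSE]
    out[r] <- patch_slice(out[r], rows, span[r])
  }
  if (any(nchar(out) != reads$read_len)) stop("corrupt archive: reconstructed length mismatch")
  rev <- which(reads$reverse)
  if (length(rev)) out[rev] <- revcomp(out[rev])
  out
}

# ---- block encoding ---------------------------------------------------

#' Encode one reference's aligned reads into an archive member
#'
#' Reads are sorted by start position and emitted as per-field integer
#' streams: (a) the first start absolute then successive differences,
#' (b) per-read variation counts, (c) within-read variation offset
#' deltas, (d) variation kind/length/base symbols, (e) read lengths,
#' (f) strand/mate flags, (g) zigzagged template offsets, (h) read-ID
#' suffix deltas (zigzagged; an opaque string table if suffixes are not
#' numeric). Every stream is coded with the configured codec.
#'
#' @param block an [aligned_reads()] object whose `reads` all share one
#'   `ref_id` and carry an `id_suffix` column.
#' @param cfg a [codec_config()].
#' @param drop_ids if `TRUE`, read-ID suffixes are not stored (lossy
#'   mode); sequences, mates and counts are still exact.
#' @return A raw vector (the serialized member).
#' @export
encode_block <- function(block, cfg = codec_config(), drop_ids = FALSE) {
  reads <- block$reads
  vt <- block$variations
  if (nrow(reads) == 0L) stop("cannot encode an empty block")
  if (length(unique(reads$ref_id)) != 1L) stop("encode_block requires a single ref_id")
  if (is.null(reads$id_suffix)) stop("block reads must carry an id_suffix column")

  ids_numeric <- all(grepl("^[0-9]+$", reads$id_suffix)) &&
    all(reads$id_suffix == as.character(as.integer(reads$id_suffix)))
  ord <- order(reads$start,
    if (ids_numeric) as.integer(reads$id_suffix) else reads$id_suffix,
    reads$mate,
    method = "radix"
  )
  reads <- reads[ord, , drop = FALSE]
  # variation rows follow their read into the new order
  new_pos <- match(seq_len(nrow(block$reads)), ord)
  if (nrow(vt)) {
    vt <- vt[order(new_pos[vt$read], seq_len(nrow(vt))), , drop = FALSE]
    vt$read <- new_pos[vt$read]
  }

  starts <- reads$start
  pos_stream <- c(starts[1L], diff(starts))
  var_count <- tabulate(vt$read, nbins = nrow(reads))
  var_off <- delta_within(vt$ref_offset, vt$read)
  var_sym <- variation_symbols(vt)
  flags <- as.integer(reads$reverse) + 2L * reads$mate

  enc <- function(v) serialize_stream(encode_integers(v, cfg$codec, cfg$m))
  streams <- list(
    pos = enc(pos_stream),
    var_count = enc(var_count),
    var_off = enc(var_off),
    var_sym = enc(var_sym),
    read_len = enc(reads$read_len),
    flags = enc(flags),
    tlen = enc(zigzag_encode(reads$tlen))
  )
  ids_kind <- 0L
  id_blob <- raw(0)
  if (!drop_ids) {
    if (ids_numeric) {
      ids_kind <- 1L
      sfx <- as.integer(reads$id_suffix)
      streams$ids <- enc(zigzag_encode(c(sfx[1L], diff(sfx))))
    } else {
      ids_kind <- 2L
      id_blob <- charToRaw(paste0(paste(reads$id_suffix, collapse = "\n"), "\n"))
    }
  }

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  write_lpstr(con, reads$ref_id[1L])
  writeBin(nrow(reads), con, size = 4L, endian = "little")
  writeBin(as.raw(ids_kind), con)
  writeBin(length(id_blob), con, size = 4L, endian = "little")
  writeBin(id_blob, con)
  for (s in streams) writeBin(s, con)
  rawConnectionValue(con)
}

#' @rdname encode_block
#' @param member raw vector produced by `encode_block`.
#' @return For the decoder, an [aligned_reads()] object with `id_suffix`
#'   restored (`NA` if the member was encoded with `drop_ids`).
#' @export
decode_block <- function(member) {
  p <- read_lpstr(member, 1L)
  ref_id <- p$value
  pos <- p$pos
  n <- readBin(member[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  ids_kind <- as.integer(member[pos + 4L])
  blob_len <- readBin(member[(pos + 5L):(pos + 8L)], "integer", 1L, size = 4L, endian = "little")
  pos <- pos + 9L
  id_blob <- if (blob_len > 0L) member[pos:(pos + blob_len - 1L)] else raw(0)
  pos <- pos + blob_len

  nm <- c("pos", "var_count", "var_off", "var_sym", "read_len", "flags", "tlen")
  if (ids_kind == 1L) nm <- c(nm, "ids")
  streams <- list()
  for (s in nm) {
    r <- read_stream(member, pos)
    streams[[s]] <- decode_integers(r$stream)
    pos <- r$pos
  }

  starts <- cumsum(streams$pos)
  flags <- streams$flags
  tlen <- zigzag_decode(streams$tlen)
  id_suffix <- if (ids_kind == 1L) {
    as.character(cumsum(zigzag_decode(streams$ids)))
  } else if (ids_kind == 2L) {
    strsplit(rawToChar(id_blob), "\n", fixed = TRUE)[[1L]]
  } else {
    rep(NA_character_, n)
  }
  reads <- data.frame(
    id = id_suffix, id_suffix = id_suffix, mate = flags %/% 2L,
    ref_id = ref_id, start = starts, reverse = flags %% 2L == 1L,
    read_len = streams$read_len, tlen = tlen, stringsAsFactors = FALSE
  )
  vt <- variations_from_symbols(streams$var_sym, streams$var_count, streams$var_off)
  aligned_reads(reads, vt)
}

# first value then within-group successive differences, concatenated
delta_within <- function(x, group) {
  if (length(x) == 0L) {
    return(integer())
  }
  d <- c(x[1L], diff(x))
  firsts <- c(TRUE, diff(group) != 0L)
  d[firsts] <- x[firsts]
  d
}

variation_symbols <- function(vt) {
  if (nrow(vt) == 0L) {
    return(integer())
  }
  base_codes <- function(s) match(strsplit(s, "")[[1L]], BASE_ALPHA) - 1L
  parts <- mapply(function(kind, len, bases) {
    kc <- VAR_KINDS[[kind]]
    switch(kind,
      sub = c(kc, match(bases, BASE_ALPHA) - 1L),
      del = c(kc, len),
      c(kc, len, base_codes(bases))
    )
  }, vt$kind, vt$len, vt$bases, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  out <- unlist(parts, use.names = FALSE)
  if (anyNA(out)) stop("variation bases outside the A/C/G/T/N alphabet")
  out
}

variations_from_symbols <- function(sym, var_count, var_off) {
  total <- sum(var_count)
  if (total == 0L) {
    return(empty_variations())
  }
  read <- rep(seq_along(var_count), var_count)
  ref_offset <- integer(total)
  # invert the within-read delta coding
  firsts <- c(TRUE, diff(read) != 0L)
  acc <- 0L
  for (k in seq_len(total)) {
    acc <- if (firsts[k]) var_off[k] else acc + var_off[k]
    ref_offset[k] <- acc
  }
  kind <- character(total)
  len <- integer(total)
  bases <- character(total)
  p <- 1L
  for (k in seq_len(total)) {
    kc <- sym[p]
    p <- p + 1L
    kn <- names(VAR_KINDS)[match(kc, VAR_KINDS)]
    if (is.na(kn)) stop("corrupt variation stream: unknown kind code ", kc)
    if (kn == "sub") {
      kind[k] <- "sub"
      len[k] <- 1L
      bases[k] <- BASE_ALPHA[sym[p] + 1L]
      p <- p + 1L
    } else if (kn == "del") {
      kind[k] <- "del"
      len[k] <- sym[p]
      bases[k] <- ""
      p <- p + 1L
    } else {
      L <- sym[p]
      p <- p + 1L
      kind[k] <- kn
      len[k] <- L
      bases[k] <- paste(BASE_ALPHA[sym[p:(p + L - 1L)] + 1L], collapse = "")
      p <- p + L
    }
  }
  data.frame(
    read = read, ref_offset = ref_offset, kind = kind, len = len,
    bases = bases, stringsAsFactors = FALSE
  )
}

write_lpstr <- function(con, s) {
  b <- charToRaw(s)
  writeBin(length(b), con, size = 4L, endian = "little")
  writeBin(b, con)
}

read_lpstr <- function(bytes, pos) {
  len <- readBin(bytes[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  value <- if (len > 0L) rawToChar(bytes[(pos + 4L):(pos + 3L + len)]) else ""
  list(value = value, pos = pos + 4L + len)
}
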