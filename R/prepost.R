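#' Read a FASTA/FASTQ file into a read table
#'
#' Thin wrapper over `Biostrings::readDNAStringSet`; IDs are the first
#' whitespace-delimited token of each header.
#'
#' @param path input file; format auto-detected from the first character.
#' @return data.frame with `id` and `seq`.
#' @export
read_seqs <- function(path) {
  first <- readChar(path, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(
    id = sub("\\s.*$", "", names(x)), seq = as.character(unname(x)),
    stringsAsFactors = FALSE
  )
}

#' Write a read table as FASTA
#'
#' @param reads data.frame with `id` and `seq`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Label paired-end mates
#'
#' Merges two paired FASTA/FASTQ files into one stream, appending `_1` or
#' `_2` to each read ID so the mate of origin survives compression; the
#' mate is also kept as an integer column. Inverse of [split_mates()].
#'
#' @param file1,file2 paired read files with matching record counts and
#'   IDs in the same order.
#' @return data.frame with `id` (labeled), `base_id`, `mate`, `seq`.
#' @export
label_mates <- function(file1, file2) {
  r1 <- read_seqs(file1)
  r2 <- read_seqs(file2)
  if (nrow(r1) != nrow(r2)) {
    stop("mate files disagree: ", nrow(r1), " vs ", nrow(r2), " records")
  }
  if (nrow(r1) == 0L) {
    return(data.frame(
      id = character(), base_id = character(), mate = integer(),
      seq = character(), stringsAsFactors = FALSE
    ))
  }
  out <- rbind(
    data.frame(
      id = paste0(r1$id, "_1"), base_id = r1$id, mate = 1L, seq = r1$seq,
      stringsAsFactors = FALSE
    ),
    data.frame(
      id = paste0(r2$id, "_2"), base_id = r2$id, mate = 2L, seq = r2$seq,
      stringsAsFactors = FALSE
    )
  )
  rownames(out) <- NULL
  out
}

#' @rdname label_mates
#' @param labeled a data.frame as produced by `label_mates`.
#' @return For `split_mates`, a list of two data.frames (`id`, `seq`),
#'   one per mate, with the labels removed.
#' @export
split_mates <- function(labeled) {
  lapply(1:2, function(m) {
    part <- labeled[labeled$mate == m, , drop = FALSE]
    data.frame(id = part$base_id, seq = part$seq, stringsAsFactors = FALSE)
  })
}

#' Strip quality scores from FASTQ
#'
#' Converts 4-line FASTQ records to FASTA with identical IDs and
#' sequences; qualities go to a plain-text sidecar (one line per read)
#' for external compression by a dedicated quality-score tool. FASTA
#' input passes through unchanged.
#'
#' @param input FASTQ (or FASTA) file.
#' @param fasta_out output FASTA path.
#' @param qual_out sidecar path for the quality lines (ignored for FASTA
#'   input).
#' @return `fasta_out`, invisibly.
#' @export
strip_quality <- function(input, fasta_out, qual_out = paste0(fasta_out, ".qual")) {
  first <- readChar(input, 1L)
  if (!identical(first, "@")) {
    file.copy(input, fasta_out, overwrite = TRUE)
    return(invisible(fasta_out))
  }
  lines <- readLines(input)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: record count is not a multiple of 4")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@"))) {
    stop("malformed FASTQ record ", which(!startsWith(ids, "@"))[1L], ": header must start with '@'")
  }
  if (any(!startsWith(plus, "+"))) {
    stop("malformed FASTQ record ", which(!startsWith(plus, "+"))[1L], ": separator must start with '+'")
  }
  if (any(nchar(quals) != nchar(seqs))) {
    stop(
      "malformed FASTQ record ", which(nchar(quals) != nchar(seqs))[1L],
      ": quality length differs from sequence length"
    )
  }
  writeLines(paste0(">", substring(ids, 2L), "\n", seqs), fasta_out, sep = "\n")
  writeLines(quals, qual_out)
  invisible(fasta_out)
}

#' Factor read IDs into a common prefix and suffix stream
#'
#' SRA-style IDs repeat a dataset stem (`"SRR359032."`) on every read;
#' the stem is stored once and re-appended at decompression. Suffixes
#' that are plain decimal numbers (no leading zeros) are flagged numeric
#' so they can be delta-coded as integers.
#'
#' @param ids non-empty character vector of read IDs.
#' @return A list with `scheme` (`prefix`, `kind`) and `suffixes`.
#' @export
factor_ids <- function(ids) {
  if (length(ids) == 0L) stop("factor_ids needs at least one ID")
  prefix <- common_prefix(ids)
  suffixes <- substring(ids, nchar(prefix) + 1L)
  numeric <- all(grepl("^[0-9]+$", suffixes)) &&
    all(suffixes == as.character(suppressWarnings(as.integer(suffixes))))
  list(
    scheme = list(prefix = prefix, kind = if (numeric) "numeric" else "opaque"),
    suffixes = suffixes
  )
}

#' @rdname factor_ids
#' @param scheme,suffixes as returned by `factor_ids`.
#' @return For `restore_ids`, the original ID vector.
#' @export
restore_ids <- function(scheme, suffixes) {
  if (length(suffixes) == 0L) {
    return(character())
  }
  paste0(scheme$prefix, suffixes)
}

# the longest common prefix of a set equals the LCP of its lexicographic
# extremes
common_prefix <- function(x) {
  if (length(x) == 1L) {
    return(x)
  }
  a <- min(x)
  b <- max(x)
  n <- min(nchar(a), nchar(b))
  i <- 0L
  while (i < n && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L)) i <- i + 1L
  substr(a, 1L, i)
}

#' Replace uniform placeholder qualities in SAM
#'
#' Aligners fed FASTA emit a QUAL column of repeated `I`; a single `*`
#' (the SAM convention for absent qualities) carries the same
#' information. Mixed-quality columns are left untouched.
#'
#' @param sam character vector of SAM lines (or a file path).
#' @return Character vector of SAM lines.
#' @export
sam_quality_placeholder <- function(sam) {
  lines <- if (length(sam) == 1L && !grepl("\t", sam) && file.exists(sam)) {
    readLines(sam)
  } else {
    as.character(sam)
  }
  body <- !startsWith(lines, "@") & nzchar(lines)
  if (!any(body)) {
    return(lines)
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  fixed <- vapply(fields, function(f) {
    if (length(f) >= 11L && grepl("^I+$", f[11L])) f[11L] <- "*"
    paste(f, collapse = "\t")
  }, character(1))
  lines[body] <- fixed
  lines
}

#' Merge decoded partitions, sort by ID, split mates
#'
#' Combines the reference-decoded and fallback-decoded reads, sorts them
#' by read ID ascending (numeric on the suffix when IDs share a stem with
#' numeric remainders, lexicographic otherwise), and, for paired data,
#' splits them into the two mate files with the `_1`/`_2` labels removed.
#'
#' @param aligned_out,unaligned_out data.frames with `id`, `mate`, `seq`.
#' @param paired logical; were the reads paired-end?
#' @param out_prefix output path stem: paired data goes to
#'   `<prefix>_1.fasta` / `<prefix>_2.fasta`, unpaired to
#'   `<prefix>.fasta`.
#' @return Character vector of the written file paths.
#' @export
merge_sort_split <- function(aligned_out, unaligned_out, paired, out_prefix) {
  all_reads <- rbind(
    aligned_out[, c("id", "mate", "seq")],
    unaligned_out[, c("id", "mate", "seq")]
  )
  if (anyDuplicated(paste(all_reads$id, all_reads$mate))) {
    stop("duplicate read ID + mate in decoded output")
  }
  key <- sort_key(all_reads$id)
  all_reads <- all_reads[order(key, all_reads$mate, method = "radix"), , drop = FALSE]
  if (paired) {
    paths <- paste0(out_prefix, c("_1.fasta", "_2.fasta"))
    for (m in 1:2) {
      write_fasta(all_reads[all_reads$mate == m, c("id", "seq")], paths[m])
    }
    paths
  } else {
    path <- paste0(out_prefix, ".fasta")
    write_fasta(all_reads[, c("id", "seq")], path)
    path
  }
}

sort_key <- function(ids) {
  if (length(ids) == 0L) {
    return(integer())
  }
  f <- factor_ids(ids)
  if (f$scheme$kind == "numeric") as.integer(f$suffixes) else ids
}
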