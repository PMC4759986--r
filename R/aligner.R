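#' Built-in naive read aligner
#'
#' A deliberately simple seed-and-verify aligner so the pipeline runs
#' with no external tools: exact k-mer seeds (default k = 16) at up to
#' three fixed offsets per read, both orientations, followed by ungapped
#' verification accepting up to `max_mismatch` substitutions. It emits
#' SAM text (primary records only, `*` qualities). It finds ungapped
#' substitution-only alignments; reads with indels relative to the
#' reference fall to the unaligned pool, which the fallback codec covers.
#'
#' @param reads data.frame with `id` (qnames, mate-labeled for paired
#'   data) and `seq`.
#' @param refs named character vector of reference sequences.
#' @param k seed length.
#' @param max_mismatch maximum substitutions accepted in verification.
#' @return Character vector of SAM lines.
#' @export
align_builtin <- function(reads, refs, k = 16L, max_mismatch = 3L) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs))
  )
  n <- nrow(reads)
  if (n == 0L) {
    return(header)
  }
  idx <- build_kmer_index(refs, k)

  fwd <- reads$seq
  rcv <- revcomp_vec(fwd)
  rl <- nchar(fwd)
  offs <- c(1L, k + 1L, 2L * k + 1L)

  queries <- data.table::rbindlist(lapply(0:1, function(orient) {
    s <- if (orient == 0L) fwd else rcv
    data.table::rbindlist(lapply(offs, function(o) {
      ok <- which(rl - o + 1L >= k)
      data.table::data.table(
        read = ok, orient = orient, off = o,
        kmer = substr(s[ok], o, o + k - 1L)
      )
    }))
  }))
  data.table::setkey(idx, kmer)
  cand <- idx[queries, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  best <- NULL
  if (nrow(cand)) {
    cand[, pos0 := pos - off + 1L]
    cand <- unique(cand[, list(read, orient, ref, pos0)])
    cand <- cand[pos0 >= 1L & pos0 + rl[read] - 1L <= nchar(refs)[match(ref, names(refs))]]
    if (nrow(cand)) {
      oriented <- ifelse(cand$orient == 0L, fwd[cand$read], rcv[cand$read])
      slices <- substr(refs[cand$ref], cand$pos0, cand$pos0 + rl[cand$read] - 1L)
      cand[, d := cpp_hamming(oriented, slices, max_mismatch)]
      cand <- cand[d <= max_mismatch]
      if (nrow(cand)) {
        data.table::setorder(cand, read, d, orient, ref, pos0)
        best <- cand[!duplicated(read)]
      }
    }
  }

  hit <- integer(0)
  records <- character(0)
  if (!is.null(best) && nrow(best)) {
    hit <- best$read
    seqs <- ifelse(best$orient == 0L, fwd[hit], rcv[hit])
    tlen <- pair_tlen(reads$id[hit], best$pos0, rl[hit])
    records <- sprintf(
      "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t%d\t%s\t*",
      reads$id[hit], ifelse(best$orient == 0L, 0L, 16L), best$ref,
      best$pos0, rl[hit], tlen, seqs
    )
  }
  miss <- setdiff(seq_len(n), hit)
  unrec <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", reads$id[miss], fwd[miss])
  c(header, records, unrec)
}

build_kmer_index <- function(refs, k) {
  data.table::rbindlist(lapply(names(refs), function(nm) {
    L <- nchar(refs[[nm]])
    if (L < k) {
      return(NULL)
    }
    starts <- seq_len(L - k + 1L)
    data.table::data.table(
      kmer = substring(refs[[nm]], starts, starts + k - 1L),
      ref = nm, pos = starts
    )
  }))
}

# signed template length for mate pairs aligned in the same batch:
# leftmost mate positive, rightmost negative, 0 when the mate is absent
pair_tlen <- function(qnames, pos, rl) {
  ms <- strip_mate_suffix(qnames)
  out <- integer(length(qnames))
  paired <- ms$mate > 0L
  if (!any(paired)) {
    return(out)
  }
  dt <- data.table::data.table(
    i = which(paired), id = ms$id[paired],
    pos = pos[paired], end = pos[paired] + rl[paired] - 1L
  )
  dt[, n := .N, by = id]
  both <- dt[n == 2L]
  if (nrow(both)) {
    both[, span := max(end) - min(pos) + 1L, by = id]
    both[, rank_in_pair := order(order(pos)), by = id] # 1 = leftmost, ties by appearance
    out[both$i] <- ifelse(both$rank_in_pair == 1L, both$span, -both$span)
  }
  out
}

#' Adapter constructors for the pipeline's external stages
#'
#' The taxonomy classifier, aligner, assembler and contig-search stages
#' are pluggable. Built-in versions keep the pipeline self-contained;
#' mock versions read ground truth from the synthetic community module so
#' the discovery loop is testable without installed tools; command
#' adapters shell out to an external program via a template with
#' `{reads}`, `{refs}`, `{out}` placeholders.
#'
#' @param report taxonomy report lines or file path (mock taxonomy).
#' @return An adapter: a list with `type` and a `fn`.
#' @export
adapter_mock_taxonomy <- function(report) {
  force(report)
  list(type = "mock", fn = function(...) report)
}

#' @rdname adapter_mock_taxonomy
#' @param k,max_mismatch built-in aligner tuning.
#' @export
adapter_builtin_aligner <- function(k = 16L, max_mismatch = 3L) {
  list(type = "builtin", fn = function(reads, refs) {
    align_builtin(reads, refs, k = k, max_mismatch = max_mismatch)
  })
}

#' @rdname adapter_mock_taxonomy
#' @param command shell template, e.g.
#'   `"bowtie2 -x {refs} -f -U {reads} -S {out}"`; the adapter writes the
#'   reads as FASTA, substitutes the placeholders, runs the command and
#'   reads the SAM back.
#' @export
adapter_command_aligner <- function(command) {
  force(command)
  list(type = "command", fn = function(reads, refs) {
    reads_f <- tempfile(fileext = ".fasta")
    refs_f <- tempfile(fileext = ".fasta")
    out_f <- tempfile(fileext = ".sam")
    write_fasta(reads, reads_f)
    write_fasta(
      data.frame(id = names(refs), seq = unname(refs), stringsAsFactors = FALSE),
      refs_f
    )
    cmd <- sub("\\{reads\\}", reads_f, command)
    cmd <- sub("\\{refs\\}", refs_f, cmd)
    cmd <- sub("\\{out\\}", out_f, cmd)
    status <- system(cmd)
    if (status != 0L || !file.exists(out_f)) stop("aligner command failed: ", cmd)
    readLines(out_f)
  })
}

#' @rdname adapter_mock_taxonomy
#' @param truth_sam ground-truth SAM lines from [simulate_reads()]; the
#'   mock assembler places each unaligned read at its true coordinates
#'   and reports the maximal covered stretches (>= `min_len`) as contigs,
#'   so contigs contain the reads' errors but true layout.
#' @param min_len minimum contig length to report.
#' @export
adapter_mock_assembler <- function(truth_sam, min_len = 200L) {
  force(truth_sam)
  force(min_len)
  list(type = "mock", fn = function(unaligned) {
    mock_assemble(unaligned, truth_sam, min_len)
  })
}

mock_assemble <- function(unaligned, truth_sam, min_len) {
  lines <- truth_sam[!startsWith(truth_sam, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, character(1), 1L)
  want_ids <- paste0(unaligned$id, ifelse(unaligned$mate > 0L, paste0("_", unaligned$mate), ""))
  keep <- match(want_ids, qname)
  keep <- keep[!is.na(keep)]
  if (length(keep) == 0L) {
    return(character())
  }
  rname <- vapply(f[keep], `[[`, character(1), 3L)
  pos <- as.integer(vapply(f[keep], `[[`, character(1), 4L))
  seqs <- vapply(f[keep], `[[`, character(1), 10L)
  contigs <- character()
  for (rn in unique(rname)) {
    sel <- rname == rn
    canvas_len <- max(pos[sel] + nchar(seqs[sel])) + 10L
    canvas <- strrep("N", canvas_len)
    ord <- order(pos[sel])
    p <- pos[sel][ord]
    s <- seqs[sel][ord]
    for (j in seq_along(p)) {
      substr(canvas, p[j], p[j] + nchar(s[j]) - 1L) <- s[j]
    }
    runs <- gregexpr("[ACGT]+", canvas)[[1L]]
    lens <- attr(runs, "match.length")
    ok <- lens >= min_len
    if (any(ok)) {
      contigs <- c(contigs, substring(canvas, runs[ok], runs[ok] + lens[ok] - 1L))
    }
  }
  if (length(contigs)) names(contigs) <- paste0("contig_", seq_along(contigs))
  contigs
}

#' @rdname adapter_mock_taxonomy
#' @param min_hits minimum number of shared k-mers for a contig-reference
#'   hit (built-in contig search, a naive stand-in for a BLAST query of
#'   assembled contigs against the reference database).
#' @export
adapter_kmer_contig_search <- function(k = 16L, min_hits = 10L) {
  list(type = "builtin", fn = function(contigs, refs_db_dir) {
    kmer_contig_search(contigs, refs_db_dir, k, min_hits)
  })
}

kmer_contig_search <- function(contigs, refs_db_dir, k = 16L, min_hits = 10L) {
  empty <- data.frame(contig = character(), taxid = integer(), stringsAsFactors = FALSE)
  if (length(contigs) == 0L) {
    return(empty)
  }
  files <- list.files(refs_db_dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(files) == 0L) {
    return(empty)
  }
  cidx <- build_kmer_index(contigs, k)
  data.table::setkey(cidx, kmer)
  hits <- lapply(files, function(fp) {
    genome <- read_seqs(fp)
    taxid <- as.integer(sub("\\.fasta$", "", basename(fp)))
    gk <- build_kmer_index(stats::setNames(genome$seq[1L], genome$id[1L]), k)
    m <- cidx[unique(gk$kmer), on = "kmer", nomatch = NULL]
    if (nrow(m) == 0L) {
      return(NULL)
    }
    cnt <- m[, list(hits = .N), by = ref]
    cnt <- cnt[hits >= min_hits]
    if (nrow(cnt) == 0L) {
      return(NULL)
    }
    data.frame(contig = cnt$ref, taxid = taxid, hits = cnt$hits, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits) || nrow(hits) == 0L) {
    return(empty)
  }
  # one best reference per contig
  hits <- hits[order(hits$contig, -hits$hits, hits$taxid), , drop = FALSE]
  hits <- hits[!duplicated(hits$contig), c("contig", "taxid")]
  rownames(hits) <- NULL
  hits
}
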