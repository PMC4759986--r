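#' Pipeline configuration
#'
#' Bundles every tunable of a compression run: the integer codec and its
#' divisor, the reference-selection policy, the number of
#' reference-discovery rounds (at most 2: align, then assemble the
#' leftovers, search the contigs for new references, realign), the lossy
#' ID-dropping switch, the stage adapters, and the execution mode for
#' independent stages.
#'
#' @param codec `"huffman"` (best archival ratio), `"golomb"`, or
#'   `"extended_golomb"`.
#' @param m Golomb-family divisor (default 3).
#' @param policy a [selection_policy()] (default: top 75 species).
#' @param rounds 1 or 2 reference-discovery rounds.
#' @param skip_assembly skip the assembly/search/realign round even when
#'   `rounds = 2`.
#' @param drop_ids lossy mode: do not store read-ID suffixes.
#' @param adapters list with `taxonomy`, `aligner`, `assembler`,
#'   `contig_search` entries (see [adapter_mock_taxonomy()] and
#'   friends). `taxonomy` may be `NULL` when a report is passed to
#'   [run_compress()] directly.
#' @param exec `"serial"` or `"parallel"` execution of independent
#'   stages; both produce byte-identical archives.
#' @param cores worker count for `exec = "parallel"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(codec = c("huffman", "golomb", "extended_golomb"),
                            m = 3L, policy = selection_policy(),
                            rounds = 2L, skip_assembly = FALSE,
                            drop_ids = FALSE,
                            adapters = list(), exec = c("serial", "parallel"),
                            cores = 2L) {
  codec <- match.arg(codec)
  exec <- match.arg(exec)
  if (!rounds %in% 1:2) stop("rounds must be 1 or 2")
  defaults <- list(
    taxonomy = NULL,
    aligner = adapter_builtin_aligner(),
    assembler = NULL,
    contig_search = adapter_kmer_contig_search()
  )
  adapters <- utils::modifyList(defaults, adapters)
  structure(
    list(
      cfg = codec_config(codec, m), policy = policy, rounds = as.integer(rounds),
      skip_assembly = isTRUE(skip_assembly), drop_ids = isTRUE(drop_ids),
      adapters = adapters, exec = exec, cores = as.integer(cores)
    ),
    class = "pipeline_config"
  )
}

load_refs <- function(refs_dir, taxids) {
  out <- character()
  tax_of <- integer()
  for (t in taxids) {
    fp <- file.path(refs_dir, paste0(t, ".fasta"))
    if (!file.exists(fp)) {
      warning("no reference genome for taxid ", t, " in ", refs_dir)
      next
    }
    g <- read_seqs(fp)
    s <- stats::setNames(g$seq, g$id)
    out <- c(out, s)
    tax_of <- c(tax_of, stats::setNames(rep(as.integer(t), length(s)), names(s)))
  }
  attr(out, "taxid") <- tax_of
  out
}

combine_aligned <- function(a, b) {
  if (nrow(b$reads) == 0L) {
    return(a)
  }
  if (nrow(a$reads) == 0L) {
    return(b)
  }
  vb <- b$variations
  if (nrow(vb)) vb$read <- vb$read + nrow(a$reads)
  aligned_reads(rbind(a$reads, b$reads), rbind(a$variations, vb))
}

#' Compress a metagenomic read set
#'
#' The full flow: pre-process (quality stripping, mate labeling),
#' taxonomy-driven reference selection, alignment, differential encoding
#' of aligned reads per reference, an optional second discovery round
#' (assemble unaligned reads, search contigs against the reference
#' database, realign), reference-free fallback coding of the residue,
#' and packing into a single self-describing archive.
#'
#' @param reads1 FASTA/FASTQ file of reads (first mates for paired
#'   data).
#' @param reads2 optional second-mate file.
#' @param refs_dir reference database directory (`<taxid>.fasta` files).
#' @param report taxonomy report (path or lines); if `NULL`, the
#'   `taxonomy` adapter in `config` is invoked.
#' @param out output archive path.
#' @param config a [pipeline_config()].
#' @return A list with `archive`, `stats` (per-round data.frame) and
#'   `manifest`, invisibly.
#' @export
run_compress <- function(reads1, reads2 = NULL, refs_dir, report = NULL,
                         out, config = pipeline_config()) {
  paired <- !is.null(reads2)
  tmp <- tempfile(fileext = ".fasta")
  if (paired) {
    tmp2 <- tempfile(fileext = ".fasta")
    strip_quality(reads1, tmp)
    strip_quality(reads2, tmp2)
    labeled <- label_mates(tmp, tmp2)
  } else {
    strip_quality(reads1, tmp)
    r <- read_seqs(tmp)
    labeled <- data.frame(
      id = r$id, base_id = r$id, mate = 0L, seq = r$seq,
      stringsAsFactors = FALSE
    )
  }
  n_total <- nrow(labeled)

  if (is.null(report)) {
    if (is.null(config$adapters$taxonomy)) stop("no taxonomy report and no taxonomy adapter")
    report <- config$adapters$taxonomy$fn(reads1)
  }
  entries <- parse_report(report)
  sel <- select_references(entries, config$policy)
  refs <- load_refs(refs_dir, sel)

  stats_rows <- list()
  if (length(refs) && n_total > 0L) {
    sam1 <- config$adapters$aligner$fn(labeled[, c("id", "seq")], refs)
    parsed <- parse_sam(sam1, refs)
    aligned <- parsed$aligned
    unaligned <- parsed$unaligned
  } else {
    aligned <- empty_aligned()
    unaligned <- data.frame(
      id = labeled$base_id, mate = labeled$mate, seq = labeled$seq,
      stringsAsFactors = FALSE
    )
  }
  stats_rows[[1L]] <- data.frame(
    round = 1L, aligned = nrow(aligned$reads), unaligned = nrow(unaligned),
    references = length(refs),
    alignment_rate = if (n_total) 100 * nrow(aligned$reads) / n_total else 0
  )

  used_taxids <- attr(refs, "taxid")
  if (config$rounds >= 2L && !config$skip_assembly && nrow(unaligned) > 0L &&
    !is.null(config$adapters$assembler)) {
    round2 <- tryCatch(
      discovery_round(unaligned, refs_dir, used_taxids, config),
      error = function(e) {
        message("assembly round failed (", conditionMessage(e), "); skipping it")
        NULL
      }
    )
    if (!is.null(round2)) {
      aligned <- combine_aligned(aligned, round2$aligned)
      unaligned <- round2$unaligned
      used_taxids <- c(used_taxids, round2$new_taxids)
      ref_tax <- c(attr(refs, "taxid"), attr(round2$new_refs, "taxid"))
      refs <- c(refs, round2$new_refs)
      attr(refs, "taxid") <- ref_tax
      stats_rows[[2L]] <- data.frame(
        round = 2L, aligned = nrow(aligned$reads),
        unaligned = nrow(unaligned), references = length(used_taxids),
        alignment_rate = if (n_total) 100 * nrow(aligned$reads) / n_total else 0
      )
    }
  }

  # factor the shared read-ID stem once; suffixes become integer streams
  all_ids <- c(aligned$reads$id, unaligned$id)
  scheme <- list(prefix = "", kind = "opaque")
  sfx_aligned <- character(0)
  sfx_unaligned <- character(0)
  if (length(all_ids)) {
    f <- factor_ids(all_ids)
    scheme <- f$scheme
    sfx_aligned <- f$suffixes[seq_len(nrow(aligned$reads))]
    sfx_unaligned <- f$suffixes[nrow(aligned$reads) + seq_len(nrow(unaligned))]
  }
  aligned$reads$id_suffix <- sfx_aligned
  unaligned$id_suffix <- sfx_unaligned

  # independent encode tasks: one per reference block, plus the fallback
  ref_ids <- unique(aligned$reads$ref_id)
  tasks <- if (length(ref_ids)) {
    stats::setNames(
      lapply(ref_ids, function(rid) {
        function() {
          idx <- which(aligned$reads$ref_id == rid)
          vt <- aligned$variations[aligned$variations$read %in% idx, , drop = FALSE]
          vt$read <- match(vt$read, idx)
          encode_block(
            aligned_reads(aligned$reads[idx, , drop = FALSE], vt),
            config$cfg, config$drop_ids
          )
        }
      }),
      paste0("ref:", ref_ids)
    )
  } else {
    list()
  }
  tasks$fallback <- function() {
    fallback_encode(unaligned, config$cfg, config$drop_ids)
  }
  members <- run_stage_plan(
    parallel_schedule(stats::setNames(
      rep(list(character()), length(tasks)), names(tasks)
    )),
    tasks,
    parallel = config$exec == "parallel", cores = config$cores
  )

  stats <- do.call(rbind, stats_rows)
  block_taxid <- function(rid) {
    t <- attr(refs, "taxid")[rid]
    if (is.null(t) || is.na(t)) NA_integer_ else as.integer(t)
  }
  manifest <- list(
    tool = "metarc",
    codec = config$cfg$codec, m = config$cfg$m,
    paired = paired, drop_ids = config$drop_ids,
    id_prefix = scheme$prefix, id_kind = scheme$kind,
    n_reads = n_total, n_aligned = nrow(aligned$reads), n_unaligned = nrow(unaligned),
    references = lapply(ref_ids, function(rid) list(ref_id = rid, taxid = block_taxid(rid))),
    rounds = lapply(seq_len(nrow(stats)), function(i) as.list(stats[i, ]))
  )
  pack_archive(manifest, members, out)
  invisible(list(archive = out, stats = stats, manifest = manifest))
}

# discovery round: assemble unaligned reads, search the
# contigs against the reference database, realign to the new references
discovery_round <- function(unaligned, refs_dir, used_taxids, config) {
  contigs <- config$adapters$assembler$fn(unaligned)
  if (length(contigs) == 0L) stop("assembler produced no contigs")
  hits <- config$adapters$contig_search$fn(contigs, refs_dir)
  new_taxids <- setdiff(unique(hits$taxid), used_taxids)
  if (length(new_taxids) == 0L) stop("contig search found no new references")
  new_refs <- load_refs(refs_dir, new_taxids)
  if (length(new_refs) == 0L) stop("no genomes available for the discovered taxids")
  relabel <- paste0(unaligned$id, ifelse(unaligned$mate > 0L, paste0("_", unaligned$mate), ""))
  sam <- config$adapters$aligner$fn(
    data.frame(id = relabel, seq = unaligned$seq, stringsAsFactors = FALSE),
    new_refs
  )
  parsed <- parse_sam(sam, new_refs)
  list(
    aligned = parsed$aligned, unaligned = parsed$unaligned,
    new_taxids = attr(new_refs, "taxid"), new_refs = new_refs
  )
}

#' Decompress an archive back to read files
#'
#' Decodes each reference member (reconstructing reads from the
#' reference FASTA named in the manifest), decodes the fallback blob,
#' merges, sorts by read ID and splits mates.
#'
#' @param archive archive path.
#' @param refs_dir reference database directory.
#' @param out_prefix output stem for the FASTA file(s).
#' @return Character vector of written file paths.
#' @export
run_decompress <- function(archive, refs_dir, out_prefix) {
  ar <- unpack_archive(archive)
  man <- ar$manifest
  scheme <- list(prefix = man$id_prefix, kind = man$id_kind)

  ref_members <- grep("^ref:", names(ar$members), value = TRUE)
  aligned <- empty_aligned()
  for (nm in ref_members) aligned <- combine_aligned(aligned, decode_block(ar$members[[nm]]))

  if (nrow(aligned$reads)) {
    taxid_of <- stats::setNames(
      vapply(man$references, function(r) as.integer(r$taxid), integer(1)),
      vapply(man$references, function(r) r$ref_id, character(1))
    )
    need <- unique(aligned$reads$ref_id)
    refs <- load_refs(refs_dir, taxid_of[need])
    missing <- setdiff(need, names(refs))
    if (length(missing)) {
      stop("reference '", missing[1L], "' is required for decompression but was not found")
    }
    seqs <- reconstruct_all(aligned, refs)
    aligned_out <- data.frame(
      id = aligned$reads$id_suffix, mate = aligned$reads$mate, seq = seqs,
      stringsAsFactors = FALSE
    )
  } else {
    aligned_out <- empty_unaligned()
  }
  fb <- fallback_decode(ar$members$fallback)
  fallback_out <- data.frame(
    id = fb$id_suffix, mate = fb$mate, seq = fb$seq,
    stringsAsFactors = FALSE
  )

  if (isTRUE(man$drop_ids)) {
    # lossy mode: suffixes were not stored; mint sequential IDs (pairing
    # by within-mate order)
    all_out <- rbind(aligned_out, fallback_out)
    all_out$id <- if (nrow(all_out)) {
      paste0(
        man$id_prefix,
        stats::ave(seq_len(nrow(all_out)), all_out$mate, FUN = seq_along)
      )
    } else {
      character()
    }
    aligned_out <- all_out
    fallback_out <- empty_unaligned()
  } else {
    aligned_out$id <- restore_ids(scheme, aligned_out$id)
    fallback_out$id <- restore_ids(scheme, fallback_out$id)
  }
  merge_sort_split(aligned_out, fallback_out, isTRUE(man$paired), out_prefix)
}

#' Reference-free fallback codec
#'
#' Residual unaligned reads are stored without a reference: sequences are
#' 2-bit packed (A/C/G/T), `N` positions travel in an escape list of
#' global-coordinate deltas, and read lengths, mate flags and ID
#' suffixes are integer streams under the run's codec. Exact round trip;
#' any non-IUPAC character is an error.
#'
#' @param unaligned data.frame with `id_suffix`, `mate`, `seq`.
#' @param cfg a [codec_config()].
#' @param drop_ids lossy mode: omit the ID suffix stream.
#' @return A raw vector (the fallback archive member).
#' @export
fallback_encode <- function(unaligned, cfg = codec_config(), drop_ids = FALSE) {
  n <- nrow(unaligned)
  seqs <- if (n) unaligned$seq else character()
  if (n && any(grepl("[^ACGTN]", seqs))) {
    stop("fallback codec accepts only A/C/G/T/N sequences")
  }
  concat <- paste(seqs, collapse = "")
  npos <- if (nzchar(concat)) {
    hits <- gregexpr("N", concat, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer() else as.integer(hits)
  } else {
    integer()
  }
  packed <- cpp_pack_dna(chartr("N", "A", concat))

  enc <- function(v) serialize_stream(encode_integers(v, cfg$codec, cfg$m))
  ids_kind <- 0L
  id_blob <- raw(0)
  id_stream <- NULL
  if (!drop_ids && n > 0L) {
    numeric <- all(grepl("^[0-9]+$", unaligned$id_suffix)) &&
      all(unaligned$id_suffix == as.character(as.integer(unaligned$id_suffix)))
    if (numeric) {
      ids_kind <- 1L
      sfx <- as.integer(unaligned$id_suffix)
      id_stream <- enc(zigzag_encode(c(sfx[1L], diff(sfx))))
    } else {
      ids_kind <- 2L
      id_blob <- charToRaw(paste0(paste(unaligned$id_suffix, collapse = "\n"), "\n"))
    }
  }

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(n, con, size = 4L, endian = "little")
  writeBin(nchar(concat), con, size = 4L, endian = "little")
  writeBin(as.raw(ids_kind), con)
  writeBin(length(id_blob), con, size = 4L, endian = "little")
  writeBin(id_blob, con)
  if (n > 0L) {
    writeBin(enc(nchar(seqs)), con)
    writeBin(enc(unaligned$mate), con)
    writeBin(enc(c(npos[1L], diff(npos))[seq_along(npos)]), con)
    if (!is.null(id_stream)) writeBin(id_stream, con)
  }
  writeBin(packed, con)
  rawConnectionValue(con)
}

#' @rdname fallback_encode
#' @param blob raw member produced by `fallback_encode`.
#' @return For the decoder, the data.frame (`id_suffix` is `NA` under
#'   `drop_ids`).
#' @export
fallback_decode <- function(blob) {
  if (is.null(blob)) {
    return(cbind(empty_unaligned(), id_suffix = character())[, c("id_suffix", "mate", "seq")])
  }
  n <- readBin(blob[1:4], "integer", 1L, size = 4L, endian = "little")
  total_len <- readBin(blob[5:8], "integer", 1L, size = 4L, endian = "little")
  ids_kind <- as.integer(blob[9L])
  blob_len <- readBin(blob[10:13], "integer", 1L, size = 4L, endian = "little")
  pos <- 14L
  id_blob <- if (blob_len > 0L) blob[pos:(pos + blob_len - 1L)] else raw(0)
  pos <- pos + blob_len
  if (n == 0L) {
    out <- data.frame(
      id_suffix = character(), mate = integer(), seq = character(),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  rd <- function() {
    r <- read_stream(blob, pos)
    pos <<- r$pos
    decode_integers(r$stream)
  }
  lens <- rd()
  mate <- rd()
  ndeltas <- rd()
  id_suffix <- if (ids_kind == 1L) {
    as.character(cumsum(zigzag_decode(rd())))
  } else if (ids_kind == 2L) {
    strsplit(rawToChar(id_blob), "\n", fixed = TRUE)[[1L]]
  } else {
    rep(NA_character_, n)
  }
  packed <- blob[pos:length(blob)]
  concat <- cpp_unpack_dna(packed, total_len)
  if (length(ndeltas)) {
    npos <- cumsum(ndeltas)
    for (p in npos) substr(concat, p, p) <- "N"
  }
  ends <- cumsum(lens)
  seqs <- substring(concat, ends - lens + 1L, ends)
  data.frame(id_suffix = id_suffix, mate = mate, seq = seqs, stringsAsFactors = FALSE)
}

#' Schedule independent stages
#'
#' Given a stage dependency graph (named list: stage -> character vector
#' of prerequisite stages), returns the execution plan as dependency
#' levels: stages within a level have no data dependencies and may run
#' concurrently. Cycles are an error. Running the plan in parallel or
#' serially yields byte-identical results because stage outputs are
#' collected by name.
#'
#' @param stages named list mapping each stage to its dependencies.
#' @return A list of character vectors (the levels, in order).
#' @export
parallel_schedule <- function(stages) {
  if (length(stages) == 0L) {
    return(list())
  }
  if (is.null(names(stages)) || any(!nzchar(names(stages)))) stop("stages must be named")
  unknown <- setdiff(unlist(stages), names(stages))
  if (length(unknown)) stop("unknown dependency: ", unknown[1L])
  remaining <- stages
  levels <- list()
  done <- character()
  while (length(remaining)) {
    ready <- names(remaining)[vapply(remaining, function(d) all(d %in% done), logical(1))]
    if (length(ready) == 0L) stop("cycle in stage dependency graph")
    levels[[length(levels) + 1L]] <- ready
    done <- c(done, ready)
    remaining <- remaining[setdiff(names(remaining), ready)]
  }
  levels
}

#' @rdname parallel_schedule
#' @param plan a level list from `parallel_schedule`.
#' @param tasks named list of zero-argument functions, one per stage.
#' @param parallel run each level's stages via forked workers?
#' @param cores worker count.
#' @return Named list of stage results (insertion order = `tasks`
#'   order).
#' @export
run_stage_plan <- function(plan, tasks, parallel = FALSE, cores = 2L) {
  results <- list()
  for (level in plan) {
    out <- if (parallel && length(level) > 1L) {
      parallel::mclapply(tasks[level], function(f) f(), mc.cores = cores)
    } else {
      lapply(tasks[level], function(f) f())
    }
    results[level] <- out
  }
  results[names(tasks)]
}

#' Summarize an archive without extracting it
#'
#' Reads only the manifest: codec, read counts, alignment rates per
#' round, and the reference list — the compressed-domain selection use
#' case (scan many archives for a taxon without decompressing).
#'
#' @param archive archive path.
#' @return The manifest, invisibly; prints a summary.
#' @export
archive_stats <- function(archive) {
  man <- read_manifest(archive)
  cat("metarc archive:", archive, "\n")
  cat(
    "  codec:", man$codec, "(m =", man$m, ")",
    if (isTRUE(man$drop_ids)) " [ids dropped]" else "", "\n"
  )
  cat(
    "  reads:", man$n_reads, "(", man$n_aligned, "aligned,",
    man$n_unaligned, "fallback )\n"
  )
  for (r in man$rounds) {
    cat(sprintf(
      "  round %d: %.1f%% aligned, %d references\n",
      r$round, r$alignment_rate, r$references
    ))
  }
  refs <- vapply(man$references, function(r) {
    paste0(r$ref_id, " (taxid ", r$taxid, ")")
  }, character(1))
  if (length(refs)) cat("  references:", paste(refs, collapse = ", "), "\n")
  invisible(man)
}
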