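#' Parse a Kraken-style taxonomy report
#'
#' The report dialect is tab-separated with columns: percentage of reads
#' in the clade, clade read count, directly-assigned read count, rank
#' code (`U`/`R`/`D`/.../`S`), NCBI taxid, and an indented scientific
#' name. Species-rank entries are flagged; abundance for reference
#' selection is the clade read count at species rank.
#'
#' @param report path to a report file, or a character vector of lines.
#' @return A data.frame with columns `percent`, `clade_reads`,
#'   `direct_reads`, `rank`, `taxid`, `name`, `is_species`.
#' @export
parse_report <- function(report) {
  lines <- if (length(report) == 1L && !grepl("\t|\n", report) && file.exists(report)) {
    readLines(report)
  } else {
    as.character(report)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(
      percent = numeric(), clade_reads = integer(), direct_reads = integer(),
      rank = character(), taxid = integer(), name = character(),
      is_species = logical(), stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stop("malformed taxonomy report line ", which(nf != 6L)[1L], ": expected 6 tab-separated fields")
  }
  pick <- function(i) vapply(fields, `[[`, character(1), i)
  percent <- suppressWarnings(as.numeric(pick(1L)))
  clade <- suppressWarnings(as.integer(pick(2L)))
  direct <- suppressWarnings(as.integer(pick(3L)))
  taxid <- suppressWarnings(as.integer(pick(5L)))
  bad <- which(is.na(percent) | is.na(clade) | is.na(direct) | is.na(taxid))
  if (length(bad)) stop("malformed taxonomy report line ", bad[1L], ": non-numeric count field")
  if (any(clade < 0L | direct < 0L)) {
    stop(
      "malformed taxonomy report line ",
      which(clade < 0L | direct < 0L)[1L], ": negative count"
    )
  }
  rank <- pick(4L)
  data.frame(
    percent = percent, clade_reads = clade, direct_reads = direct,
    rank = rank, taxid = taxid, name = sub("^ +", "", pick(6L)),
    is_species = rank == "S", stringsAsFactors = FALSE
  )
}

#' Reference selection policy
#'
#' Two threshold semantics are supported: `top_n` keeps the `T` most
#' abundant species (the default, `T = 75`), `min_abundance` keeps every
#' species with at least `T` assigned reads.
#'
#' @param mode `"top_n"` or `"min_abundance"`.
#' @param T non-negative threshold.
#' @return A list of class `selection_policy`.
#' @export
selection_policy <- function(mode = c("top_n", "min_abundance"), T = 75L) {
  mode <- match.arg(mode)
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0) stop("threshold T must be >= 0")
  structure(list(mode = mode, T = T), class = "selection_policy")
}

#' Select reference genomes by abundance
#'
#' Species-rank entries are ranked from most to least abundant (clade
#' read count, ties broken by ascending taxid for determinism) and
#' thresholded per the policy.
#'
#' @param entries parsed report, from [parse_report()].
#' @param policy a [selection_policy()].
#' @return Integer vector of taxids, most abundant first.
#' @export
select_references <- function(entries, policy = selection_policy()) {
  sp <- entries[entries$is_species, , drop = FALSE]
  if (nrow(sp) == 0L) {
    return(integer())
  }
  sp <- sp[order(-sp$clade_reads, sp$taxid), , drop = FALSE]
  if (policy$mode == "top_n") {
    sp <- utils::head(sp, policy$T)
  } else {
    sp <- sp[sp$clade_reads >= policy$T, , drop = FALSE]
  }
  sp$taxid
}
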