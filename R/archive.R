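ARCHIVE_MAGIC <- "METARC1\n"
ARCHIVE_VERSION <- 1L

# Adler-32, chunked so the running sums stay inside double precision.
adler32 <- function(bytes) {
  MOD <- 65521
  a <- 1
  b <- 0
  n <- length(bytes)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + 999999L)
    x <- as.integer(bytes[i:j])
    L <- length(x)
    b <- (b + L * a + sum(x * (L - seq_len(L) + 1))) %% MOD
    a <- (a + sum(x)) %% MOD
    i <- j + 1L
  }
  b * 65536 + a
}

#' Pack an archive
#'
#' The archive is a single file: an 8-byte magic, a length-prefixed JSON
#' manifest, then the raw members back to back. The manifest carries the
#' format version, the codec parameters, the read-ID prefix, read counts,
#' the optional reference list, and a member index (name, size, Adler-32
#' checksum) — so the manifest, including the reference list, is readable
#' without extracting any member.
#'
#' @param manifest a list of metadata; `format_version` and the member
#'   index are filled in here.
#' @param members named list of raw vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
pack_archive <- function(manifest, members, path) {
  stopifnot(is.list(members))
  if (length(members) && is.null(names(members))) stop("members must be named")
  manifest$format_version <- ARCHIVE_VERSION
  manifest$member_index <- lapply(names(members), function(nm) {
    list(name = nm, size = length(members[[nm]]), adler32 = adler32(members[[nm]]))
  })
  json <- charToRaw(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(ARCHIVE_MAGIC), con)
  writeBin(length(json), con, size = 4L, endian = "little")
  writeBin(json, con)
  for (m in members) writeBin(m, con)
  invisible(path)
}

#' @rdname pack_archive
#' @export
read_manifest <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(ARCHIVE_MAGIC)))
  if (!identical(magic, ARCHIVE_MAGIC)) stop("not a metarc archive: bad magic")
  len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  manifest <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", len)), simplifyVector = FALSE)
  if (!identical(as.integer(manifest$format_version), ARCHIVE_VERSION)) {
    stop("unsupported archive format version: ", manifest$format_version)
  }
  manifest
}

#' @rdname pack_archive
#' @return For `unpack_archive`, a list with `manifest` and `members`
#'   (named list of raw vectors); member checksums are verified.
#' @export
unpack_archive <- function(path) {
  manifest <- read_manifest(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", nchar(ARCHIVE_MAGIC))
  len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "raw", len)
  members <- list()
  for (entry in manifest$member_index) {
    payload <- readBin(con, "raw", entry$size)
    if (length(payload) != entry$size) stop("truncated archive: member ", entry$name)
    if (adler32(payload) != entry$adler32) {
      stop("checksum failure in archive member ", entry$name)
    }
    members[[entry$name]] <- payload
  }
  list(manifest = manifest, members = members)
}
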