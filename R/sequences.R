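#' DNA sequence records with optional base masks
#'
#' A `sequence_record` carries a DNA string over A/C/G/T/N plus an optional
#' set of masked positions.  Masked or N positions never enter affinity
#' calculations: any scoring window covering one is skipped.  Masks are used
#' to exclude closed-chromatin positions and to separate concatenated
#' intervals so no window spans a junction.
#'
#' @param id record identifier.
#' @param bases DNA string (A/C/G/T/N, case-insensitive).
#' @param mask integer vector of 1-based masked positions (optional).
#' @return An object of class `sequence_record`: list with `id`, `bases`
#'   (upper case), `mask` (sorted integer vector).
#' @export
sequence_record <- function(id, bases, mask = integer()) {
  bases <- toupper(as.character(bases))
  if (nchar(bases) < 1L) stopf("sequence '%s' is empty", id)
  if (grepl("[^ACGTN]", bases))
    stopf("sequence '%s' contains characters outside A/C/G/T/N", id)
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1L || max(mask) > nchar(bases)))
    stopf("sequence '%s': mask positions out of bounds", id)
  structure(list(id = as.character(id), bases = bases, mask = mask),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  n <- nchar(x$bases)
  shown <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<sequence_record '%s'> %d bp, %d masked\n%s\n",
              x$id, n, length(x$mask), shown))
  invisible(x)
}

#' @export
#' @rdname sequence_record
is.sequence_record <- function(x) inherits(x, "sequence_record")

#' Read a (multi-)FASTA file into sequence records
#'
#' @param path FASTA file.
#' @return Named list of [sequence_record()] objects (names = record ids,
#'   first whitespace-delimited token of each header).
#' @export
read_fasta_records <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stopf("%s: no FASTA records", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  recs <- mapply(sequence_record, ids, as.character(set), SIMPLIFY = FALSE)
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' Masked positions are written as `N` so the mask survives the round trip.
#'
#' @param records list of [sequence_record()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_records <- function(records, path) {
  seqs <- vapply(records, function(r) {
    b <- strsplit(r$bases, "", fixed = TRUE)[[1]]
    if (length(r$mask)) b[r$mask] <- "N"
    paste(b, collapse = "")
  }, "")
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# positions (1-based) usable for scoring: neither masked nor N
usable_positions <- function(record) {
  code <- encode_dna(record$bases)
  ok <- !is.na(code)
  if (length(record$mask)) ok[record$mask] <- FALSE
  ok
}
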