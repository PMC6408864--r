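# Sequence collections.
#
# Sequences are stored as integer vectors of byte values.  The end-marker is
# NOT stored; it is implicit, one per string, written as '$' (0x24) on disk
# and ranked below every other symbol in memory, with co-located end-markers
# ordered by global string id.

#' Reserved end-marker byte (`$`, 0x24)
#'
#' Sequences may contain any byte except this one.  In lexicographic
#' comparisons the end-marker ranks below every other symbol; end-markers of
#' different strings are ranked among themselves by string id.
#' @export
SENTINEL <- 36L

str_to_ints <- function(s) {
  if (nchar(s) == 0L) return(integer(0))
  utf8ToInt(s)
}

ints_to_str <- function(v) intToUtf8(v)

#' Create a sequence collection
#'
#' A `seq_collection` holds an ordered list of non-empty strings over a byte
#' alphabet.  Each string carries an implicit end-marker; the total length
#' `n` counts one end-marker per string.
#'
#' @param x character vector, or list of integer vectors of byte values.
#' @param names optional sequence names.
#' @return An object of class `seq_collection` with fields `sequences`
#'   (list of integer vectors), `alphabet` (sorted distinct symbol bytes,
#'   end-marker excluded), `m` (number of strings) and `n` (total length
#'   including one end-marker per string).
#' @examples
#' coll <- seq_collection(c("abcab", "aabcabc"))
#' coll$m  # 2
#' coll$n  # 14
#' @export
seq_collection <- function(x, names = NULL) {
  seqs <- if (is.character(x)) lapply(x, str_to_ints) else lapply(x, as.integer)
  if (length(seqs) < 1L) stop("a collection must contain at least one sequence")
  lens <- vapply(seqs, length, integer(1))
  if (any(lens == 0L)) stop("every sequence must be non-empty")
  if (any(vapply(seqs, function(s) any(s == SENTINEL), logical(1))))
    stop("sequences must not contain the reserved end-marker byte '$' (0x24)")
  obj <- list(
    sequences = seqs,
    alphabet  = sort(unique(unlist(seqs, use.names = FALSE))),
    m         = length(seqs),
    n         = sum(lens + 1L),
    names     = names
  )
  class(obj) <- "seq_collection"
  obj
}

#' @export
print.seq_collection <- function(x, ...) {
  cat(sprintf("seq_collection: %d sequence(s), total length n = %d (incl. end-markers)\n",
              x$m, x$n))
  cat(sprintf("  alphabet (%d): %s\n", length(x$alphabet),
              paste(vapply(x$alphabet, ints_to_str, character(1)), collapse = " ")))
  show <- utils::head(seq_len(x$m), 6L)
  for (i in show) {
    s <- x$sequences[[i]]
    lab <- if (!is.null(x$names)) x$names[i] else sprintf("seq %d", i - 1L)
    str <- if (length(s) > 60L) paste0(ints_to_str(s[1:60]), "...") else ints_to_str(s)
    cat(sprintf("  [%s] (%d) %s\n", lab, length(s), str))
  }
  if (x$m > 6L) cat(sprintf("  ... and %d more\n", x$m - 6L))
  invisible(x)
}

#' Content lengths of the sequences (end-markers excluded)
#' @param coll a `seq_collection`.
#' @return integer vector of per-sequence lengths.
#' @export
seq_lengths <- function(coll) vapply(coll$sequences, length, integer(1))

#' Read a sequence collection from FASTA or FASTQ
#'
#' Records are kept in file order; bytes are mapped to upper case; FASTQ
#' quality strings are discarded.  `'N'` is treated as an ordinary symbol.
#'
#' @param path path to a FASTA or FASTQ file.
#' @param format `"auto"` (sniff first byte: `>` FASTA, `@` FASTQ),
#'   `"fasta"` or `"fastq"`.
#' @return a [seq_collection()].
#' @export
read_collection <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readChar(path, 1L, useBytes = TRUE)
    if (length(first) == 0L || !nzchar(first)) stop("empty file: ", path)
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     stop("cannot sniff format of ", path,
                          " (first byte not '>' or '@')"))
  }
  set <- Biostrings::readBStringSet(path, format = format)
  if (length(set) == 0L) stop("no records in ", path)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("empty record in ", path)
  if (any(grepl("$", seqs, fixed = TRUE)))
    stop("record contains the reserved end-marker byte '$': ", path)
  seq_collection(unname(seqs), names = names(set))
}

#' Write a collection as FASTA
#'
#' Used to dump generated fixtures so any failing case can be replayed from
#' the command line.
#' @param coll a `seq_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collection <- function(coll, path) {
  nm <- if (!is.null(coll$names)) coll$names else sprintf("seq%d", seq_len(coll$m) - 1L)
  lines <- character(2L * coll$m)
  lines[c(TRUE, FALSE)] <- paste0(">", nm)
  lines[c(FALSE, TRUE)] <- vapply(coll$sequences, ints_to_str, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Restrict a collection to strings first..last (1-based), keeping names.
subset_collection <- function(coll, first, last) {
  seq_collection(coll$sequences[first:last],
                 names = if (!is.null(coll$names)) coll$names[first:last] else NULL)
}
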