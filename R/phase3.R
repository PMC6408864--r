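# Phase 3: merge the per-value LCP pair files into the final LCP array and
# special-suffix bit array by hierarchical multiway merging on position.

# First-level inputs are pair files (value implied by the file name);
# intermediate round files carry an explicit 4-byte value per record.
write_triplet_file <- function(path, pos, value, bit) {
  con <- file(path, "wb")
  write_uints(con, pos %% 2^32, 4L)
  write_uints(con, pos %/% 2^32 + as.double(bit) * 2^31, 4L)
  write_uints(con, value, 4L)
  close(con)
  path
}

read_triplet_file <- function(path) {
  sz <- file.size(path)
  nrec <- sz / 12
  con <- file(path, "rb")
  on.exit(close(con))
  lo <- read_uints(con, nrec, 4L)
  hi <- read_uints(con, nrec, 4L)
  value <- read_uints(con, nrec, 4L)
  bit <- hi >= 2^31
  list(pos = lo + (hi - as.double(bit) * 2^31) * 2^32,
       value = as.integer(value), bit = bit)
}

# Merge one group of sorted record streams into one sorted stream.
merge_group <- function(recs) {
  pos <- unlist(lapply(recs, `[[`, "pos"), use.names = FALSE)
  value <- unlist(lapply(recs, `[[`, "value"), use.names = FALSE)
  bit <- unlist(lapply(recs, `[[`, "bit"), use.names = FALSE)
  for (r in recs) if (is.unsorted(r$pos, strictly = TRUE))
    stop("pair file not sorted by position")
  ord <- order(pos, method = "radix")
  pos <- pos[ord]
  if (anyDuplicated(pos)) stop("duplicate position across pair files: ",
                               pos[which(duplicated(pos))[1L]])
  list(pos = pos, value = value[ord], bit = bit[ord])
}

#' Multiway-merge LCP pair files into the LCP and xlcp arrays
#'
#' The pair files (one per LCP value, each sorted by position) are merged
#' hierarchically with fan-in `lambda`: each round merges groups of up to
#' `lambda` sorted files into one, so `ceiling(log(#files, lambda))` rounds
#' suffice.  Positions must cover `{2..n}` exactly once (for a truncated
#' early-stop merge, set `complete = FALSE` and missing rows get
#' `fill_value`).  Row 1's LCP is 0 by convention; the special bit of row
#' `r - 1` rides with row `r`'s record, and row n's bit is set directly
#' from the definition (a row is special iff its suffix, end-marker aside,
#' prefixes the next one; row n has no next row and its suffix is never a
#' bare end-marker for non-empty strings).
#'
#' @param pair_files named character vector or list: names are LCP values
#'   (as written by the merge), elements are file paths.  Value gaps
#'   (missing files) are fine.
#' @param n total number of rows.
#' @param lambda merge fan-in (default 256).
#' @param tmp_dir directory for intermediate round files.
#' @param complete require exact coverage of rows 2..n.
#' @param fill_value LCP value for rows without a record (only with
#'   `complete = FALSE`).
#' @return list with `lcp` (integer), `xlcp` (logical) and `rounds`.
#' @export
multiway_merge_pairs <- function(pair_files, n, lambda = 256L,
                                 tmp_dir = tempfile("lcpmerge-"),
                                 complete = TRUE, fill_value = NA_integer_) {
  stopifnot(lambda >= 2L)
  vals <- as.integer(names(pair_files))
  if (anyNA(vals)) stop("pair_files must be named by their LCP value")
  recs <- lapply(seq_along(pair_files), function(q) {
    d <- pair_read(pair_files[[q]])
    list(pos = d$pos, value = rep.int(vals[q], nrow(d)), bit = d$bit)
  })
  rounds <- 0L
  level <- 0L
  dir.create(tmp_dir, recursive = TRUE, showWarnings = FALSE)
  while (length(recs) > 1L) {
    rounds <- rounds + 1L
    groups <- split(recs, (seq_along(recs) - 1L) %/% lambda)
    recs <- lapply(seq_along(groups), function(g) {
      merged <- merge_group(groups[[g]])
      # round-trip through the intermediate triplet format
      p <- file.path(tmp_dir, sprintf("round%d.%d.trip", level, g))
      write_triplet_file(p, merged$pos, merged$value, merged$bit)
      read_triplet_file(p)
    })
    level <- level + 1L
  }
  final <- if (length(recs) == 1L) merge_group(recs) else
    list(pos = double(0), value = integer(0), bit = logical(0))
  if (rounds == 0L && length(recs) == 1L) rounds <- 1L  # single file: one pass
  lcp <- rep.int(if (complete) 0L else as.integer(fill_value), n)
  lcp[1L] <- 0L
  xlcp <- logical(n)
  if (complete) {
    if (n > 1L && !identical(final$pos, as.double(2:n)))
      stop("pair files do not cover rows 2..n exactly")
  } else if (any(final$pos < 2 | final$pos > n))
    stop("pair position out of range")
  pos <- as.integer(final$pos)
  lcp[pos] <- final$value
  xlcp[pos - 1L] <- final$bit
  xlcp[n] <- FALSE
  list(lcp = lcp, xlcp = xlcp, rounds = rounds)
}
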