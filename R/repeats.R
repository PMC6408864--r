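# Maximal repeat detection by a single left-to-right scan of (bwt, lcp).
#
# Type 1: occurs >= 2 times, every one-symbol extension occurs fewer times.
#   Detected as LCP intervals: a run of rows sharing a length-l prefix whose
#   interior LCP minimum equals l, flanked by smaller LCP values, with at
#   least two distinct symbols in the bwt window (left extensions).
# Type 2: occurs >= 2 times, every extension occurs at most once.
#   Detected as strict LCP plateaus whose bwt window has pairwise distinct
#   symbols.
# End-marker occurrences in the bwt are pairwise distinct symbols ($_t are
# formally distinct), so each one counts as a fresh character.

repeat_df <- function(rtype, len, lo, hi) {
  data.frame(rtype = rtype, length = len, occ = hi - lo + 1L,
             row_lo = lo, row_hi = hi, distinct_sequences = NA_integer_)
}

empty_repeats <- function() {
  data.frame(rtype = integer(), length = integer(), occ = integer(),
             row_lo = integer(), row_hi = integer(),
             distinct_sequences = integer())
}

# Symbol identity for distinctness tests: end-marker occurrences are all
# distinct (negative row code); other bytes compare as themselves.
bwt_symcode <- function(bwt) ifelse(bwt == SENTINEL, -seq_along(bwt), bwt)

#' Find Type 1 maximal repeats
#'
#' One scan of `bwt` and `lcp` with a stack of `(start, lcp-value)`
#' entries carrying character sets; an entry popped when the LCP drops
#' below its value spans exactly the rows prefixed by a right-maximal
#' repeat, which is emitted if its window holds at least two distinct
#' preceding characters (left-maximality).  A virtual `lcp[n+1] = -1`
#' flushes the stack.
#'
#' @param idx a `merged_index` (or any list with `bwt` and `lcp`).
#' @param min_len,min_occ report only repeats at least this long/frequent.
#' @return data.frame: `rtype` (1), `length`, `occ`, `row_lo`, `row_hi`,
#'   `distinct_sequences` (NA until [restrict_repeats_by_sequences()]).
#'   Attributes `pushes` and `pops` expose the stack work done.
#' @export
find_type1_repeats <- function(idx, min_len = 1L, min_occ = 2L) {
  bwt <- idx$bwt; lcp <- idx$lcp
  if (length(bwt) != length(lcp)) stop("bwt/lcp length mismatch")
  n <- length(bwt)
  sym <- bwt_symcode(bwt)
  # Stack entry q: start js[q], LCP value vs[q], and a constant-size char
  # summary of its window (one representative symbol s_sym, 0 = empty, plus
  # a flag s_two set once two distinct symbols were seen).  The summary of
  # an entry at its pop covers exactly bwt rows [js-1, i-1]: entries above
  # were popped first and merged downward, and a freshly pushed entry is
  # seeded with the symbol of the row preceding it.
  js <- integer(n + 2L); vs <- integer(n + 2L)
  s_sym <- integer(n + 2L); s_two <- logical(n + 2L)
  top <- 1L
  js[1L] <- 1L; vs[1L] <- -1L; s_sym[1L] <- sym[1L]  # base, never popped
  pushes <- 0L; pops <- 0L
  minlen <- max(1L, min_len)
  out <- list()
  for (i in 2:(n + 1L)) {
    cur <- if (i <= n) lcp[i] else -1L
    lastj <- 0L; lp_sym <- 0L; lp_two <- FALSE
    while (vs[top] > cur) {
      pj <- js[top]; pv <- vs[top]; psym <- s_sym[top]; ptwo <- s_two[top]
      top <- top - 1L; pops <- pops + 1L
      lastj <- pj; lp_sym <- psym; lp_two <- ptwo
      if (ptwo && pv >= minlen && i - pj + 1L >= min_occ)
        out[[length(out) + 1L]] <- repeat_df(1L, pv, pj - 1L, i - 1L)
      # merge the popped summary into the new top (pops cascade downward,
      # so the last popped entry accumulates every window above lastj-1)
      if (s_sym[top] == 0L) { s_sym[top] <- psym; s_two[top] <- ptwo }
      else if (ptwo || (psym != 0L && psym != s_sym[top])) s_two[top] <- TRUE
    }
    if (vs[top] < cur) {
      top <- top + 1L; pushes <- pushes + 1L
      vs[top] <- cur
      if (lastj > 0L) {  # replacement keeps the removed index and window
        js[top] <- lastj; s_sym[top] <- lp_sym; s_two[top] <- lp_two
      } else {           # fresh entry: window starts at the preceding row
        js[top] <- i; s_sym[top] <- sym[i - 1L]; s_two[top] <- FALSE
      }
    }
    if (i <= n) {  # row i's char joins the current top's window
      if (s_sym[top] == 0L) s_sym[top] <- sym[i]
      else if (sym[i] != s_sym[top]) s_two[top] <- TRUE
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_repeats()
  res <- res[order(res$row_lo, res$length), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "pushes") <- pushes; attr(res, "pops") <- pops
  res
}

#' Find Type 2 maximal repeats
#'
#' Scans for strict LCP plateaus `lcp[j] < lcp[j+1] = ... = lcp[i] >
#' lcp[i+1]` (boundary convention `lcp[1] = lcp[n+1] = -1`): rows `j..i`
#' are exactly the occurrences of a repeat whose right extensions are all
#' unique; it is emitted when the `bwt` window over those rows is pairwise
#' distinct (left extensions unique too).
#'
#' @inheritParams find_type1_repeats
#' @return data.frame as in [find_type1_repeats()] with `rtype` 2.
#' @export
find_type2_repeats <- function(idx, min_len = 1L) {
  bwt <- idx$bwt; lcp <- idx$lcp
  if (length(bwt) != length(lcp)) stop("bwt/lcp length mismatch")
  n <- length(bwt)
  sym <- bwt_symcode(bwt)
  ext <- c(-1L, lcp[-1L], -1L)  # ext[i] = lcp[i] with boundaries, length n+1
  r <- rle(ext[2:n])            # runs over lcp[2..n]
  out <- list()
  hi_run <- cumsum(r$lengths) + 1L       # last row index i of each run
  lo_run <- hi_run - r$lengths + 1L      # first row index j+1 of each run
  for (q in seq_along(r$lengths)) {
    v <- r$values[q]
    if (v < max(1L, min_len)) next
    jp1 <- lo_run[q]; i <- hi_run[q]
    before <- if (jp1 == 2L) 0L else r$values[q - 1L]
    after <- if (i == n) -1L else r$values[q + 1L]
    if (before >= v || after >= v) next
    rows <- (jp1 - 1L):i
    if (anyDuplicated(sym[rows])) next
    out[[length(out) + 1L]] <- repeat_df(2L, v, rows[1L], rows[length(rows)])
  }
  res <- if (length(out)) do.call(rbind, out) else empty_repeats()
  rownames(res) <- NULL
  res
}

#' Filter repeats by the number of distinct sequences they occur in
#'
#' Fills `distinct_sequences` from the document array over each record's
#' row interval and keeps records reaching `r_min`.
#'
#' @param records output of [find_type1_repeats()]/[find_type2_repeats()].
#' @param da document array (0-based string ids).
#' @param r_min minimum number of distinct sequences.
#' @return the filtered data.frame.
#' @export
restrict_repeats_by_sequences <- function(records, da, r_min = 1L) {
  if (is.null(records) || nrow(records) == 0L) return(empty_repeats())
  if (any(records$row_lo < 1L) || any(records$row_hi > length(da)))
    stop("repeat interval out of bounds")
  records$distinct_sequences <- vapply(seq_len(nrow(records)), function(q)
    length(unique(da[records$row_lo[q]:records$row_hi[q]])), integer(1))
  records[records$distinct_sequences >= r_min, , drop = FALSE]
}
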