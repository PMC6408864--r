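# All-pairs suffix-prefix overlaps in one scan of (bwt, lcp, da, xlcp).
#
# Per-sequence stacks hold the special suffixes whose common prefix with
# the current row exceeds tau; lcpStack keeps the active LCP values in
# increasing order and top[l] lists the sequences whose stack top equals l,
# so pops and emissions touch only the affected stacks.  When a row's bwt
# symbol is an end-marker the row's suffix is prefixed by the whole
# sequence da[i], and each stack top is the longest suffix-prefix overlap
# onto that sequence.

#' Compute all-pairs suffix-prefix overlaps longer than a threshold
#'
#' Reports, for ordered pairs of sequences, the longest overlap between a
#' suffix of the source and a prefix of the target, when longer than
#' `tau`.  Self-overlaps are reported but must be proper (shorter than the
#' sequence); for distinct pairs the overlap may equal the whole source,
#' which is flagged in the `contained` column.
#'
#' @param idx a `merged_index` (needs `bwt`, `lcp`, `da`, `xlcp`).
#' @param tau minimum overlap length (exclusive); `tau >= 0`.
#' @return data.frame: `source_id`, `target_id` (0-based), `length`,
#'   `contained`; attributes `pushes`/`pops` expose the stack work.
#' @export
compute_overlaps <- function(idx, tau = 0L) {
  bwt <- idx$bwt; lcp <- idx$lcp; da <- idx$da; xlcp <- idx$xlcp
  n <- length(bwt)
  if (length(lcp) != n || length(da) != n || length(xlcp) != n)
    stop("array length mismatch")
  if (tau < 0L) stop("tau must be >= 0")
  m <- max(da) + 1L
  src_len <- tabulate(da + 1L, nbins = m) - 1L   # per-string content lengths
  content <- suffix_lengths(bwt, da)              # per-row suffix lengths
  stacks <- vector("list", m)                     # increasing lcp values
  lcpStack <- integer(0)                          # active values, increasing
  top <- new.env(parent = emptyenv())             # as.character(l) -> seq ids
  pushes <- 0L; pops <- 0L
  rs <- integer(0); rt <- integer(0); rl <- integer(0)
  ext_lcp <- c(lcp[-1L], -1L)                     # lcp[i+1], virtual -1 at n
  for (i in seq_len(n)) {
    # (a) emit: row i prefixed by the whole sequence da[i]
    if (bwt[i] == SENTINEL) {
      tgt <- da[i]
      # containment care: a source suffix equal to the WHOLE target sorts
      # after row i when its string id exceeds the target's (end-marker
      # ranks); those duplicate-content rows sit in a contiguous run just
      # below row i and are not on the stacks yet
      skip <- integer(0)
      Lt <- content[i]
      r <- i + 1L
      while (r <= n && lcp[r] == Lt && content[r] == Lt) {
        if (Lt > tau) {
          rs <- c(rs, da[r]); rt <- c(rt, tgt); rl <- c(rl, Lt)
        }
        skip <- c(skip, da[r] + 1L)
        r <- r + 1L
      }
      for (l in lcpStack) {
        for (k in top[[as.character(l)]]) {
          if (k %in% skip) next  # superseded by the whole-target overlap
          rs <- c(rs, k - 1L); rt <- c(rt, tgt); rl <- c(rl, l)
        }
      }
    }
    nxt <- ext_lcp[i]
    # (b) pop every entry with value > lcp[i+1]
    while (length(lcpStack) && lcpStack[length(lcpStack)] > nxt) {
      l <- lcpStack[length(lcpStack)]
      key <- as.character(l)
      for (k in top[[key]]) {
        s <- stacks[[k]]
        s <- s[-length(s)]
        stacks[[k]] <- s
        pops <- pops + 1L
        if (length(s)) {
          l2 <- s[length(s)]
          k2 <- as.character(l2)
          top[[k2]] <- c(top[[k2]], k)
        }
      }
      rm(list = key, envir = top)
      lcpStack <- lcpStack[-length(lcpStack)]
    }
    # (c) push the special suffix of row i
    if (xlcp[i] && nxt > tau) {
      k <- da[i] + 1L
      s <- stacks[[k]]
      if (length(s)) {  # leave the old top's membership list
        kold <- as.character(s[length(s)])
        top[[kold]] <- setdiff(top[[kold]], k)
      }
      stacks[[k]] <- c(s, nxt)
      key <- as.character(nxt)
      top[[key]] <- c(top[[key]], k)
      if (!length(lcpStack) || lcpStack[length(lcpStack)] < nxt)
        lcpStack <- c(lcpStack, nxt)
      pushes <- pushes + 1L
    }
  }
  res <- data.frame(source_id = rs, target_id = rt, length = rl,
                    contained = rl == src_len[rs + 1L])
  res <- res[order(res$source_id, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "pushes") <- pushes; attr(res, "pops") <- pops
  res
}

#' Dense overlap length matrix
#'
#' @param records output of [compute_overlaps()] (one record per ordered
#'   pair).
#' @param m number of sequences.
#' @return `m x m` integer matrix: entry `(source+1, target+1)` is the
#'   recorded overlap length, 0 where no record.
#' @export
overlap_matrix <- function(records, m) {
  if (nrow(records)) {
    if (any(records$source_id < 0L | records$source_id >= m |
            records$target_id < 0L | records$target_id >= m))
      stop("sequence id out of range")
    if (anyDuplicated(records[c("source_id", "target_id")]))
      stop("duplicate ordered pair in overlap records")
  }
  mat <- matrix(0L, m, m)
  mat[cbind(records$source_id + 1L, records$target_id + 1L)] <- records$length
  mat
}
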