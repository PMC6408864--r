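# Phase 1: split the collection under a memory budget and suffix-sort each
# sub-collection into a partial BWT + document array.
#
# The suffix sorter is a prefix-doubling construction (Manber-Myers style)
# over the concatenation of the sub-collection with per-string distinct
# end-marker ranks, so each string's end-marker terminates comparisons and
# co-located end-markers rank by string id.  Any correct sorter would do;
# this one is O(n log n) with radix order() passes and is independent of
# the comparison-sort oracle it is tested against.

#' Split a collection under a memory budget
#'
#' Greedy left-to-right split into contiguous slices whose total content
#' length does not exceed `mem_budget_bytes / 9` (the working-space ratio
#' of an induced-sorting suffix sorter: 8 bytes of suffix array plus 1 byte
#' of text per input byte).  A string is never split; a single string
#' larger than the capacity forms its own slice.
#'
#' @param coll a [seq_collection()].
#' @param mem_budget_bytes memory budget in bytes (> 0); `Inf` keeps the
#'   collection whole.
#' @return list of `seq_collection` slices, each with attribute
#'   `first_global_id` (0-based id of its first string).
#' @export
split_collection <- function(coll, mem_budget_bytes = Inf) {
  stopifnot(mem_budget_bytes > 0)
  cap <- mem_budget_bytes / 9
  lens <- seq_lengths(coll)
  slices <- list()
  first <- 1L
  while (first <= coll$m) {
    last <- first
    tot <- lens[first]
    while (last < coll$m && tot + lens[last + 1L] <= cap) {
      last <- last + 1L
      tot <- tot + lens[last]
    }
    sl <- subset_collection(coll, first, last)
    attr(sl, "first_global_id") <- first - 1L
    slices[[length(slices) + 1L]] <- sl
    first <- last + 1L
  }
  slices
}

#' Number of merge rounds needed for a slice count
#'
#' With at most `fan_in` inputs per merge, `k` partial indexes need
#' `ceiling(log(k, fan_in))` rounds.
#' @param n_slices number of partial indexes.
#' @param fan_in maximum inputs per merge (128 by default; 8 in the
#'   semi-external regime).
#' @export
plan_rounds <- function(n_slices, fan_in = 128L) {
  if (n_slices <= 1L) return(0L)
  as.integer(ceiling(log(n_slices) / log(fan_in)))
}

# Suffix array of a sub-collection by prefix doubling.  Returns the sorted
# order (1-based positions into the concatenation content+$ per string) and
# the rank vector used (end-marker of local string t has rank t; byte b has
# rank m_sub + b).
sa_prefix_doubling <- function(ranks) {
  n <- length(ranks)
  rank <- match(ranks, sort(unique(ranks)))
  k <- 1L
  repeat {
    if (max(rank) == n) break
    next_rank <- c(rank[-seq_len(k)], rep(0L, k))  # rank of i+k, 0 past end
    ord <- order(rank, next_rank, method = "radix")
    key1 <- rank[ord]; key2 <- next_rank[ord]
    newr <- cumsum(c(1L, (key1[-1L] != key1[-n]) | (key2[-1L] != key2[-n])))
    rank[ord] <- newr
    k <- 2L * k
  }
  order(rank, method = "radix")
}

# Concatenated representation of a sub-collection: per-position owner
# (local 1-based), local position, original byte (end-marker as SENTINEL),
# and the rank vector for sorting.
concat_collection <- function(sub) {
  lens <- seq_lengths(sub)
  m <- sub$m
  owner <- rep.int(seq_len(m), lens + 1L)
  pos <- unlist(lapply(lens + 1L, seq_len), use.names = FALSE)
  orig <- unlist(lapply(sub$sequences, function(s) c(s, SENTINEL)),
                 use.names = FALSE)
  ranks <- unlist(lapply(seq_len(m), function(t) c(sub$sequences[[t]] + m, t)),
                  use.names = FALSE)
  list(owner = owner, pos = pos, orig = orig, ranks = ranks, lens = lens, m = m)
}

#' Build the partial BWT and document array of a sub-collection
#'
#' Suffix-sorts the sub-collection (end-markers terminating, ranked by
#' string id) and derives the partial multi-string BWT, the document array
#' in global 0-based ids, and per-symbol counts.
#'
#' @param sub a `seq_collection` slice.
#' @param first_global_id 0-based global id of the slice's first string.
#' @return a `partial_index`.
#' @export
build_partial_index <- function(sub, first_global_id = 0L) {
  cc <- concat_collection(sub)
  sa <- sa_prefix_doubling(cc$ranks)
  ot <- cc$owner[sa]; op <- cc$pos[sa]
  prev <- sa - 1L
  bwt <- ifelse(op == 1L, SENTINEL, cc$orig[pmax(prev, 1L)])
  new_partial_index(bwt = bwt, da = ot - 1L + first_global_id,
                    counts = count_symbols(bwt),
                    first_global_id = first_global_id, num_strings = sub$m)
}

# Kasai's algorithm on the rank representation (distinct end-marker ranks
# terminate matches, so LCP values never cross a string boundary).
kasai_lcp <- function(ranks, sa) {
  n <- length(ranks)
  rank_of <- integer(n); rank_of[sa] <- seq_len(n)
  lcp <- integer(n)
  h <- 0L
  for (i in seq_len(n)) {
    r <- rank_of[i]
    if (r > 1L) {
      j <- sa[r - 1L]
      while (i + h <= n && j + h <= n && ranks[i + h] == ranks[j + h]) h <- h + 1L
      lcp[r] <- h
      if (h > 0L) h <- h - 1L
    } else h <- 0L
  }
  lcp
}

#' Build the full merged index of a collection directly
#'
#' Fast path used when the whole collection fits one slice: one suffix
#' sort yields bwt, lcp (Kasai), da and the special-suffix bits, with no
#' merge.  Output is identical to the merge path on the same input.
#'
#' @param coll a [seq_collection()].
#' @return a `merged_index`.
#' @export
build_full_index_direct <- function(coll) {
  cc <- concat_collection(coll)
  sa <- sa_prefix_doubling(cc$ranks)
  ot <- cc$owner[sa]; op <- cc$pos[sa]
  bwt <- ifelse(op == 1L, SENTINEL, cc$orig[pmax(sa - 1L, 1L)])
  lcp <- kasai_lcp(cc$ranks, sa)
  n <- coll$n
  content_len <- cc$lens[ot] - op + 1L
  xlcp <- logical(n)
  if (n > 1L) xlcp[1:(n - 1L)] <- content_len[1:(n - 1L)] == lcp[2:n]
  xlcp[n] <- content_len[n] == 0L
  new_merged_index(bwt = bwt, lcp = lcp, da = ot - 1L, xlcp = xlcp,
                   stats = list(maxlcp = max(lcp), avelcp = mean(lcp),
                                iterations = 0L, Ir = 0L, rounds = 0L))
}

#' Write a partial index as slice files
#'
#' `<prefix>.slice<idx>.bwt` (bytes) and `<prefix>.slice<idx>.da`
#' (4-byte little-endian global ids); used by the streaming merge modes.
#' @param partial a `partial_index`.
#' @param prefix path prefix.
#' @param idx slice index (0-based).
#' @return list of the two paths.
#' @export
write_partial <- function(partial, prefix, idx) {
  pb <- sprintf("%s.slice%d.bwt", prefix, idx)
  pd <- sprintf("%s.slice%d.da", prefix, idx)
  writeBin(as.raw(partial$bwt), pb)
  con <- file(pd, "wb"); write_uints(con, partial$da, 4L); close(con)
  list(bwt = pb, da = pd)
}

#' Write a slice manifest TSV
#' @param slices list from [split_collection()].
#' @param path output TSV path.
#' @export
write_slice_manifest <- function(slices, path) {
  d <- data.frame(
    slice = seq_along(slices) - 1L,
    first_global_id = vapply(slices, function(s) attr(s, "first_global_id"), integer(1)),
    num_strings = vapply(slices, function(s) s$m, integer(1)),
    length = vapply(slices, function(s) s$n, integer(1)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
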