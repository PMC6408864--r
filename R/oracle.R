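# Brute-force reference implementations.
#
# Everything here favours clarity over speed: suffixes are materialised as
# strings and sorted with a comparison sort, LCP values come from direct
# character comparison, and the application oracles enumerate substrings /
# string pairs / row contexts exhaustively.  A hard cap on n guards against
# accidental use on large inputs.  These functions are deliberately
# independent of the production code paths (prefix-doubling sorter, Gap
# merge, single-scan applications) so they can serve as oracles for them.

ORACLE_MAX_N <- 100000L

# Map collection symbols to a per-collection dense code in which the m
# end-markers get codes 1..m (ranked by string id) and byte b gets m + b + 1.
# Encoded as single UTF-8 characters so that order(method = "radix") on the
# encoded suffix strings realises the collection's suffix order.
oracle_code <- function(coll) {
  m <- coll$m
  list(
    enc_seq = function(t) c(coll$sequences[[t]] + m + 1L, t),  # content + $_t
    m = m
  )
}

#' Brute-force suffix index of a collection
#'
#' Comparison-sorts all suffixes (end-markers ranked by string id) and
#' derives the multi-string BWT, LCP array, document array and
#' special-suffix (xlcp) bit vector by direct application of their
#' definitions.  A suffix is *special* when, end-marker aside, it is a
#' prefix of the lexicographically next suffix; equivalently its content
#' length equals the next LCP value.  Row 1's LCP is stored as 0 (files
#' hold unsigned integers); row n is special only when its suffix is a
#' bare end-marker, which cannot happen for non-empty strings.
#'
#' @param coll a [seq_collection()].
#' @return list with `sa` (global 1-based start positions in the
#'   concatenation, end-markers included), `da` (0-based string ids),
#'   `bwt` (integer byte values, end-markers as `SENTINEL`), `lcp`
#'   (integer), `xlcp` (logical), `content_len` (suffix lengths excluding
#'   the end-marker) and `stats` (maxlcp, avelcp).
#' @export
naive_index <- function(coll) {
  if (coll$n > ORACLE_MAX_N) stop("oracle capped at n <= ", ORACLE_MAX_N)
  cd <- oracle_code(coll)
  m <- coll$m
  lens <- seq_lengths(coll)
  offs <- cumsum(c(0L, lens + 1L))[seq_len(m)]  # concatenation offsets

  enc <- lapply(seq_len(m), cd$enc_seq)
  owner <- rep.int(seq_len(m), lens + 1L)
  pos <- unlist(lapply(lens + 1L, seq_len), use.names = FALSE)
  keys <- character(coll$n)
  idx <- 1L
  for (t in seq_len(m)) {
    e <- enc[[t]]
    for (p in seq_along(e)) {
      keys[idx] <- intToUtf8(e[p:length(e)])
      idx <- idx + 1L
    }
  }
  ord <- order(keys, method = "radix")
  ot <- owner[ord]; op <- pos[ord]
  n <- coll$n

  content_len <- lens[ot] - op + 1L  # 0 for the bare end-marker suffix
  da <- ot - 1L
  bwt <- integer(n)
  for (r in seq_len(n)) {
    t <- ot[r]; p <- op[r]
    bwt[r] <- if (p == 1L) SENTINEL else coll$sequences[[t]][p - 1L]
  }

  lcp <- integer(n)  # row 1 stored as 0
  if (n > 1L) {
    for (r in 2L:n) {
      a <- enc[[ot[r - 1L]]]; ia <- op[r - 1L]
      b <- enc[[ot[r]]];      ib <- op[r]
      l <- 0L
      while (a[ia + l] == b[ib + l]) l <- l + 1L  # distinct $ codes terminate
      lcp[r] <- l
    }
  }
  xlcp <- logical(n)
  if (n > 1L) xlcp[1:(n - 1L)] <- content_len[1:(n - 1L)] == lcp[2:n]
  xlcp[n] <- content_len[n] == 0L

  list(sa = offs[ot] + op, da = da, bwt = bwt, lcp = lcp, xlcp = xlcp,
       content_len = content_len,
       stats = list(maxlcp = max(lcp), avelcp = mean(lcp)))
}

# All substring occurrence counts of a collection, as an environment keyed
# by substring.  Occurrences are within strings (never across end-markers),
# overlapping occurrences counted.
substring_counts <- function(coll) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (s in coll$sequences) {
    str <- ints_to_str(s)
    L <- length(s)
    for (i in seq_len(L)) for (j in i:L) {
      key <- substr(str, i, j)
      env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    }
  }
  env
}

#' Brute-force maximal repeats
#'
#' Enumerates every substring of the collection and applies the definitions
#' directly: a Type 1 maximal repeat occurs at least twice and every
#' one-symbol extension (either side) occurs fewer times; a Type 2 maximal
#' repeat occurs at least twice and every extension occurs at most once.
#' Row intervals are located in the sorted-suffix order of [naive_index()].
#'
#' @param coll a [seq_collection()].
#' @param rtype 1 or 2.
#' @param min_len,min_occ filters on repeat length and occurrence count.
#' @return data.frame: `string`, `length`, `occ`, `row_lo`, `row_hi`.
#' @export
naive_repeats <- function(coll, rtype, min_len = 1L, min_occ = 2L) {
  stopifnot(rtype %in% c(1L, 2L))
  cnt <- substring_counts(coll)
  oi <- naive_index(coll)
  cd <- oracle_code(coll)
  sigma_chars <- vapply(coll$alphabet, ints_to_str, character(1))
  keys_sorted <- {
    # re-encode sorted suffixes for prefix search
    m <- coll$m
    vapply(seq_len(coll$n), function(r) {
      t <- oi$da[r] + 1L
      e <- cd$enc_seq(t)
      p <- length(e) - oi$content_len[r]
      intToUtf8(e[p:length(e)])
    }, character(1))
  }
  occ_of <- function(a) { v <- cnt[[a]]; if (is.null(v)) 0L else v }
  out <- list()
  for (a in ls(cnt)) {
    occ <- cnt[[a]]
    if (occ < max(2L, min_occ) || nchar(a) < min_len) next
    exts_r <- vapply(paste0(a, sigma_chars), occ_of, integer(1))
    exts_l <- vapply(paste0(sigma_chars, a), occ_of, integer(1))
    ok <- if (rtype == 1L) all(exts_r < occ) && all(exts_l < occ)
          else all(exts_r <= 1L) && all(exts_l <= 1L)
    if (!ok) next
    enc_a <- intToUtf8(str_to_ints(a) + coll$m + 1L)
    rows <- which(startsWith(keys_sorted, enc_a))
    stopifnot(length(rows) == occ, all(diff(rows) == 1L))
    out[[length(out) + 1L]] <-
      data.frame(string = a, length = nchar(a), occ = occ,
                 row_lo = rows[1L], row_hi = rows[length(rows)],
                 stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(string = character(), length = integer(), occ = integer(),
                      row_lo = integer(), row_hi = integer()))
  res <- do.call(rbind, out)
  res[order(res$row_lo, res$length), , drop = FALSE]
}

#' Brute-force all-pairs suffix-prefix overlaps
#'
#' Direct comparison of every suffix of every source string against the
#' prefix of every target string.  Ordered pairs; for a pair of distinct
#' strings the overlap may equal the whole source (the source is then
#' contained, flagged); a self-overlap must be proper (shorter than the
#' string).  Only the longest overlap per ordered pair is kept, and only
#' when longer than `tau`.
#'
#' @param coll a [seq_collection()].
#' @param tau length threshold; overlaps of length `> tau` are reported.
#' @return data.frame: `source_id`, `target_id` (0-based), `length`,
#'   `contained`.
#' @export
naive_overlaps <- function(coll, tau = 0L) {
  stopifnot(tau >= 0L)
  lens <- seq_lengths(coll)
  strs <- vapply(coll$sequences, ints_to_str, character(1))
  out <- list()
  for (i in seq_len(coll$m)) for (j in seq_len(coll$m)) {
    lmax <- if (i == j) lens[i] - 1L else min(lens[i], lens[j])
    if (lmax <= tau) next
    for (l in seq(lmax, tau + 1L)) {
      if (substr(strs[i], lens[i] - l + 1L, lens[i]) == substr(strs[j], 1L, l)) {
        out[[length(out) + 1L]] <- data.frame(
          source_id = i - 1L, target_id = j - 1L, length = l,
          contained = (i != j && l == lens[i]))
        break
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(source_id = integer(), target_id = integer(),
                      length = integer(), contained = logical()))
  res <- do.call(rbind, out)
  res[order(res$source_id, res$target_id), , drop = FALSE]
}

#' Brute-force BOSS construction
#'
#' Enumerates each sorted row's length-`k` context (the suffix truncated at
#' its own end-marker, end-markers pairwise distinct), groups consecutive
#' rows with equal context into nodes, and applies the definitions of `W`
#' (distinct preceding symbols per node, end-markers collapsed to one `$`
#' symbol, ascending with `$` lowest), `last`, and `W-` (first occurrence
#' of a symbol within the enclosing `(k-1)`-context group).
#'
#' @param coll a [seq_collection()].
#' @param k graph order, >= 1.
#' @param drop_dollar drop nodes whose context contains an end-marker
#'   (computed on the full graph, then filtered).
#' @param colored attach per-edge sorted sets of string ids.
#' @return a `boss_graph` (see [build_boss()]).
#' @export
naive_boss <- function(coll, k, drop_dollar = FALSE, colored = FALSE) {
  stopifnot(k >= 1L)
  oi <- naive_index(coll)
  cd <- oracle_code(coll)
  n <- coll$n
  ctx_of <- function(r, kk) {
    t <- oi$da[r] + 1L
    e <- cd$enc_seq(t)
    p <- length(e) - oi$content_len[r]
    intToUtf8(e[p:min(p + kk - 1L, length(e))])
  }
  ctx_k  <- vapply(seq_len(n), ctx_of, character(1), kk = k)
  ctx_k1 <- if (k > 1L) vapply(seq_len(n), ctx_of, character(1), kk = k - 1L)
            else rep("", n)
  node_id <- cumsum(c(TRUE, ctx_k[-1L] != ctx_k[-n]))
  km1_id  <- cumsum(c(TRUE, ctx_k1[-1L] != ctx_k1[-n]))
  symcls <- ifelse(oi$bwt == SENTINEL, SENTINEL, oi$bwt)

  W <- integer(0); last <- logical(0); wm <- logical(0)
  node_of_edge <- integer(0); colors <- list()
  has_dollar <- logical(max(node_id))
  seen <- integer(0); cur_km1 <- 0L
  for (nd in seq_len(max(node_id))) {
    rows <- which(node_id == nd)
    if (km1_id[rows[1L]] != cur_km1) { cur_km1 <- km1_id[rows[1L]]; seen <- integer(0) }
    syms <- unique(symcls[rows])
    syms <- syms[order(ifelse(syms == SENTINEL, -1L, syms))]
    for (s in syms) {
      W <- c(W, s); last <- c(last, FALSE)
      wm <- c(wm, !(s %in% seen)); seen <- c(seen, s)
      node_of_edge <- c(node_of_edge, nd)
      if (colored) {
        sel <- rows[symcls[rows] == s]
        colors[[length(colors) + 1L]] <- sort(unique(oi$da[sel]))
      }
    }
    last[length(last)] <- TRUE
    # context contains an end-marker iff shorter than k symbols or its last
    # code is an end-marker code (<= m)
    cc <- utf8ToInt(ctx_k[rows[1L]])
    has_dollar[nd] <- length(cc) < k || any(cc <= coll$m)
  }
  keep_edge <- rep(TRUE, length(W))
  nnodes <- max(node_id)
  if (drop_dollar) {
    keep_edge <- !has_dollar[node_of_edge]
    nnodes <- sum(!has_dollar)
  }
  structure(list(k = as.integer(k), W = W[keep_edge], last = last[keep_edge],
                 Wminus = wm[keep_edge], N = as.integer(nnodes),
                 colors = if (colored) colors[keep_edge] else NULL),
            class = "boss_graph")
}
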