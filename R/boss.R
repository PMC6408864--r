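# BOSS succinct de Bruijn graph construction from one scan of (bwt, lcp).
#
# Lexicographic variant (arc direction reversed relative to the
# co-lexicographic original): nodes are the maximal row ranges delimited by
# LCP values < k; each node's edge symbols C_i are the distinct bwt symbols
# of its range in ascending order (end-markers collapse to a single '$',
# ranked lowest); last marks the end of each C_i; W- marks the first
# occurrence of a symbol within the enclosing (k-1)-range.  Ranges whose
# representative context is shorter than k (it then contains an
# end-marker) are kept as nodes by default and can be dropped.

#' Suffix content lengths from the BWT via LF-mapping
#'
#' Walks the LF-mapping outward from the end-marker rows: the bare
#' end-marker suffixes (rows `1..m`) have content length 0, and each LF
#' step prepends one symbol.  With `max_depth = d` only lengths `< d + 1`
#' are resolved (`NA` beyond), which stays valid on arrays from a
#' `k`-truncated merge for `d = k - 1`: rows with short suffixes are
#' already in final position there.
#'
#' @param bwt,da merged BWT and document array.
#' @param max_depth resolve lengths up to this value (`Inf` for all).
#' @return integer vector of per-row content lengths (`NA` where beyond
#'   `max_depth`).
#' @export
suffix_lengths <- function(bwt, da, max_depth = Inf) {
  n <- length(bwt)
  m <- sum(bwt == SENTINEL)
  # LF-mapping: an end-marker occurrence maps to its string's singleton
  # slot; symbol c at rank r among c's maps to (rows before bucket c) + r
  syms <- sort(setdiff(unique(bwt), SENTINEL))
  lf <- integer(n)
  is_sent <- bwt == SENTINEL
  lf[is_sent] <- da[is_sent] - min(da) + 1L
  before <- m
  for (s in syms) {
    sel <- which(bwt == s)
    lf[sel] <- before + seq_along(sel)
    before <- before + length(sel)
  }
  content <- rep(NA_integer_, n)
  frontier <- seq_len(m)    # rows with content length d - 1
  content[frontier] <- 0L
  d <- 0L
  while (length(frontier) && d < max_depth) {
    d <- d + 1L
    # an end-marker read maps back to a depth-0 row (already resolved);
    # every other read extends its row's suffix by one symbol
    nxt <- lf[frontier[!is_sent[frontier]]]
    nxt <- nxt[is.na(content[nxt])]
    content[nxt] <- d
    frontier <- nxt
  }
  content
}

boss_sortkey <- function(s) ifelse(s == SENTINEL, -1L, s)

#' Build the BOSS representation of the order-k de Bruijn graph
#'
#' @param idx a `merged_index` (needs `bwt`, `lcp`; `da` additionally for
#'   `drop_dollar`).
#' @param k graph order, `>= 1`.
#' @param drop_dollar remove nodes whose context contains an end-marker
#'   (ranges of rows with suffix content shorter than `k`; always
#'   singleton ranges).  `W`/`last` entries of dropped nodes are removed;
#'   the remaining `Wminus` bits are kept as computed on the full graph.
#' @return a `boss_graph`: `k`, edge symbols `W` (integer bytes,
#'   end-markers as `$`), bit vectors `last` and `Wminus`, node count `N`,
#'   and `colors` (NULL here, see [build_colored_boss()]).
#' @export
build_boss <- function(idx, k, drop_dollar = FALSE) {
  if (k < 1L) stop("k must be >= 1")
  bwt <- idx$bwt; lcp <- idx$lcp
  n <- length(bwt)
  node_b <- lcp < k; node_b[1L] <- TRUE
  km1_b <- lcp < (k - 1L); km1_b[1L] <- TRUE
  node_id <- cumsum(node_b)
  km1_id <- cumsum(km1_b)
  nnodes <- node_id[n]
  starts <- which(node_b)
  ends <- c(starts[-1L] - 1L, n)
  drop_node <- logical(nnodes)
  if (drop_dollar) {
    content <- suffix_lengths(bwt, idx$da, max_depth = k - 1L)
    short <- !is.na(content) & content < k
    # a short-suffix row always forms a singleton node range
    drop_node <- seq_len(nnodes) %in% node_id[short]
  }
  W <- integer(0); last <- logical(0); wm <- logical(0)
  edge_node <- integer(0)
  seen <- integer(0); cur_km1 <- 0L
  symcls <- ifelse(bwt == SENTINEL, SENTINEL, bwt)
  for (nd in seq_len(nnodes)) {
    rows <- starts[nd]:ends[nd]
    if (km1_id[starts[nd]] != cur_km1) { cur_km1 <- km1_id[starts[nd]]; seen <- integer(0) }
    syms <- unique(symcls[rows])
    syms <- syms[order(boss_sortkey(syms))]
    W <- c(W, syms)
    lt <- rep(FALSE, length(syms)); lt[length(syms)] <- TRUE
    last <- c(last, lt)
    wm <- c(wm, !(syms %in% seen))
    seen <- c(seen, syms)
    edge_node <- c(edge_node, rep(nd, length(syms)))
  }
  keep <- !drop_node[edge_node]
  structure(list(k = as.integer(k), W = W[keep], last = last[keep],
                 Wminus = wm[keep], N = as.integer(sum(!drop_node)),
                 colors = NULL, node_starts = starts, node_ends = ends,
                 edge_node = edge_node[keep]),
            class = "boss_graph")
}

#' Build the colored BOSS representation
#'
#' As [build_boss()], additionally scanning the document array: the color
#' set of edge `W[j]` of node `i` is the sorted set of string ids whose
#' rows in node `i`'s range carry that bwt symbol.
#'
#' @inheritParams build_boss
#' @return a `boss_graph` with a `colors` list (0-based id vectors).
#' @export
build_colored_boss <- function(idx, k, drop_dollar = FALSE) {
  g <- build_boss(idx, k, drop_dollar = drop_dollar)
  symcls <- ifelse(idx$bwt == SENTINEL, SENTINEL, idx$bwt)
  g$colors <- lapply(seq_along(g$W), function(j) {
    rows <- g$node_starts[g$edge_node[j]]:g$node_ends[g$edge_node[j]]
    sort(unique(idx$da[rows[symcls[rows] == g$W[j]]]))
  })
  g
}

boss_equal <- function(a, b) {
  identical(a$k, b$k) && identical(a$N, b$N) && identical(a$W, b$W) &&
    identical(a$last, b$last) && identical(a$Wminus, b$Wminus) &&
    identical(a$colors, b$colors)
}

#' Merge partial indexes in k-mer prefix order only (de Bruijn early stop)
#'
#' Runs the Gap merge for exactly `k + 1` iterations (or to natural
#' termination if that comes first): the merged symbols are then sorted by
#' their length-`k` contexts and every LCP value `< k` is final, which is
#' all [build_boss()] consumes.  Unresolved LCP entries are stored as `k`.
#'
#' @param x a [seq_collection()] or list of `partial_index`.
#' @param k de Bruijn order.
#' @param cfg a [merge_config()].
#' @param mem_budget phase-1 split budget when `x` is a collection.
#' @return a `merged_index` whose `lcp` is capped at `k` (stats carry
#'   `truncated_at = k`); `xlcp` bits are only valid for rows with
#'   `lcp < k`.
#' @export
merge_prefix_order <- function(x, k, cfg = merge_config(), mem_budget = Inf) {
  partials <- if (inherits(x, "seq_collection")) {
    slices <- split_collection(x, mem_budget)
    lapply(slices, function(s) build_partial_index(s, attr(s, "first_global_id")))
  } else x
  if (is.null(cfg$tmp_dir)) cfg$tmp_dir <- tempfile("bwtmerge-")
  on.exit(unlink(cfg$tmp_dir, recursive = TRUE), add = TRUE)
  st <- run_merge(partials, cfg, emit = TRUE, max_iter = k + 1L, prefix = "trunc")
  fin <- finalize_merge(st)
  close_merge(st)
  lm <- multiway_merge_pairs(st$pair_paths, st$n,
                             tmp_dir = file.path(st$cfg$tmp_dir, "lcp"),
                             complete = FALSE, fill_value = k)
  new_merged_index(bwt = fin$bwt, lcp = lm$lcp, da = fin$da, xlcp = lm$xlcp,
                   stats = list(maxlcp = NA_integer_, avelcp = NA_real_,
                                iterations = st$iterations, Ir = st$Ir,
                                rounds = 1L, truncated_at = as.integer(k)))
}
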