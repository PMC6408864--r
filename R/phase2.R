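# Phase 2: merge k partial BWTs (and document arrays) with the iterative
# Gap procedure, emitting LCP pair files and special-suffix bits.
#
# State per merge: two interleave arrays Zold/Znew of source ids (double
# buffered: at the start of iteration h, Znew still holds Z^(h-2), which is
# what makes skipping frozen ranges sound), a block bit array B (current and
# next copy), a frozen bit array Bx (set once a row's LCP pair has been
# emitted), special-suffix bits Sold/Snew, and the bucket table F with the
# end-marker region subdivided into one singleton slot per string, ordered
# by global string id (realising $_1 < ... < $_m).
#
# During iteration h the scan reads source symbols in Zold order and
# rewrites them bucket-sequentially into Znew.  A next-copy B bit is set at
# a write position when the writing block differs from the bucket's previous
# writing block (a bit newly set at iteration h means lcp = h-1).  A pair
# <i, h-2, S[i-1]> is emitted the first time a set B bit is seen with Bx
# clear.  S propagates along the rewrite (Lemma-style: the target of a
# special suffix is special iff the current-copy B bit after it is still
# clear), with the m end-marker rows forced special every iteration.
#
# Maximal runs of Bx longer than the threshold t are recorded as irrelevant
# ranges after each iteration and skipped from the next iteration on; a
# skip advances the source cursors and bucket write slots by per-range
# stored counts.  The per-bucket offset of the range's last write is also
# stored so the block-change test of the first write after the range stays
# exact.

#' Merge configuration
#'
#' @param mode `"in_memory"` (all state and inputs in RAM),
#'   `"semi_external"` (state in RAM, input BWT/DA streamed from slice
#'   files), or `"external"` (input streamed and the Z/B/Bx/S state round
#'   tripped through their packed disk layouts between iterations).
#' @param t_threshold minimum length for a frozen run to be stored as a
#'   skippable range; default `max(256, k + sigma)`, computed at merge
#'   init.  Use `Inf` to disable skipping, `1` to skip aggressively;
#'   outputs are identical either way.
#' @param max_inputs maximum partial BWTs per merge: 128 (7-bit source
#'   ids), or 8 in semi-external mode (3-bit ids); larger collections are
#'   merged in rounds by the driver.
#' @param tmp_dir directory for pair files, slice files and merge state;
#'   created on demand.
#' @export
merge_config <- function(mode = c("in_memory", "semi_external", "external"),
                         t_threshold = NULL, max_inputs = NULL,
                         tmp_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(max_inputs)) max_inputs <- if (mode == "semi_external") 8L else 128L
  if (!is.null(t_threshold)) stopifnot(t_threshold >= 1)
  structure(list(mode = mode, t_threshold = t_threshold,
                 max_inputs = as.integer(max_inputs), tmp_dir = tmp_dir),
            class = "merge_config")
}

# ---- sources --------------------------------------------------------------

src_memory <- function(partial) {
  e <- new.env(parent = emptyenv())
  e$bwt <- partial$bwt; e$da <- partial$da
  e$n <- length(partial$bwt); e$lo <- 1L; e$hi <- e$n
  e$streamed <- FALSE
  e
}

src_stream <- function(paths, n, chunk = 8192L) {
  e <- new.env(parent = emptyenv())
  e$con_bwt <- file(paths$bwt, "rb"); e$con_da <- file(paths$da, "rb")
  e$n <- n; e$lo <- 1L; e$hi <- 0L; e$chunk <- chunk
  e$streamed <- TRUE
  e
}

src_refill <- function(sb, cur) {
  if (cur > sb$n) stop("source cursor overrun (corrupt input)")
  if (!sb$streamed) stop("source cursor overrun (corrupt input)")
  len <- min(sb$chunk, sb$n - cur + 1L)
  seek(sb$con_bwt, cur - 1L)
  sb$bwt <- as.integer(readBin(sb$con_bwt, "raw", n = len))
  seek(sb$con_da, (cur - 1L) * 4)
  sb$da <- as.integer(read_uints(sb$con_da, len, 4L))
  sb$lo <- cur; sb$hi <- cur + len - 1L
  invisible(sb)
}

src_close <- function(sb) {
  if (sb$streamed) { close(sb$con_bwt); close(sb$con_da) }
}

# ---- initialization -------------------------------------------------------

#' Initialize a Gap merge
#'
#' Sets `Zold = 1^{n_1} 2^{n_2} ... k^{n_k}`, `B = 1 0^{n-1} 1` (one block:
#' every length-0 context is equal), `Bx = B`, and the bucket table `F`
#' from the summed symbol counts, with the end-marker region subdivided
#' into `m` singleton slots ordered by global string id.
#'
#' @param partials list of `partial_index` in global id order (contiguous).
#' @param cfg a [merge_config()].
#' @return merge state (an environment; see [gap_iteration()],
#'   [run_merge()], [finalize_merge()]).
#' @export
init_merge <- function(partials, cfg = merge_config()) {
  k <- length(partials)
  stopifnot(k >= 1L)
  if (k > cfg$max_inputs)
    stop(sprintf("%d inputs exceed the %d-way merge limit; schedule rounds",
                 k, cfg$max_inputs))
  lens <- vapply(partials, function(p) length(p$bwt), integer(1))
  if (any(lens == 0L)) stop("empty partial index")
  firsts <- vapply(partials, function(p) p$first_global_id, integer(1))
  nums <- vapply(partials, function(p) p$num_strings, integer(1))
  if (k > 1L && !all(firsts[-1L] == (firsts + nums)[-k]))
    stop("partial indexes must cover contiguous global string ids, in order")

  st <- new.env(parent = emptyenv())
  st$k <- k; st$n <- sum(lens); st$lens <- lens
  st$mm <- sum(nums); st$min_gid <- firsts[1L]
  counts <- Reduce(`+`, lapply(partials, `[[`, "counts"))
  stopifnot(counts[SENTINEL + 1L] == st$mm)
  syms <- setdiff(which(counts > 0L) - 1L, SENTINEL)
  st$alphabet <- syms
  st$bucket_sizes <- counts[syms + 1L]
  st$bucket_start <- st$mm + 1L + c(0L, cumsum(st$bucket_sizes))[seq_along(syms)]
  st$bucket_map <- rep(NA_integer_, 256L)
  st$bucket_map[syms + 1L] <- seq_along(syms)
  n <- st$n
  st$Zold <- rep.int(seq_len(k), lens)
  st$Znew <- st$Zold                      # Z^(h-2) buffer
  st$Bcur <- c(TRUE, rep(FALSE, n - 1L), TRUE)
  st$Bx <- st$Bcur                        # boundary rows never emit
  st$Sold <- logical(n); st$Snew <- logical(n)
  st$symAt <- integer(n)
  st$h <- 1L; st$iterations <- 0L
  st$ranges <- list(); st$Ir <- 0L
  st$max_emitted <- -1L
  st$t <- if (is.null(cfg$t_threshold)) max(256, k + length(syms)) else cfg$t_threshold
  if (is.null(cfg$tmp_dir)) cfg$tmp_dir <- tempfile("bwtmerge-")
  st$cfg <- cfg
  st$srcs <- lapply(partials, src_memory)
  st$pair_paths <- character(0)
  st$writers <- list()
  st$emit <- TRUE
  st$prefix <- "merge"
  st
}

# Bucket start table as in the paper's F, for inspection and tests:
# m singleton end-marker slots followed by one bucket per symbol.
#' Bucket start offsets of a merge state
#' @param st a merge state from [init_merge()].
#' @return named integer vector: start row of each end-marker slot
#'   (`$0`, `$1`, ...) and of each symbol bucket.
#' @export
f_table <- function(st) {
  v <- c(seq_len(st$mm), st$bucket_start)
  names(v) <- c(paste0("$", seq_len(st$mm) - 1L + st$min_gid),
                vapply(st$alphabet, ints_to_str, character(1)))
  v
}

pair_writer_for <- function(st, value) {
  key <- as.character(value)
  w <- st$writers[[key]]
  if (is.null(w)) {
    dir.create(st$cfg$tmp_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(st$cfg$tmp_dir, sprintf("%s.pairs.%d", st$prefix, value))
    w <- pair_open(path)
    st$writers[[key]] <- w
    st$pair_paths <- c(st$pair_paths, stats::setNames(path, key))
  }
  w
}

# ---- one iteration --------------------------------------------------------

#' Run one Gap iteration
#'
#' Scans `Zold` once (skipping stored irrelevant ranges), rewrites the
#' interleave into `Znew` bucket-sequentially, refines the block bits,
#' emits `<position, h-2, special-bit>` pair records for rows whose block
#' bit appeared in the previous iteration, propagates special-suffix bits,
#' then swaps buffers and recomputes the skippable ranges.
#'
#' @param st merge state from [init_merge()].
#' @return the state, invisibly; emitted records are appended to the pair
#'   file `F_{h-2}` (when emission is enabled) and `Bx` is updated.
#' @export
gap_iteration <- function(st) {
  n <- st$n; h <- st$h
  Zold <- st$Zold; Bcur <- st$Bcur; Sold <- st$Sold
  Znew <- st$Znew; Bnext <- Bcur; Snew <- Sold
  Bx <- st$Bx; BxPre <- st$Bx; symAt <- st$symAt
  bucket_next <- st$bucket_start
  nb <- length(bucket_next)
  last_block <- integer(nb)
  bucket_map <- st$bucket_map
  cursors <- integer(st$k)
  srcs <- st$srcs
  for (sb in srcs) if (sb$streamed) { sb$lo <- 1L; sb$hi <- 0L }
  min_gid <- st$min_gid
  ranges <- st$ranges
  nranges <- length(ranges)
  ri <- 1L
  next_start <- if (nranges >= 1L) ranges[[1L]]$start else 0L
  ePos <- integer(n); eBit <- logical(n); ne <- 0L
  blockcnt <- 0L
  i <- 1L
  while (i <= n) {
    if (i == next_start) {
      rng <- ranges[[ri]]
      seg <- rng$start:rng$end
      Znew[seg] <- Zold[seg]
      Snew[seg] <- Sold[seg]
      cursors <- cursors + rng$src_counts
      wb <- rng$written_buckets
      if (length(wb)) {
        bucket_next[wb] <- bucket_next[wb] + rng$sym_counts[wb]
        last_block[wb] <- blockcnt + rng$last_off[wb]
      }
      blockcnt <- blockcnt + rng$len
      st$Ir <- st$Ir + 1L
      ri <- ri + 1L
      next_start <- if (ri <= nranges) ranges[[ri]]$start else 0L
      i <- rng$end + 1L
      next
    }
    if (Bcur[i]) blockcnt <- blockcnt + 1L
    l <- Zold[i]
    cur <- cursors[l] + 1L; cursors[l] <- cur
    sb <- srcs[[l]]
    if (cur > sb$hi) src_refill(sb, cur)
    ci <- cur - sb$lo + 1L
    cc <- sb$bwt[ci]
    symAt[i] <- cc
    if (cc == SENTINEL) {
      j <- sb$da[ci] - min_gid + 1L
      Bnext[j] <- TRUE
    } else {
      b <- bucket_map[cc + 1L]
      j <- bucket_next[b]
      bucket_next[b] <- j + 1L
      if (last_block[b] != blockcnt) Bnext[j] <- TRUE
      last_block[b] <- blockcnt
    }
    if (Bcur[i] && !Bx[i]) {
      ne <- ne + 1L; ePos[ne] <- i; eBit[ne] <- Sold[i - 1L]
      Bx[i] <- TRUE
    }
    Znew[j] <- l
    if (Sold[i] && !Bcur[j + 1L]) Snew[j] <- TRUE
    i <- i + 1L
  }
  if (!identical(bucket_next - st$bucket_start, st$bucket_sizes))
    stop("bucket overflow: write accounting is inconsistent")
  Snew[seq_len(st$mm)] <- TRUE
  st$Zold <- Znew; st$Znew <- Zold
  st$Bcur <- Bnext
  st$Sold <- Snew; st$Snew <- Sold
  st$Bx <- Bx; st$symAt <- symAt
  if (ne > 0L) {
    v <- h - 2L
    st$max_emitted <- max(st$max_emitted, v)
    if (st$emit) pair_append(pair_writer_for(st, v), ePos[seq_len(ne)], eBit[seq_len(ne)])
  }
  st$h <- h + 1L
  st$iterations <- st$iterations + 1L
  update_ranges(st, BxPre)
  invisible(st)
}

#' Recompute the stored irrelevant ranges of a merge state
#'
#' Called at the end of every iteration: maximal runs of set `Bx` bits
#' longer than the threshold `t` become skippable ranges, stored with their
#' per-source read counts, per-bucket write counts and the in-range offset
#' of each bucket's last write.  Adjacent frozen runs coalesce by
#' construction (the runs are recomputed maximal each time).
#'
#' @param st merge state.
#' @return the state, invisibly; `st$ranges` holds the ranges skipped by
#'   the next [gap_iteration()].
#' @export
update_ranges <- function(st, bx = st$Bx) {
  if (!is.finite(st$t)) { st$ranges <- list(); return(invisible(st)) }
  # A run of set Bx bits over positions a..b freezes ENTRIES a..b-1 only:
  # both boundary bits of every skipped entry must be frozen, otherwise the
  # entry still sits in an open block and its source id can change.  The
  # run detection uses the bits as they stood at the START of the just
  # finished iteration: an entry is skipped only once BOTH Z buffers have
  # been rewritten since it froze (its write is then a guaranteed no-op).
  r <- rle(bx)
  ends <- cumsum(r$lengths) - 1L   # entry range end = bit-run end - 1
  starts <- ends - r$lengths + 2L
  sel <- which(r$values & (ends - starts + 1L) > st$t)
  nb <- length(st$bucket_start)
  ranges <- vector("list", length(sel))
  for (q in seq_along(sel)) {
    a <- starts[sel[q]]; b <- ends[sel[q]]
    seg <- a:b
    sy <- st$symAt[seg]
    nons <- which(sy != SENTINEL)
    bidx <- st$bucket_map[sy[nons] + 1L]
    sym_counts <- tabulate(bidx, nbins = nb)
    last_off <- integer(nb)
    if (length(nons)) {
      mx <- tapply(nons, bidx, max)  # offsets within the range, 1-based
      last_off[as.integer(names(mx))] <- as.integer(mx)
    }
    ranges[[q]] <- list(start = a, end = b, len = b - a + 1L,
                        src_counts = tabulate(st$Zold[seg], nbins = st$k),
                        sym_counts = sym_counts, last_off = last_off,
                        written_buckets = which(sym_counts > 0L))
  }
  st$ranges <- ranges
  invisible(st)
}

# ---- external-memory state round trip ------------------------------------

# Packed layouts: one byte per Z entry, low 7 bits source id - 1, high bit
# the B copy riding with that buffer; Bx, Sold, Snew as packed bit files;
# ranges as little-endian records (start, end, k source counts, nb write
# counts, nb last-write offsets, all 4-byte).
ext_save <- function(st) {
  tmp <- st$cfg$tmp_dir
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  zb <- function(z, bbits) as.raw((z - 1L) + 128L * as.integer(bbits[seq_len(st$n)]))
  writeBin(zb(st$Zold, st$Bcur), file.path(tmp, paste0(st$prefix, ".z.0")))
  writeBin(zb(st$Znew, st$Bcur), file.path(tmp, paste0(st$prefix, ".z.1")))
  write_bits(file.path(tmp, paste0(st$prefix, ".bx")), st$Bx)
  write_bits(file.path(tmp, paste0(st$prefix, ".s.0")), st$Sold)
  write_bits(file.path(tmp, paste0(st$prefix, ".s.1")), st$Snew)
  con <- file(file.path(tmp, paste0(st$prefix, ".ranges")), "wb")
  for (rng in st$ranges)
    write_uints(con, c(rng$start, rng$end, rng$src_counts, rng$sym_counts,
                       rng$last_off), 4L)
  close(con)
  invisible(st)
}

ext_load <- function(st) {
  tmp <- st$cfg$tmp_dir
  rd <- function(f) as.integer(readBin(file.path(tmp, f), "raw", n = st$n))
  z0 <- rd(paste0(st$prefix, ".z.0")); z1 <- rd(paste0(st$prefix, ".z.1"))
  st$Zold <- (z0 %% 128L) + 1L
  st$Znew <- (z1 %% 128L) + 1L
  st$Bcur <- c(z0 >= 128L, TRUE)
  st$Bx <- read_bits(file.path(tmp, paste0(st$prefix, ".bx")), st$n + 1L)
  st$Sold <- read_bits(file.path(tmp, paste0(st$prefix, ".s.0")), st$n)
  st$Snew <- read_bits(file.path(tmp, paste0(st$prefix, ".s.1")), st$n)
  con <- file(file.path(tmp, paste0(st$prefix, ".ranges")), "rb")
  nb <- length(st$bucket_start)
  reclen <- 2L + st$k + 2L * nb
  nrec <- file.size(file.path(tmp, paste0(st$prefix, ".ranges"))) / (4L * reclen)
  ranges <- vector("list", nrec)
  for (q in seq_len(nrec)) {
    v <- as.integer(read_uints(con, reclen, 4L))
    sym_counts <- v[(2L + st$k + 1L):(2L + st$k + nb)]
    ranges[[q]] <- list(start = v[1L], end = v[2L], len = v[2L] - v[1L] + 1L,
                        src_counts = v[3L:(2L + st$k)],
                        sym_counts = sym_counts,
                        last_off = v[(2L + st$k + nb + 1L):reclen],
                        written_buckets = which(sym_counts > 0L))
  }
  close(con)
  st$ranges <- ranges
  invisible(st)
}

# ---- full merge -----------------------------------------------------------

#' Run a Gap merge to termination
#'
#' Iterates [gap_iteration()] until every row in `2..n` has emitted its LCP
#' pair (all `Bx` bits set), which takes at most `maxlcp + 2` iterations.
#' With `max_iter = k + 1` the merge stops after the symbols are sorted by
#' their length-`k` contexts (the de Bruijn early-stop regime).
#'
#' @param partials list of `partial_index`, in global id order.
#' @param cfg a [merge_config()].
#' @param emit write pair files (disabled for intermediate merge rounds,
#'   where only the merged BWT/DA are needed).
#' @param max_iter cap on iterations (default none).
#' @param prefix name prefix for temporary and pair files.
#' @return terminal merge state; pass to [finalize_merge()] and feed
#'   `st$pair_paths` to [multiway_merge_pairs()].
#' @export
run_merge <- function(partials, cfg = merge_config(), emit = TRUE,
                      max_iter = Inf, prefix = "merge") {
  if (is.null(cfg$tmp_dir)) cfg$tmp_dir <- tempfile("bwtmerge-")
  st <- init_merge(partials, cfg)
  st$emit <- emit
  st$prefix <- prefix
  if (cfg$mode != "in_memory") {
    dir.create(cfg$tmp_dir, recursive = TRUE, showWarnings = FALSE)
    st$slice_paths <- lapply(seq_along(partials), function(i)
      write_partial(partials[[i]], file.path(cfg$tmp_dir, prefix), i - 1L))
    st$srcs <- lapply(seq_along(partials), function(i)
      src_stream(st$slice_paths[[i]], length(partials[[i]]$bwt)))
  }
  n <- st$n
  repeat {
    gap_iteration(st)
    if (st$cfg$mode == "external") { ext_save(st); ext_load(st) }
    if (st$iterations >= max_iter) break
    if (n < 2L || all(st$Bx[2:n])) break
    if (st$iterations > n + 2L) stop("merge failed to converge (logic fault)")
  }
  for (w in st$writers) pair_close(w)
  st$writers <- list()
  update_ranges(st)  # terminal coalesced ranges, from the final Bx state
  st
}

#' Produce the merged BWT and document array from a terminal merge state
#'
#' A final sequential pass over the input BWTs in `Zold` order.
#' @param st terminal state from [run_merge()].
#' @return list with integer vectors `bwt` and `da`.
#' @export
finalize_merge <- function(st) {
  n <- st$n
  bwt <- integer(n); da <- integer(n)
  for (l in seq_len(st$k)) {
    idx <- which(st$Zold == l)
    sb <- st$srcs[[l]]
    if (sb$streamed) {
      seek(sb$con_bwt, 0); seek(sb$con_da, 0)
      sbwt <- as.integer(readBin(sb$con_bwt, "raw", n = sb$n))
      sda <- as.integer(read_uints(sb$con_da, sb$n, 4L))
    } else { sbwt <- sb$bwt; sda <- sb$da }
    if (length(idx) != length(sbwt)) stop("source exhausted early")
    bwt[idx] <- sbwt
    da[idx] <- sda
  }
  list(bwt = bwt, da = da)
}

close_merge <- function(st) {
  if (!is.null(st$srcs)) for (sb in st$srcs) src_close(sb)
  invisible(NULL)
}
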