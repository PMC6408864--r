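# End-to-end drivers: collection -> merged index (phases 1-3), array file
# output, and the application commands.

partial_from_merge <- function(st, fin) {
  new_partial_index(bwt = fin$bwt, da = fin$da, counts = count_symbols(fin$bwt),
                    first_global_id = st$min_gid, num_strings = st$mm)
}

#' Build the multi-string BWT, LCP, document and special-suffix arrays
#'
#' The full pipeline: split the collection under the memory budget
#' (phase 1), suffix-sort each slice into a partial BWT/DA, merge the
#' partial indexes with the iterative Gap procedure, in rounds of at most
#' `max_inputs` when there are many slices (phase 2), and multiway-merge
#' the emitted LCP pair files into the final LCP/xlcp arrays (phase 3).
#' When one slice suffices the direct single-sort path is used instead,
#' unless `force_merge` is set; both paths produce bit-identical output.
#'
#' @param x a [seq_collection()], or a path to a FASTA/FASTQ file.
#' @param mem_budget memory budget in bytes for phase 1 splitting
#'   (default: no split).
#' @param cfg a [merge_config()].
#' @param lambda phase-3 merge fan-in.
#' @param force_merge run the merge path even for a single slice.
#' @param force_slices split into (at least) this many slices regardless
#'   of the budget, for testing merge behaviour; `NULL` to respect the
#'   budget.
#' @param keep_temps keep the per-run temporary directory.
#' @return a `merged_index`; `$stats` carries `maxlcp`, `avelcp`,
#'   `iterations` (final merge round), `Ir` (skipped ranges), `rounds`
#'   (merge rounds) and `lcp_rounds` (phase-3 rounds).
#' @export
bwt_index <- function(x, mem_budget = Inf, cfg = merge_config(), lambda = 256L,
                      force_merge = FALSE, force_slices = NULL,
                      keep_temps = FALSE) {
  coll <- if (is.character(x)) read_collection(x) else x
  stopifnot(inherits(coll, "seq_collection"))
  slices <- if (is.null(force_slices)) split_collection(coll, mem_budget)
            else split_even(coll, force_slices)
  if (length(slices) == 1L && !force_merge && is.null(force_slices))
    return(build_full_index_direct(coll))
  if (is.null(cfg$tmp_dir)) cfg$tmp_dir <- tempfile("bwtmerge-")
  if (!keep_temps) on.exit(unlink(cfg$tmp_dir, recursive = TRUE), add = TRUE)
  partials <- lapply(slices, function(s)
    build_partial_index(s, attr(s, "first_global_id")))

  rounds <- 0L
  while (length(partials) > cfg$max_inputs) {   # intermediate rounds: BWT/DA only
    rounds <- rounds + 1L
    groups <- split(partials, (seq_along(partials) - 1L) %/% cfg$max_inputs)
    partials <- lapply(seq_along(groups), function(g) {
      st <- run_merge(groups[[g]], cfg, emit = FALSE,
                      prefix = sprintf("round%d.%d", rounds, g))
      p <- partial_from_merge(st, finalize_merge(st))
      close_merge(st)
      p
    })
  }
  rounds <- rounds + 1L
  st <- run_merge(partials, cfg, emit = TRUE, prefix = "final")
  fin <- finalize_merge(st)
  close_merge(st)
  lm <- multiway_merge_pairs(st$pair_paths, st$n, lambda = lambda,
                             tmp_dir = file.path(st$cfg$tmp_dir, "lcp"))
  new_merged_index(bwt = fin$bwt, lcp = lm$lcp, da = fin$da, xlcp = lm$xlcp,
                   stats = list(maxlcp = max(lm$lcp), avelcp = mean(lm$lcp),
                                iterations = st$iterations, Ir = st$Ir,
                                rounds = rounds, lcp_rounds = lm$rounds))
}

# Split a collection into n_slices contiguous slices of near-equal string
# counts (testing hook for forced 2-way/3-way merges).
split_even <- function(coll, n_slices) {
  n_slices <- min(n_slices, coll$m)
  cut <- floor(seq(0L, coll$m, length.out = n_slices + 1L))
  lapply(seq_len(n_slices), function(q) {
    sl <- subset_collection(coll, cut[q] + 1L, cut[q + 1L])
    attr(sl, "first_global_id") <- cut[q]
    sl
  })
}

#' Index a sequence file and write the binary arrays plus a stats report
#'
#' @param input path to FASTA/FASTQ.
#' @param out_prefix output prefix for `.bwt/.lcp/.da/.xlcp` and a
#'   `.stats.tsv` report (maxlcp, avelcp, merge iterations, skipped
#'   ranges, merge rounds).
#' @param lcp_bytes,da_bytes on-disk widths, see [write_arrays()].
#' @param ... passed to [bwt_index()].
#' @return the `array_files` descriptor, invisibly.
#' @export
bwt_index_files <- function(input, out_prefix, lcp_bytes = 4L, da_bytes = 4L, ...) {
  idx <- bwt_index(input, ...)
  af <- write_arrays(idx, out_prefix, lcp_bytes = lcp_bytes, da_bytes = da_bytes)
  s <- idx$stats
  utils::write.table(
    data.frame(maxlcp = s$maxlcp, avelcp = s$avelcp,
               iterations = if (is.null(s$iterations)) NA else s$iterations,
               skipped_ranges = if (is.null(s$Ir)) NA else s$Ir,
               rounds = if (is.null(s$rounds)) NA else s$rounds),
    paste0(out_prefix, ".stats.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(af)
}

as_merged_index <- function(x, ...) {
  if (inherits(x, "merged_index")) x
  else if (inherits(x, "seq_collection")) bwt_index(x, ...)
  else if (is.character(x)) bwt_index(read_collection(x), ...)
  else stop("expected a merged_index, seq_collection or file path")
}

#' Report maximal repeats of a collection or index
#'
#' @param x a `merged_index`, [seq_collection()] or FASTA/FASTQ path.
#' @param type 1, 2 or "both".
#' @param min_len,min_occ,min_seqs filters: minimum repeat length,
#'   occurrence count, and number of distinct sequences containing it
#'   (`min_seqs > 1` needs the document array).
#' @return data.frame: `rtype`, `length`, `occ`, `row_lo`, `row_hi`,
#'   `distinct_sequences`.
#' @export
bwt_repeats <- function(x, type = "both", min_len = 1L, min_occ = 2L,
                        min_seqs = 1L) {
  idx <- as_merged_index(x)
  out <- list()
  if (type %in% c(1, "1", "both"))
    out$t1 <- find_type1_repeats(idx, min_len = min_len, min_occ = min_occ)
  if (type %in% c(2, "2", "both"))
    out$t2 <- find_type2_repeats(idx, min_len = min_len)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  restrict_repeats_by_sequences(res, idx$da, r_min = min_seqs)
}

#' Report all-pairs suffix-prefix overlaps longer than a threshold
#'
#' @param x as in [bwt_repeats()].
#' @param tau report overlaps of length `> tau`.
#' @return data.frame: `source_id`, `target_id`, `length`, `contained`.
#' @export
bwt_overlaps <- function(x, tau = 0L) {
  compute_overlaps(as_merged_index(x), tau = tau)
}

#' Build the BOSS de Bruijn graph representation of a collection
#'
#' @param x as in [bwt_repeats()]; for `early_stop` a collection (or path)
#'   is required, since the merge itself is truncated.
#' @param k graph order.
#' @param colors attach per-edge color sets (string ids).
#' @param drop_dollar remove nodes whose context contains an end-marker.
#' @param early_stop stop the merge after `k + 1` iterations instead of
#'   completing the LCP computation (same BOSS output).
#' @param cfg a [merge_config()] (early-stop path).
#' @return a `boss_graph`.
#' @export
bwt_dbg <- function(x, k, colors = FALSE, drop_dollar = FALSE,
                    early_stop = FALSE, cfg = merge_config()) {
  if (early_stop) {
    coll <- if (is.character(x)) read_collection(x) else x
    stopifnot(inherits(coll, "seq_collection"))
    idx <- merge_prefix_order(coll, k = k, cfg = cfg)
  } else idx <- as_merged_index(x)
  if (colors) build_colored_boss(idx, k, drop_dollar = drop_dollar)
  else build_boss(idx, k, drop_dollar = drop_dollar)
}
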