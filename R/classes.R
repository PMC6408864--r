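# Container classes and print methods.

new_merged_index <- function(bwt, lcp, da, xlcp, stats) {
  structure(list(bwt = as.integer(bwt), lcp = as.integer(lcp),
                 da = as.integer(da), xlcp = as.logical(xlcp), stats = stats),
            class = "merged_index")
}

#' @export
print.merged_index <- function(x, ...) {
  n <- length(x$bwt)
  m <- sum(x$bwt == SENTINEL)
  cat(sprintf("merged_index: n = %d rows, m = %d sequences\n", n, m))
  s <- x$stats
  cat(sprintf("  maxlcp = %s, avelcp = %s, special rows = %d\n",
              format(s$maxlcp), format(round(s$avelcp, 3)), sum(x$xlcp)))
  if (!is.null(s$iterations) && !is.na(s$iterations))
    cat(sprintf("  merge: %d iteration(s), %d skipped range(s), %d round(s)\n",
                s$iterations, s$Ir, s$rounds))
  if (n <= 40L) {
    chr <- vapply(x$bwt, ints_to_str, character(1))
    cat("  bwt :", paste(chr, collapse = ""), "\n")
    cat("  lcp :", paste(x$lcp, collapse = ","), "\n")
    cat("  da  :", paste(x$da, collapse = ","), "\n")
    cat("  xlcp:", paste(as.integer(x$xlcp), collapse = ""), "\n")
  }
  invisible(x)
}

new_partial_index <- function(bwt, da, counts, first_global_id, num_strings) {
  structure(list(bwt = as.integer(bwt), da = as.integer(da),
                 counts = counts,  # integer vector length 256, counts[sym+1]
                 first_global_id = as.integer(first_global_id),
                 num_strings = as.integer(num_strings)),
            class = "partial_index")
}

#' @export
print.partial_index <- function(x, ...) {
  cat(sprintf("partial_index: %d rows, strings %d..%d\n", length(x$bwt),
              x$first_global_id, x$first_global_id + x$num_strings - 1L))
  invisible(x)
}

#' @export
print.boss_graph <- function(x, ...) {
  cat(sprintf("boss_graph: order k = %d, N = %d nodes, %d edges%s\n",
              x$k, x$N, length(x$W),
              if (is.null(x$colors)) "" else " (colored)"))
  if (length(x$W) <= 60L) {
    cat("  W     :", paste(vapply(x$W, ints_to_str, character(1)), collapse = ""), "\n")
    cat("  last  :", paste(as.integer(x$last), collapse = ""), "\n")
    cat("  Wminus:", paste(as.integer(x$Wminus), collapse = ""), "\n")
  }
  invisible(x)
}

#' Convert a BOSS graph to a data frame
#'
#' One row per edge: edge index, node index, edge symbol, `last` and
#' `Wminus` bits, and (for colored graphs) the comma-separated color set.
#' @param x a `boss_graph`.
#' @param ... unused.
#' @export
as.data.frame.boss_graph <- function(x, ...) {
  node <- cumsum(c(1L, utils::head(as.integer(x$last), -1L)))
  d <- data.frame(edge = seq_along(x$W),
                  node = if (length(x$W)) node else integer(0),
                  symbol = vapply(x$W, ints_to_str, character(1)),
                  last = as.integer(x$last), Wminus = as.integer(x$Wminus),
                  stringsAsFactors = FALSE)
  if (!is.null(x$colors))
    d$colors <- vapply(x$colors, paste, character(1), collapse = ",")
  d
}

# Count symbols of a partial/merged bwt into a length-256 vector (counts[b+1]).
count_symbols <- function(bwt) tabulate(bwt + 1L, nbins = 256L)
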