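# Shared fixtures: the two-string worked example and comparison helpers.

fig1_collection <- function() seq_collection(c("abcab", "aabcabc"))

# Expected arrays for {abcab, aabcabc}, fixed by the published worked
# example and re-derived independently by the comparison-sort oracle.
fig1_expected <- list(
  bwt = utf8ToInt("bc$cc$aaaaabbb"),
  lcp = c(0L, 0L, 0L, 1L, 2L, 3L, 5L, 0L, 1L, 2L, 4L, 0L, 1L, 3L),
  da = c(0L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L),
  xlcp_rows = c(1L, 2L, 4L, 5L, 6L, 8L, 9L, 10L, 12L, 13L),
  maxlcp = 5L
)

expect_index_equal <- function(got, want, info = NULL) {
  expect_identical(got$bwt, want$bwt, info = info)
  expect_identical(got$lcp, want$lcp, info = info)
  expect_identical(got$da, want$da, info = info)
  expect_identical(got$xlcp, want$xlcp, info = info)
}

oracle_as_index <- function(coll) {
  o <- naive_index(coll)
  list(bwt = o$bwt, lcp = o$lcp, da = o$da, xlcp = o$xlcp, stats = o$stats)
}

# Repeat records reduced to comparable columns, in canonical order.
repeat_key <- function(d) {
  d <- d[order(d$row_lo, d$length), c("length", "occ", "row_lo", "row_hi")]
  rownames(d) <- NULL
  d
}

expect_same_repeats <- function(scan, oracle, info = NULL) {
  expect_equal(repeat_key(scan), repeat_key(oracle),
               ignore_attr = TRUE, info = info)
}

expect_same_overlaps <- function(scan, oracle, info = NULL) {
  expect_equal(as.data.frame(scan), as.data.frame(oracle),
               ignore_attr = TRUE, info = info)
}

boss_equal_test <- function(a, b) {
  identical(a$k, b$k) && identical(a$N, b$N) && identical(a$W, b$W) &&
    identical(a$last, b$last) && identical(a$Wminus, b$Wminus) &&
    identical(a$colors, b$colors)
}

write_fig1_fasta <- function(path = tempfile(fileext = ".fa")) {
  writeLines(c(">s1", "abcab", ">s2", "aabcabc"), path)
  path
}
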