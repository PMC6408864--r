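# All-pairs suffix-prefix overlap scan against brute force.

test_that("the worked example yields the published overlaps", {
  idx <- build_full_index_direct(fig1_collection())
  ov1 <- compute_overlaps(idx, 1L)
  expect_identical(ov1$source_id, c(0L, 1L))
  expect_identical(ov1$target_id, c(0L, 0L))
  expect_identical(ov1$length, c(2L, 3L))     # self "ab", and "abc" of s2
  expect_false(any(ov1$contained))
  ov2 <- compute_overlaps(idx, 2L)
  expect_identical(nrow(ov2), 1L)
  expect_identical(ov2$length, 3L)
  expect_identical(nrow(compute_overlaps(idx, 5L)), 0L)
  expect_error(compute_overlaps(idx, -1L), "tau")

  expect_identical(overlap_matrix(ov1, 2L),
                   matrix(c(2L, 3L, 0L, 0L), 2L))
  expect_identical(overlap_matrix(ov1[0, ], 3L), matrix(0L, 3L, 3L))
  dup <- rbind(ov1, ov1[1L, ])
  expect_error(overlap_matrix(dup, 2L), "duplicate")
})

test_that("scan equals brute force for every threshold", {
  for (s in 0:39) {
    cl <- gen_collection(s, m = (s %% 6L) + 1L, len_lo = 1L, len_hi = 40L,
                         sigma = if (s %% 3L) 4L else 2L)
    idx <- build_full_index_direct(cl)
    prev <- NULL
    for (tau in c(0L, 1L, 2L, 4L, 8L)) {
      got <- compute_overlaps(idx, tau)
      expect_same_overlaps(got, naive_overlaps(cl, tau),
                           info = paste("seed", s, "tau", tau))
      # monotonicity: larger tau keeps a subset of the records
      if (!is.null(prev)) {
        key <- function(d) paste(d$source_id, d$target_id, d$length)
        expect_true(all(key(got) %in% key(prev)),
                    info = paste("subset seed", s, "tau", tau))
      }
      prev <- got
    }
  }
})

test_that("planted overlaps in read sets are recovered", {
  for (s in 1:8) {
    reads <- gen_reads(s, genome_len = 80L, read_len = 15L, coverage = 4)
    idx <- build_full_index_direct(reads)
    for (tau in c(0L, 4L, 8L)) {
      got <- compute_overlaps(idx, tau)
      expect_same_overlaps(got, naive_overlaps(reads, tau),
                           info = paste("reads seed", s, "tau", tau))
    }
    # circular sampling at 4x coverage plants real overlaps
    expect_gt(nrow(compute_overlaps(idx, 4L)), 0L)
  }
})

test_that("push/pop work is bounded by the special-suffix count", {
  cl <- gen_reads(3, genome_len = 120L, read_len = 20L, coverage = 5)
  idx <- build_full_index_direct(cl)
  ov <- compute_overlaps(idx, 0L)
  expect_lte(attr(ov, "pushes"), sum(idx$xlcp))
  expect_lte(attr(ov, "pops"), attr(ov, "pushes"))
})

test_that("whole-string containments and duplicate strings are reported once", {
  # "GG" is both a full suffix of "TAGG" and a prefix of "GGA"; duplicates
  # report mutual whole-length overlaps, flagged as contained
  cl <- seq_collection(c("GG", "TAGG", "GGA", "GG"))
  idx <- build_full_index_direct(cl)
  for (tau in 0:2) {
    expect_same_overlaps(compute_overlaps(idx, tau), naive_overlaps(cl, tau),
                         info = paste("tau", tau))
  }
  ov <- compute_overlaps(idx, 1L)
  key <- paste(ov$source_id, ov$target_id)
  expect_identical(anyDuplicated(key), 0L)
  # source 1 ("TAGG") is wholly... source 0 ("GG") contained in targets 0/3
  expect_true(all(ov$contained[ov$source_id == 0L & ov$target_id == 3L]))
})
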