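# Maximal repeat scans against brute-force enumeration.

test_that("the worked example yields the published repeat sets", {
  idx <- build_full_index_direct(fig1_collection())
  t1 <- find_type1_repeats(idx)
  expect_identical(t1$length, c(1L, 2L, 3L, 5L))
  expect_identical(t1$row_lo, c(3L, 4L, 5L, 6L))
  expect_identical(t1$row_hi, rep(7L, 4L))
  expect_identical(t1$occ, c(5L, 4L, 3L, 2L))
  t2 <- find_type2_repeats(idx)
  expect_identical(t2$length, 5L)
  expect_identical(t2$occ, 2L)
  expect_identical(t2$row_lo, 6L)
  expect_identical(t2$row_hi, 7L)
})

test_that("single-string corner cases", {
  expect_identical(nrow(find_type1_repeats(build_full_index_direct(seq_collection("ab")))), 0L)
  aa <- build_full_index_direct(seq_collection("aa"))
  t1 <- find_type1_repeats(aa)
  expect_identical(t1$length, 1L); expect_identical(t1$occ, 2L)
  t2 <- find_type2_repeats(aa)
  expect_identical(t2$length, 1L); expect_identical(t2$occ, 2L)
  # "abab": scan agrees with brute force, whatever it decides
  abab <- seq_collection("abab")
  expect_same_repeats(find_type2_repeats(build_full_index_direct(abab)),
                      naive_repeats(abab, 2L))
})

test_that("scan equals brute force on random collections", {
  pushes_tot <- 0L; pops_tot <- 0L; n_tot <- 0L
  for (s in 0:39) {
    cl <- gen_collection(s, m = (s %% 6L) + 1L, len_lo = 1L, len_hi = 40L,
                         sigma = if (s %% 2L) 4L else 2L)
    idx <- build_full_index_direct(cl)
    t1 <- find_type1_repeats(idx)
    expect_same_repeats(t1, naive_repeats(cl, 1L), info = paste("T1 seed", s))
    t2 <- find_type2_repeats(idx)
    expect_same_repeats(t2, naive_repeats(cl, 2L), info = paste("T2 seed", s))
    # every Type 2 interval sits inside a Type 1 interval of equal length
    if (nrow(t2)) {
      for (q in seq_len(nrow(t2))) {
        hit <- t1$length == t2$length[q] & t1$row_lo <= t2$row_lo[q] &
          t1$row_hi >= t2$row_hi[q]
        expect_true(any(hit), info = paste("nesting seed", s))
      }
    }
    pushes_tot <- pushes_tot + attr(t1, "pushes")
    pops_tot <- pops_tot + attr(t1, "pops")
    n_tot <- n_tot + cl$n
  }
  # stack discipline: at most one push per scanned boundary, pops <= pushes
  expect_lte(pushes_tot, n_tot + 40L)
  expect_lte(pops_tot, pushes_tot)
})

test_that("length/occurrence/sequence filters act as documented", {
  coll <- fig1_collection()
  idx <- build_full_index_direct(coll)
  expect_identical(find_type1_repeats(idx, min_len = 2L)$length, c(2L, 3L, 5L))
  expect_identical(find_type1_repeats(idx, min_occ = 3L)$length, c(1L, 2L, 3L))

  t1 <- find_type1_repeats(idx)
  kept <- restrict_repeats_by_sequences(t1, idx$da, r_min = 2L)
  expect_identical(nrow(kept), 4L)      # all span both strings
  expect_true(all(kept$distinct_sequences == 2L))
  expect_identical(nrow(restrict_repeats_by_sequences(t1, idx$da, 3L)), 0L)
  # r_min = 1 is the identity
  expect_identical(restrict_repeats_by_sequences(t1, idx$da, 1L)[, 1:5],
                   t1[, 1:5])
  bad <- t1; bad$row_hi[1] <- 99L
  expect_error(restrict_repeats_by_sequences(bad, idx$da, 1L), "bounds")
})
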