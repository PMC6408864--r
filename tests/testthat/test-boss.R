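# BOSS de Bruijn graph construction.

test_that("the worked example's order-2 graph matches the derivation", {
  idx <- build_full_index_direct(fig1_collection())
  g <- build_boss(idx, 2L)
  expect_identical(g$N, 8L)
  expect_identical(intToUtf8(g$W), "bc$$acaabb")
  expect_identical(as.integer(g$last), c(1L,1L,1L,0L,0L,1L,1L,1L,1L,1L))
  expect_identical(as.integer(g$Wminus), c(1L,1L,1L,0L,1L,1L,1L,0L,1L,0L))
  expect_identical(sum(g$last), g$N)

  gc <- build_colored_boss(idx, 2L)
  # node "ab" (rows 4..7): entry 'a' comes from s2 only, 'c' from both
  expect_identical(gc$colors[[5L]], 1L)
  expect_identical(gc$colors[[6L]], c(0L, 1L))
  # single-string collection: all colors are {0}
  g1 <- build_colored_boss(build_full_index_direct(seq_collection("ACGT")), 2L)
  expect_true(all(vapply(g1$colors, identical, logical(1), 0L)))
})

test_that("order 1 groups rows by first symbol, large k degenerates", {
  idx <- build_full_index_direct(fig1_collection())
  g1 <- build_boss(idx, 1L)
  # sigma + m single-symbol groups: $_1, $_2, a, b, c
  expect_identical(g1$N, 5L)
  expect_error(build_boss(idx, 0L), "k must be")
  ghuge <- build_boss(idx, 50L)   # every distinct context is a singleton
  expect_identical(ghuge$N, 14L)
})

test_that("scan equals brute-force context grouping for k in 1,2,3,5", {
  for (s in 0:24) {
    cl <- gen_collection(s, m = (s %% 5L) + 1L, len_lo = 2L, len_hi = 40L)
    idx <- build_full_index_direct(cl)
    for (k in c(1L, 2L, 3L, 5L)) {
      g <- build_colored_boss(idx, k)
      expect_true(boss_equal_test(g, naive_boss(cl, k, colored = TRUE)),
                  info = paste("seed", s, "k", k))
      expect_identical(sum(g$last), g$N)
      gd <- build_boss(idx, k, drop_dollar = TRUE)
      expect_true(boss_equal_test(gd, naive_boss(cl, k, drop_dollar = TRUE)),
                  info = paste("drop seed", s, "k", k))
      # W- uniqueness: exactly one first-occurrence bit per
      # (symbol, (k-1)-range) pair
      km1 <- cumsum(pmax(idx$lcp < (k - 1L), seq_along(idx$lcp) == 1L))
      edge_rng <- km1[g$node_starts][g$edge_node]
      expect_identical(anyDuplicated(data.frame(edge_rng, g$W)[g$Wminus, ]), 0L)
      expect_identical(nrow(unique(data.frame(edge_rng, g$W))), sum(g$Wminus))
    }
  }
})

test_that("suffix lengths from the LF walk match the oracle", {
  for (s in c(2L, 9L)) {
    cl <- gen_collection(s, m = 4L, len_lo = 1L, len_hi = 30L)
    o <- naive_index(cl)
    expect_identical(suffix_lengths(o$bwt, o$da), o$content_len)
    bounded <- suffix_lengths(o$bwt, o$da, max_depth = 3L)
    known <- !is.na(bounded)
    expect_identical(bounded[known], o$content_len[known])
    expect_true(all(o$content_len[!known] > 3L))
  }
})

test_that("k-truncated early-stop merge yields the identical graph", {
  for (s in c(11L, 4L, 19L)) {
    cl <- gen_collection(s, m = (s %% 5L) + 2L, len_lo = 3L, len_hi = 30L)
    full <- build_full_index_direct(cl)
    for (k in c(1L, 3L)) {
      tr <- merge_prefix_order(cl, k = k, cfg = merge_config(),
                               mem_budget = 9L * 20L)  # forces several slices
      expect_lte(tr$stats$iterations, k + 1L)
      expect_true(boss_equal_test(build_colored_boss(tr, k),
                                  build_colored_boss(full, k)),
                  info = paste("seed", s, "k", k))
      expect_true(boss_equal_test(build_boss(tr, k, drop_dollar = TRUE),
                                  build_boss(full, k, drop_dollar = TRUE)),
                  info = paste("drop seed", s, "k", k))
    }
    # k beyond maxlcp: truncation never engages, graphs equal trivially
    kbig <- full$stats$maxlcp + 1L
    trb <- merge_prefix_order(cl, k = kbig, cfg = merge_config())
    expect_true(boss_equal_test(build_boss(trb, kbig), build_boss(full, kbig)))
  }
})
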