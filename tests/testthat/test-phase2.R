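# The Gap merge: initialization, single iterations, termination, range
# skipping, storage modes.

fig1_partials <- function() {
  list(build_partial_index(seq_collection("abcab"), 0L),
       build_partial_index(seq_collection("aabcabc"), 1L))
}

test_that("merge initialization lays out Z, B and the bucket table F", {
  st <- init_merge(fig1_partials(), merge_config())
  expect_identical(st$Zold, rep(c(1L, 2L), c(6L, 8L)))
  expect_identical(which(st$Bcur), c(1L, 15L))
  expect_identical(st$Bx, st$Bcur)
  f <- f_table(st)
  expect_identical(unname(f), c(1L, 2L, 3L, 8L, 12L))
  expect_identical(names(f), c("$0", "$1", "a", "b", "c"))
  expect_error(init_merge(fig1_partials(), merge_config(max_inputs = 1L)),
               "merge limit")
})

test_that("the first iterations permute Z and emit the lcp-0 pairs", {
  st <- init_merge(fig1_partials(), merge_config())
  gap_iteration(st)
  expect_identical(st$Zold,
                   c(1L, 2L, 1L, 1L, 2L, 2L, 2L, 1L, 1L, 2L, 2L, 1L, 2L, 2L))
  # after iteration 1 exactly the m end-marker rows are special
  expect_identical(which(st$Sold), 1:2)
  # new block bits at the slot/bucket starts
  expect_identical(which(st$Bcur), c(1L, 2L, 3L, 8L, 12L, 15L))
  gap_iteration(st)
  d <- pair_read(st$pair_paths[["0"]])
  expect_identical(d$pos, c(2, 3, 8, 12))
  # bits of rows 1, 2, 7: rows 1 and 2 are special end-marker rows
  expect_identical(d$bit, c(TRUE, TRUE, FALSE, FALSE))
  for (w in st$writers) pair_close(w)
})

test_that("run_merge terminates within maxlcp + 2 iterations", {
  st <- run_merge(fig1_partials(), merge_config())
  expect_lte(st$iterations, fig1_expected$maxlcp + 2L)
  expect_identical(st$max_emitted, fig1_expected$maxlcp)
  fin <- finalize_merge(st)
  expect_identical(fin$bwt, fig1_expected$bwt)
  expect_identical(fin$da, fig1_expected$da)

  # two copies of "ab": lcp rows 2..6 are 0,0,2,0,1
  dup <- seq_collection(c("ab", "ab"))
  parts <- lapply(1:2, function(i)
    build_partial_index(seq_collection("ab"), i - 1L))
  std <- run_merge(parts, merge_config())
  lm <- multiway_merge_pairs(std$pair_paths, std$n)
  expect_identical(lm$lcp, c(0L, 0L, 0L, 2L, 0L, 1L))
  o <- naive_index(dup)
  expect_identical(lm$lcp, o$lcp)
  expect_identical(finalize_merge(std)$bwt, o$bwt)

  # degenerate single string
  st1 <- run_merge(list(build_partial_index(seq_collection("a"), 0L)),
                   merge_config())
  expect_identical(finalize_merge(st1)$bwt, c(utf8ToInt("a"), SENTINEL))

  # merging {a} and {b} equals the oracle on {a, b}
  stab <- run_merge(list(build_partial_index(seq_collection("a"), 0L),
                         build_partial_index(seq_collection("b"), 1L)),
                    merge_config())
  oab <- naive_index(seq_collection(c("a", "b")))
  expect_identical(finalize_merge(stab)$bwt, oab$bwt)
})

test_that("source order is preserved and symbols conserved (Property 1)", {
  for (s in c(3L, 14L, 27L)) {
    cl <- gen_collection(s, m = 4L, len_lo = 5L, len_hi = 40L)
    sl <- lapply(1:4, function(i) {
      x <- seq_collection(cl$sequences[i]); attr(x, "first_global_id") <- i - 1L; x
    })
    parts <- lapply(sl, function(x) build_partial_index(x, attr(x, "first_global_id")))
    st <- run_merge(parts, merge_config())
    fin <- finalize_merge(st)
    for (j in seq_along(parts)) {
      sel <- st$Zold == j
      expect_identical(fin$bwt[sel], parts[[j]]$bwt,
                       info = paste("order seed", s, "src", j))
      expect_identical(fin$da[sel], parts[[j]]$da)
    }
  }
})

test_that("irrelevant-range skipping never changes the output", {
  # high-LCP repetitive input maximises frozen runs
  cl <- gen_repetitive(3, "ACG", 25, noise = 0.03, m = 4)
  o <- oracle_as_index(cl)
  r_skip <- bwt_index(cl, cfg = merge_config(t_threshold = 1),
                      force_merge = TRUE, force_slices = 2)
  r_none <- bwt_index(cl, cfg = merge_config(t_threshold = Inf),
                      force_merge = TRUE, force_slices = 2)
  expect_index_equal(r_skip, o)
  expect_index_equal(r_none, o)
  expect_gt(r_skip$stats$Ir, 0L)
  expect_identical(r_none$stats$Ir, 0L)

  # random collection: bit-identical outputs for t in {1, default, Inf}
  cl2 <- gen_collection(3, m = 4, len_lo = 450, len_hi = 550)
  o2 <- oracle_as_index(cl2)
  for (t in list(1, NULL, Inf)) {
    r <- bwt_index(cl2, cfg = merge_config(t_threshold = t),
                   force_merge = TRUE, force_slices = 2)
    expect_index_equal(r, o2, info = paste("t =", deparse(t)))
  }

  # small n below the default threshold: nothing stored
  rf <- bwt_index(fig1_collection(), cfg = merge_config(t_threshold = 256),
                  force_merge = TRUE)
  expect_identical(rf$stats$Ir, 0L)
})

test_that("terminal state at t = 1 coalesces the frozen runs to one range", {
  parts <- fig1_partials()
  st <- run_merge(parts, merge_config(t_threshold = 1))
  # after the final iteration every position is frozen; the stored entry
  # range spans the whole array (bit run 1..n+1, entries 1..n)
  expect_length(st$ranges, 1L)
  expect_identical(st$ranges[[1L]]$start, 1L)
  expect_identical(st$ranges[[1L]]$end, 14L)
})

test_that("storage modes are exchangeable bit for bit", {
  for (s in c(5L, 21L)) {
    cl <- gen_collection(s, m = 6L, len_lo = 10L, len_hi = 60L)
    o <- oracle_as_index(cl)
    for (mode in c("in_memory", "semi_external", "external")) {
      r <- bwt_index(cl, cfg = merge_config(mode), force_merge = TRUE,
                     force_slices = 3L)
      expect_index_equal(r, o, info = paste(mode, "seed", s))
    }
  }
})

test_that("merge rounds handle more inputs than the per-round limit", {
  cl <- gen_collection(77, m = 6, len_lo = 10, len_hi = 30)
  o <- oracle_as_index(cl)
  r <- bwt_index(cl, cfg = merge_config(max_inputs = 2L), force_slices = 6L)
  expect_index_equal(r, o)
  expect_identical(r$stats$rounds, 3L)
})
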