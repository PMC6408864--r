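# Sequence input and on-disk array formats.

test_that("FASTA and FASTQ collections load identically, qualities dropped", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">r1", "ACGT", ">r2", "A"), fa)
  coll <- read_collection(fa)
  expect_s3_class(coll, "seq_collection")
  expect_identical(coll$m, 2L)
  expect_identical(coll$n, 7L)
  expect_identical(coll$alphabet, utf8ToInt("ACGT"))

  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "A", "+", "F"), fq)
  collq <- read_collection(fq)
  expect_identical(collq$sequences, coll$sequences)

  # lowercase is uppercased; format sniffing by first byte
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "abcab", ">s2", "aabcabc"), fa2)
  coll2 <- read_collection(fa2)
  expect_identical(coll2$m, 2L)
  expect_identical(coll2$n, 14L)
  expect_identical(coll2$sequences[[1]], utf8ToInt("ABCAB"))
})

test_that("malformed collections are rejected", {
  expect_error(seq_collection(character(0)), "at least one")
  expect_error(seq_collection(c("AC", "")), "non-empty")
  expect_error(seq_collection("AC$G"), "end-marker")
  fa <- tempfile(); writeLines(c(">only-header"), fa)
  expect_error(read_collection(fa, format = "fasta"))
  empty <- tempfile(); file.create(empty)
  expect_error(read_collection(empty), "empty")
})

test_that("array files round-trip at every width and catch overflow", {
  coll <- fig1_collection()
  idx <- build_full_index_direct(coll)
  for (lb in c(1L, 2L, 4L, 8L)) for (db in c(1L, 2L, 4L)) {
    pre <- tempfile()
    af <- write_arrays(idx, pre, lcp_bytes = lb, da_bytes = db)
    expect_identical(file.size(af$paths$lcp), as.double(14L * lb))
    back <- read_arrays(pre, lcp_bytes = lb, da_bytes = db)
    expect_index_equal(back, idx)
  }
  # lcp file of the worked example starts with a zero byte at width 1
  pre <- tempfile()
  write_arrays(idx, pre, lcp_bytes = 1L)
  expect_identical(readBin(paste0(pre, ".lcp"), "raw", 1L), as.raw(0L))

  big <- idx
  big$lcp[5] <- 300L
  expect_error(write_arrays(big, tempfile(), lcp_bytes = 1L), "overflow")

  # random index round-trip
  cl <- gen_collection(7, m = 4, len_lo = 3, len_hi = 30)
  ridx <- build_full_index_direct(cl)
  pre <- tempfile()
  write_arrays(ridx, pre, lcp_bytes = 2L, da_bytes = 1L)
  expect_index_equal(read_arrays(pre, lcp_bytes = 2L, da_bytes = 1L), ridx)

  # truncated file on read
  bad <- readBin(paste0(pre, ".lcp"), "raw", 5L)
  writeBin(bad, paste0(pre, ".lcp"))
  expect_error(read_arrays(pre, lcp_bytes = 2L, da_bytes = 1L), "mis-sized|truncated")
})

test_that("pair files round-trip, enforce order, and carry the special bit", {
  p <- tempfile()
  w <- pair_open(p)
  pair_append(w, c(2, 3), c(TRUE, FALSE))
  expect_error(pair_append(w, 3, FALSE), "increase")
  pair_append(w, 2^40 + 5, TRUE)
  pair_close(w)
  d <- pair_read(p)
  expect_identical(d$pos, c(2, 3, 2^40 + 5))
  expect_identical(d$bit, c(TRUE, FALSE, TRUE))
  expect_identical(file.size(p), 24)

  w2 <- pair_open(tempfile())
  expect_error(pair_append(w2, 2^63, FALSE), "2\\^63")
  pair_close(w2)
})

test_that("the merge writes the expected pair files for the worked example", {
  coll <- fig1_collection()
  parts <- list(build_partial_index(seq_collection("abcab"), 0L),
                build_partial_index(seq_collection("aabcabc"), 1L))
  st <- run_merge(parts, merge_config())
  f0 <- pair_read(st$pair_paths[["0"]])
  expect_identical(f0$pos, c(2, 3, 8, 12))
  f5 <- pair_read(st$pair_paths[["5"]])
  expect_identical(f5$pos, 7)
  # rows 2..n covered exactly once across all files
  all_pos <- sort(unname(unlist(lapply(st$pair_paths, function(p) pair_read(p)$pos))))
  expect_identical(all_pos, as.double(2:coll$n))
  close_merge <- getFromNamespace("close_merge", "bwtmerge")
  close_merge(st)
})
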