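# On-disk array formats.
#
# All integers are little-endian and fixed width.  Layouts:
#   <prefix>.bwt   n bytes, end-markers stored as '$' (0x24)
#   <prefix>.lcp   n unsigned ints of width lcp_bytes in {1,2,4,8}
#   <prefix>.da    n unsigned ints of width da_bytes in {1,2,4}
#   <prefix>.xlcp  ceiling(n/8) bytes, bit (r-1) (LSB-first) <-> row r
#   <prefix>.pairs.<h>  LCP pair file: 8-byte little-endian unsigned
#       positions in increasing order; the most significant bit of each
#       record carries the special-suffix bit of row (position - 1).

# Little-endian byte packing via raw vectors (R's signed 32-bit integers
# cannot carry the 0x80000000 bit pattern, so u32 words go through raw).
u32_to_raw <- function(v) {
  v <- as.double(v)
  as.raw(rbind(v %% 256, v %/% 256 %% 256, v %/% 65536 %% 256,
               v %/% 16777216 %% 256))
}

raw_to_u32 <- function(r) {
  m <- matrix(as.integer(r), nrow = 4L)
  m[1L, ] + m[2L, ] * 256 + m[3L, ] * 65536 + m[4L, ] * 16777216
}

write_uints <- function(con, x, width) {
  x <- as.double(x)
  if (any(x < 0) || any(x >= 2^(8 * width)))
    stop(sprintf("value out of range for %d-byte unsigned field (first bad row: %d)",
                 width, which(x < 0 | x >= 2^(8 * width))[1L]))
  switch(as.character(width),
    "1" = writeBin(as.raw(x), con),
    "2" = writeBin(as.raw(rbind(x %% 256, x %/% 256)), con),
    "4" = writeBin(u32_to_raw(x), con),
    "8" = {
      lo <- u32_to_raw(x %% 2^32); hi <- u32_to_raw(x %/% 2^32)
      both <- raw(8L * length(x))
      sel <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                 length(x))
      both[sel] <- lo; both[!sel] <- hi
      writeBin(both, con)
    },
    stop("unsupported width: ", width))
  invisible(NULL)
}

read_uints <- function(con, count, width) {
  r <- readBin(con, "raw", n = count * width)
  if (length(r) < count * width) stop("truncated integer field")
  switch(as.character(width),
    "1" = as.double(as.integer(r)),
    "2" = { m <- matrix(as.integer(r), nrow = 2L); m[1L, ] + m[2L, ] * 256 },
    "4" = raw_to_u32(r),
    "8" = {
      m <- matrix(r, nrow = 8L)
      raw_to_u32(m[1:4, ]) + raw_to_u32(m[5:8, ]) * 2^32
    },
    stop("unsupported width: ", width))
}

write_bits <- function(path, bits) {
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  writeBin(packBits(c(as.logical(bits), rep(FALSE, pad)), type = "raw"), path)
}

read_bits <- function(path, n) {
  need <- ceiling(n / 8)
  raw <- readBin(path, "raw", n = need + 1L)
  if (length(raw) < need) stop("truncated bit file: ", path)
  as.logical(rawToBits(raw))[seq_len(n)]
}

array_paths <- function(prefix) {
  list(bwt = paste0(prefix, ".bwt"), lcp = paste0(prefix, ".lcp"),
       da = paste0(prefix, ".da"), xlcp = paste0(prefix, ".xlcp"))
}

#' Write a merged index to binary array files
#'
#' @param index a `merged_index` (fields `bwt`, `lcp`, `da`, `xlcp`).
#' @param prefix output path prefix; files `<prefix>.bwt/.lcp/.da/.xlcp`
#'   are created.
#' @param lcp_bytes width of LCP entries, one of 1, 2, 4, 8.
#' @param da_bytes width of document-array entries, one of 1, 2, 4.
#' @return an `array_files` descriptor (paths, widths, n), invisibly
#'   usable with [read_arrays()].
#' @export
write_arrays <- function(index, prefix, lcp_bytes = 4L, da_bytes = 4L) {
  stopifnot(lcp_bytes %in% c(1L, 2L, 4L, 8L), da_bytes %in% c(1L, 2L, 4L))
  p <- array_paths(prefix)
  if (any(index$lcp >= 2^(8 * lcp_bytes)))
    stop(sprintf("lcp width overflow: row %d holds %d >= 2^%d",
                 which(index$lcp >= 2^(8 * lcp_bytes))[1L],
                 max(index$lcp), 8L * lcp_bytes))
  if (any(index$da >= 2^(8 * da_bytes)))
    stop(sprintf("da width overflow at row %d",
                 which(index$da >= 2^(8 * da_bytes))[1L]))
  writeBin(as.raw(index$bwt), p$bwt)
  con <- file(p$lcp, "wb"); write_uints(con, index$lcp, lcp_bytes); close(con)
  con <- file(p$da, "wb");  write_uints(con, index$da,  da_bytes);  close(con)
  write_bits(p$xlcp, index$xlcp)
  structure(list(prefix = prefix, paths = p, lcp_bytes = lcp_bytes,
                 da_bytes = da_bytes, n = length(index$bwt)),
            class = "array_files")
}

#' Read a merged index back from binary array files
#'
#' Inverse of [write_arrays()]; `n` is inferred from the `.bwt` file size
#' and the other files are length-checked against it.  Summary statistics
#' (`maxlcp`, `avelcp`) are recomputed; merge statistics are `NA`.
#'
#' @param prefix path prefix used by [write_arrays()].
#' @param lcp_bytes,da_bytes the widths the files were written with.
#' @return a `merged_index`.
#' @export
read_arrays <- function(prefix, lcp_bytes = 4L, da_bytes = 4L) {
  p <- array_paths(prefix)
  for (f in p) if (!file.exists(f)) stop("missing array file: ", f)
  n <- file.size(p$bwt)
  bwt <- as.integer(readBin(p$bwt, "raw", n = n))
  for (nm in c("lcp", "da")) {
    w <- if (nm == "lcp") lcp_bytes else da_bytes
    if (file.size(p[[nm]]) != n * w)
      stop(sprintf("truncated or mis-sized %s file: expected %d bytes, found %d",
                   nm, n * w, file.size(p[[nm]])))
  }
  con <- file(p$lcp, "rb"); lcp <- read_uints(con, n, lcp_bytes); close(con)
  con <- file(p$da, "rb");  da  <- read_uints(con, n, da_bytes);  close(con)
  new_merged_index(bwt = bwt, lcp = as.integer(lcp), da = as.integer(da),
                   xlcp = read_bits(p$xlcp, n),
                   stats = list(maxlcp = as.integer(max(lcp)),
                                avelcp = mean(lcp),
                                iterations = NA_integer_, Ir = NA_integer_,
                                rounds = NA_integer_))
}

# ---- LCP pair files -------------------------------------------------------

#' Open an LCP pair file for appending records
#'
#' Records are `(position, special-bit)` with strictly increasing 1-based
#' positions in `[2, n]`; the bit is the special-suffix flag of row
#' `position - 1`.  The LCP value itself is implicit in the file (one file
#' per value `h`).
#'
#' @param path file path (conventionally `<prefix>.pairs.<h>`).
#' @return a writer object for [pair_append()] / [pair_close()].
#' @export
pair_open <- function(path) {
  env <- new.env(parent = emptyenv())
  env$con <- file(path, "wb")
  env$last <- 1
  env$path <- path
  class(env) <- "pair_writer"
  env
}

#' Append records to an LCP pair file
#' @param w a writer from [pair_open()].
#' @param pos numeric vector of positions (strictly increasing across the
#'   lifetime of the file, each `< 2^63`).
#' @param bit logical/0-1 vector of special-suffix bits of rows `pos - 1`.
#' @export
pair_append <- function(w, pos, bit) {
  if (length(pos) == 0L) return(invisible(w))
  pos <- as.double(pos)
  if (any(pos >= 2^63)) stop("pair position >= 2^63")
  if (any(diff(c(w$last, pos)) <= 0)) stop("pair positions must strictly increase")
  w$last <- pos[length(pos)]
  hi <- u32_to_raw(pos %/% 2^32 + as.double(bit) * 2^31)
  lo <- u32_to_raw(pos %% 2^32)
  both <- raw(8L * length(pos))
  sel <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), length(pos))
  both[sel] <- lo; both[!sel] <- hi
  writeBin(both, w$con)
  flush(w$con)
  invisible(w)
}

#' @rdname pair_append
#' @export
pair_close <- function(w) { close(w$con); invisible(w$path) }

#' Read an LCP pair file
#' @param path file path.
#' @return data.frame with `pos` (double) and `bit` (logical), in file
#'   order (increasing positions).
#' @export
pair_read <- function(path) {
  sz <- file.size(path)
  if (is.na(sz)) stop("missing pair file: ", path)
  if (sz %% 8 != 0) stop("truncated pair file: ", path)
  m <- matrix(readBin(path, "raw", n = sz), nrow = 8L)
  lo <- raw_to_u32(m[1:4, , drop = FALSE])
  hi <- raw_to_u32(m[5:8, , drop = FALSE])
  bit <- hi >= 2^31
  data.frame(pos = lo + (hi - as.double(bit) * 2^31) * 2^32, bit = bit)
}
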