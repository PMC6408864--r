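# Seeded synthetic collection generators.
#
# These produce the three regimes the pipeline is exercised on: generic
# random collections, read sets sampled from a random circular genome (so
# suffix-prefix overlaps are planted), and highly repetitive collections
# with large average LCP.  All are bit-for-bit reproducible from the seed;
# the caller's RNG state is saved and restored.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

gen_alphabet <- function(sigma) {
  stopifnot(sigma >= 2L, sigma <= 26L)
  base <- c("A", "C", "G", "T")
  chars <- if (sigma <= 4L) base[seq_len(sigma)]
           else c(base, setdiff(LETTERS, base))[seq_len(sigma)]
  vapply(chars, utf8ToInt, integer(1))
}

#' Generate a random sequence collection
#'
#' `m` i.i.d. uniform strings with lengths drawn uniformly from
#' `[len_lo, len_hi]` over the first `sigma` symbols of a DNA-first
#' alphabet (`A,C,G,T`, then other letters).
#'
#' @param seed integer seed (the collection is a pure function of it).
#' @param m number of strings.
#' @param len_lo,len_hi string length bounds.
#' @param sigma alphabet size (>= 2).
#' @return a [seq_collection()].
#' @export
gen_collection <- function(seed, m, len_lo, len_hi, sigma = 4L) {
  stopifnot(m >= 1L, len_lo >= 1L, len_hi >= len_lo)
  ab <- gen_alphabet(sigma)
  with_seed(seed, {
    lens <- sample(len_lo:len_hi, m, replace = TRUE)
    seq_collection(lapply(lens, function(L) sample(ab, L, replace = TRUE)))
  })
}

#' Generate reads from a random circular genome
#'
#' Samples `m = round(coverage * genome_len / read_len)` reads of length
#' `read_len` at uniform start positions on a random circular genome, so
#' that true suffix-prefix overlaps between reads are planted by
#' construction.
#'
#' @param seed integer seed.
#' @param genome_len circular genome length.
#' @param read_len read length (<= genome_len).
#' @param coverage target coverage; determines the number of reads.
#' @param sigma alphabet size.
#' @return a [seq_collection()].
#' @export
gen_reads <- function(seed, genome_len, read_len, coverage, sigma = 4L) {
  stopifnot(genome_len >= 2L, read_len >= 1L, read_len <= genome_len, coverage > 0)
  ab <- gen_alphabet(sigma)
  m <- as.integer(round(coverage * genome_len / read_len))
  stopifnot(m >= 1L)
  with_seed(seed, {
    genome <- sample(ab, genome_len, replace = TRUE)
    starts <- sample.int(genome_len, m, replace = TRUE)
    seq_collection(lapply(starts, function(s) {
      idx <- ((s - 1L + 0:(read_len - 1L)) %% genome_len) + 1L
      genome[idx]
    }))
  })
}

#' Generate a repetitive collection with high average LCP
#'
#' Each of `m` strings is `copies` concatenated copies of `unit`, with each
#' symbol substituted independently with probability `noise`.
#'
#' @param seed integer seed.
#' @param unit repeat unit (character scalar).
#' @param copies number of tandem copies per string.
#' @param noise per-symbol substitution probability in `[0, 1)`.
#' @param m number of strings.
#' @param sigma alphabet size used for substitutions.
#' @return a [seq_collection()].
#' @export
gen_repetitive <- function(seed, unit, copies, noise = 0, m = 2L, sigma = 4L) {
  stopifnot(copies >= 1L, noise >= 0, noise < 1, m >= 1L)
  u <- str_to_ints(toupper(unit))
  ab <- gen_alphabet(sigma)
  with_seed(seed, {
    seq_collection(lapply(seq_len(m), function(i) {
      s <- rep.int(u, copies)
      hit <- which(stats::runif(length(s)) < noise)
      if (length(hit)) s[hit] <- sample(ab, length(hit), replace = TRUE)
      s
    }))
  })
}
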