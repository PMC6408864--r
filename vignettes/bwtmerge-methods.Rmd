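---
title: "Merging partial BWTs: the algorithms behind bwtmerge"
author: "bwtmerge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging partial BWTs: the algorithms behind bwtmerge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwtmerge)
```

# The problem

Given a collection of `m` byte strings (DNA reads, contigs, proteins —
any bytes except the reserved `$`), bwtmerge computes four arrays over
the `n` suffixes of the collection, where each string carries its own
end-marker and end-markers rank below every symbol and among themselves
by string id ($_1 < ... < $_m$):

* **bwt** — the multi-string Burrows–Wheeler transform: the symbol
  preceding each suffix, with suffixes in lexicographic order;
* **lcp** — the length of the longest common prefix between
  lexicographically consecutive suffixes (row 1 stored as 0);
* **da** — the document array: the 0-based id of the string owning each
  row's suffix;
* **xlcp** — the *special suffix* bits: row `r` is special when its
  suffix, end-marker aside, is a prefix of the suffix at row `r + 1`
  (equivalently, its content length equals `lcp[r + 1]`).  Special
  suffixes are exactly the candidate suffix–prefix overlaps.

Three single-scan algorithms then consume the arrays: Type 1/2 maximal
repeats, all-pairs suffix–prefix overlaps above a threshold `tau`, and
the BOSS succinct representation of the order-`k` de Bruijn graph.

# Pipeline

## Phase 1 — split and sort

`split_collection()` cuts the collection greedily into contiguous slices
whose total content length fits `mem_budget / 9` — the working-space
ratio of an induced-sorting suffix sorter (8 bytes of suffix array plus
1 byte of text per input byte).  Strings are never split; an oversized
string forms its own slice.  Each slice is suffix-sorted by
`build_partial_index()` using a prefix-doubling construction over the
concatenation with per-string distinct end-marker ranks, which makes the
end-marker terminate every comparison and realises the
$_1 < ... < $_m$ convention exactly.  Any correct sorter could be
substituted; the contract is agreement with the comparison-sort oracle
(`naive_index()`), which sorts materialised suffix strings with a
byte-wise radix order and is kept entirely independent of the
prefix-doubling path.

When one slice suffices, `bwt_index()` takes the direct path
(`build_full_index_direct()`: one sort, Kasai's LCP algorithm, xlcp by
definition); its output is bit-identical to the merge path.

## Phase 2 — the iterative merge

`run_merge()` merges up to 128 partial BWTs (8 in semi-external mode,
matching 7-bit / 3-bit packed source ids; more inputs are merged in
greedy left-to-right rounds).  The state is the classic Gap machinery:

* `Zold` / `Znew` — the interleave vectors of source ids.  At iteration
  `h`, `Zold` holds the interleave sorted by length-`(h-1)` contexts and
  `Znew` still holds the one from iteration `h - 2`; the scan reads each
  source's next symbol in `Zold` order and writes the source id into the
  next free slot of that symbol's bucket.  The end-marker region is
  subdivided into `m` singleton slots keyed by global string id, which
  realises the end-marker order exactly and keeps `lcp = 0` at rows
  `2..m` without special cases.
* `B` (current and next copy) — block boundaries.  A next-copy bit is
  set at a write position whenever the writing block differs from the
  bucket's previous writing block; a bit newly set at iteration `h`
  means `lcp = h - 1` at that row.
* `Bx` — set when a row's LCP pair has been emitted.  During iteration
  `h`, a row with a current-copy `B` bit but no `Bx` bit gets the
  triplet `<row, h-2, S[row-1]>` appended to pair file `F_{h-2}` (rows
  arrive in increasing order because the scan is sequential).
* `Sold` / `Snew` — the special-suffix bits, double-buffered.  `Snew`
  starts each iteration as a copy of `Sold` and only gains bits: a write
  from a special source row marks its target special when the
  current-copy `B` bit after the target is still clear (the target's
  next LCP is then at least `h - 1`, and at most the target's content
  length, hence equal).  The `m` end-marker rows are forced special
  every iteration.  Double-buffering matters: updating a single array in
  place would let a bit set earlier in the same scan propagate again
  within that scan, one iteration early, where the lagging `B` copy can
  no longer distinguish "prefix of the next suffix" from "shares
  `h - 1` symbols with it" — a rare false positive that the
  end-of-iteration buffer discipline rules out by construction.

The merge stops when every row in `2..n` has emitted its pair, which
takes at most `maxlcp + 2` iterations; a guard at `n + 2` iterations
turns any logic fault into an error instead of a hang.

### Irrelevant ranges

Long frozen runs are the key optimisation: once rows freeze, later
iterations may skip them at `O(k + sigma)` bookkeeping cost.  After each
iteration the maximal runs of set `Bx` bits longer than a threshold `t`
(default `max(256, k + sigma)`) are stored with per-source read counts,
per-bucket write counts, and the in-range offset of each bucket's last
write; a skip advances the cursors, bucket slots and block counter by
those amounts.  Two timing rules make this exact, and both are enforced
deliberately (each one, when relaxed, corrupts output on repetitive
inputs):

1. a run of set `Bx` bits over positions `a..b` freezes *entries*
   `a..b-1` only — entry `b` still sits in an open block (its following
   boundary bit is not frozen) and its source id can change;
2. runs are detected from the `Bx` state at the *start* of the just
   finished iteration, so an entry is skipped only once both `Z` buffers
   have been rewritten since it froze; the skipped write is then
   guaranteed to be a no-op against the two-iteration-stale `Znew`.

The stored last-write offsets keep the block-change test exact for the
first write into each bucket after a skipped range.  Because skipping is
purely an optimisation, the package asserts bit-identical output across
`t` in `{1, default, Inf}` on random and highly repetitive collections.

### Storage regimes

One code path serves three residency regimes, selected by
`merge_config(mode = ...)`: `in_memory` keeps inputs and state in RAM;
`semi_external` keeps the state in RAM and streams the input BWT/DA
slice files in chunks; `external` additionally round-trips the packed
state through its disk layouts between iterations (one byte per `Z`
entry: 7-bit source id plus one `B` bit; `Bx` and `S` as packed bit
files; ranges as fixed-width records).  Range bookkeeping keeps a
transient n-byte buffer of last-read symbols in RAM in every regime.
The regimes are asserted exchangeable bit for bit.

## Phase 3 — LCP assembly

Each pair file `F_h` holds the rows with LCP value `h` in increasing
order; `multiway_merge_pairs()` merges them hierarchically with fan-in
`lambda` (default 256, so two rounds cover 65536 distinct values),
checks that positions cover `2..n` exactly once, and unpacks the
special bit of row `r - 1` from row `r`'s record.  Row `n`'s special bit
is set directly from the definition: its suffix has no successor and is
never a bare end-marker for non-empty strings, so the bit is 0.  Output
is asserted invariant under `lambda` in `{2, 3, 256}`.

# The scan applications

**Type 1 maximal repeats** (`find_type1_repeats()`): substrings
occurring at least twice whose every one-symbol extension occurs fewer
times.  The scan keeps a stack of `(start, lcp)` entries with a
constant-size character summary (one representative symbol plus a
"two distinct seen" flag); popping at a falling LCP emits the interval
when the summary shows two distinct preceding characters.  End-marker
occurrences in the bwt are pairwise distinct symbols, so each one counts
as a fresh character.  **Type 2** repeats (every extension at most once)
are strict LCP plateaus with pairwise distinct window symbols.

**Overlaps** (`compute_overlaps()`): per-sequence stacks of special
suffixes with common prefix above `tau`, maintained through `lcpStack`
and per-value top lists so pops touch only affected stacks.  A row whose
bwt symbol is an end-marker is prefixed by the whole sequence `da[row]`,
and each stack top is the longest live overlap onto it.  One case needs
care: a source suffix equal to the *entire* target sorts after the
target's row whenever its string id is larger, so it is not on any stack
yet; those rows form a contiguous duplicate-content run just below the
target row and are resolved by a bounded forward walk, using per-row
suffix lengths recovered from the bwt/da by an LF-mapping walk
(`suffix_lengths()`).  Ordered pairs are reported once each (the
longest overlap); self-overlaps must be proper, and a source wholly
contained in its target is flagged in the `contained` column.  Mutual
whole-length overlaps between duplicate strings are reported — a
convention, fixed identically in the scan and the brute-force oracle.

**BOSS** (`build_boss()` / `build_colored_boss()`): nodes are maximal
row ranges delimited by `lcp < k`; each node contributes its distinct
preceding symbols in ascending order (end-markers collapse to a single
`$`, ranked lowest — ascending order is what aligns the
first-occurrence rule with the lexicographically smallest incoming
k-mer), `last` marks each node's final edge, and `Wminus` marks the
first occurrence of a symbol within the enclosing `(k-1)`-range.
Ranges whose context is shorter than `k` (they contain an end-marker and
are always singletons) are kept by default; `drop_dollar` removes them,
identifying them via `suffix_lengths()` bounded at depth `k - 1` — the
lcp/xlcp arrays alone cannot always tell (an isolated short suffix can
have zero flanking LCPs and no xlcp bit).  The count of set `Wminus`
bits is *not* asserted equal to `N`: with end-marker nodes present it
equals the number of distinct (symbol, `(k-1)`-range) pairs, which is
the property the tests assert instead.  `drop_dollar` filters the full
graph, leaving the remaining `Wminus` bits as computed before dropping.

**Early stop** (`merge_prefix_order()`): to build only the order-`k`
graph, the merge stops after `k + 1` iterations — every LCP value below
`k` is then final and the symbols are sorted by length-`k` context;
unresolved LCP entries are stored as `k`.  The bounded LF walk used by
`drop_dollar` remains valid on these truncated arrays because rows with
content shorter than `k` are already in final position and all complete
blocks below them are stable.  Equality of the truncated-merge graph
with the full-merge graph is asserted on seeded collections.

# Synthetic data

Three seeded generators drive all tests; no external data is required.

* `gen_collection(seed, m, len_lo, len_hi, sigma)` — i.i.d. uniform
  strings.  The equivalence suites use `m <= 8`, lengths up to 64,
  `sigma = 4` (DNA-sized alphabet): large enough to hit every merge
  code path (multiple buckets, deep LCPs, duplicate strings at small
  alphabets) while keeping hundreds of full pipeline-versus-oracle runs
  cheap.
* `gen_reads(seed, genome_len, read_len, coverage)` — reads sampled at
  uniform positions from a random *circular* genome, so true
  suffix–prefix overlaps are planted by construction; used for the
  overlap suites (default test scale: genome 100, reads of 20 at 4–5x).
* `gen_repetitive(seed, unit, copies, noise, m)` — tandem repeats with
  per-symbol substitution noise, producing the high average-LCP regime
  where irrelevant-range skipping actually engages (hundreds of skips at
  `t = 1` on a 4-string, 90-symbol-unit fixture).

What these do not emulate: realistic read-error models and quality
strings, genome-scale repeat structure, or any input large enough to
exercise true out-of-core behaviour — the external mode here validates
layouts and algorithms at desk scale, not disk bandwidth.  Passing tests
therefore certify correctness of the arrays and scans, not performance
claims.

# Numerical and interface choices

* Sentinel on disk is the byte `0x24` (`$`), making DNA dumps readable;
  in memory it ranks below every byte, co-located sentinels by global
  string id.  Sequences containing `0x24` are rejected.
* String ids are 0-based everywhere on disk and in reports; rows and
  pair-file positions are 1-based.  Row 1's LCP is stored as 0 (files
  hold unsigned integers); scans re-introduce the `-1` boundary
  convention internally where it matters (final stack flushes).
* Array files are little-endian fixed width (`lcp` 1/2/4/8 bytes, `da`
  1/2/4, xlcp packed LSB-first); width overflow reports the offending
  row.  Pair records are 8 bytes with the special bit in the most
  significant bit.  All u32 packing goes through raw vectors because
  R's integers cannot carry the `0x80000000` pattern.
* FASTQ qualities are discarded; lowercase maps to uppercase; `N` is an
  ordinary symbol.
* Test problem sizes (chosen once for the study conditions): 200 random
  collections and 20 planted-overlap read sets for index equivalence
  across five configurations; 100 collections for the application
  oracles with `tau` in `{0,1,2,4,8}` and `k` in `{1,2,3,5}`; 20
  collections for the early-stop property.  The whole suite runs in a
  couple of minutes on one core.

# Limitations

* Everything is desk-scale R: the external regime demonstrates the
  layouts and the skipping logic, not multi-gigabyte throughput, and
  the oracles cap `n` at 1e5.
* No rank/select navigation over the BOSS arrays, no unitig extraction,
  no string-graph construction on top of the overlaps, and no
  suffix-array output.
* Pair files are written to disk in every storage regime (they are the
  phase 2/3 interface); only the Z/B/Bx/S state and input streaming
  distinguish the regimes.
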