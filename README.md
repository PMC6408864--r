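# bwtmerge

Multi-string BWT, LCP array, document array and special-suffix bits for a
sequence collection, built by merging partial transforms — with single-scan
algorithms for maximal repeats, all-pairs suffix–prefix overlaps and BOSS
de Bruijn graph construction.

## What it computes

For a collection of `m` strings (total length `n`, one end-marker per
string, end-markers ranked `$₁ < … < $ₘ` below every symbol), the package
produces:

* `bwt[1..n]` — the multi-string Burrows–Wheeler transform: row `i` holds
  the symbol preceding the `i`-th suffix in lexicographic order;
* `lcp[1..n]` — `lcp[i] = LCP(suffix at row i−1, suffix at row i)`;
* `da[1..n]` — the document array (0-based id of the string owning row `i`);
* `xlcp[1..n]` — bit `i` set when row `i`'s suffix, end-marker aside, is a
  prefix of row `i+1`'s suffix (a *special* suffix — the candidate
  suffix–prefix overlaps).

Construction follows the three-phase merge design: (1) split the
collection under a memory budget (`≈ budget/9` content bytes per slice)
and suffix-sort each slice into a partial BWT + DA; (2) merge the partial
BWTs with the iterative Gap procedure — the interleave vector `Z` is
refined once per iteration, block bits `B` discover each row's LCP value
`h−1` at iteration `h`, frozen runs are skipped as *irrelevant ranges*,
and every row's `⟨position, lcp, special-bit⟩` triplet is emitted to a
per-value pair file; (3) multiway-merge the pair files (fan-in λ) into the
final `lcp`/`xlcp` arrays.  In-memory, semi-external and external storage
regimes share one code path and produce bit-identical output.

On top of the arrays, one left-to-right scan each:

* **Type 1 / Type 2 maximal repeats** — substrings occurring ≥ 2 times
  whose every one-symbol extension occurs fewer times / at most once
  (LCP-interval stack, strict-plateau scan);
* **overlaps** — for ordered string pairs, the longest suffix–prefix
  overlap longer than a threshold `τ`, via per-sequence stacks of special
  suffixes (`O(n + #reported)` work);
* **BOSS** — edge symbols `W`, node delimiters `last` and first-incoming
  bits `W⁻` of the order-`k` de Bruijn graph (lexicographic variant),
  optionally colored by string of origin via `da`; the merge can stop
  after `k+1` iterations when only the graph is wanted.

Brute-force oracles (`naive_index`, `naive_repeats`, `naive_overlaps`,
`naive_boss`) and seeded generators (`gen_collection`, `gen_reads`,
`gen_repetitive`) make every component verifiable with no external data.

## Worked example

The two-string collection `{abcab, aabcabc}`:

```r
library(bwtmerge)
coll <- seq_collection(c("abcab", "aabcabc"))
idx <- bwt_index(coll, force_merge = TRUE, force_slices = 2)  # full merge path
idx
#> merged_index: n = 14 rows, m = 2 sequences
#>   maxlcp = 5, avelcp = 1.571, special rows = 10
#>   merge: 7 iteration(s), 0 skipped range(s), 1 round(s)
#>   bwt : bc$cc$aaaaabbb
#>   lcp : 0,0,0,1,2,3,5,0,1,2,4,0,1,3
#>   da  : 0,1,1,0,1,0,1,0,1,0,1,1,0,1
#>   xlcp: 11011101110110
```

The merged BWT interleaves the two partial BWTs `bc$aab` and `c$caaabb`;
the two `$` rows (3 and 6) are the whole-string suffixes; `maxlcp = 5` is
the shared prefix `abcab` of rows 6 and 7, and the merge needs
`maxlcp + 2 = 7` iterations.

```r
find_type2_repeats(idx)
#>   rtype length occ row_lo row_hi distinct_sequences
#> 1     2      5   2      6      7                 NA
```

`abcab` (length 5, rows 6–7) is the unique repeat whose every extension
occurs at most once.

```r
compute_overlaps(idx, tau = 1)
#>   source_id target_id length contained
#> 1         0         0      2     FALSE
#> 2         1         0      3     FALSE
```

The suffix `abc` of string 1 (`aabcabc`) overlaps the prefix of string 0
(`abcab`) by 3; `abcab` self-overlaps by 2 (`ab`).

```r
build_boss(idx, k = 2)
#> boss_graph: order k = 2, N = 8 nodes, 10 edges
#>   W     : bc$$acaabb
#>   last  : 1110011111
#>   Wminus: 1110111010
```

Eight distinct length-2 contexts; the node for `ab` (rows 4–7) has the
three in-edges `$`, `a`, `c`.

A command-line driver wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","bwtmerge.R",package="bwtmerge"))')" \
    index --input reads.fa --out-prefix out/reads
# subcommands: index, repeats, overlaps, dbg, selfcheck
```

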