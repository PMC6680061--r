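---
title: "Event-based depth of coverage: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based depth of coverage: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventcov)
```

## The model

Depth of coverage at reference position $j$ is the count of kept reads
whose alignment covers $j$. eventcov computes it by delta encoding rather
than pileup. Each read's CIGAR is decomposed into maximal
reference-contiguous *alignment blocks* $(\text{start}, \text{len})$:
`M`/`=`/`X` consume reference and cover it; `D` consumes reference and
covers it under the default policy (see below); `N` consumes reference but
never covers it and therefore splits blocks; `I`/`S`/`H`/`P` consume no
reference and never split a block. For each block the *events* vector gains
$+1$ at `start` and $-1$ at `start + len`, and coverage is the prefix sum

$$\mathrm{coverage}(j) \;=\; \sum_{m \le j} \mathrm{events}(m).$$

This turns an $O(\text{bases})$ pileup into an $O(\text{blocks} +
\text{span})$ computation.

### Partitioned execution and overlap correction

The coordinate-sorted read stream is cut into $n$ contiguous slices of
near-equal read count (differing by at most one). Slicing is deliberately
blind to contig boundaries — a slice may span contigs, and the genomic
extents of consecutive slices may intersect wherever a boundary falls
inside a pile of reads. Each slice independently produces per-contig
partial coverage vectors over its covered extent only (an offset plus a
dense array, never a whole-contig allocation).

For consecutive holders of a contig, an overlap of length
$l = \mathrm{end}(\text{left}) - \mathrm{start}(\text{right}) + 1$ (when
positive) is corrected by adding the left vector's $l$ tail values
elementwise to the right vector's head and deleting the left tail. The sum
of all values is unchanged, and the corrected right vector participates in
the comparison with the *next* partition. That sequential left-to-right
fold is the design answer to a case a pairwise-only correction cannot
handle: a single long block spanning three or more slices' extents. When
the left vector extends past the right vector's end, the right vector is
zero-padded to the overlap extent before the addition, so the surplus tail
cascades onward. The fold makes the final result identical — bitwise — to
a single-partition computation, which the test suite asserts for partition
counts 1–64, worker counts 1 and 4, and layouts containing 8 kb blocks at
64 partitions.

Workers are realized with forked processes (`parallel::mclapply`) over
slices; because the merge consumes partials strictly in partition order,
the worker count cannot affect the result, only the wall time.

## Result types

* **per-base** — one record per position; zero-depth positions omitted
  unless `include_zeros`.
* **blocks** — maximal runs of equal depth merged into intervals;
  expanding them reproduces per-base exactly (lossless).
* **windows** — the contig tiled from position 1 in fixed windows
  $[1,w], [w+1,2w], \dots$; each record is the arithmetic mean of per-base
  depth over the window's actual positions, zeros included. The terminal
  window may be shorter than $w$ and its mean is over its actual length.

Anchoring the window grid at position 1 is the only convention that needs
no extra parameter. Zero-coverage windows are emitted over the whole
reference — including contigs without any reads and tails beyond the last
read — because a tiling that silently drops empty windows is ambiguous for
downstream consumers; a mean over a fixed tile is well defined regardless
of read support.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `exclude_flags` | `0x704` | FLAG mask: UNMAP, SECONDARY, QCFAIL, DUP — the `samtools depth` default, so default outputs are comparable with the field's reference tool |
| `min_mapq` | 0 | minimum mapping quality, inclusive |
| `count_deletions` | `TRUE` | deleted (`D`) reference positions count as covered — pileup semantics, where a read spanning a deletion still supports depth there; `FALSE` splits blocks at deletions |
| `window` | — | window length in bases, required for windows output |
| `n_partitions` | 1 | read-stream slices; any value ≥ 1 gives identical results |
| `workers` | 1 | forked processes for the per-slice stage |
| `include_zeros` | `FALSE` | emit zero-depth positions/blocks (windows always include zeros in means) |

Coordinates are 1-based inclusive everywhere internally and in TSV/CSV
output; only the BED writer converts to 0-based half-open.

## Numerical and degenerate-input choices

* **Counter width.** Partial coverage values carry a `width` field:
  `"short"` while every value fits the compact 16-bit range (≤ 65,535),
  `"int"` beyond it, `"numeric"` past the 32-bit integer range. R has no
  16-bit storage type, so compactness is tracked as a checked contract
  rather than a memory layout: a cumulative sum or head addition that
  would overflow is recomputed in doubles. Wraparound is impossible by
  construction, and a 70,000-deep locus is asserted exact in the tests.
* **Negative prefix sums** in an events vector indicate corruption and
  raise an error rather than clamping.
* **Empty inputs** (header-only files, all-zero delta vectors, slices with
  no reads on a contig) flow through as empty objects, never as errors.
* **Sort checking.** The header `SO` tag is trusted when present; absent a
  tag, a monotonicity scan rejects the first out-of-order record. Unsorted
  input is always an explicit error, never a silent wrong answer.
* **Ties and ordering.** Output is sorted by (contig order in the file
  header, start); the partitioner is deterministic (first `N mod n` slices
  take the extra read), so byte-identical output across runs is a tested
  invariant.

## What the synthetic generator emulates — and what it does not

`fixture_spec()`/`generate_fixture()` produce coordinate-sorted SAM/BAM
with controllable contigs, read counts and lengths, a CIGAR grammar
(insertions, deletions, splice-like `N` skips, soft clips with
length ranges), flag fractions (duplicates, secondary, QC-fail, unmapped)
and a MAPQ range. Defaults emulate a small deduplicated short-read WGS
sample: 100 bp reads, uniform starts over two contigs, 5% duplicates,
2% secondary, 1% QC-fail, 2% unmapped, MAPQ uniform on 0–60. A long-read
profile (multi-kilobase reads, large skips) is used alongside it in the
acceptance suite. Coverage depends only on read layout, so the generator
deliberately omits base sequences, base qualities and error models; it
also draws read starts uniformly, so it does not reproduce GC bias,
mappability gaps, or paired-end insert structure. Passing tests therefore
demonstrate algorithmic correctness on arbitrary layouts — including
adversarial ones real data rarely shows, like 70,000-fold piles and
reads spanning dozens of partitions — but say nothing about
platform-specific artifacts of real libraries.

The correctness bar is the in-package brute-force pileup oracle: an
independent regex-based CIGAR walker that increments a per-base counter
for every covered position of every kept read. It shares no extraction
code with the pipeline (which parses CIGARs through
`GenomicAlignments`), so row-for-row agreement — asserted on 50 seeded
fixtures per run — is evidence, not tautology. During development the
nonzero rows were also spot-checked as identical against `samtools depth
-J` on a 300-read fixture.

## Problem sizes

The shipped suite and acceptance script use fixtures of 10–10,000 reads on
contigs of 0.6–60 kb, 50 oracle-equivalence fixtures per run, ten
partition/worker configurations on a 10,000-read file, and one
70,000-read single-locus pile — sizes chosen so the whole validation runs
comfortably on a laptop while still exercising multi-partition spans,
multi-contig layouts and counter promotion.

## Known limitations

* CRAM input is not supported; SAM text is converted to BAM internally
  before scanning.
* No region (`.bai`-indexed) restriction: files are always scanned fully.
* No GC/mappability normalization and no median-based window statistics —
  the windows output is the arithmetic mean only.
* The whole filtered read stream is held in memory; the target scale is
  desk-size experiments, not population cohorts.
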