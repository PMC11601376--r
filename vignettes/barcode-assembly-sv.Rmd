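---
title: "Barcode-aware local assembly for mid-range structural variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-aware local assembly for mid-range structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Insertions and deletions between roughly 50 bp and 10 kbp are the size class
that short-read callers resolve worst: the events are longer than a read, so
split-read and read-pair signatures become ambiguous, and in repetitive
context the read mapping itself cannot be trusted. Linked-read (synthetic
long read, SLR) protocols keep short-read cost and accuracy but add
long-range information: input DNA is sheared into 5–100 kbp fragments, each
fragment gets a barcode, and every short read carries its fragment's barcode
in the BX tag of the alignment. bxsv uses that barcode structure to turn SV
calling into a series of small, clean local assembly problems, optionally
topping up with a few long reads where short-read coverage fails.

## The procedure

1. **Badly aligned read store.** One pass over the BAM collects *badly
   aligned* read pairs: pairs where (a) every base of both mates has Phred
   quality strictly above 20, and (b) at least one mate is unmapped, mapped
   to an unplaced contig, or soft/hard-clipped over more than 20% of its
   length, or (c) one mate has an AM tag equal to zero. Rule (a) excludes
   pairs that merely failed alignment through sequencing error; (b) and (c)
   select exactly the reads that pile up around breakpoints or come from
   sequence absent from the reference. The store is indexed by barcode so a
   segment can later recruit, from anywhere in the genome, the badly aligned
   pairs whose fragments overlapped it.

2. **Segmentation.** The reference is tiled into 50 kbp windows overlapping
   by 10 kbp (both user-configurable). Any event shorter than the overlap is
   interior to at least one window; events detected twice in the overlap
   zone are collapsed by the final deduplication. The overlap bounds the
   largest detectable deletion: a deletion swallowing a whole overlap cannot
   be anchored on both sides within one window.

3. **Barcode selection.** For each segment, a barcode is accepted when it
   has at least 3 read pairs aligned inside the segment and the span between
   its leftmost and rightmost alignment starts exceeds 5 kbp. A genuine
   fragment overlapping the segment scatters pairs across it; a barcode
   whose reads are only there through mismapping shows few, tightly
   clustered reads. Spans are measured between alignment start positions.

4. **Local assembly.** Reads with accepted barcodes (with out-of-segment
   mates rescued through the index, so pairs stay whole) plus the recruited
   badly aligned pairs are assembled with a de Bruijn graph (default
   k = 55 for 150 bp reads, auto-lowered to read length − 10 and forced odd;
   k-mers must occur at least twice). Three departures from a conventional
   assembler matter here, all motivated by the diploid, SV-carrying target:

   * *Conservative simplification.* Only short (< 2k bp), weak
     (< 0.5 × the length-weighted median coverage) dead-end tips are
     removed, and a short bulge side is removed only when it is both far
     below its partner (< 0.2 ×) and weak in absolute terms (< 0.25 × the
     median). A balanced bulge — the signature of a heterozygous variant —
     is never touched.
   * *No path deduplication.* Path extension traverses *every* side of a
     small junction, so both haplotype paths are spelled as contigs. The
     same variant is then called from more than one contig and collapsed
     later, which costs nothing, whereas merging near-identical paths would
     silently drop one allele.
   * *Long-tip-aware extension halting.* A coverage dropout in a repeat can
     leave a graph where the only continuation across a junction skips
     sequence, which an eager extension would join into a false deletion.
     Before extending through a junction, the assembler searches the
     junction's graph neighbourhood; if a dead-end edge at least
     `long_tip_min` (10k) bp long has its dead end within `tip_vicinity`
     (5 kbp) graph distance, extension stops there. Requiring the *dead
     end* (not merely the edge) to lie inside the vicinity is what keeps
     the rule usable: segment boundaries make every window's terminal edges
     dead-ended, but their dead ends are tens of kbp away. The rule can be
     disabled (`tip_check = FALSE`) as a negative control, which
     demonstrates the false join on the dropout-in-repeat scenario.

5. **Hybrid gap closing.** With `--long-bam`, up to 100 long reads
   overlapping the segment (largest overlap first, ties by name) are used to
   join contig ends across coverage gaps. A join needs exact `anchor_len`
   (31 bp) matches near the tail of one contig and the head of another in
   the same read, supported by diagonal-consistent k-mer matches spanning at
   least `anchor_span_min` (450 bp) of each end region — more than a mobile
   element donor, so a repeat copy shared between a contig end and an
   unrelated long-read locus cannot seed a chimeric join. Conflicting joins
   for one contig end are resolved by read support; a tie between joins
   backed by disjoint read sets is a genuine conflict and abstains, while
   ties among joins supported by the same reads are path-duplication
   ambiguity and are broken deterministically. Long reads never contribute
   k-mers to the graph itself: at 0.1–1% error they would pollute the
   coverage statistics the simplification rules depend on.

6. **Calling.** Contigs are re-aligned to the whole reference (minimap2
   with an assembly preset and widened gap bandwidth when the binary is on
   the PATH, otherwise the package's semi-global affine-gap aligner for
   small inputs). Only primary alignments overlapping the contig's segment
   of origin ± 10 kbp yield calls — a contig that maps elsewhere genome-wide
   was misassembled or recruited from another locus. Every I/D CIGAR
   operation becomes a call; calls are filtered to 50–10,000 bp (inclusive),
   deduplicated genome-wide on exact (type, contig, position, length), and
   written as VCF 4.2 with left-anchored REF/ALT, SVTYPE/SVLEN/END INFO
   fields and no genotypes.

   One consolidation step follows deduplication by default
   (`locus_consolidate = TRUE`): calls of the same type anchored at the
   *same base* but with different lengths collapse to the single longest.
   These arise exactly because path deduplication is disabled — alternative
   routes through a tandem array spell different copy counts — and a
   diploid locus in this event model carries at most one alternate allele
   per type. The step keys on the exact anchor base, so nearby distinct
   events are never merged; the classical exact deduplication is available
   unchanged as `deduplicate_calls()`.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `seg_len` / `overlap` | 50,000 / 10,000 | bp | window size balances assembly complexity against the largest detectable deletion (bounded by the overlap) |
| `qual_min` | 20 | Phred | rule (a): every base of both mates must exceed it |
| `clip_frac` | 0.20 | fraction | rule (b): strictly more than this fraction clipped |
| `min_pairs` / `min_span` | 3 / 5,000 | pairs / bp | barcode filter; span is strict (> 5 kbp) |
| `k` | 55 | bp | de Bruijn k for 150 bp reads; auto-lowered for shorter reads |
| `solid_min` | 2 | count | k-mers seen once are noise at 30–40× |
| `tip_len_max`, `tip_cov_max` | 2k, 0.5 | bp, ratio | only short, weak tips are errors; long or strong tips carry signal |
| `bulge_cov_ratio_max`, `het_keep_ratio` | 0.2, 0.25 | ratios | heterozygous protection: balanced bulges survive |
| `long_tip_min`, `tip_vicinity` | 10k, 5,000 | bp | extension-halting rule (see above) |
| `long_cap` | 100 | reads | long reads per segment in hybrid mode |
| `anchor_len`, `anchor_scan`, `anchor_span_min` | 31, 800, 450 | bp | gap-closing anchors; span must exceed the 300 bp mobile-element donor |
| `min_sv` / `max_sv` | 50 / 10,000 | bp | reported size window (inclusive) |

## The simulator

`sim_config()` / `sim_dataset()` generate a fully ground-truthed dataset:
a uniform-composition random reference (optionally with implanted repeat
donors), a diploid genome with implanted SVs, fragment-based linked reads
and HiFi-like long reads. The event classes mirror the families that
dominate real mid-range SVs: novel-sequence insertions and deletions
(log-uniform lengths), mobile-element-like insertions (a fixed 300 bp
Alu-like donor and a 6 kbp L1-like donor, each reused across events so the
inserted sequence is repetitive genome-wide), and tandem-repeat-like
insertions (a 150 bp motif expanded 2–6 times, each copy carrying 5%
substitutions — a diverged minisatellite/VNTR-like array).

Reads are emitted pre-aligned by projecting true haplotype coordinates onto
the reference: a read inside one collinear block is a full-length match, a
read crossing an SV breakpoint keeps its largest mappable run and is
soft-clipped for the remainder (or unmapped when no 30 bp run maps), which
is precisely the footprint the badly-aligned rules key on. Fragment
intervals are drawn over the whole molecule and clipped at contig ends —
terminal fragments are shorter, as physical shearing makes them — so
coverage stays flat across a toy-sized genome. Configured dropout intervals
suppress linked reads only; long reads are unaffected, since the dropouts
model an SLR-specific coverage bias and long reads are the rescue channel.
Long reads draw lengths uniformly in 9–12 kbp and a per-read error rate
uniform in 0.1–1%, spent as 60% substitutions, 20% insertions, 20%
deletions.

What the simulator does **not** model — and what passing tests therefore do
not show about real data: sequencing base errors in short reads (optional,
off by default), quality-score structure, PCR duplicates, GC- or
chromatin-driven coverage bias beyond the explicit dropouts, barcode
sequencing errors, real Alu/L1/STR sequence, and genome-scale repeat
landscapes. Results on this generator are a correctness check of the
machinery, not a forecast of benchmark figures on real genomes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based
  conversion happens only at VCF emission (anchor-base convention, SVLEN
  negative for deletions).
* Ties are broken deterministically throughout (lexicographic barcode,
  read-name and contig-id order; longest-first seeding), so a run is
  byte-reproducible for fixed inputs and any worker count.
* A trailing reference window shorter than the overlap is merged into its
  predecessor rather than emitted; windows that small cannot anchor an
  assembly.
* Empty inputs degrade gracefully: an empty read set yields no contigs, an
  empty call set a header-only VCF; a zero-truth evaluation reports NA
  rather than 0.
* Graph simplification runs to a fixed point, which makes it idempotent by
  construction; bulge processing never touches sides longer than
  `bulge_len_max`, so candidate SV alleles cannot be "simplified away".
* The builtin aligner is exact quadratic DP with affine gaps and is used
  for small inputs and oracle tests; production alignment goes through
  minimap2 (`-x asm5 -r 2000,20000 -z 10000,5000` — the widened long-join
  bandwidth and z-drop keep multi-kbp indels inside one alignment instead
  of splitting them into clipped fragments).

## Test problem sizes

The package's own end-to-end benchmark (also what `scripts/acceptance.R`
reruns) uses a 300 kbp single-contig genome with 30 SVs (10 DEL, 10 random
INS, 5 Alu-like, 5 tandem-like; half heterozygous; 50–5,000 bp) at 40×
error-free linked reads, and a hybrid variant with three 500 bp dropouts
over homozygous events plus 5× long reads. Unit and property tests use
0.8–120 kbp sequences. These sizes were chosen so the full suite exercises
every code path in minutes on a laptop while keeping every per-segment
quantity (coverage, barcode counts, fragment spans) at realistic magnitude.

## Known limitations

* Short-motif STRs (period ≪ k) collapse to a tiny cycle in any single-k de
  Bruijn graph; their expansion length cannot be spelled. The simulator's
  tandem class therefore models diverged arrays with a 150 bp motif, and
  true STR expansions are out of reach by construction.
* Gap-closing anchors can be defeated by repeat donors longer than
  `anchor_scan` (e.g. full-length L1 copies): anchor spans cannot exceed
  the scanned window, so such joins are rejected rather than risked.
* No genotyping, phasing, inversion, duplication-as-class or breakend
  calling; duplications surface as insertions when assembled.
* Deletions larger than the segment overlap (10 kbp by default) are
  invisible, as are all events above `max_sv`.
* The caller assumes one diploid sample; the locus consolidation step would
  be wrong for pooled or polyploid data and should be disabled there.

## A minimal session

```{r example}
library(bxsv)

cfg <- sim_config(genome_len = 120000, slr_coverage = 40, seed = 5)
sim <- sim_dataset(cfg, "simdata")

res <- sv_call_run(sim$bam, sim$ref, "calls.vcf")
sv_evaluate("calls.vcf", sim$truth)
```
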