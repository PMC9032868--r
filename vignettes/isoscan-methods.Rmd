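---
title: "Methods: full-length transcriptome post-processing with isoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-length transcriptome post-processing with isoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscan)
```

## Scope and model of the data

`isoscan` post-processes full-length cDNA consensus reads (the circular
consensus output of single-molecule isoform sequencing) for species without
a reference genome. The input unit is a read or transcript over
`{A,C,G,T,N}`; every other IUPAC letter is mapped to `N` on input, because
all scanners in the package define their behaviour only over the five-letter
alphabet. All coordinates, in memory and on disk, are 1-based inclusive —
the convention shared by the 12-column tabular alignment format, GFF3 and
the microsatellite-reporting tools this package interoperates with.
Adopting a single convention end to end removes the most common source of
off-by-one errors in pipelines that mix 0- and 1-based systems.

A full-length read is modelled as

```
5'-primer + insert + poly(A) + reverseComplement(3'-primer)
```

and the package's stages mirror the standard long-read workflow: FLNC
classification, isoform clustering and collapse, then feature mining
(microsatellites, ORFs, lncRNAs, splicing events) on the non-redundant
transcript set.

## FLNC classification

A read is **full-length non-chimeric (FLNC)** when both terminal primers
are found, a poly(A) tail sits immediately inside the 3' primer, the
trimmed insert is long enough, and no *additional* primer occurrence lies
inside the insert. An interior primer copy is the signature of a cDNA
fusion artifact and demotes the read to **chimeric**; any other failure
gives **non-full-length**. Classification is total — no read errors out.

Parameter choices (all exposed in `flnc_params()`):

* `max_primer_mismatch = 3` edits. Primer hits are located by edit
  distance (substitutions *and* indels) because indels are the dominant
  error mode of long reads; a Hamming matcher would miss shifted primers.
  Among hits the smallest distance wins, with ties resolved to the
  outermost position.
* `search_window = 100` bp: terminal primers must begin within this
  distance of the read end, so an interior primer can never be mistaken
  for a terminal one.
* `min_polya_len = 20` bp with `max_polya_nonA_frac = 0.1`. The tail is
  the longest suffix of the region 5' of the 3'-primer hit whose non-A
  fraction stays within the tolerance; this accepts tails with occasional
  interrupting bases, which real libraries show.
* `min_insert_len = 50` bp, mirroring the usual short-fragment floor of
  long-read preprocessing.

If the primer pair is found in the flipped arrangement the read is
reverse-complemented before reporting, so downstream stages always see
sense-strand inserts. The classifier recovers the planted truth label for
every synthetic read whose primers carry no more planted errors than
`max_primer_mismatch` — with error-free plants, recovery is exact, which
is what the recovery tests assert.

## Isoform clustering and collapse

Consensus-building from FLNC reads is approximated by greedy incremental
identity clustering in the style of CD-HIT-EST: sequences are sorted by
decreasing length (ties by id in the C locale, which makes the result
independent of input order), and each sequence joins the first existing
cluster whose *founder* it matches at

* global-alignment identity ≥ `identity_threshold` (default 0.99), where
  identity = matches / alignment columns under match 2, mismatch −3, gap
  open 5, gap extend 2, and
* length coverage of the shorter sequence ≥ `min_coverage` (default 0.9).
  Because the alignment is end-to-end, coverage of the shorter sequence
  reduces to the length ratio shorter/longer, and that ratio is what the
  test uses.

The 0.99 default matches the accuracy regime of polished consensus reads;
both knobs are exposed because redundancy-collapse cutoffs are a study
choice, not a property of the algorithm. Collapse keeps the longest member
of each cluster (ties by id), which under the length-descending insertion
order is the founder itself. An optional shared-11-mer prescreen skips
alignments between candidates that share no 11-mer at all; such a pair
cannot reach any high identity threshold, so the prescreen provably leaves
results unchanged (and the suite checks filter-on equals filter-off).

This stage is a documented, testable stand-in for iterative clustering
plus consensus polishing; it selects representatives rather than computing
quality-weighted consensus sequences.

## Microsatellite (SSR) mining

The scanner reports every maximal perfect tandem repeat of a 1–6 bp unit
meeting the per-unit-size minimum repeat counts `10, 6, 5, 5, 5, 5`
(mono- through hexanucleotide) — the default definition file of the
standard microsatellite search tool. Motifs are *primitive*: a poly-A run
is motif `A`, never `AA`, so a run qualifying at several unit sizes is
reported exactly once, at its smallest primitive unit. Spans cover whole
units only; `N` terminates any run. Two hits separated by at most 100 bp
(`max_compound_interruption`) share a compound-SSR group id.

The implementation derives maximal runs from a vectorised periodicity
comparison (`s[i] == s[i+u]`), which is linear per unit size; the test
suite proves it equivalent, hit for hit, to an independent brute-force
oracle built on greedy backreference regular expressions over 100 random
10-kb sequences. Density reports aggregate by *canonical* motif — the
lexicographic minimum over all rotations of the motif and of its reverse
complement — so `GA`, `AG`, `TC` and `CT` count as one class, per the
usual density-plot convention.

## ORF prediction and completeness classes

For each transcript all open reading frames are enumerated in three frames
of both strands (start `ATG`, stops `TAA/TAG/TGA`, standard code, no
alternative initiators). Transcript ends open the partial classes: a
leading frame region with a downstream stop but no start codon is
`5prime_partial`, a started region running off the 3' end without a stop
is `3prime_partial`, a frame with neither boundary is `internal`, and
`complete` ORFs have both. Each inter-stop region contributes at most one
candidate (from its first `ATG`, or from the frame start for the leading
region).

The best ORF is the one with the longest *nucleotide span*, stop codon
included — this makes a complete ORF outrank a partial one of equal coding
length, which is the behaviour the remaining tie-breaks (complete first,
then forward strand, then smaller start) only have to refine. The
`min_aa = 100` default follows the long-ORF convention of transcriptome
CDS predictors. No hexamer/Markov coding-likelihood rescoring is applied;
this is deliberately the transparent longest-ORF criterion, and the test
suite holds it equal to an exhaustive six-frame enumeration oracle on 500
random kilobase sequences, including lengths not divisible by three.

Length-distribution reports bin *complete* ORFs only (`≤ 1000`,
`1000–2000`, `> 2000` amino acids), since completeness is what makes a
protein-length histogram interpretable.

## lncRNA screening

Long non-coding RNA calling is a consensus operation: a transcript enters
the lncRNA set when its length exceeds 200 nt and **every** supplied
coding-potential method voted non-coding. External predictor outputs are
ingested as two-column tables (id, `coding`/`noncoding`); a built-in
ORF-evidence classifier is provided as one more votable method. The
built-in rule calls a transcript non-coding when it has no start-anchored
ORF at all, or when its best ORF is both short (< 100 aa) and covers less
than half the transcript. Frames without an `ATG` are not coding evidence
— otherwise every transcript would carry a full-length `internal` "ORF"
and nothing would ever be non-coding.

The length rule is applied strictly (`> 200 nt`); whether a given
screen used `>` or `≥` is rarely stated, so the operator is a parameter
(`strict`). Venn-region counts are computed over the raw method sets (the
length filter applies to the consensus set only), and the disjoint regions
provably sum to the union of the method sets.

## Alternative-splicing candidate events

Between two transcripts, the signature of a candidate splicing event is a
*pair* of same-orientation high-scoring segment pairs (HSPs) that are
contiguous on one sequence while flanking a long unaligned gap on the
other. The calling rules, each a parameter of `as_criteria()`:

* contiguous side: overlap **strictly less than 5 bp**; separation is
  bounded by the same tolerance (the rule as commonly stated bounds only overlap,
  but alignment-boundary wobble produces small separations just as often,
  so the tolerance is applied symmetrically);
* gapped side: gap **strictly greater than 100 bp**, with both gap
  boundaries **at least 100 bp** (inclusive) from the sequence ends;
* "almost completely aligned" is operationalised as the two HSPs jointly
  covering ≥ 80% of the contiguous sequence (`min_joint_coverage`,
  disable with `NA`) — a qualitative description turned into a
  testable threshold;
* the rule is evaluated over *every* pair of HSPs, not only when exactly
  two exist.

HSPs are produced by greedy iterated local alignment (same scoring scheme
as clustering): the best local alignment across both orientations is
taken, split into separate HSPs at internal indel runs of ≥ 10 bp —
a dynamic-programming aligner happily bridges a multi-hundred-bp deletion
that a database-search tool would report as two HSPs, and the split
restores that geometry — then the footprint is masked with `N` (scored −6
against everything, so masked regions cannot re-align) and the search
repeats. The 10-bp split threshold sits well above alignment wobble and
well below the 100-bp gap rule, so it cannot blur the calling boundary.
The boundary tests sweep gap length, end distance and overlap through
`{99,100,101}` / `{4,5,6}` and require event presence to flip exactly at
the thresholds.

All-vs-all scans align each unordered pair once, with ids in canonical
order taking the query/subject roles, so the scan is symmetric by
construction. A shared-11-mer prescreen (default: at least 5 shared
11-mers) skips pairs with no detectable homology; unlike the clustering
prescreen this one is a heuristic speed/sensitivity trade-off, and it can
be disabled.

## Synthetic data: what it emulates, and what it does not

The generator (`make_reads()`) emulates the *structure* of a full-length
cDNA library at the scale typical of such datasets: log-normal insert
lengths centred at 2 kb (sd 800 bp, clamped to 200 bp–12 kb), the
primer/poly(A) read layout above, a class mixture of 80% FLNC / 12%
missing-primer / 5% chimeric reads (remainder: missing poly(A)), poly(A)
tails geometric around 30 bp above a 20-bp floor with up to two non-A
interruptions, and planted SSR motifs, complete ORFs, near-identical
isoform families (`make_cluster_families()`) and deletion pairs
(`make_as_pair()`) recorded in an exact truth table. Default primers are
the common template-switching adapter pair; they are configurable because
published studies rarely print their primer sequences.

It deliberately does **not** simulate instrument error profiles,
subread-level consensus building, quality-score realism, expression-level
abundance skew, or biological splice-graph structure. Passing recovery
tests on these fixtures therefore demonstrates the correctness of the
*rules* — classification logic, scanner semantics, boundary arithmetic —
not sensitivity on error-rich real data. Sizes used by the shipped tests
(1,000 reads for classification recovery, 5 families × 4 members for
clustering, 10 planted deletion pairs among 50 decoys for splicing
recovery, 100 × 10 kb and 500 × 1 kb for the scanner oracles) were chosen
as the smallest sets that exercise every rule boundary while keeping the
whole suite comfortably interactive.

## Numerical conventions and degenerate inputs

* Percentages round half away from zero (`round_half_up()`), the
  convention of count tables in the genomics literature; base R's half-to-even would
  disagree on boundary values. Recomputed percentages are reported even
  where a source table's printed rounding differs, and exhaustive
  category percentages are only guaranteed to sum to 100 within ±0.05 per
  category.
* Empty inputs return empty, correctly-typed results (empty cluster sets,
  zero-count reports); they are not errors. Denominators of zero are
  errors.
* All randomness flows from the session RNG; every pipeline entry point
  that simulates takes an explicit seed, and byte-identical outputs under
  a fixed seed are part of the test contract.

## Known limitations

* Clustering compares members to cluster *founders* only (single-linkage
  to the representative), like the tool it emulates; chains of
  just-sub-threshold members can split families that a full-linkage
  method would join.
* The HSP search is greedy; after masking, a weaker overlapping alignment
  is not revisited. Repeat-rich transcripts can therefore yield fewer
  HSPs than an exhaustive search would.
* The built-in coding-potential rule is ORF evidence only — no codon
  usage, no homology — and is meant as one conservative vote alongside
  external predictors, not as their replacement.
* Splicing events are *candidates*: without a genome no splice-site
  validation is possible, and event types (exon skip, intron retention,
  alternative donors/acceptors) are not classified.
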