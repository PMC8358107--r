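---
title: "Locating a transgene insertion in a repetitive genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating a transgene insertion in a repetitive genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insertlocus)
```

## The problem

A single-copy T-DNA insertion in a crop genome is easy to *detect* and
surprisingly hard to *place*. Junction fragments recovered by TAIL-PCR or
short-read sequencing give a few hundred base pairs of host flank, but
when the insertion lands in an LTR-retrotransposon-rich region that flank
may match hundreds of near-identical positions at more than 90% identity.
`insertlocus` implements the combined strategy that resolves this: an F2
segregation/linkage arm that narrows the locus to a marker-bounded
chromosomal interval, a long-read arm that detects host–vector chimeric
("mixed") reads and clusters their junction breakpoints, and an
integration step in which the genetic interval vetoes repeat-induced
spurious clusters. Two companion modules quantify *why* the combination
is needed (the flank-specificity profile) and close the loop to a
diagnostic assay (in-silico PCR of event-specific primers).

Everything is testable without external data because the package ships a
seeded simulator whose truth record (chromosome, insertion position,
orientation) is known by construction.

## The sequencing arm

Reads are aligned to a combined reference that simply concatenates the
host chromosomes and the vector record, each tagged with its provenance
(`build_combined_reference()`). Alignment is done in-package by
seed-and-extend: exact k-mer seeds (k = 15 for short reads, 13 for long
reads) are clustered by diagonal, chains are extended outward by exact
matching, and each chained region is re-scored with a banded global
alignment (match +2, mismatch −3, linear gap −3) to obtain an identity.
All chains above the length and identity floors are reported, so a read
lying in a dispersed repeat deliberately yields one segment per similar
copy — downstream logic, not the aligner, decides which copy is real.
Long-read mode accepts identities down to 0.70 because a 10–15% error
rate puts even a correctly placed read near 0.85 identity; short-read
mode uses 0.90.

Classification follows the partition host-only / vector-only / mixed /
unmapped. A read is *mixed* when it carries a host anchor and a vector
anchor (defaults 200 bp each in long mode, 30 bp in short mode — the
short-mode floor is permissive because genuine junction fragments can
carry anchors as short as ~50 bp) occupying read intervals that overlap
by at most 20 bp.

Junction extraction walks outward from the read's main vector anchor and
selects, on each side, the *adjacent* host anchor (read-coordinate gap at
most 500 bp), preferring the longest candidate. This choice matters in
repetitive genomes: a mixed read typically has several host segments
(one per repeat copy), but only the one abutting the vector on the read
is junction evidence, and among near-ties the anchor reaching furthest
into unique sequence is the informative one. The breakpoint is the host
coordinate at the read boundary facing the vector, 1-based, with
microhomology resolved by the greedy leftward extension of the host
chain. The junction side is read off the abutting vector coordinate:
left half of the vector record = LB, right half = RB; a reverse-oriented
insert therefore presents its RB at the genomic left, which is the
biologically correct label. Breakpoints are clustered per chromosome by
single linkage with a 100-bp gap; the cluster representative is the
median breakpoint, and the reported interval is the envelope of the
supporting reads' host anchors, which by construction contains every
member breakpoint (and in practice the truth position, since LB anchors
end at the insertion and RB anchors start just after it).

The long-read quality model and the Q7 filter deserve a note: each
simulated read draws one mean-quality level (10% of reads in [3, 7),
the rest in [9, 25]) and per-base scores are that level plus ±2 integer
jitter. Mean quality is the arithmetic mean of Phred scores — the common
basecaller summary — not an error-probability average, and the filter
simply thresholds it at 7.

## The genetic-mapping arm

Transgene presence/absence in an F2 is scored from a presence column
standing in for a PCR assay. `chi_square_segregation()` tests the counts
against 3:1 with the Yates continuity correction on by default; the
correction is the default because the worked 266:87 example reproduces
the published statistic (0.008) only with it (uncorrected Pearson gives
0.024). The critical value is computed from `qchisq()`, never
hard-coded. `infer_locus_count()` runs the same machinery against 3:1
and 15:1 and answers one locus / two loci / indeterminate.

Linkage uses the strict cosegregation rule: a marker is linked when
*every* verified non-transgenic plant is homozygous for the
non-transgenic parent's allele; any plant carrying at least one
transgenic-parent allele is a recombinant (heterozygotes count as
recombinants; missing genotypes are excluded from the count, not
scored). A relaxed `max_recombinants` threshold exists but is off by
default. The interval is then bounded by the nearest markers flanking
the linked block that each show at least one recombinant, and its size
is reported as `end − start` — deliberately matching the convention of
published SSR interval reports rather than the `end − start + 1` base
count; the off-by-one is documented on `genomic_interval()`.

## Flank specificity

`find_flank_matches()` reports every genomic locus aligning to the flank
above 90% identity without any single indel run over 100 bp; identity is
counted over the full flank's alignment columns, so partial copies score
low, and the gap rule excludes copies fragmented by long deletions.
`extend_and_profile()` then extends each match outward — leftward for an
LB flank, rightward for RB, mirrored on minus-strand matches — in 0.5-kb
steps up to 7.5 kb, truncating at chromosome ends, and compares all
extended sequences pairwise. Two sequences are "similar" when the banded
global alignment identity, with matches counted over the shorter
sequence, reaches 0.90; the shorter-sequence denominator is a
documented, configurable choice since ">90%" alone does not fix one.
`n_similar` counts sequences with at least one partner and `max_hits`
the largest partner count of any single sequence (the per-sequence
reading of "maximum hit number"; a per-position reading is also
defensible, which is why the definition is isolated in one function).
`minimal_unique_extension()` returns the smallest profiled length at
which `max_hits ≤ 1` (and, when a focal locus is tracked, the focal
sequence has no partner). On exact-repeat fixtures embedded in random
background the counts are provably non-increasing with extension length,
which the tests assert alongside agreement with an all-pairs full-DP
oracle. One numerical caveat: globally aligned *random* DNA attains
roughly 50–55% identity under this scoring, so uniqueness emerges not
exactly at the repeat-unit length but within a step or two beyond it;
the corresponding test allows that lag.

## Integration and the final call

`intersect_evidence()` keeps only clusters whose representative lies in
the genetic interval (recording each rejection), and `call_insertion()`
selects the surviving cluster with the highest distinct-read support,
breaking ties by most junction sides present, then chromosome, then
leftmost coordinate. Long-read mixed reads define the call; short-read
junction pairs only corroborate. A run reports conservation:
`reads_in = q7_dropped + host_only + vector_only + mixed + unmapped`.
With zero surviving clusters the result is an explicit no-call object
carrying the stage counts, not an empty value. LB/RB breakpoint
estimates are clustered together (they differ by 1 bp on a clean event);
had they disagreed by more than the 100-bp link distance they would
surface as separate clusters rather than being averaged.

## What the simulator emulates, and what it does not

The generator produces: a host genome of i.i.d. background carrying one
family of dispersed repeat copies derived from a single master unit with
independent per-copy substitutions (default ten 2-kb copies at 1%
divergence in 50 kb); a clean insertion — no host deletion, no filler,
no vector truncation, matching a transformant with no detected
rearrangements — of an 8-kb construct; 150-bp paired-end reads with
substitution-only errors; long reads with normal lengths, mixed
substitution/insertion/deletion errors (50/25/25 of the total rate, with
the realistic long-read regime at 5–15%) and the quality model above;
and an F2 population built from two independently recombined gametes per
plant under the Haldane map function, so marker–transgene linkage decays
with distance and segregation converges to 3:1.

It does not emulate: real LTR family structure (nested, truncated,
divergently aged copies), coverage or GC bias, chimeric library
artifacts, basecalling from raw signal, segregation distortion, or
dominant/ambiguous marker systems. Passing tests therefore demonstrate
the pipeline's logic — classification partitions, breakpoint recovery
within ±10 bp on clean events, interval coverage of the truth — under a
*favourable but honest* model of the data, not performance on a real
maize-scale genome, where flank ambiguity is far worse (hundreds of
matches) and only the relative shapes of the profiles carry over.

## Problem sizes and numeric choices

Simulated studies in the tests and the acceptance script use a 50-kb
single-chromosome host, ten 2-kb repeat copies, an 8-kb construct,
long reads of mean 15 kb at 10x coverage and 10% error, F2 populations
of 300 plants genotyped on a 10-kb marker grid plus one marker
cosegregating with the locus (100 bp away), and 10 replicate seeds.
These sizes were chosen so a replicate exercises every stage — repeats
ambiguous enough to mislead a naive caller, reads long enough to span
the construct — while a full run stays comfortably on a laptop. The
genetic scale is compressed to 2×10⁻⁶ Morgans/bp so that a 10-kb marker
spacing behaves like a realistic few-centimorgan panel on a toy
chromosome; on a real genome the default 10⁻⁸ (1 cM/Mb) applies. The
strict cosegregation rule only identifies a linked marker when one lies
within a fraction of a centimorgan of the locus — with ~75 non-transgenic
plants, even 1 cM of separation yields an expected 1.5 recombinants —
which is why the fixture panel includes a cosegregating marker, just as
real BSA panels are densified around the locus until one cosegregates.

Degenerate inputs are handled explicitly: empty segment lists classify
as unmapped; a single flank match profiles as trivially unique; clusters
with equal support tie-break deterministically; alignment bands widen
with the observed seed-diagonal spread so indel drift cannot push a true
alignment off-band; and interval delineation at a map edge reports an
open-ended side bounded by the chromosome end when lengths are known.

## Known limitations

The aligner is exact-seed based: a region whose every k-mer is disrupted
(error bursts, very short anchors) produces no seed and no segment. The
breakpoint convention resolves microhomology leftmost, so LB/RB
breakpoints on a microhomologous junction can each be biased by its
length. Flank profiling is all-pairs quadratic and meant for the tens of
matches a desk-scale fixture produces, not for hundreds. The caller
models exactly one insertion; multi-locus events violate its assumptions
(the segregation arm would flag them via `infer_locus_count()` first).
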