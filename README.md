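# insertlocus

Locating a single-copy T-DNA insertion in a large, repetitive host
genome by combining sequencing and genetic-mapping evidence.

## The problem

Event characterization of a transgenic line needs the insertion's
chromosomal position, but the few hundred base pairs of host flank
recovered from a junction (by TAIL-PCR or short reads) are often useless
on their own: when the insertion sits in an LTR-retrotransposon-rich
region, the flank matches hundreds of genomic positions at >90%
identity. `insertlocus` is for molecular geneticists and GMO-safety
analysts facing exactly this situation. It implements:

- **Chimeric-read detection** — reads aligned to a combined host+vector
  reference; a read with a host anchor and a vector anchor on disjoint
  read intervals is *mixed* (classes: host-only / vector-only / mixed /
  unmapped, a partition). Long reads pass a mean-Q ≥ 7 filter first.
  Junction breakpoints from mixed reads are clustered (single linkage,
  100-bp gap; representative = median) and the call interval is the
  envelope of the supporting host anchors.
- **Segregation mapping** — an F2 scored for transgene presence is
  tested against 3:1 with the continuity-corrected chi-square
  χ² = Σ(|O−E|−½)²/E vs χ²₀.₀₅,₁ = 3.84; a marker is *linked* when all
  non-transgenic plants carry only the non-transgenic parent's allele
  (zero recombinants), and the insertion interval is bounded by the
  nearest flanking markers showing ≥1 recombinant, size = end − start.
- **Integration** — the genetic interval vetoes junction clusters
  outside it, eliminating repeat-induced decoys; the best-supported
  surviving cluster becomes the insertion call.
- **Flank specificity** — all ≥90%-identity genomic copies of a junction
  flank (no indel run >100 bp) are found, then extended outward in
  0.5-kb steps (0.5–7.5 kb) and compared all-pairs to profile how
  ambiguity (`n_similar`, `max_hits`) decays with extension length.
- **Assay design** — junction assembly arithmetic (host + vector border
  lengths) and in-silico PCR with IUPAC-aware primer matching, a
  2-mismatch budget and an exact 3'-terminal 3-nt requirement, verifying
  that event-specific primers amplify the transgenic genome only.
- **A seeded simulator** — repeat-bearing host genomes, clean construct
  insertions with a truth record, 150-bp paired-end reads, error-prone
  long reads (5–15% mixed errors, quality strings supporting the Q7
  filter), and F2 populations recombined under the Haldane map function.

## Worked example

Simulate a hard case — a 50-kb chromosome with ten 2-kb repeat copies at
1% divergence, an 8-kb construct — sequence it with noisy long reads,
map it with an F2, and call the insertion:

```r
library(insertlocus)

case  <- simulate_insertion_case(1)          # truth: insertion after chr1:29,880
reads <- simulate_long_reads(case$genome, length_mean = 15000,
                             length_sd = 5000, min_len = 1000,
                             coverage = 10, error_rate = 0.10, seed = 1001)

mk <- data.frame(name = c(sprintf("m%02d", 1:5), "mloc"), chrom = "chr1",
                 position = c(seq(5000, 45000, by = 10000),
                              case$truth$insert_pos + 100))
f2 <- simulate_f2_population(300, mk, list("chr1", case$truth$insert_pos),
                             recomb_rate_per_bp = 2e-6, seed = 2001)
chi_square_segregation(sum(f2$transgene), sum(!f2$transgene))
#> chi-square vs 3:1 | observed 223:77, expected 225.00:75.00
#>   statistic = 0.040 (df 1, continuity-corrected), critical = 3.84 at alpha 0.05 -> consistent

bsa <- delineate_interval(linkage_scan(f2), chrom_lengths = c(chr1 = 50000))
bsa
#> chr1:25,000-35,000 (size 10,000 bp)
#>   bounded by: m03 / m04

locate_insertion(reads, case$host, case$vector, mode = "long",
                 bsa_interval = bsa)
#> insertion call: 21 reads (LB,RB sides) support
#> chr1:3,487-48,909 (size 45,422 bp)
#>   stages: reads_in=41, q7_dropped=2, host_only=17, vector_only=0,
#>           mixed=22, unmapped=0, clusters=2, rejected=1
```

Reading the output: the F2 segregates 223:77, consistent with a single
locus; the strict cosegregation rule links marker `mloc` and the
recombinant-bearing markers `m03`/`m04` bound a 10-kb interval that
contains the truth. Of 41 long reads, 2 fail the Q7 filter and 22 are
host–vector mixed; their breakpoints form 2 clusters, one of which —
a repeat-induced decoy — lies outside the genetic interval and is
rejected. The surviving cluster's 21 reads place the insertion inside
the anchor-envelope interval; its representative breakpoint (median of
the clustered junction positions) lands at the truth position.

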