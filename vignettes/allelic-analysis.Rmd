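---
title: "Allele-specific epigenomic analysis with INDEL-aware diploid pseudogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific epigenomic analysis with INDEL-aware diploid pseudogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelign)
```

## The problem

Standard short-read analysis aligns everything to a single reference
genome and thereby averages over the two parental alleles of a diploid
sample. Allele-specific phenomena — genomic imprinting, X inactivation,
*cis*-regulatory variation — are invisible at that resolution, and worse,
alignment to the reference systematically favours reads carrying reference
alleles (reference bias). In an F1 hybrid of two inbred strains, or in a
phased human sample, the two haplotypes are known, which makes a different
strategy possible: build an *in silico* diploid pseudogenome containing
both haplotype sequences, align reads to both at once, and classify each
fragment by where it aligns best.

`allelign` implements that engine end to end, with one deliberate emphasis:
short insertions and deletions (INDELs) are applied during pseudogenome
construction alongside SNVs. INDELs make up a substantial minority of the
genetic differences between mouse strains (roughly one INDEL per five
SNVs), and some regions carry INDELs but no SNVs at all, so an
SNV-only pseudogenome forfeits every allelic read — and every allelic
CpG — in such regions. Because INDELs change coordinates, the package also
maintains, per haplotype, a *refmap*: an index of collinear alignment
blocks that lets every downstream result be projected back onto reference
coordinates for visualization and region-based summaries.

## The model and its pieces

**Diploid pseudogenome.** `build_haplotype()` applies phased variants
left to right. An SNV substitutes a base and never splits a block; an
INDEL closes the current refmap block after the aligned prefix of REF and
ALT (the shared anchor bases, the same anchoring convention VCF uses) and
opens the next block after the inserted or deleted bases. Variants whose
REF span overlaps an already applied edit are skipped deterministically
and counted; REF-mismatches against the reference sequence are skipped or,
under `strict = TRUE`, abort. Contigs are named `<chrom>_<hap_name>` so
the classifier can recover the haplotype from the contig name alone.

**Coordinate projection.** Within a block the two coordinate systems
differ by a constant. A haplotype position inside an insertion has no
reference base; it reports the anchor base immediately to its left
(`status = "inside_insertion"`). Intervals (read footprints) spanning a
deletion are *stretched* across it in reference space, mirroring what a
gapped alignment would show. Coverage tracks are treated differently:
`project_bedgraph()` splits each interval at block boundaries and maps
the exact pieces collinearly, because a coverage value is a per-base
quantity — splitting conserves the signal at every exact base and
guarantees non-overlapping output, which stretching would not.

**Allelic classification.** A fragment (both mates treated as a unit) is
allele-specific if it has exactly one best alignment location on the
diploid genome; two or more equally good locations mean it is
non-allelic; none, unaligned. This is uniqueness-based calling: no
per-variant genotyping of reads is involved, which is what lets a mate
that covers no variant inherit the call of its uniquely-anchored pair
(mate rescue). Ties in mismatch count between the two haplotypes at the
same locus are exactly the "aligns at least twice" case and stay
non-allelic.

**The built-in aligner.** For download-free testing the package includes
a toy aligner for genomes up to a few megabases. It is seed-and-extend
with `max_mismatch + 1` non-overlapping k-mer seeds per read: by
pigeonhole, any gapless placement within the mismatch budget contains at
least one exact seed, so the enumeration of placements is *complete* —
the property the uniqueness rule needs. Bisulfite mode performs
directional three-letter matching: read and genome are C→T-collapsed for
the original-top strand comparison and G→A-collapsed for the
original-bottom one. Sequencing errors are substitution-only at this
scale, so the aligner stays gapless; real libraries go through a
production aligner and enter via SAM (`classify_sam()`), where uniqueness
falls back to the NH tag, then secondary/supplementary flags plus a MAPQ
threshold (default 20), because aligners report uniqueness differently.

**Methylation calling.** On the original-top comparison a read base C
over a CpG's C is methylated and T unmethylated; on the original-bottom
comparison the informative base is the CpG's G (G methylated, A
unmethylated); anything else is ambiguous and dropped. Only CpG context
is called. CpG sites are located on each haplotype sequence, so a CpG
destroyed by a variant on one haplotype simply never yields calls for
that haplotype, and a CpG created on one haplotype is reported for it
alone. Overlapping mates are clipped so one fragment contributes at most
one observation per site. Counts are keyed by the projected reference
position of the CpG C; sites inside haplotype-specific insertions have no
reference coordinate and are dropped from the aggregate table (they are
still visible in per-read calls).

**Region summaries and diagnostics.** Regions report, per allele, the
number of informative CpGs (coverage ≥ 5 by default, the empirical
definition of an informative CpG) and the *unweighted* mean of per-CpG
methylation percentages — unweighted because the summary is paired with a
CpG count, not a read count. Allelic imbalance tables combine per-region
total RPKM (`n × 10⁹ / (length × library size)`, the enrichment filter)
with per-haplotype fragment counts; the monoallelic-expression rule is
RPKM > 1, allelic reads > 100, and allelic ratio strictly above 0.9 (or
below 0.1), all strict inequalities as printed. Reference bias is
`100 × (n_hap1 − n_hap2) / (n_hap1 + n_hap2)`; both the pooled
(count-weighted) global value and the unweighted per-chromosome mean are
reported, with the pooled value as headline, since the aggregation rule
behind published global figures is not stated. False-positive reports
take an isogenic dataset (all fragments truly one haplotype) and score
calls to the other haplotype, as a fraction of allelic calls and of all
aligned fragments, before and after blacklisting.

## The synthetic data generator

Every stage above is exercised by `sim_reference()`, `sim_variants()`,
`sim_fragments()`, `sim_bisulfite()` and `sim_enrichment()`, which
emulate the F1-hybrid design: two haplotypes differing by SNVs and
INDELs at controllable densities, paired-end genomic / bisulfite /
enrichment reads with known allelic origin, per-allele CpG methylation
rates, and i.i.d. substitution sequencing error. Every fragment carries a
truth row (haplotype, haplotype and projected reference interval, count
of distinguishing variants overlapped by the *sequenced* read intervals)
and bisulfite simulations additionally record each drawn per-molecule CpG
state and whether its informative base was sequenced. All outputs are
byte-reproducible given the seed.

Default study conditions used by the acceptance checks (chosen once, as
realistic strain-like settings, and stated here because the problem sizes
are the package's own choice):

* genomes of 20–50 kb per chromosome at GC 0.42, CpG islands as segments
  with an elevated CpG emission rate (0.1/position vs ~0.044 background);
* SNV densities of 1–8 per kb with a 4–5:1 SNV:INDEL ratio, geometric
  INDEL lengths capped at 10 bp — the density regime of a laboratory
  mouse cross, scaled to toy chromosomes;
* 75–100 bp paired reads, 180–300 bp inserts; 10,000 fragments for
  haplotype-recovery checks, 30,000 for the bias benchmark (at ~23,000
  allelic fragments the binomial noise floor of the bias statistic is
  ~0.4 points, comfortably inside the 1-point check), ~50× for
  methylation recovery;
* the bias benchmark assigns exactly half the fragments to each
  haplotype (`balanced = TRUE`), so the statistic measures classification
  asymmetry rather than sampling noise of the haplotype draw;
* the false-positive decoy is a 160-unit tandem array of a 24 bp unit
  with a single SNV inside one unit, read single-ended at 1% error: an
  error landing on the variant's unit offset creates a spurious unique
  best placement on the wrong haplotype, clustering false positives in
  the array exactly as satellite DNA does in real data. (With the
  complete paired-end enumeration the partner mate multi-maps across
  units and the effect vanishes — a real aligner's mapq heuristic is
  what produces it for pairs.)

What the generator does *not* emulate — and hence what green tests do not
show about real data: PCR duplicates and base-quality variation
(deduplicated input is assumed; qualities are constant), read-length
INDel sequencing errors, CHH/CHG methylation, incomplete bisulfite
conversion by default (the `conversion_rate` knob exists but conversion
failure chemistry is not the test target), splice-aware RNA alignment
(enrichment mode restricts fragments to intervals; gapped alignment is an
external aligner's job), and aligner-specific mapq behaviour.

## Numerical and edge-case choices

* Coordinates are 0-based half-open in every on-disk format and public
  table (refmap, BED-like regions, bedGraph, truth tables, CpG tables);
  VCF positions are 1-based on parse, alignment coordinates 1-based
  internally.
* Methylation-recovery checks compare pipeline levels against the
  *realized* drawn states of the very molecules the pipeline called, not
  against the rate parameter: at 20–30 reads per site the binomial noise
  of the rate itself (~7 points) would swamp a ±3-point fidelity check.
  Those simulations run error-free so the comparison isolates
  conversion/strand/projection fidelity; sequencing errors are exercised
  by the aligner oracle and the false-positive scenarios.
* A zero-length projected interval (a fragment entirely inside an
  insertion) is anchored at anchor+1; empty input intervals are errors.
* Unphased heterozygous genotypes are skipped (deterministic output);
  unphased homozygous genotypes are unambiguous and kept.
* `classify_expression` treats its gates as strict: ratio exactly 0.9,
  exactly 100 allelic reads, or RPKM exactly 1 are not monoallelic.
* Region counting uses ≥ 1 bp overlap, no fractional assignment; a
  fragment overlapping two regions counts in both.
* The aligner requires reads long enough for `max_mismatch + 1` seeds of
  at least 8 bp and refuses genomes over 5 Mb with a pointer to the SAM
  route.

## Known limitations

The toy aligner is gapless: a read whose *own* sequence contains an
INDEL-length error cannot be placed (real data should come through
Bismark/STAR/BWA and the SAM path). Bisulfite conversion erases C/T SNV
distinctions on the converted strand, so allelic recovery from WGBS reads
is intrinsically lower than from genomic reads (~93% vs ~99.8% of
variant-overlapping fragments under the default densities) — a property
of three-letter alignment, not of the implementation. Structural
variants are out of scope (symbolic ALTs are rejected), as are phasing
itself (a phased VCF is required), chain-file export, significance
testing of allelic ratios, and BigWig emission (bedGraph is the on-disk
format; BigWig is a binary conversion step for external tools).

## A worked run

```{r example, eval = FALSE}
ref <- sim_reference(1, lengths = c(chr1 = 50000L))
v   <- sim_variants(ref, 2, snv_per_kb = 4, indel_per_kb = 0.8)
dg  <- build_diploid(ref, v)

sim   <- sim_fragments(dg, 3, n_fragments = 2000, variants = v)
calls <- classify_fragments(align_fragments(sim$reads, dg), dg)
table(calls$call)

bias <- reference_bias(calls)
tracks <- partition_alignments(calls)
rpm <- depth_normalize(tracks$total, sum(calls$call != "unaligned"))
```

The acceptance script (`scripts/acceptance.R`) chains these stages —
pseudogenome oracle agreement, per-base liftover agreement, haplotype
recovery, INDEL-awareness contrast, methylation recovery, bias and
false-positive diagnostics, threshold grid, and format round-trips — and
writes the resulting numbers as JSON.
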