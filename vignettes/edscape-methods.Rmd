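---
title: "Detecting A-to-I RNA editing with edscape: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA editing with edscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscape)
```

## The measurement model

A-to-I editing deaminates adenosine in double-stranded RNA; sequencers
read the resulting inosine as guanosine. On forward-genome coordinates an
edited site therefore shows an A→G excess in RNA over a plus-strand
transcript and a T→C excess over a minus-strand transcript, while the
matched DNA stays homozygous reference. The per-site *editing level* is
the binomial proportion G/(A+G) among filtered RNA reads covering the
site; pooled levels over samples or regions are formed by summing counts,
never by averaging proportions, so a pooled level is the coverage-weighted
mean of its members.

Everything downstream — overall editing (summed G over summed A+G across
all sites of a sample), the region-specificity classes, the Fisher test
for cross-species bias — operates on these counts.

## Evidence filters and why they exist

Each filter addresses a concrete failure mode of RNA-vs-DNA comparison:

* **PCR duplicates** (`remove_duplicates`): at most one read per
  (chromosome, start, strand), keeping the highest base-quality sum with
  lexicographic read-id tie-breaks. This mirrors coordinate-based
  `rmdup` semantics for single-end data. A consequence worth knowing: at
  very high local depth coordinate collapsing removes genuine coverage
  too, which is why the level-convergence analyses in this package run on
  libraries simulated without duplicates rather than on deduplicated
  ones.
* **Base quality** (`build_pileup`, `quality_min = 30`): bases below Q30
  are unreliable for single-nucleotide evidence. We apply the same filter
  to DNA counts — the homozygosity decision deserves clean evidence too;
  this was an open point and is configurable.
* **End clipping** (`end_clip = 6`): the first and last six bases of each
  aligned RNA read are ignored, removing random-primer and end-artifact
  mismatches. DNA reads are not clipped.
* **gDNA homozygosity** (`is_dna_homozygous`): depth ≥ 10 and a
  major-allele fraction of 1.0 by default. The strict default is
  deliberately conservative and testable; a relaxed fraction (e.g. 0.95)
  is a single argument away.
* **Paralog filter** (`paralog_filter`): every variant-supporting read is
  realigned with the package's seed-and-extend aligner; a read qualifies
  only if its best hit is unique and overlaps the site. Sites with < 50%
  qualifying reads are discarded, which removes systematic false calls
  inside recently duplicated sequence.
* **Multi-sample support**: a site enters the master list only when at
  least two samples independently pass *all* per-sample criteria — a
  literal reading of "supported", not mere coverage.

Round 2 then revisits every master site in every sample with ≥ 10
covering reads, recording counts, level, and an edited flag (≥ 1 edited
read). Covered-but-unedited records are kept at level 0: without them,
pooled denominators and Fisher tables would be wrong. A `known_min_total`
of 4 reads supports quantifying a fixed catalogue of sites in external
(e.g. cell-line) data.

## Hyper-editing recovery

Reads from heavily edited molecules fail direct alignment because their
mismatch count exceeds any sensible threshold. The rescue collapses the
editable base: reads are A→G transformed and aligned against two collapsed
forward-genome indexes — A→G (sense editing) and T→C (which is exactly how
antisense editing presents on forward coordinates). Both read strands are
tried against both indexes; the best transformed-space hit must be unique
across the union. The original sequence is then restored at the hit locus
and accepted only if A→G (or T→C) mismatches dominate: fraction among all
mismatches ≥ 0.6, count ≥ 5, other mismatches ≤ 5% of the read. The
method this follows does not restate its thresholds, so all three are
configurable (`hyper_config()`) and the defaults are documented here. The
mismatch-free corner case passes trivially: an unedited read that happens
to land in the unmapped pool is simply re-admitted. Recovered reads enter
the same pileup with the same Q30/clip filters as any other RNA read.

## The synthetic-data generator

The generator is first-class code, not a fixture: its defaults define the
study conditions under which the package's claims are tested.

* **Genome and genes**: 2 chromosomes × 200 kb of uniform random
  sequence; 60 genes (3 exons × 400 bp, 1.6 kb introns, 150/250 bp UTRs)
  with valid reading frames written into the sequence (ATG, no internal
  stops) so recoding annotation is exact; strands alternate.
* **Repeats**: ~25% of each chromosome tiled with copies of six
  subfamily consensi (five SINE-like at 246 bp, one LINE-like at 500 bp)
  at 12% per-copy divergence. The divergence matters: aged repeat copies
  are what makes unique realignment possible at all, and 12% is typical
  of an old SINE expansion.
* **Sites**: 500 positions on reference A of the transcribed strand;
  55% in intronic repeats (60% of them planted in ≥ 3-within-100-bp
  clusters), 25% elsewhere in introns, the rest in UTRs and CDS. True
  levels are drawn per class: Beta(1, 9) for the low-level repeat/intron
  bulk, Beta(1, 4) for UTRs, and a recoding mixture in which 20% of CDS
  recoding sites sit at 0.995 — the near-obligatory Q/R-type recoding
  seen in glutamate-receptor transcripts. At least one CDS site is
  guaranteed ≥ 0.99 in all regions.
* **Confounders**: 50 heterozygous A/G SNPs inside genes (visible in
  both DNA and RNA at ~50%), 0.1% uniform base error, 5% of bases at
  Phred 20 (below the pileup filter), 2% exact PCR copies, and 0.5% of
  RNA reads drawn from hyper-edited molecules in which each A is edited
  with probability 0.3, topped up so every such molecule has at least
  max(5, 20% of its As) edits — the definition of hyper-edited used by
  the recovery thresholds.
* **Depths**: RNA at 60× over gene spans (3 regions × 4 animals = 12
  samples), DNA at 30× genome-wide per animal. These sizes keep a full
  end-to-end run in the low minutes on one CPU while leaving every
  threshold comfortably testable.

What the generator deliberately does **not** model: splice junctions
(reads are placed on unspliced pre-mRNA, consistent with intronic editing
signal), indels, quality miscalibration, strand-protocol failures,
fragment-length structure (single-end reads), and molecular phasing —
editing is sampled independently per read except for the designated
hyper-edited molecules. Tests passing on this simulator therefore
validate the *arithmetic and the filter logic*, not robustness to
alignment artefacts of real spliced reads; the caller consumes standard
SAM, so real aligner output can be substituted where that robustness
matters. Coverage also ramps down over the terminal read-length of each
gene (reads must start within the gene), so a handful of UTR-edge sites
are under-covered — visible in recall summaries and intentionally left in
as a realistic edge effect.

## Numerical and procedural choices

* **Aligner**: seeded (k = 16) ungapped extension reporting *all* loci
  within a 10% mismatch ceiling, both strands; uniqueness means the best
  score is achieved at exactly one locus. On desk-scale genomes this is
  exhaustively verifiable, and the test suite holds it to an exhaustive
  sliding-window oracle.
* **Fisher test**: direct hypergeometric enumeration with the
  point-probability rule (sum of all tables whose probability is at most
  the observed table's, within a 1e-7 relative tolerance) — the same
  convention as `stats::fisher.test`, which serves as an independent
  cross-check in the tests, not as the implementation.
* **Wilcoxon**: exact enumeration for pooled n ≤ 12 without ties, normal
  approximation with tie correction otherwise.
* **PCA**: centred, unscaled (levels share units), via `prcomp`, after
  gating sites to ≥ 10 reads in every column.
* **Size factors**: median-of-ratios to per-gene geometric means over
  genes positive in all samples.
* **Clustering**: "at least 3 sites within a 100-bp window", scanned over
  sorted positions; the source material uses both "at least" and "more
  than" three in different places, so `min_sites` is an argument and 3 is
  the default.
* **Specificity order**: enriched → group-enriched → enhanced →
  low-specificity, making the classes disjoint; the margin is an absolute
  20-percentage-point difference and the group search takes the smallest
  qualifying set (which is necessarily a prefix of the level-sorted
  regions), ties by region name. Sites with undefined levels in more than
  a third of regions are not evaluated. Group sizes run from 2 to
  ⌊n/3⌋, so with fewer than 6 regions the group class cannot fire.
  The two-thirds coverage quorum rounds up by default (8 of 12 either
  way); both roundings are exposed.
* **miRNA seeds**: default scheme is positions 2–8 (7 nt), honouring the
  stated 7-bp seed length over the literal 2–7 span; the 6-nt scheme is
  selectable. A match must be a perfect Watson–Crick reverse complement
  (no G·U) and its window must cover the edited position — otherwise the
  edit could not alter the match.
* **Coefficient of variation**: population convention (divide by n) across
  region means; configurable, since the convention was not specified.
* **Strand assignment**: annotated gene strand when a site lies in exactly
  one gene; otherwise the strand that reads A-to-G, defaulting to "+".
  Two variant bases with ≥ 3 reads each mark a site multi-allelic and drop
  it — ambiguous evidence is discarded rather than adjudicated.
* **Coordinates**: 0-based half-open internally; 1-based in emitted TSVs;
  bedGraph stays 0-based half-open with levels × 100.
* **Pipeline determinism**: all randomness descends from one integer
  seed (reference, truth and reads use seed, seed+1, seed+2), so reruns
  are byte-identical; the manifest records checksums, and a rerun whose
  previous artifacts all verify is returned without recomputation
  (corruption of any artifact triggers a full re-execution).

## Known limitations

Mate-aware duplicate marking, spliced alignment, indel handling and BAM
binary I/O are out of scope (SAM text captures the contract; a BAM
adapter can wrap the same reader interface). The homozygosity model is a
threshold rule, not a genotype likelihood. The specificity gates assume a
single host gene per site (sites in overlapping genes are counted once).
Conserved-site maps are consumed as tables, not produced (coordinate
lift-over is a separate concern). P values in the cross-species module
are reported raw by default, matching the thresholds this analysis family
uses; Benjamini–Hochberg adjustment is available as an option.
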