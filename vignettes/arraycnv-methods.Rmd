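---
title: "Methods: consensus CNV calling, mosaicism and trio analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus CNV calling, mosaicism and trio analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arraycnv)
```

`arraycnv` turns per-caller SNP-array CNV callsets and probe-level
BAF/LRR data into a restrictive consensus callset with quality control,
mosaicism quantification and trio interpretation. This vignette documents
the models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Coordinates and data model

All coordinates are 1-based inclusive internally and in every TSV dialect;
conversion to BED's 0-based half-open convention happens only in
`write_bed()` / `read_bed_track()`. Chromosome names are normalised to the
unprefixed set 1..22, X, Y ("chr" stripped on input, added on BED output).
Genotypes are biallelic A/B calls (AA, AB, BB, NC). Within one caller's
callset, overlapping same-direction calls are merged on construction
(minimum start, maximum end, the higher-confidence member's copy number)
so that each caller contributes at most one direction per probe; callers
are not guaranteed to emit disjoint calls, and the vote needs
per-probe/per-caller directions to be well defined.

Caller confidence cut-offs (log Bayes factor 8.5 for QuantiSNP-style
files, confidence 10 for PennCNV rawcnv) are **inclusive**: a call at
exactly the threshold is retained. The convention is a package decision —
the customary threshold statements do not specify strictness — and
documented here once; both parsers expose the threshold as an argument.

## Consensus voting

The vote is defined per probe, which makes "supported by more than one
method" exact and testable: for each map probe, each caller's filtered
calls assign a direction (loss for copy number < 2, gain for > 2; a probe
covered by both directions from one caller contributes nothing for that
caller). A probe is a consensus probe for a direction when at least
`min_methods` callers (default 2) assign it; consensus regions are maximal
runs of consecutive consensus probes of one direction, kept when the run
has at least `min_probes` (default 3) members, and delineated by the
first/last probe of the run — the conservative common overlap rather than
the union of the callers' boundaries. Runs break at chromosome boundaries
and at any intervening non-consensus probe (a strict "consecutive probes"
reading; adjacent runs separated by a single failed probe are *not*
merged). Agreement is on direction, not exact copy number — callers differ
in copy-number granularity — and the region's reported copy number is the
probe-weighted mode over supporting calls, ties resolved toward 2, then
toward the smaller value.

Asymmetric voting (`trusted_dup_method`) lets one caller's gain calls
stand without confirmation, reflecting the situation where one caller is
demonstrably stronger on duplications; such regions carry
`vote_mode = "trusted_dup"` unless a second caller supports them, which
upgrades them to `"majority"`.

The implementation aggregates intervals with cumulative per-probe counts;
its contract is checked against a per-probe brute-force oracle
(independent loops over probes and calls followed by a run scan) on
randomized callset triples in the test suite.

## Quality control and the mosaicism trigger

Metrics, all excluding sex chromosomes (hemizygosity in males distorts
both SDs):

* **call rate** — fraction of SNP probes with a genotype call; pass
  requires > 0.994 (strict).
* **LRR SD** — SD of autosomal log R ratios; pass < 0.2.
* **BAF SD** — SD of BAF over autosomal SNP probes inside the
  heterozygous band [0.25, 0.75]; pass < 0.6. The restriction is a package
  decision: the raw BAF distribution is tri-modal and its SD would be
  dominated by the homozygous modes, making a fixed threshold
  uninterpretable. A consequence is that this statistic is not numerically
  interchangeable with PennCNV's BAF-drift measure.
* **wave factor** — genomic waving is modelled as a single linear
  regression of per-window median LRR on window GC fraction (1 Mb windows
  recommended, size configurable); the slope is the wave factor (pass
  |slope| < 0.03) and subtracting the fitted line de-waves the data. A
  deliberately simple stand-in for iterative wave-adjustment procedures:
  adequate for the QC statistic and idempotent (correcting corrected data
  returns a slope below 1e-9). Constant GC across windows is degenerate
  and defined as slope 0 with unchanged data; fewer than two usable
  windows or coverage of less than half the probes is an error.

Per-chromosome heterozygous-band BAF SDs feed the mosaicism screen: a
chromosome is flagged when its SD exceeds the median + `k_mad` · MAD
(default 3; MAD scaled 1.4826 for SD consistency) of the per-chromosome
values. "Significant outlier" has no canonical definition at n ≈ 22
chromosomes; the median/MAD rule is robust to one or two genuinely
aberrant chromosomes inflating the spread, and is scale-invariant. Flagged
chromosomes are handed to BAF segmentation; with only a handful of
autosomes (< 5) the screen refuses to run.

## Mirrored-BAF segmentation and mosaic fractions

Heterozygous SNPs sit at BAF 0.5 in pure diploid tissue; an event in a
fraction *p* of cells shifts them symmetrically. Mirroring
(`mBAF = max(BAF, 1−BAF)`) folds the signal onto [0.5, 1].

The pipeline in `segment_sample_baf()`:

1. **Confident-homozygote exclusion.** Probes with a homozygous call *and*
   mBAF above `informative_threshold` (0.97) are dropped first. They carry
   no allelic-imbalance dosage information, and on a tri-modal SNP series
   their density would let the triplet rule (below) protect them en masse
   and dilute segment means. Heterozygotes whose calls flip to homozygous
   under strong imbalance have mBAF below the threshold and survive.
2. **Informative filter.** Remaining probes with mBAF >
   `informative_threshold` are removed as homozygous, *except* when the
   median of the probe's centered triplet exceeds `triplet_threshold`
   (0.8) — protecting dense stretches of true near-1 imbalance from being
   deleted as "homozygous". The exact triplet semantics (protect, using
   the probe and its immediate neighbours in the filtered candidate
   series) is this package's interpretation of the protection idea;
   NC-genotype probes are always removed.
3. **Segmentation.** Recursive binary splitting minimising within-segment
   squared error; a split is accepted when the Gaussian
   log-likelihood-ratio statistic `m·log(SSE_before/SSE_after)` exceeds
   the penalty. The default penalty is `2·log(n)`: BIC-style, charging
   each change point for its two parameters (location and new mean). A
   zero-SSE (constant) segment never splits.
4. **Calling.** A segment is an allelic-imbalance call when its mean mBAF
   reaches `ai_threshold` (0.56) over at least `ai_size` (4) informative
   probes. The event type comes from the segment's mean LRR: below −0.1 →
   mosaic deletion, above +0.05 → mosaic duplication, else copy-neutral
   imbalance. The LRR typing cut-offs are a package addition (the segment
   caller itself is copy-number-agnostic) and are configurable.

The mosaic cell fraction inverts the heterozygous-SNP dosage
expectations: deletion `p = 2 − 1/mBAF`, duplication
`p = (2·mBAF−1)/(1−mBAF)` capped at 1 (mBAF = 1 flags "at-bound"),
copy-neutral LOH `p = 2·mBAF − 1`, clipped to [0, 1]. The estimate uses
the mean mBAF of the segment's heterozygous-called probes; when strong
imbalance has removed all heterozygous calls, it falls back to the median
of sub-threshold probes, which resists the residual homozygous tail that
the mean does not. Inverse consistency (`estimate` ∘ `expected` = identity
to 1e-9) and recovery of planted fractions (median absolute error ≤ 0.05
at p ∈ {0.2, 0.4, 0.6, 0.8} with ~500 informative probes and BAF noise SD
0.03) are enforced by the test suite.

Note one consequence of thresholding segment means on a series that still
contains a minority homozygous tail: a normal-diploid segment can clear
`ai_threshold` while its heterozygous-based fraction estimate is near
zero. Filter reported segments on `mosaic_fraction`, not only on their
presence.

## Trio genotype analytics

Seven transmission models are enumerated for each (father, mother, child)
triple: biparental; paternal/maternal iso-UPD (one homolog of one parent
doubled); paternal/maternal hetero-UPD (both homologs of one parent); and
maternal/paternal deletion, in which the hemizygous child's single allele
— read by the array as a homozygous call, a stated modelling assumption —
comes from the other parent. The per-SNP state is CONSISTENT when
biparental transmission fits; otherwise the fitting side's state, with
`*_ISO_ONLY` when the hetero-UPD model is excluded but iso fits (the iso
signature coincides with the complementary deletion's, so the two are
never separable per SNP); DOUBLE_INCONSISTENT when nothing fits;
UNINFORMATIVE_NC when any genotype is missing. The classification is
generated from a 4³ lookup table and verified in the tests against an
independent brute-force enumerator of allele transmissions; it is
parent-swap symmetric by construction. The X chromosome is excluded from
all trio analytics (hemizygous males break the biparental model).

**UPD detection** scans each autosome for maximal runs of informative
states of one parental direction over the informative-SNP subsequence,
merging across opposing states while the opposing fraction stays within
`max_opposing_fraction` (0.05), and requires `min_run` (10) informative
states. Runs that are actually deletions are excluded by two routes: mean
child LRR below −0.1, or overlap with a consensus loss region when a
consensus callset is supplied. Subtyping is run-level (single SNPs cannot
separate iso from hetero when the transmitting parent is homozygous):
isodisomy when the child is homozygous at ≥ 98 % of the run's SNPs and no
informative SNP requires the hetero model; heterodisomy when child
heterozygosity is retained (≥ 0.9) at run SNPs where the transmitting
parent is heterozygous; otherwise mixed. Each run gets a binomial tail
p-value for its informative-state enrichment against the genome-wide
informative rate. All run parameters are this package's parameterisation
of a capability usually described without printed parameters; each is a
`trio_config()` field.

**Non-paternity** is genome-wide scatter, not clustering: the flag
requires the paternal-exclusion state rate (M-side states plus
DOUBLE_INCONSISTENT) to exceed `nonpaternity_mi_rate` (0.02, far above
plausible genotyping-error Mendelian-inconsistency rates) on at least
`nonpaternity_min_chromosomes` (20) autosomes. A single UPD chromosome
therefore cannot raise it. Both the flag and the per-chromosome rate
table are returned, so a reviewer can always inspect the evidence.

**Inheritance and parent of origin.** A child region is inherited when a
same-direction parental region achieves reciprocal overlap ≥ 0.5 (both
fractions); both parents → "both"; neither → de novo. For a de novo loss,
in-region SNPs with opposite-homozygote parents are informative: the
child's remaining allele names the retained parent, and the *other*
parent — who contributed the lost homolog — is the origin. For a de novo
gain, the child's BAF at opposite-homozygote SNPs is assigned to the
nearest of {0, 1/3, 2/3, 1} within a margin of 0.08; the 1/3 and 2/3
clusters reveal which allele is duplicated and hence the originating
parent. A verdict requires ≥ 2 informative SNPs at ≥ 0.9 concordance,
else "undetermined" — the design goal is to return "undetermined", never
the wrong parent, under genotyping noise.

## Annotation and reporting

Track overlap uses interval ranges per chromosome; a hit requires the
overlap to cover at least `min_overlap_fraction` of the region (default:
any overlap — the canonical "known benign" overlap rule is not
standardised, so the fraction is exposed rather than hard-coded). Control
frequency counts *distinct control samples* (not intervals) with an
overlapping **same-direction** variant, divided by the declared panel
size; direction-less tracks match either direction. Genome build is
carried as metadata and never converted.

ISCN-style strings are `arr {chrom}{band}[{band2}]({start}-{end})x{cn}`
with thousands-separated coordinates and suffixes dn / pat / mat for de
novo / paternal / maternal; "both parents" is rendered `inh`. Reports are
deterministic: stable ordering, no timestamps, byte-identical JSON for
identical inputs.

## The synthetic-data generator

`sim_config()` / `simulate_sample()` / `simulate_trio()` /
`simulate_callsets()` are first-class, tested code: every planted event
records its exact probe span, and trio children are built by recorded
haplotype transmission, so downstream claims are checked against
construction truth rather than re-inferred labels.

The dosage model is analytic by design: per-probe B-allele population
frequencies ~ Uniform(0.05, 0.95) (so opposite-homozygote,
trio-informative SNPs are common), Hardy-Weinberg genotypes, and for an
event of copy number `cn` in a cell fraction `p`, effective copies
`n_eff = (1−p)·2 + p·cn`, LRR ~ Normal(log2(n_eff/2), 0.15) with copy 0
floored at −5, BAF ~ Normal(b_eff/n_eff, 0.03) clipped to [0, 1], where
`b_eff` is the mixture B dosage. Genotype calls re-derive from the
noiseless dosage (hemizygous → homozygous call, as on a real array), with
a 0.005 no-call rate and an optional genotype error rate (0 by default).
The default genome is 2 autosomes × 5,000 probes at 10 kb spacing —
minutes of compute, not hours; tests and the acceptance script size their
genomes per scenario (e.g. 8 × 600 probes for chromosome-level QC
screens, 22 autosomes × 250 probes for the non-paternity scatter rule,
1 × 1,600 probes for ~500-informative-probe mosaic recovery).

What it does *not* emulate — and hence what passing tests do not show
about real arrays: no linkage disequilibrium or recombination (one
transmitted haplotype per chromosome), no platform-calibrated LRR cluster
means, no probe-specific noise or batch structure, no genomic waves beyond
an optional linear GC term, and BAF noise that is Gaussian-clipped rather
than rail-compressed. Thresholds tuned here should be revalidated on
platform data before clinical use.

## Known limitations

* The consensus never re-delineates beyond probe resolution; single-probe
  gaps split runs, which can fragment large events called with
  inconsistent boundaries.
* BAF-SD screening detects chromosome-scale mosaicism; small mosaic
  segments on an otherwise quiet chromosome will not trip the per-chromosome
  screen (run `segment_sample_baf(..., all chromosomes)` when in doubt).
* Integer-copy-number assumptions make the consensus pipeline unsuited to
  heavily aneuploid cancer samples; the BAF segmentation stage is the
  appropriate tool there.
* Trio analytics assume the stated pedigree except for the explicit
  non-paternity screen; sample swaps masquerade as non-paternity.
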