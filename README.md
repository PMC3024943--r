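# arraycnv

Consensus CNV calling, mosaicism quantification and trio analytics for
SNP-array data.

Clinical interpretation of SNP-array experiments needs a restrictive,
reproducible set of copy-number variants, not the raw output of any single
HMM caller. `arraycnv` is a desk-scale toolkit for that workflow: it reads
probe-level Illumina-style reports and per-caller CNV callsets (QuantiSNP,
PennCNV rawcnv, or any column-mapped TSV), combines the callers by
probe-level majority vote, screens samples for quality and mosaicism,
quantifies mosaic cell fractions from B-allele frequencies, and — when a
trio is available — detects uniparental disomy, non-paternity, inherited vs
de novo status and the parent of origin of de novo events. Results are
annotated against control/gene tracks and exported as ISCN-style strings,
BED and JSON reports.

## The statistics at the core

**Majority-vote consensus.** For each map probe, each caller's filtered
calls assign a direction (loss if cn < 2, gain if cn > 2). A probe is a
consensus probe when at least `min_methods` (default 2 of 3) callers agree
on its direction; consensus regions are maximal runs of consecutive
consensus probes of one direction with at least `min_probes` (default 3)
members, delineated by the first and last supporting probe — the
conservative common overlap. Calls seen by a single caller are discarded as
method-specific artefacts; an asymmetric mode lets one trusted caller's
duplication calls stand alone. Caller confidence filters are inclusive:
log Bayes factor ≥ 8.5 (QuantiSNP) and confidence ≥ 10 (PennCNV).

**Mosaicism.** Sample QC (call rate > 99.4 %, autosomal LRR SD < 0.2,
heterozygous-band BAF SD < 0.6, |GC wave factor| < 0.03) computes
per-chromosome BAF SDs; robust outliers (median + 3·MAD) trigger
mirrored-BAF segmentation (`informative_threshold` 0.97,
`triplet_threshold` 0.8, `ai_threshold` 0.56, `ai_size` 4). For a
heterozygous SNP with a fraction *p* of cells carrying the event, the
expected mirrored BAF is

* deletion: `mBAF = 1/(2−p)`, so `p = 2 − 1/mBAF`
* duplication: `mBAF = (1+p)/(2+p)`, so `p = (2·mBAF−1)/(1−mBAF)`
* copy-neutral LOH: `mBAF = (1+p)/2`, so `p = 2·mBAF − 1`

**Trio genotypes.** Every (father, mother, child) genotype triple is tested
against seven transmission models — biparental, paternal/maternal iso- and
hetero-UPD, and hemizygous-deletion models — giving per-SNP states whose
runs reveal uniparental disomy (with iso/hetero subtype), whose genome-wide
scatter reveals non-paternity, and whose in-region alleles give the parent
of origin of de novo CNVs.

## Worked example

Simulate a trio whose child carries a de novo 1 Mb deletion on chromosome 1
and a 40 % mosaic deletion of chromosome 7 territory, run two perfect
callers over the truth, and vote:

```r
library(arraycnv)

cfg <- sim_config(n_chromosomes = 8, probes_per_chromosome = 600, seed = 42)
ev  <- sim_events(c("del", "mosaic_del"), c("1", "7"),
                  c(5e5, 1), c(1.5e6, 4e6), fraction = c(1, 0.4))
st  <- simulate_trio(cfg, ev, seed = 42)

profiles <- list(
  quantisnp  = list(sensitivity = 1, fp_rate_per_genome = 0),
  penncnv    = list(sensitivity = 1, fp_rate_per_genome = 0),
  vanillaice = list(sensitivity = 0, fp_rate_per_genome = 0))
css  <- simulate_callsets(st$truth, cfg$map, profiles,
                          sample_id = "child", seed = 42)
vote_consensus(css, cfg$map)
#>   sample_id chromosome  start     end direction copy_number n_probes
#> 1     child          1 500000 1500000      loss           1      101
#>   supporting_methods vote_mode
#> 1  penncnv,quantisnp  majority
```

The deletion is recovered exactly (101 probes, two agreeing callers); the
silent third caller costs nothing. QC flags the mosaic chromosome and BAF
segmentation quantifies it:

```r
qc <- compute_qc(st$trio$child)
qc$mosaic_flagged_chromosomes
#> [1] "7"
segment_sample_baf(st$trio$child, "7")
#>   chromosome start     end n_informative mean_mbaf  mean_lrr      event_type mosaic_fraction
#> 1          7 10000 4250000           206 0.6887866 -0.30156      mosaic_deletion      0.391
#> 2          7 4300000 5960000            77 0.6100595  0.00649 cn_neutral_imbalance      0.041
```

The first segment is the planted event: boundaries within a few probes of
the planted 1–4 Mb locus, estimated cell fraction 0.391 vs the planted
0.40, and a deletion-typing LRR. (The trailing segment is the chromosome's
normal remainder; its near-zero fraction marks it as noise — filter on
`mosaic_fraction` when reporting.) Parent of origin of the de novo loss:

```r
parent_of_origin(st$trio, data.frame(chromosome = "1", start = 5e5,
                                     end = 1.5e6, direction = "loss"))
#> $origin: "paternal"   $n_informative: 16   $concordance: 1
```

Sixteen SNPs where the parents are opposite homozygotes all show the child
retaining the maternal allele, so the deleted homolog is paternal.

A shell front-end wraps the same functions:

```sh
exec/arraycnv simulate --out sim --seed 5
exec/arraycnv run --map sim/map.tsv --sample sim/sim1.finalreport.tsv --out run1
```

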