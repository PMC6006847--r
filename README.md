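# haplodenovo

Haplotype-resolved filtering and phasing of de novo mutations (DNMs) in
parent–parent–child trios sequenced with barcoded linked reads.

## The problem

A candidate DNM is a site where the child is called heterozygous and
both parents homozygous reference.  Trio sequencing yields thousands of
such candidates, and most are inherited variants in disguise: when the
sequencing evidence for a parent's alternate-bearing haplotype drops
out (coverage bias, alignment artifacts), the diploid caller genotypes
that parent 0/0 and the inherited het looks de novo.

Linked reads solve this.  Reads sharing a barcode that align near each
other come from one long molecule, hence one haplotype.  `haplodenovo`
assigns each molecule (and so each read) to haplotype 1 or 2 of its
phase block by a majority vote over phased heterozygous sites, then
calls a **haploid genotype** for each of the six trio haplotypes at
every candidate site from the per-haplotype pileups.  A candidate is

* **H** (high confidence) if all six haploid calls are clean, all four
  parental haploids are REF, the child's are exactly REF + ALT, and the
  child's variant is phased;
* **L** (low confidence) if a required haplotype is uncovered or the
  variant is unphased — missing information, kept for review;
* **REMOVED** if any parental haploid carries ALT, any haploid call is
  conflicted, or the child's callable haploids contradict the het call
  — a haploid pileup needs only two reads on the minor haplotype to
  expose an inherited variant that fooled the diploid caller.

Hemizygous X logic (male child: mother's two haploids and the child's
single naturally phased X; female child: five haploids including the
father's X; PARs treated as autosomal) and parent-of-origin inference
by a transmission vote over the child's phase block are included, as is
a linked-read trio **simulator** with complete ground truth so the
whole pipeline is testable without external data.

## Worked example

Simulate a trio at the reference conditions — 500 kb contig, 20 planted
DNMs, 200 inherited-het artifact sites with allele-specific dropout of
severity 0.9, 8× per haplotype, 0.5 % base error — and run the filter:

```r
library(haplodenovo)
sim <- simulate_trio(sim_config(seed = 7))
res <- hapdenovo_run(sim$variants, sim$reads, sim$obs)
#> candidates: 206 | H: 18 L: 5 removed: 183

table(res$classified$label)
#>       H       L REMOVED
#>      18       5     183
```

Of 206 candidate DNMs, 183 — essentially all of the injected
inherited-variant artifacts — are removed because the parent's
alternate haplotype is plainly visible in its own pileup, while the
planted DNMs survive as H (or L when a haplotype happens to lack
coverage).  Parent-of-origin matches the planted truth:

```r
truth <- sim$truth$sites
dnm <- truth[truth$kind == "dnm", ]
m <- match(dnm$pos, res$classified$pos)
table(planted = dnm$dnm_origin, inferred = res$classified$parent_of_origin[m])
#>           inferred
#> planted    maternal paternal
#>   maternal        9        0
#>   paternal        0       11
```

A high-confidence row shows the six haploid calls behind the label:

```r
res$classified[label == "H"][1,
  .(chrom, pos, ref, alt, label, parent_of_origin,
    father_hp1, father_hp2, mother_hp1, mother_hp2, child_hp1, child_hp2)]
#>    chrom  pos ref alt label parent_of_origin father_hp1 father_hp2
#> 1:  chr1 8618   T   A     H         paternal        REF        REF
#>    mother_hp1 mother_hp2 child_hp1 child_hp2
#> 1:        REF        REF       ALT       REF
```

`write_dnm_report(res$classified, "out")` writes the H/L flat file
(`out.dnm.tsv`) and the removed-candidate audit file
(`out.removed.tsv`).

File-based use mirrors this: `merge_phased_vcfs()` +
`read_linked_alignments()` + `hapdenovo_run_files()`, or the CLI

```sh
inst/cli/haplodenovo full \
  --phased-vcf-father f.vcf --phased-vcf-mother m.vcf --phased-vcf-child c.vcf \
  --bam-father f.sam --bam-mother m.sam --bam-child c.sam \
  --depth 2 --out results/trio
```

with `simulate`, `tag`, `genotype` and `classify` subcommands for the
individual stages (external callers' candidate VCFs enter at
`classify` / via `--trio-vcf`, with `--score-filter DQ:7:ge`-style
thresholds).

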