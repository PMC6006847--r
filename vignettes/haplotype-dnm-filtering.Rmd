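---
title: "Haplotype-resolved filtering of de novo mutations: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved filtering of de novo mutations: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodenovo)
library(data.table)
```

## The problem

A de novo mutation (DNM) is a variant present in a child and absent from
both parents' germlines.  Naively, a candidate DNM is any site called
heterozygous in the child while both parents are homozygous reference.
Trio sequencing produces enormous numbers of such candidates, and most
are false: the dominant failure mode is *allele-specific coverage
dropout* in a parent.  If a parent is truly heterozygous but the
sequencing evidence for the alternate-bearing haplotype is depleted --
through coverage bias, batch effects, or alignment artifacts at the
alternate allele -- the diploid caller genotypes that parent 0/0, and an
ordinary inherited variant masquerades as a mutation.

Linked-read sequencing offers a way out.  Long DNA molecules are
partitioned and barcoded before short-read sequencing, so reads sharing
a barcode that align near each other derive from one molecule, hence
one haplotype.  Combined with the phased variant calls such data
support, every read in a phase block can be assigned to haplotype 1 or
haplotype 2 of its individual.  The six haplotypes of a trio can then
be genotyped *haploidly* at each candidate site, and the candidate
judged against a much stronger standard than the diploid genotypes
allow: a real DNM shows four parental haplotypes that are all
reference and child haplotypes that are exactly one reference and one
alternate.  An inherited variant hiding behind dropout betrays itself
the moment even a couple of reads from the parent's alternate haplotype
are inspected in isolation -- a haploid pileup needs only 2 reads to
call an allele confidently, where a diploid caller needs a substantial
minor-allele fraction.

## The procedure

`haplodenovo` implements this as four stages over standard files
(VCF 4.2, SAM/BAM with `BX` barcode tags, TSV reports):

1. **Candidate extraction** (`merge_phased_vcfs()`,
   `extract_candidate_dnms()`, `apply_score_threshold()`).  The three
   independently phased single-sample VCFs are merged into one phased
   trio table; phase-set identifiers are namespaced per individual
   because haplotype labels are arbitrary per phase block and never
   comparable across people.  Candidates are sites with observed 0/0
   parents and a heterozygous child; candidate sets from external DNM
   callers can be substituted, and their per-record scores (DQ, PP,
   GL, PL) thresholded -- never recomputed.

2. **Molecule reconstruction and haplotype tagging**
   (`group_reads_into_molecules()`, `assign_molecule_haplotypes()`,
   `tag_reads()`, `split_by_tag()`).  Reads sharing a barcode on one
   chromosome are chained into a molecule while consecutive read starts
   lie within the gap threshold (default 50 kb, standard practice for
   linked-read molecule reconstruction).  Each molecule votes over the
   phased heterozygous sites it covers: a base matching the haplotype-1
   allele is a vote for HP1, matching haplotype-2 for HP2; bases below
   phred 13 or matching neither allele do not vote.  Votes are pooled
   at molecule level -- the premise of the technology is that a barcode
   chain is one haplotype -- and every read inherits its molecule's
   tag.  Any tie, including zero informative votes, yields HP0
   (undetermined), which is the designated channel for "don't know";
   a molecule whose informative sites straddle two phase blocks is
   assigned within the block holding the majority of them, ties again
   HP0.  Per-read voting is available behind a flag for comparison,
   as is trusting pre-existing HP tags produced upstream.

3. **Haploid genotyping** (`pileup_at_sites()`,
   `call_haploid_genotype()`).  For each (individual, haplotype) at
   each candidate site, quality-filtered bases are counted as
   reference, alternate, or other.  The haploid call is deterministic:
   `UNCOVERED` below `min_depth` (default 2, i.e. more than one read
   per haplotype; the depth demand is a user parameter); `CONFLICT`
   when both alleles are convincingly present (minor count >= 2 and
   minor fraction >= 0.15, a pair of thresholds that tolerates one
   sequencing error at typical per-haplotype depths) or on an exact
   ref/alt tie; otherwise the majority allele, `REF` or `ALT`.
   Re-genotyping split alignments with a full diploid caller would
   reach similar calls; an explicit counting rule was chosen so the
   stage is deterministic, fast, and testable in isolation, with all
   three thresholds exposed.

4. **Classification** (`classify_dnms()`, `infer_parent_of_origin()`,
   `write_dnm_report()`).  Each candidate's six haploid calls are
   reduced to one of three labels:

   * `REMOVED` -- positive counter-evidence: any parental haploid
     `ALT` (the inherited-variant signature), any haploid `CONFLICT`,
     or a callable child pattern other than one `REF` plus one `ALT`.
     Reason codes are attached in a fixed precedence
     (`parental-alt-haplotype`, `haploid-conflict`, `child-not-0-1`)
     so reports are deterministic.
   * `L` (low confidence) -- no counter-evidence but missing
     information: an uncovered haplotype, or the full high-confidence
     pattern without a phased child variant.  These are kept for
     further consideration; absence of evidence is not treated as
     evidence of absence.
   * `H` (high confidence) -- all six haploids callable, all four
     parental haploids `REF`, child haploids exactly `REF` and `ALT`,
     and the child's variant phased.

   "Phased" is operationalized as: the child's diploid het call
   carries a phase-set identifier *and* the two child haploid calls
   disagree, which also identifies the haplotype bearing the mutation.
   Parent-of-origin then follows from a transmission vote: every other
   phased het site in the same child phase block where the allele on
   the mutation-bearing haplotype could have been transmitted by
   exactly one parent votes for that parent; the majority decides, and
   ties or empty blocks return `unknown`.

### The X chromosome

Pseudoautosomal positions (configurable BED; hg19 defaults
chrX:60001-2,699,520 and chrX:154,931,044-155,260,560) are routed to
the autosomal rules.  On the remainder of the X a male is hemizygous,
so his X is naturally phased and a single pooled haploid call stands in
for a phase block.  With a female child the autosomal contract runs
over five haploids (father's single X, mother's two, child's two); with
a male child only the mother's two haploids and the child's single X
are consulted, and the high-confidence pattern is mother `REF`/`REF`
with the child's X `ALT`.  Note that mapping quality is typically poor
in the PARs because they are duplicated in the reference; the package
flags rather than filters there.

### HP0 reads

Reads that cannot be assigned to a haplotype still carry information.
When a child haplotype is uncovered, the child's HP0 pileup is checked
for consistency with the original diploid het call (at least one read
of each allele) and the result is reported in an `hp0_supports`
column.  HP0 evidence never upgrades a candidate to `H` and never
causes removal -- it is an annotation for the analyst triaging the
low-confidence list, reflecting that undetermined reads support but
cannot phase a call.

## The simulator

Every stage is testable without external data through
`simulate_trio()`, which generates a synthetic linked-read trio with
complete ground truth.  Design choices, in order of consequence:

* **Abstract allele-vector genomes.**  Variant positions carry
  ref/alt bases; intervening sequence is constant filler.  Alignment
  is out of scope, so reads are emitted pre-placed with coordinates
  while still round-tripping through real SAM and VCF files.  This
  tests the method's logic, not a mapper.  Base-call errors (uniform
  flips to another base, probability `base_error_rate`) are applied at
  variant positions, the only positions any computation reads.
* **Mendelian structure.**  Four parental haplotypes carry planted het
  sites; the child receives one whole haplotype per parent (no
  recombination within the single simulated contig -- molecule-scale
  phasing is insensitive to recombination at this size).  DNMs are
  planted on the child's haplotypes only, split between maternal and
  paternal transmission by `dnm_parent_split`.
* **The artifact mechanism.**  Artifact sites are parental hets whose
  alternate allele sits on the *transmitted* haplotype, so the child
  is genuinely heterozygous there.  At each such site a
  `dropout_severity` fraction of the parent's alternate-bearing
  molecules is withheld from the simulated diploid genotype call,
  which declares the parent heterozygous only when at least
  `het_min_alt` (default 3) alternate reads survive; below that the
  parent is emitted 0/0 and the site enters the candidate list as a
  fake DNM.  The withheld reads remain in the emitted alignments.
  This models the observed phenomenon -- the caller loses the minor
  haplotype's evidence to coverage bias and filtering, while the reads
  are still recoverable by haplotype-aware re-analysis -- and it is
  the regime in which haploid genotyping has its advantage: at
  severity 0.9 and 8x per haplotype about 95% of artifact sites are
  miscalled into the candidate list, yet the parent's alternate
  haplotype remains covered for the classifier to find.  Physically
  deleting 90% of the alternate reads instead would leave both the
  caller and any downstream method blind (about 0.8x surviving
  depth), a scenario no read-based filter can rescue and not the one
  the method addresses.
* **Molecules and reads.**  Molecule lengths are exponential (mean
  30 kb) with uniform starts spilling past the contig ends so interior
  depth is flat; reads are tiled uniformly within molecules to hit the
  per-haplotype depth target in expectation (about 0.2x within each
  molecule, matching linked-read internal sparsity).  No GC bias,
  chimeras, or barcode collisions -- the minimum structure the
  method's assumptions require.
* **Phase blocks from molecule connectivity.**  Adjacent called het
  sites share a phase set when some molecule of that individual spans
  both, giving realistic block fragmentation without implementing a
  phasing algorithm.  Each block's haplotype orientation is flipped at
  random, so VCF haplotype 1 bears no fixed relation to the parental
  origin -- exactly as in real phased VCFs, and the reason
  parent-of-origin must be inferred rather than read off.

### Reference conditions and problem sizes

The `sim_config()` defaults are the package's reference conditions: a
500 kb contig, 300 het sites per parent, 20 DNMs, 200 artifact sites at
dropout severity 0.9, 8x per haplotype, 0.5% base error.  At this size
one replicate simulates ~240,000 reads and runs through the full
pipeline in about a second, so the test suite exercises five-replicate
experiments comfortably; the unit tests use a 50 kb miniature of the
same design.  Under these conditions the pipeline removes ~99% of
artifact candidates while keeping every covered true DNM (the
acceptance script, `scripts/acceptance.R`, recomputes this number from
scratch), consistent with the 80-99% false-positive elimination that
haplotype-based filtering achieves on real linked-read trios.

## What passing tests do and do not show

The simulator emulates the *mechanism* of the dominant false-positive
class and the phasing structure of linked reads.  It does not emulate
mapping artifacts in repeats, indel realignment effects, barcode
collisions, chimeric molecules, GC-dependent coverage, or
quality-score miscalibration.  Passing the suite therefore shows the
decision rules are implemented exactly and behave correctly under the
stated model; performance numbers on real data depend additionally on
upstream alignment and phasing quality.

## Numerical and degenerate-input choices

* Exact vote ties (including zero votes) are HP0; exact haploid
  count ties are `CONFLICT` -- both alleles observed, no majority.
  A tie that fails the minor-evidence rule (possible only as 1 read
  against 1 read at the default depth minimum) is still `CONFLICT`,
  the honest reading of perfectly split evidence.
* Depth 1 is folded into `UNCOVERED`: one read is not enough to call a
  haplotype, but raw depths are reported so the distinction stays
  recoverable.
* A phased genotype without a phase-set identifier is treated as
  unphased for DNM purposes; phase blocks require a PS.
* Multiallelic records are decomposed; allele indices of foreign
  alternates become missing.  Only SNVs are processed by default
  (indels can be enabled but are untested territory).
* Records with any missing parental genotype are never candidates:
  the definition requires *observed* hom-ref parents.
* Coordinates are 1-based inclusive throughout the variant layer;
  alignment offsets are converted at the boundary.

## Known limitations

Trios only (no extended pedigrees or tumor-normal pairs); no
recalibrated numeric DNM quality score (the output is categorical
H/L plus reason codes); haplotype assembly is consumed, not computed;
the haploid genotyper is a counting rule, not a likelihood model, by
design.
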