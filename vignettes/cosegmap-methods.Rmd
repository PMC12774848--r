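---
title: "Mapping recessive trait loci by windowed co-segregation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive trait loci by windowed co-segregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegmap)
library(dplyr)
```

## The problem and the design

cosegmap localizes the causal locus of a monogenic recessive trait from
four whole-genome sequencing libraries of one family: a homozygous
(affected) parent, a heterozygous carrier parent, a pool of
homozygous-phenotype offspring and a pool of heterozygous offspring,
each pool sequenced as a single library and genotyped as one sample.
If a variant is linked to the causal allele, its genotypes must mirror
the phenotype sorting: homozygous in the homozygous libraries,
heterozygous in the heterozygous ones. Far from the locus,
recombination decouples genotype from phenotype and the pattern breaks
down.

Two per-variant predicates formalize this:

* **informative** — the variant passes the quality filter, lies outside
  the repeat mask, belongs to a permitted class, and the *parents*
  already show the expected pattern (homozygous parent `HOM_ALT`,
  carrier parent `HET` under the `alt_is_mutant` orientation). This is
  the denominator.
* **co-segregating** — among informative variants, the *pools* also
  show the transmitted pattern (`HOM_ALT` in the homozygous pool, `HET`
  in the heterozygous pool). A missing pool call never counts as
  co-segregating, and a missing parental call makes a site
  uninformative: 0/0 is not evidence, and absence of a call is not a
  genotype.

The scan statistic in a genomic window *W* is simply

p(W) = #{co-segregating variants in W} / #{informative variants in W},

undefined when the denominator is zero. The causal locus is expected to
sit in the region where p approaches 1.

## Scan parameters

| parameter | default | meaning |
|---|---|---|
| `window_bp` / `step_bp` | 1 Mb / 100 kb | genome-wide sliding window |
| `min_scaffold_bp` | 1 Mb | scaffolds at or below this are not scanned |
| `fine_window_bp` / `fine_step_bp` | 200 kb / 50 kb | fine scan of a candidate region |
| `genomewide_classes` | SNP, MNP | classes counted genome-wide |
| `fine_classes` | SNP, MNP, INDEL | indels join at fine scale |
| `min_interval_coseg` | 100 | peak triage threshold |
| `allele_orientation` | `alt_is_mutant` | see below |

Windows are anchored at position 0 of each scaffold and advance by the
step; the final partial windows are retained and flagged `truncated` so
plots cover the scaffold ends, and undefined windows are plotted as
gaps and excluded from peak calling. The two-tier class scheme reflects
practice: substitution calls are reliable enough for a genome-wide
denominator, while indel calls add local resolution inside an already
credible region.

`min_interval_coseg = 100` separates, by an order of magnitude on each
side, intervals supported by only a handful of co-segregating variants
(single digits to a few tens — typically repeat-adjacent artefacts or
sparse regions) from genuine candidate regions supported by thousands.
Flagged intervals are reported, not deleted, so triage stays auditable.

### Allele orientation

`alt_is_mutant` assumes the reference genome carries the wild-type
allele, so the mutant lineage shows up as `ALT`. When the reference
individual itself carries the mutant haplotype, the expected pattern is
mirrored (`HOM_REF` in the homozygous libraries). `auto` accepts both
patterns, recording per-variant orientation, at the cost of doubling
the accepted parental configurations.

### The peak-calling threshold

Candidate intervals are maximal runs of overlapping-or-adjacent windows
whose proportion reaches a threshold. The default is adaptive:

threshold = max(0.5, (median + max) / 2)

over defined window proportions. The rationale: in any realistic genome
the overwhelming majority of windows are unlinked to the trait, so the
median estimates the background co-segregation level, while the maximum
estimates the linked plateau; the midpoint separates the two modes
regardless of how large a fraction of the genome the linked region
occupies. A high genome-wide quantile (say the 99th percentile) behaves
identically when the linked region is a vanishing fraction of the
genome, but on a small simulated genome — where the linked scaffold can
be a third of all windows — a quantile cuts *into* the linked plateau
and selects only its noise tips, fragmenting the candidate region. The
midpoint rule is scale-invariant in this respect. A fixed threshold can
be set with `scan_config(proportion_threshold =)`.

Each merged interval's supporting counts are recounted over its full
span rather than summed over overlapping windows, so `n_coseg_total`
counts every variant exactly once. Survivors are ranked by maximum
window proportion, then total co-segregating variants, then (scaffold
order, start). Width is reported in Mb rounded to 0.1; density divides
the *unrounded* width and rounds to an integer, matching how such
metrics are conventionally printed (e.g. 13,906 variants over
51.9–56.7 Mb gives 4.8 Mb and 2,897/Mb).

## Consequence annotation

Within candidate intervals, SNV/MNP consequences are called against the
canonical transcript of each overlapping gene — the transcript with the
longest total CDS, ties broken by the lexicographically smallest
transcript ID; this is deterministic and annotation-agnostic, though it
may differ from the transcript another annotator would pick. Codons are
extracted strand-awarely and translated under the standard genetic
code; classes are `synonymous`, `missense`, `stop_gained`, `stop_lost`,
`start_lost`, `splice_site_proximal` (within 2 bp of an exon boundary
inside an intron, or any substitution spanning an exon/intron
boundary), and `non_coding`. MNPs are decomposed codon-wise and report
the most severe class. Indels in a CDS are reported as `indel_in_CDS`
without protein-level detail — frameshift annotation is out of scope.
Codon changes are printed in the RNA alphabet (`UGG>UAG`), the
convention for nonsense-mutation reporting. A reference allele that
disagrees with the genome FASTA is a hard error rather than a warning,
because it almost always indicates mismatched coordinate systems or the
wrong assembly, which would silently corrupt every downstream call.

Alignment columns supporting a candidate missense site are classified
with the Clustal symbols: `*` when all non-gap residues are identical,
`:` when all residues fall within one strong similarity group (STA,
NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW), blank otherwise.

## The synthetic cross

`simulate_cross()` generates data with exactly the statistical
structure the scan assumes, and nothing more:

1. **Founders.** Each marker gets four founder haplotype alleles. A
   fraction (`informative_fraction`, default 0.7) carries the
   founder-informative pattern — the mutant lineage fixed for the
   alternate allele, the carrier's wild haplotype for the reference.
   The remaining markers draw any other biallelic pattern uniformly,
   which includes parental patterns that *look* informative but are
   anti-linked; these contribute realistic non-co-segregating
   informative sites.
2. **Meiosis.** Crossovers per gamete per scaffold are Poisson with
   mean `rate × length_Mb / 100` at uniform positions —
   interference-free, so genetic distance maps to recombinant fraction
   through the Haldane function r(d) = (1 − e^(−2d))/2, giving
   closed-form expectations for calibration tests. The default rate of
   1 cM/Mb is a typical vertebrate genome-wide average.
3. **Pools.** Offspring join the homozygous pool iff homozygous for the
   causal allele (recessive), the heterozygous pool iff carriers; a
   carrier × carrier design discards homozygous wild-type offspring.
   Pool depth per site is Poisson (default mean 30); alternate-read
   counts are binomial at the true pooled allele fraction perturbed by
   a symmetric per-base error (default 0.005). The threshold caller
   mimics a diploid variant caller run on a pooled library: `HOM` when
   the major-allele fraction is at least `f_hom` (0.9), `HET` when the
   minor fraction is at least `f_het` (0.25), missing in between or at
   zero depth.
4. **Parents** are genotyped error-free, as deep individual libraries
   effectively are for the sites that matter here.

Default scale is 3 scaffolds × 10 Mb, 200 markers/Mb, 10 offspring per
pool — a desk-scale cross that runs in a fraction of a second, used 100
times over in the recovery tests. `make_fixture_suite()` writes the
matching FASTA/VCF/BED/GFF3/JSON files, with three synthetic genes
around the causal locus; the causal gene is on the minus strand and
carries the causal genomic C→T inside its CDS so that the coding UGG
(Trp) codon becomes the UAG stop — the configuration in which a
genomic C→T produces that codon change. Non-causal markers inside the
synthetic CDSs are dropped so the planted stop is the only
protein-truncating variant, which makes the end-to-end assertion sharp.

### What the simulator does *not* emulate

Read mapping bias, reference bias beyond the optional orientation flip,
base-quality structure, indel realignment artefacts, structural
variants, non-uniform recombination (hotspots), crossover interference,
and linkage disequilibrium among founder haplotypes beyond the single
mutant haplotype. Passing the recovery tests therefore shows the scan
is correct *given* its genotype-level model; it does not certify
performance against alignment- or caller-level artefacts in real data.

### Resolution at desk scale

With 10 offspring per pool, one recombinant gamete shifts a pooled
allele fraction by only 0.05, which the `f_hom = 0.9` caller absorbs;
co-segregation therefore forms a plateau spanning several centimorgans
around the causal locus, and the honest desk-scale candidate interval
is wide — typically the whole 10-Mb causal scaffold. Real designs
localize more finely because their genomes are two orders of magnitude
larger than the linked region and their scans accumulate many more
informative windows; at either scale the top-ranked interval contains
the causal locus, which is what the recovery tests assert (≥95 of 100
replicates). Co-segregation still decays monotonically with genetic
distance within the plateau, and the suite checks this by Spearman
correlation on distance-binned means.

## Numerical and degenerate-input choices

* Window counts use sorted-position interval counting and are tested
  bit-for-bit against a naive per-window recount on 1,000 random
  instances.
* Genotypes are stored as alternate-allele dosage (0/1/2/NA); phased
  and unphased VCF genotypes are equivalent.
* Multi-allelic sites are skipped and counted, never decomposed.
* Records failing FILTER stay in the table with `pass_filter = FALSE`;
  exclusion happens in the scan, keeping filtering auditable.
* BED masks are merged to disjoint intervals on load; queries are
  identical before and after merging.
* An empty pool draw (possible in principle in a carrier × carrier
  design) triggers a warning and a redraw, capped at 100 attempts.
* Fixture files contain no timestamps, so identical seeds give
  byte-identical files.

## Problem sizes used by the test suite

Scan exactness uses 1,000 random instances of up to 5 scaffolds and a
few thousand variants; recovery uses 100 default-scale crosses;
calibration uses 1,000 replicates of a 5-marker transmission design
(20,000 gametes per distance) and 1,000 offspring for the Mendelian
ratio check. These sizes give the comparisons their stated resolution
(2 SE bands on proportions of order 0.05–0.3) while keeping the whole
suite in the minutes range on one CPU.

## Known limitations

* The co-segregation statistic is genotype-class based; allele-
  frequency BSA statistics (Δ-SNP-index, G′) are out of scope.
* One consequence call per gene (canonical transcript only); no HGVS
  nomenclature, UTR/regulatory effects, or frameshift protein
  consequences.
* The scan assumes a single fully penetrant recessive locus; multi-locus
  traits and misphenotyped offspring are not modelled.
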