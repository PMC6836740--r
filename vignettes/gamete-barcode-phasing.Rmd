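---
title: "Gamete barcode phasing: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamete barcode phasing: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenphase)
```

## The model

A diploid individual carries two haplotypes, A and B, that differ at
heterozygous SNP sites (~1 site per 100 bp in a highly heterozygous
outcrosser). Each haploid pollen cell inherits, per chromosome, one of the
two haplotypes with a small number of meiotic crossovers (MCOs) between
them. Single-cell whole-genome amplification (MDA) of a pollen cell yields
uneven, incomplete coverage: each cell observes only a fraction of the SNP
sites (allelic dropout), and occasionally reports the wrong allele.

The phasing unit is a long haplotype-pure fragment (a BAC clone or
contig). For a fragment anchored to a chromosome, every SNP on it is
encoded as a binary **barcode** over the cells: bit $c = 1$ if cell $c$'s
observed base equals the fragment's base, $0$ if it differs *or was not
observed*. Two fragments from the same haplotype and the same recombination
context share a barcode; fragments from opposite haplotypes carry
complementary barcodes at mutually informative bits. Distances between
barcodes are hamming distances, $d(x, y) = \mathrm{popcount}(x \oplus y)$.

Because each cell may cross over, the family barcode of one haplotype is
not constant along a chromosome: every crossover in one cell flips that
cell's bit from the crossover position onward. Phasing therefore chains
fragments positionally, letting the two family barcodes drift, and a
cell's sequence of per-fragment bits along a chromosome is a **phase
track** whose persistent switches are the crossovers.

## Pipeline parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_coverage` (anchor) | 0.80 | minimum breadth of coverage (interval union / fragment length) to assign a chromosome |
| `k`, `max_hits` (anchor) | 21, 10 | canonical k-mer length; k-mers at more locations are dropped as repetitive |
| `min_cells` (barcode) | 2 | a SNP's genotype must be observed in at least this many cells |
| `min_snps` (phase) | 3 | fragments with fewer informative SNPs are unphaseable: one or two SNPs cannot outvote a single genotype error |
| `min_margin` (phase) | 1 | minimum difference between the distances to the two families |
| `window` (phase) | 5 | family barcode = bitwise majority of the last 5 members, allowing drift across crossovers |
| `min_consensus_support` (phase) | 0.6 | minimum mean per-bit agreement of a fragment's SNP barcodes with its consensus |
| `min_run` (mco) | 2 | a phase switch must persist for this many informative points; `min_run = 1` is the literal switch rule |

## The simulator

`sim_config()` defaults emulate the study system: 12 haploid cells,
heterozygosity 0.0102 per bp, per-cell SNP observation fraction drawn
uniformly from (0.50, 0.78), genotype error rate $10^{-3}$, Poisson(1.3)
crossovers per chromosome per gamete with positions from a symmetric
Beta(0.5, 0.5) density (concentrating mass at both chromosome ends, as
observed in real recombination landscapes), and haplotype-pure fragments
of 10–120 kb. The genome itself is desk-scale — two chromosomes of 200 kb
by default — so the full pipeline runs in seconds; all rates are the
study's, only the sequence length is reduced.

What it does **not** model (documented simplifications): dropout is
site-independent, whereas real MDA drops out in long tracts; there are no
chimeric amplification artifacts, no copy-number bias, no read-level noise
(fragment genotypes are compared allele-to-allele), and no obligate
crossover (a chromosome may receive zero crossovers). Structural variants
other than SNPs are absent. Passing tests on these simulations therefore
demonstrate the correctness of the barcode/phasing/crossover logic under
the stated noise model, not robustness to every artifact of real
single-cell data — the tract structure of real dropout, in particular,
would make per-fragment cell bits more all-or-none than simulated.

## Numerical and design choices

* **NOCALL collapses to 0** in barcodes, reproducing the published
  encoding. The tri-state genotype matrix and an observed-cell mask are
  retained, and `masked_distance = TRUE` computes distances over observed
  bits only, as a refinement option. With the two-cell minimum-support
  filter in place the collapse has little effect, which is why it is the
  default.
* **Barcode-frequency filtering** is realized as *consensus support*: the
  mean fraction of a fragment's non-NOCALL entries agreeing with its
  consensus bit. Under site-independent dropout, exact barcode types
  fragment combinatorially (every SNP row gets a different dropout
  pattern), so a literal threshold on the most frequent exact type would
  reject nearly everything; per-bit agreement measures the same
  homogeneity robustly. Type counts are still tallied and reported.
* **Seeding and ties.** The first phaseable fragment seeds family A; the
  complement seeds B. Label orientation per chromosome is therefore
  arbitrary, and evaluation optimizes the orientation per chromosome (no
  trans-chromosome linkage exists in gamete data). Every tie — equal
  distances, equal majority counts — breaks deterministically toward
  "unphased" or toward the previous state, never randomly.
* **Second pass.** After the chain pass, every fragment is re-scored
  against the final piecewise family barcodes at its position; calls that
  flip between passes are demoted to unphased. This guards against a
  poorly chosen seed fragment.
* **Track-point positions.** A cell's track point on a fragment is placed
  at the median position of the SNP rows where that cell voted its
  majority bit, not at the fragment midpoint. A fragment spanning a
  crossover then localizes the cell's evidence on the correct side of the
  breakpoint, which is what makes the bracketing invariant (true
  breakpoint inside the event interval) exact in noise-free data.
* **Crossover detectability.** A breakpoint is only observable when
  informative markers flank it before the neighboring breakpoint: an even
  number of crossovers between two adjacent markers cancels (parity), and
  fragment coverage decays to zero at chromosome ends while the crossover
  density peaks there. Evaluation therefore classifies truth breakpoints
  by detectability (odd-sized gap group, at least `min_run` informative
  points on each side up to the neighboring group) and requires exact
  recovery on the detectable set. With `min_run = 2`, short runs at track
  ends are suppressed as indistinguishable from noise.
* **Anchoring** votes with canonical k-mers, so it is strand-invariant,
  and is performed against the diploid reference (both haplotype copies
  labeled by chromosome): haplotype identity comes from phasing, never
  from anchoring. Equal best coverage on two chromosomes is reported
  `ambiguous` rather than resolved arbitrarily.
* **Mosaic classification** aligns each haplotype copy to the reference
  gene (global, affine gaps: match +1, mismatch −1, open −4, extend −1)
  and projects to reference coordinates; pairwise alignment replaces a
  three-way multiple alignment because only the projection to the
  reference is needed and pairwise dynamic programming is deterministic.
  Indel-only A/B differences are excluded from diagnostic sites and
  counted separately. The minority haplotype's sites are the mosaic
  errors; any exonic minority site classifies the gene `mosaic_exon`
  (exon takes precedence over intron when both contain errors), and a
  gene whose diagnostic sites are mostly matched by neither haplotype is
  `unresolved`. A minority tie breaks toward the segment after the first
  switch.
* **Per-SNP error correction** (penalized bit-flip optimization over
  adjacent SNPs) is deliberately not implemented; the barcode majority
  plus the support filters carry the noise levels simulated here.

## Problem sizes

The test suite and the acceptance script run the full pipeline on two
200 kb chromosomes with 300 fragments (the noisy-regime sweep uses ten
replicates at 2 × 150 kb with 200 fragments), chosen so each end-to-end
run finishes in well under a minute while every fragment still carries
hundreds of SNPs — the same marker density per fragment as the real
system.

## Known limitations

* Unanchored fragments are not rescued by overlap-based placement; they
  are reported `unphased(unanchored)`.
* Haplotype-resolved sequence assembly downstream of phasing is out of
  scope; `export_family_fasta()` hands the partitioned fragments to an
  external assembler.
* Gene conversions and crossover interference are neither simulated nor
  detected.
* The crossover rate recovered from markers underestimates the simulated
  rate whenever crossovers fall beyond the outermost informative marker —
  on short simulated chromosomes with an end-biased density this is
  common, and the acceptance output reports both the detected and the
  simulated rates.
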