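---
title: "Mapping a recessive EMS mutant by dual-bulk SNP-index analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive EMS mutant by dual-bulk SNP-index analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

## The mapping problem

An EMS-mutagenized line carries a few hundred induced point mutations,
homozygous and private to the mutant. One of them — recessive, fully
penetrant in the cases this package targets — causes a visible phenotype.
Crossing the mutant to its own wild-type parent and selfing the F1 yields an
F2 in which every induced SNP segregates 1:2:1, and the phenotype segregates
3:1 wild-type : mutant. Because the cross is to the isogenic parent, *all*
segregating SNPs are mutant-derived, which is what makes the SNP-index
signal clean.

Two phenotype-selected DNA bulks are sequenced: the MP bulk (individuals
**with** the mutant phenotype) and the WP bulk (individuals **without** it).
For each SNP and bulk the **SNP index** is the fraction of reads carrying
the mutant-line allele,

$$\text{index} = \frac{n_\text{alt}}{n_\text{ref} + n_\text{alt}},$$

undefined at zero depth. The genetics pin down its expectation:

* **MP bulk.** Every member is homozygous mutant at the causal SNP, so the
  causal index is exactly 1 (with error-free reads). At a linked locus with
  recombination fraction $r$ the expected mutant-allele frequency is
  $1 - r$; at an unlinked locus it is $1/2$.
* **WP bulk.** The phenotypically wild-type class of an F2 is
  $AA : Aa = 1 : 2$, so the expected mutant-allele dosage is
  $(0 \cdot 1 + 1 \cdot 2) / (2 \cdot 3) = 1/3$ at the causal SNP, rising
  monotonically to $1/2$ for unlinked loci. `expected_wp_index()` computes
  this from the class composition rather than hard-coding it.

The causal SNP is therefore the one whose MP index is 1 *and* whose WP
index is about 1/3 — the dual-bulk criterion that `candidate_snp_filter()`
implements. Fixed background differences (index 1 in both bulks) and
unlinked noise (1/2 in both) fail it.

## The pipeline

`run_pipeline()` chains the stages:

1. **Per-SNP indices** for both bulks (`compute_index_table()`), then a
   depth filter (`filter_sites()`, default 10 reads per bulk — indices from
   fewer reads are dominated by sampling noise; the depth cutoff is the one
   place coverage decisions happen, which is why the simulator emits
   zero-depth sites rather than dropping them).
2. **Sliding-window smoothing** of the MP index
   (`sliding_window_mean()`, 1 Mb windows advanced by 1 kb). Windows are
   anchored at 0 and half-open; a SNP at 1-based position $p$ belongs to
   window $[s, s+W)$ iff $s \le p-1 < s+W$. The two-pointer implementation
   is required (and tested) to equal naive per-window recomputation.
3. **Candidate-region detection** (`detect_candidate_regions()`): maximal
   runs of windows with mean index at or above 0.9. Literal mean 1.0 is
   brittle under sequencing error and finite depth, so "index of 1 or
   approximation" is operationalized as a 0.9 threshold, configurable.
4. **The dual-bulk filter** (`candidate_snp_filter()`), a single
   conjunction of per-record verdicts so that filter order cannot matter:
   * MP index $\ge$ 1 − 0.1: the tolerance mirrors the window threshold,
     since a depth-30 site at error rate 0.005 occasionally shows 29/30
     mutant reads;
   * position inside the candidate region (the top detected region when
     none is configured);
   * WP index inside $[1/6, 1/2)$ *and* not rejected by an exact binomial
     test against 1/3 at $\alpha = 0.05$. The band separates the three
     genetic hypotheses (causal 1/3, unlinked 1/2, fixed background 1);
     the test scales the tolerance with depth. The two-sided p-value uses
     the minimum-likelihood convention (the sum of outcome probabilities no
     larger than the observed one), computed by direct summation;
   * an exonic nonsynonymous (or stop-gain) annotation, when gene models
     are available.

   Survivors are ranked by $|\text{WP index} - 1/3|$, ties broken by
   genomic coordinate for determinism. Every record keeps all its verdicts
   in the report; nothing is silently dropped.
5. **Coding-effect annotation** (`annotate_variants()`): region classes
   with precedence exonic > UTR > intronic > upstream/downstream (1 kb
   flanks, strand-aware, in the style of exon-centric annotators) >
   intergenic; codon arithmetic `codon = floor((cds_pos - 1)/3) + 1` (CDS
   position 745 is codon 249); translation under the standard genetic code
   only.

The packaged ten-SNP worked example (`load_table1()`, `table1_demo()`)
exercises stage 4 end to end: ten SNPs with MP index 1 narrow to six inside
the 23–27 Mb candidate interval, two nonsynonymous ones, and a single
survivor at position 26,056,055 with WP index 0.35.

```{r table1}
demo <- table1_demo()
demo$cascade
demo$top[, c("chrom", "pos", "ref", "alt", "wp_index", "mp_index", "orf")]
```

## The cross simulator

`simulate_cross()` makes every downstream stage testable without external
data. Its defaults are the study conditions, not tuning knobs:

* **Genome**: one 30 Mb chromosome with 20 single-exon CDS intervals;
  positions up to the high-20-Mb range are representable so candidate
  coordinates look realistic.
* **Genetic map**: uniform 4 cM/Mb — a rice-like genome-wide average — with
  a Poisson, no-interference crossover process. The crossover count per
  gamete is Poisson in the chromosome's genetic length; consequently the
  recombination fraction between loci at map distance $d$ Morgans is
  Haldane's $(1 - e^{-2d})/2$, which gives closed-form oracles for every
  linkage test.
* **EMS spectrum**: 100% G:C→A:T transitions by default (EMS chemistry),
  configurable down to 0. Exactly one variant is causal, placed in coding
  sequence such that its transition is nonsynonymous.
* **Cross**: fully homozygous mutant parent (the generation at crossing is
  taken as advanced enough for residual heterozygosity to be negligible),
  F1 heterozygous at every variant, F2 of 208 individuals with phenotype
  counts drawn by 3:1 segregation. A `match_paper` switch instead fixes
  the composition at 164 wild-type : 44 mutant, one observed draw of that
  segregation. If a random draw leaves a phenotype class smaller than its
  30-individual bulk, more F2 individuals are simulated until both bulks
  fill.
* **Phenotype**: fully penetrant recessive readout of the causal genotype;
  an optional misclassification rate exists for robustness experiments and
  defaults to 0.
* **Sequencing**: per site and bulk, depth is Poisson(30) and each read
  carries the mutant allele with probability $q(1-e) + (1-q)e$, with
  per-read miscall rate $e = 0.005$. Read counts, not reads, are the unit
  of exchange: alignment and variant calling are upstream of this package's
  scope.

Everything is reproducible byte-identically from the seed, including the
bulk memberships recorded in the ground truth.

### What the simulator does not emulate

Mapping results on simulated counts show that the statistics and decision
rules behave as the genetics dictates. They do not probe: alignment and
variant-calling artifacts (repeats, indel realignment, strand bias),
non-uniform recombination maps or interference, segregation distortion,
residual heterozygosity in the mutant parent, polygenic or incompletely
penetrant traits, or contamination between bulks. Real data adds those
failure modes on top.

## Numerical and degenerate-input choices

* Zero-depth sites carry `NA` indices and are removed only by the depth
  filter; `NA` never propagates into window means (windows average defined
  member indices, and a window with no defined member is `NA`).
* Region intervals are reported 0-based half-open (BED); variant positions
  are 1-based (VCF/GFF3). `pos_to_bed()` / `bed_to_pos()` are exact at the
  boundaries and tested both ways.
* Unsorted inputs are an error, not silently reordered, because they signal
  a malformed upstream file.
* A record that survives every other filter but lacks an annotation is an
  error (a broken join), not a silent drop.
* The WP-band/target containment is a warning rather than an error, so a
  deliberately exclusive band can be used to demonstrate an empty candidate
  report.
* Frameshift reports carry *both* the codon containing the edit point and
  the first codon whose amino acid actually changes, verified against full
  re-translation. The two differ in general (an insertion after CDS
  position 170 sits in codon 57, but the first changed residue may come
  later), and published descriptions do not always state which convention
  they use; reporting both keeps the output unambiguous.

## Known limitations

With 30-individual bulks sequenced at mean depth 30, the WP index at the
true causal SNP is noticeably overdispersed relative to pure read-sampling
noise: the bulk's allele frequency is itself a draw (dosage sum
$\sim \mathrm{Bin}(30, 2/3)$, SD $\approx 0.043$ on the frequency scale) on
top of binomial read noise (SD $\approx 0.086$ at depth 30). Enumerating
bulk compositions, Poisson depths and read counts shows the causal SNP
satisfies the default WP band-plus-test criterion with probability about
0.90 at these sizes, and the replicate recovery experiments in the test
suite measure the same rate empirically. Deeper sequencing, larger bulks, a
wider band or a smaller $\alpha$ all raise it; at the default study sizes a
miss rate of roughly one in ten is intrinsic to the dual-bulk criterion,
and a practitioner should treat a near-miss WP index (e.g. just above 0.5)
as grounds for relaxing the band, not for discarding the locus.

The test suite and examples run at desk scale deliberately: one 30 Mb
chromosome, 300 simulated EMS SNPs, bulks of 30 at depth 30, 100 replicate
runs, 5 Mb window-oracle instances. These sizes were chosen so the whole
suite exercises every law (segregation, linkage, window equivalence,
recovery) at meaningful precision while staying quick to iterate on.
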