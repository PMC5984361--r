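---
title: "Detecting somatic selection with substitution-bias-corrected dN/dS"
author: "ssbdnds authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic selection with substitution-bias-corrected dN/dS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbdnds)
```

## The problem

Somatic mutations accumulating in a tumour are shaped by selection: driver
genes gain an excess of protein-altering mutations (positive selection),
while genes whose function the tumour cannot afford to lose are depleted of
them (negative, or purifying, selection). The classical statistic for this
is dN/dS — the rate of non-synonymous change per non-synonymous site
divided by the rate of synonymous change per synonymous site. A ratio
above one indicates positive selection, below one negative selection.

Applying dN/dS to somatic data naively is misleading, because somatic
mutational processes are heavily biased: transitions outnumber
transversions, methylated CpG sites mutate an order of magnitude faster
than other cytosines, and different tumour types carry different
signatures. A gene whose sequence composition is rich in mutable contexts
will accumulate more mutations without any selection acting on it, and the
naive ratio mistakes that for selection. `ssbdnds` implements a corrected
estimator in which site counts are reweighted by the observed cohort
mutation spectrum before the ratio is formed.

## Site counting

Every coding position of a transcript can change into three alternate
bases. Each possible change contributes 1/3 of a site to either the
non-synonymous total (`Na`) or the synonymous total (`Ns`) of its
substitution class, depending on whether the induced codon change
preserves the amino acid. This is the approximate (Nei–Gojobori-style)
counting scheme: it needs no evolutionary model and gives the exact
conservation law that `sum(Na) + sum(Ns)` over all classes equals the
counted CDS length — a property the test suite checks for every
transcript.

Two conventions matter:

* Changes to or from a stop codon count as non-synonymous (nonsense
  mutations are non-silent). The terminal stop codon itself is excluded
  from counting, but still supplies flanking context for its neighbours.
* The per-change weight of 1/3 is an assumption; the weighting of
  multi-path codon changes in the original approximate method is not
  restated anywhere, and 1/3 is the variant that makes the conservation
  law exact and therefore testable.

## Substitution classes

Two class systems are provided:

* **SSB7** — six strand-collapsed base changes (`A>T`, `A>C`, `A>G`,
  `C>A`, `C>T`, `C>G`) plus `CpG>N` for any change whose reference base
  lies in a CpG dinucleotide on either strand, regardless of the alternate
  allele. Purine-reference changes map through the reverse complement.
  Unknown neighbours at sequence boundaries are treated as non-CpG.
* **SSB192** — the full pyrimidine-centred trinucleotide context plus a
  strand flag: 6 substitutions x 16 flanking contexts x 2 strands. The
  exact parameterisation (which factor of the 192 is strand) is our
  choice, documented as an assumption; only the count 192 is fixed
  externally. Boundary positions without full context are excluded from
  SSB192 site counting (so its conservation total is the CDS length minus
  the one or two context-less positions); SSB7 keeps the exact law.

All headline analyses use SSB7; SSB192 is available through the `system`
argument throughout.

## The SSB correction

Let `expected_k` be class `k`'s share of all sites in the transcriptome,
`observed_k` the class's share of the cohort's coding mutations. The
fold-change weight `w_k = observed_k / expected_k` rescales each class's
site counts:

```
Na' = sum_k w_k * Na_k,    Ns' = sum_k w_k * Ns_k
```

This has a defining property (tested): when every class is observed, the
corrected class shares `w_k (Na_k + Ns_k) / sum_j w_j (Na_j + Ns_j)`
reproduce the observed mutation-class frequencies exactly. In other
words, the corrected site totals are what the raw totals would have been
had the mutational process been uniform. A short calculation shows the
consequence: for every gene the expected non-silent count under
neutrality is proportional to `Na'` and the expected silent count to
`Ns'`, so `dN = n/Na'` and `dS = s/Ns'` estimate the same rate and their
ratio is centred on one for any signature.

Observed frequencies are computed at **cohort** level by default and
applied to every gene's spectrum. Per-gene observed frequencies are
selectable (`weights_scope = "gene"`), but for typical per-gene mutation
counts they are dominated by sampling noise, so cohort scope is the
default and the one used in all benchmarks. Classes with zero observed
mutations get weight zero — they contribute no mutations, so removing
their sites cannot bias either rate; a warning is raised when more than
two classes are empty, since that indicates a very sparse cohort.

## The neutrality test

Under the passenger-synonymous assumption — synonymous somatic mutations
are selectively neutral passengers — the silent count calibrates the
expected non-silent count. Conditional on a gene's total coding mutation
count `n + s`, the non-silent count is binomial with success probability
`pi = Na'/(Na' + Ns')` under neutrality. The test is the exact two-sided
binomial test, with two-sidedness defined by summing all outcomes whose
point probability does not exceed that of the observed outcome (the
minimum-likelihood rule). The precise form of the test behind the
published gene lists is not restated in public text; the exact binomial
is the minimal test implied by the passenger argument, and is our
documented choice.

Multiple testing uses Benjamini–Hochberg; genes with `Q < 0.1` are
labelled positive or negative by the side of one their ratio falls on.
When `s = 0` the ratio is undefined (`NA`) but the P value is still
computed; such genes can only be called positive. The 95% confidence
interval is a log-ratio normal approximation,
`exp(log(dN/dS) +/- 1.96 sqrt(1/n + 1/s))` — again a documented choice,
since no CI method is stated externally.

The global (exome-wide) estimate treats the whole exome as a single gene:
summed spectra, cohort weights, summed counts. Cohorts are combined into
a pan-cancer estimate by weighting each cohort's corrected site totals
with its share of (post-filter) mutations and summing the counts;
cohort-specific correction weights are used, since pooling weights before
combination is equally defensible but not what the per-cohort workflow
produces.

## Mutation filters

Six per-mutation exclusion criteria with their printed operators: VAF
< 0.1; alternate reads < 5; population allele frequency >= 1%; segmental
duplication score > 0.5; simple-repeat overlap; ABB score <= 0.7. A
record missing an annotation passes that criterion with a warning (the
external scores are cohort-specific resources). The drop ledger
attributes each dropped record to the first violated criterion in the
order above, so input = retained + ledger sum. The diploid-only analysis
keeps mutations whose copy-number segment mean lies in the closed band
[-0.01, 0.01]; the boundary is taken inclusive, a convention choice at
measure-zero for real data.

Gene-level filters: an external blocklist (known sequencing artefacts or
non-expressed genes — expression filtering itself is out of scope and
enters only as a list), genes with `Na/Ns > 5` (extreme site composition
makes the silent calibration fragile), and genes with no coding
mutations.

## Epitope regions and the permutation test

Epitopes are 1-based closed amino-acid intervals on proteins; amino acid
`i` maps to CDS nucleotides `[3(i-1), 3i)`, so every mask is
codon-aligned. All intervals are fused into a super-epitope; the
remaining parts of the same proteins (only those proteins) form the
super-non-epitope, after excluding the first two amino acids of every
protein — the N-terminal methionine region is atypical in both mutation
calling and peptide processing. Region dN/dS restricts counts and sites
to the mask and reuses the cohort-level correction weights; recomputing
weights from a region's own mutations would absorb exactly the selection
signal being measured.

The permutation test shifts each interval within its own protein,
preserving its length, to a start drawn uniformly among placements fully
contained in the protein's non-epitope territory (amino acids >= 3).
Full containment is the default because partial overlap with the true
epitope would leak signal into the null; `placement = "overlap"` relaxes
this for sensitivity analyses. Intervals
are shifted independently; permuted intervals of the same protein may
collide and are merged before counting, mirroring how the observed mask
is merged. Each permutation recomputes the region dN/dS with the fixed
cohort weights; the one-sided exact P value (toward negative selection)
uses the add-one rule `p = (1 + #[null <= observed]) / (1 + B)`, which can
never return zero. Permutations without a silent mutation give an
undefined ratio and never count as at-or-below the observation, which is
conservative. Intervals with no eligible placement (epitope nearly
covering the protein) are skipped from the null with a warning rather
than failing the whole test.

## The simulator

The generator emulates the features of somatic exome data the estimator
is sensitive to: codon structure, sequence-context-dependent mutation
classes, a cohort-level signature, and gene composition.

* `make_toy_transcriptome()` builds CDS sequences codon-wise: `ATG`, a
  body drawn from the 61 sense codons with probabilities induced by a
  per-base GC bias (no internal stops can arise), and a stop codon.
  Lengths are log-normal (median 1300 nt, `sdlog` 0.55, floored at 30
  codons), matching the median-to-mean ratio of human CDS lengths.
* `simulate_neutral()` draws each SNV by sampling a class from the
  signature, then a (position, alternate) pair uniformly among the
  class's eligible coding changes across the transcriptome. Gene
  composition therefore enters through per-gene eligible-site counts, and
  the realised class frequencies recover the signature within multinomial
  error (tested). The default signature is a pan-cancer-like spectrum
  dominated by C>T with a strong CpG component
  (`default_signature()`).
* `impose_selection()` retains each non-synonymous mutation of a targeted
  gene with probability `min(omega, 1)`; for `omega > 1` it adds
  Poisson(`(omega-1) * n`) extra non-synonymous mutations drawn from the
  gene's class-weighted eligible sites. Synonymous mutations are never
  touched. By construction the target omega is the asymptotic measured
  dN/dS, which the parameter-recovery tests verify for omega in
  {0.2, 0.5, 2, 5}.

What the generator does **not** emulate: inter-patient heterogeneity of
signatures and mutation rates, regional mutation-rate covariates
(replication timing, expression), indels and MNVs, copy-number structure,
and germline contamination. Passing benchmarks therefore demonstrate the
statistical behaviour of the estimator under its own assumptions, not
robustness to every artefact of real tumour data — the quality filters
exist precisely because real data violate these assumptions.

## Benchmarks and problem sizes

`benchmark_recall()` simulates a neutral cohort, imposes a selection
panel (default: genes with omega drawn from {0.1, ..., 0.9}), round-trips
the cohort through the MAF dialect so the full I/O path is exercised,
runs the pipeline, and scores `Q < 0.1` calls against the truth.

The packaged analyses run at desk scale: a fixed fraction (0.1 in the
test suite, 0.15 in `scripts/acceptance.R`) of a 19,000-gene
transcriptome, a 500-gene panel and the nominal cohort sizes, shrunk by
the same factor. This preserves the per-gene mutation density — the
quantity recall actually depends on — while keeping a full benchmark in
tens of seconds. Recall under this panel is limited by test power, not
by the caller: at the one-million-SNV density (about 53 mutations per
average gene) only omega <= 0.3 is reliably detectable at `Q < 0.1`, and
at the three-million density only omega <= 0.6, so a uniform
{0.1, ..., 0.9} panel caps mean recall near 25% and 55% respectively.
Published recall figures based on differently composed panels (skewed
toward stronger selection) are correspondingly higher.

## Numerical choices and degenerate inputs

* Exact binomial P values use the minimum-likelihood two-sided rule with
  the conventional `1 + 1e-7` relative tolerance when comparing point
  probabilities (identical to `binom.test`; cross-checked in the tests).
* P values are capped at 1; permutation P values are bounded away from 0
  by the add-one rule.
* Genes with `na_corr` or `ns_corr` of zero (possible when several
  classes are unobserved) are excluded with a warning rather than
  propagating infinities.
* Transcripts must be in-frame, A/C/G/T-only, and free of internal stops
  when a terminal stop is declared; violations are classed errors at
  load, not silent coercions.
* Identical seeds give byte-identical simulated cohorts, MAF files and
  permutation nulls; all exported entry points accept a seed and restore
  the caller's RNG state.

## Known limitations

* One transcript per gene; genome-coordinate annotation (splicing, UTRs)
  and alternative codon tables are out of scope. Mutations are consumed
  in CDS space; mapping from genomic MAFs is the caller's concern.
* The cohort-level correction assumes a shared signature across genes;
  strong per-gene signature deviations (e.g. localised APOBEC showers)
  are absorbed only by the `weights_scope = "gene"` variant, at the cost
  of noise.
* The binomial test conditions on the total mutation count and therefore
  ignores over-dispersion across patients.
* The epitope analysis measures depletion within annotated intervals
  only; binder prediction, HLA typing and epitope discovery are upstream
  of this package.
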