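---
title: "Candidate-gene association genetics with cgassoc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene association genetics with cgassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgassoc)
```

# Overview

`cgassoc` implements the statistical workflow of a candidate-gene
association study in an outcrossing plant population, of the kind used to
connect nucleotide variation in a single resequenced gene — here modelled
on a ~4.4 kb UDP-glucuronate decarboxylase (UXS) gene of *Populus* — to
quantitative growth and wood-property traits. The pipeline has six layers:

1. **Gene annotation**: a strand-aware partition of the gene into
   5'UTR / exon / intron / 3'UTR regions, with Nei–Gojobori fractional
   synonymous/nonsynonymous site counting on the consensus coding sequence.
2. **Nucleotide diversity**: segregating sites *S*, nucleotide diversity
   π, Watterson's θ~w~ and bp-per-SNP frequencies per region and for the
   gene, with gap-containing and multiallelic columns excluded.
3. **Linkage disequilibrium**: pairwise *r*² from unphased diploid
   genotypes via a two-locus EM, permutation significance, decay-with-
   distance fits (ordinary least squares and the Hill–Weir drift
   expectation) and haplotype-block detection at *r*² > 0.75.
4. **Association**: a Q+K mixed linear model
   *y* = µ + *Qv* + *Zu* + *e* with Var(*u*) = σ²~a~*K*, Ritland
   marker-based kinship, Storey q-values, and gene-action decomposition
   (2a, d, d/a) of significant markers.
5. **Haplotype trend regression**: EM haplotype dosages over 3-SNP
   sliding windows regressed on each trait, with permutation p-values.
6. **Validation**: Mendelian segregation χ² tests and single-marker ANOVA
   in an F1 full-sib cross.

Because the study's raw data are external, the package carries a
first-class synthetic-data module that generates inputs with the
statistical structure the analysis assumes; every stage is exercised and
tested end-to-end on those synthetic inputs.

# The models

## Diversity statistics

For an alignment of *n* haplotype sequences, a column is *usable* when it
contains no gap character and at most two alleles; *S* counts the
biallelic usable columns. π is the average proportion of differing usable
sites over all *n(n−1)/2* sequence pairs, computed column-wise as
Σ 2·c₁c₂ / (n(n−1)) over segregating columns, divided by the usable
length. θ~w~ = S / (a~n~ L) with a~n~ = Σ_{i=1}^{n−1} 1/i. No
finite-sites (Jukes–Cantor) correction is applied anywhere: diversity is
reported as raw proportions, matching the defaults of the standard
desktop tools for this analysis. SNP frequency is reported as
round(L/S) bp per SNP, half rounded away from zero.

Synonymous and nonsynonymous site denominators follow Nei–Gojobori
counting: at each codon position the synonymous fraction is the number of
the three possible single-base changes that preserve the amino acid,
divided by 3; changes creating a stop codon count as nonsynonymous.
Observed stop-creating SNPs are labelled nonsense but pooled with
missense as "nonsynonymous" in the region table. The codon context is
the alignment **consensus** (majority base per column), not a designated
reference individual — the choice matters only when the derived allele is
the majority, and no reference allele is defined for a population sample.

## Two-locus EM and r²

Genotypes are unphased, so the four haplotype frequencies of a pair of
biallelic loci are estimated by EM over the double-heterozygote phase
ambiguity. The EM runs on the 3×3 genotype count table (the sufficient
statistic), making all-pairs scans cheap; it starts at linkage
equilibrium and stops when the largest frequency change is below 1e−8 or
after 200 iterations. When coupling and repulsion solutions are exactly
equally likely (the all-double-heterozygote degeneracy) the EM remains at
its symmetric stationary point and reports D = 0; r² is identical in
either resolution, so this tie-break only fixes the sign of D.

The decay of r² with distance is summarised two ways, because the
published convention ("least squares fit of r² to its expectation") is
ambiguous between them: an ordinary least-squares line, and the
Hill–Weir drift expectation
E[r²] = [(10+C)/((2+C)(11+C))]·[1 + ((3+C)(12+12C+C²))/(n(2+C)(11+C))]
with C = ρd, fitted by least squares over the single composite parameter
ρ. Both crossing distances at a threshold (default r² = 0.1) are
reported; "beyond range" (NA) when the fitted curve does not cross
within the observed distances.

Haplotype blocks are maximal runs of ≥ 2 consecutive SNPs in map order
whose *every* within-run pair exceeds the r² threshold (0.75 by
default), found greedily left to right. Published block lists for this
kind of analysis give contiguous index ranges without defining an
algorithm; the all-pairs rule over consecutive SNPs is our documented
convention, and block membership depends only on the > threshold
predicate, never on the r² magnitudes above it.

## The Q+K mixed model

The single-marker model is y = Xβ + u + e with X = [1, Q (one column
dropped), marker], Var(u) = σ²~a~K and Var(e) = σ²~e~I. A single
symmetric eigendecomposition of K rotates the model to independent
errors with weights λᵢ + δ, and the REML criterion is profiled over the
one-dimensional variance ratio δ = σ²~e~/σ²~a~ on the log scale
(searched over log δ ∈ [−12, 12]). The marker is tested by the Wald F on
its coefficient with n − p denominator degrees of freedom; the explained
variance is reported as 100·var(marker·β̂)/var(y), a convention (the
published tables never define their R² column). At K = I the weights are
constant and the fit collapses exactly to ordinary least squares — the
package's main oracle test. Missing genotypes and traits are handled by
per-marker complete-case analysis, with no imputation.

Kinship is the Ritland-style moment estimator: with allele fractions
x = dosage/2 and sample frequencies p, r<sub>ij</sub> =
Σₗ(x<sub>il</sub>−pₗ)(x<sub>jl</sub>−pₗ) / Σₗ pₗ(1−pₗ)/2, which is 1 in
expectation for self-pairs. Following common Q+K usage, negative
pairwise estimates are truncated to 0 and the diagonal is set to 1;
because entry-wise truncation can leave the matrix indefinite, the
truncated matrix is then projected onto the positive-semidefinite cone
and rescaled to correlation form, so the REML eigendecomposition is
always well-defined. The raw (untruncated) estimator remains available
for diagnostics.

q-values follow Storey's positive-FDR construction:
q(p) = min_{t ≥ p} π̂₀ m t / #{p ≤ t}, with π̂₀ estimated on the λ grid
0, 0.05, …, 0.90 and smoothed by a cubic spline, capped at 1. With π₀
forced to 1 the output equals Benjamini–Hochberg step-up values exactly.
Families are per trait across SNPs by default — matching the way
trait-wise Q-values are presented in this literature — with a global
family available as an option.

## Gene action

For a significant marker, 2a = |G_BB − G_bb| and
d = G_Bb − 0.5(G_BB + G_bb) from the genotype-class means, with the
orientation chosen so B labels the high-value homozygote (a > 0, d/a
reported signed). Classification uses |d/a|: additive (codominant)
≤ 0.5, partial-to-full dominance strictly between 0.50 and 1.25,
over/underdominance above 1.25. The boundary |d/a| = 1.25 is not covered
by the published windows; it is assigned overdominant with a warning.
The reported additive effect follows the published footnote formula
a = p_B·G_BB + p_b·G_Bb − G verbatim, even though it omits a bb-class
term; whether that omission is a typo in the source convention is
unknowable, so the average allele-substitution effect
α = a + d(p_b − p_B) is provided as the `"substitution"` alternative.

## Haplotype trend regression

Windows of three consecutive SNPs are phased probabilistically by EM over
the ≤ 8 possible haplotypes (tolerance 1e−8, ≤ 500 iterations,
equilibrium start); each individual contributes its posterior expected
haplotype counts, which sum to 2 by construction. The trait is regressed
on the dosage columns of haplotypes with frequency ≥ 1% (rarer
haplotypes are pooled and excluded; the most frequent haplotype is the
reference and is dropped for identifiability). Using expected dosages
rather than best-guess phases is the deterministic "trend" construction
of this method family. Significance is a permutation p-value of the
model F statistic, p = (1 + #{F* ≥ F}) / (1 + B), permuting the trait;
the +1 correction avoids zero p-values. The permutations are vectorized
through one QR decomposition of the design, so B = 1000 per window is
desk-scale.

## Validation in an F1 cross

Marker panels forwarded from the discovery population (p < 0.05) are
first screened by a Pearson χ² test of Mendelian segregation against the
expectation derived from the two parents' genotypes (df = expected
classes − 1); loci rejecting at the 0.01 level — or showing progeny
classes that are Mendelian-impossible — are dropped. Surviving loci are
tested by fixed-effects one-way ANOVA, y = µ + mᵢ + e, with per-trait
Storey FDR.

# The synthetic-data generator

The generator's defaults encode the study design the analysis assumes:

* **Alignment**: 88 haplotypes (configurable; the diversity examples use
  44, the number of resequenced alleles in the motivating design) over
  the 4374-bp gene model with 133 bp 5'UTR, seven exons (1293 bp CDS),
  six introns (2574 bp) and a 374 bp 3'UTR. Sequences evolve on a
  neutral Kingman coalescent without recombination; mutations fall on
  branches with per-site rate θ/2 per 2N generations under infinite
  sites, so E[S] = θ·L·a_n and Watterson recovery is a genuine
  parameter-recovery check. The default θ = 0.0128/bp is the
  gene-level Watterson estimate reported for the motivating gene. The
  ancestral CDS is drawn from sense codons so the consensus translates.
* **Genotype panel**: 426 individuals in three subpopulations
  (proportions 180/86/160 of 426), 82 SNPs with minor allele frequency
  ≥ 0.10 enforced by bounded rejection sampling. Subpopulation allele
  frequencies follow Balding–Nichols Beta((1−F)/F·p, (1−F)/F·(1−p))
  with F_ST = 0.05 by default (a typical within-species value for
  outcrossing trees). LD is produced by thresholding a stationary latent
  Gaussian over SNP positions with correlation 0.5^(d/scale) at each
  SNP's frequency quantile — a tunable, smooth r²-decay without a full
  coalescent-with-recombination machinery; the default half-distance of
  350 bp makes r² decay below 0.1 within several hundred bp, the regime
  the analysis targets. Planted blocks share one latent variable
  (perfect LD). MAF rejection re-draws only the frequencies, keeping the
  latent field fixed, so LD structure survives the constraint.
* **Phenotypes**: y = µ + Σ a(dosage−1) + d·1(het) + g + e with
  polygenic g ~ N(0, σ²~a~K), σ²~a~ = noise²·h²/(1−h²), default
  h² = 0.3 polygenic share and unit residual sd — ten traits.
* **F1 cross**: 1200 progeny by independent Mendelian gametes per locus
  (no within-gene linkage in the cross by default).
* **Seeding**: one master seed; every generator derives its own stream
  by stable hashing of (master, generator name), so draws are
  bit-reproducible and adding one generator never shifts another.

The alignment and the genotype panel are generated independently by
default, mirroring the fact that common SNPs were genotyped with a
different instrument than the discovery resequencing; nothing in the
published design specifies their joint distribution, so independence is
a modelling choice, not a statement about the real data.

What the generator does *not* emulate: recombination within the gene's
genealogy, demographic history, selection, genotyping error, null
alleles and shared environment. Passing tests therefore demonstrate that
the statistical machinery is correct and calibrated under the assumed
model, not that the model captures every feature of real resequencing
panels.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based only at I/O
  boundaries (GFF3, VCF).
* EM tolerances: 1e−8 on frequencies; two-locus EM ≤ 200 iterations,
  window EM ≤ 500. The EM log-likelihood is asserted non-decreasing in
  the tests.
* Monomorphic loci: LD undefined and flagged; kinship skips them;
  the MLM skips markers below the MAF filter with a reason code.
* Multiallelic alignment columns are excluded with a warning (the
  analysis treats SNPs as biallelic throughout); gap-containing columns
  are excluded from all counts and denominators.
* bp-per-SNP rounds half away from zero; S = 0 yields a no-SNP sentinel
  (NA).
* Permutation p-values use the +1 correction; defaults are 1000
  permutations for haplotype tests (the published setting) and 1000 for
  LD significance, with larger counts available by argument.
* The REML profile is searched on log δ ∈ [−12, 12]; at the boundary the
  model degenerates gracefully to OLS (δ → ∞ ⇒ no polygenic variance).

# Problem sizes used in the tests

The test suite exercises the study-scale dimensions where they matter
statistically (n = 426 individuals for power and calibration checks;
82 SNPs for the planted-QTL recovery scan; 44 haplotypes and θ = 0.01/bp
across 200 replicates for Watterson recovery; 2000 replicates for
type-I-error calibration of the MLM and the permutation HTR) and smaller
dimensions (tens of SNPs, hundreds of individuals) for structural
checks, where the property under test does not depend on size. Block and
decay recovery use 20-SNP panels over 20 seeds.

# Known limitations

* The MLM tests a single marker at a time; multi-locus models and
  epistasis are out of scope.
* Ancestry (the Q matrix) is consumed as an input, never inferred.
* The LD generator's latent-Gaussian construction controls the *decay
  shape* of r², not its exact marginal distribution; tests of decay
  recovery therefore check the fitted crossing distance, not pointwise
  r² values.
* Fractional synonymous-site denominators depend on the consensus
  sequence; they cannot reproduce the printed fractional lengths of any
  particular published alignment without that alignment's sequences, and
  the package only asserts the internal arithmetic (partition, sums,
  ratios) on its own data.
* D′-based block definitions (Gabriel-style confidence intervals) are
  not implemented; the block rule here is the all-pairs r² convention
  described above.
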