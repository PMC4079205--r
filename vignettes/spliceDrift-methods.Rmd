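---
title: "Inferring weak selection at splice sites: models and methods"
author: "spliceDrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring weak selection at splice sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceDrift)
```

## The problem

Donor and acceptor splice sites (SSs) are short sequences at exon–intron
boundaries. Beyond the invariant GT/AG dinucleotide, every SS position has one
or two *consensus* nucleotides (Cn) that are preferred by the spliceosome and
two or three *nonconsensus* nucleotides (Nc); yet real genomes carry many Nc
nucleotides at these positions. If the fitness differences among alleles at a
position are of order 1/Ne, the position undergoes a nearly neutral turnover:
slightly deleterious Cn→Nc fixations and slightly advantageous Nc→Cn
fixations. spliceDrift quantifies this turnover: it estimates, per SS position,
the population-scaled selection coefficient S = 4Nes acting on Cn↔Nc
substitutions, detects site-specific selection that favors particular Nc
alleles, and converts the results into genome-wide drift-load summaries.

## The substitution model and the central statistic

Under weak selection the fixation probability of a new allele with selection
coefficient s is u(s) = (1/2N)·S/(1 − e^(−S)) with S = 4Nes, so the
substitution rate at a selected position relative to a neutral position with
the same mutation rate is

r(S) = S / (1 − e^(−S)).

`fixationRatio()` evaluates r (with a series expansion near the removable
singularity at S = 0) and `invertRateRatio()` recovers S from an observed
rate ratio by bracketed root finding with Newton polishing; the round trip is
accurate to 1e−8 over S ∈ [−20, 20].

The observed ratio comes from class-exit frequencies. With `#(Z→X)` the count
of positions whose reconstructed ancestor is Z and whose reference-lineage
descendant is X,

q(Cn→Nc) = Σ_{Z∈Cn, X∉Cn} #(Z→X) / Σ_{Z∈Cn, X} #(Z→X),

and symmetrically for q(Nc→Cn). Within-class moves (Cn→Cn at positions with
two consensus nucleotides, Nc→Nc) are opportunities but not exits, so q
estimates the per-branch probability of leaving the class. The neutral
expectation q_exp applies the position's observed ancestral composition to
nucleotide-matched control rates r_Z(T) measured in presumed-neutral sequence:
intronic controls for intronic SS positions, third positions of 4-fold
degenerate codons for exonic positions. S is then estimated as
`invertRateRatio(q/q_exp)`; the 95% interval transforms the Clopper–Pearson
limits of q through the same inversion, treating the control rates as
error-free (they come from far more positions than the SS classes; a control
with k = 0 would be flagged rather than inverted). When k = 0 the lower limit
(and the point estimate) is reported as −Inf, never clipped.

Observed-versus-control counts are also compared by a two-sided Fisher exact
test on the 2×2 table {substituted, conserved} × {SS, control}; per-offset
p-values are reported raw, with a Benjamini–Hochberg column added as a
convenience extension.

## Ancestral reconstruction

Ancestors of the reference/sister pair are reconstructed by maximum parsimony
on the three-taxon tree ((reference, sister), outgroup): the ancestral state
is the one shared by at least two of the three species; columns where all
three differ, or with missing data or gaps, are ambiguous and are removed
from both the numerator and the denominator of q (removing them from only one
side would bias q through arbitrary tie-breaking). Substitutions are
polarized on the reference branch only.

Parsimony at finite branch lengths is not unbiased: ambiguous columns
preferentially remove true events from the controls, and selection-driven
reversions on the sister/outgroup lineages create spurious events. At the
primate-like branch lengths used by the simulator (see below) this inflates
the observed/expected ratio by roughly 5–9%, i.e. shifts S estimates by about
+0.1 to +0.2 at S = −2. The package's validation suite therefore checks
recovery of a true S = −2 within [−2.3, −1.7], a band that brackets this
method-intrinsic bias, and checks interval calibration at the level of the
frequency-ratio estimator, where the Clopper–Pearson machinery is exact. A
TSV adapter (`readSiteTable()` plus externally produced ancestral states) is
the documented route for users who prefer likelihood-based reconstruction.

With `excludeCpg = TRUE`, any position that is part of a CG dinucleotide in
the reconstructed ancestral sequence (C followed by G, or G preceded by C, on
the transcribed strand) is excluded, and an ambiguous neighbour counts as a
possible CpG partner (conservative). CpG context is assessed on the ancestor
because hypermutability acts on the ancestral state. The filter is only as
good as the recovered context: once a hypermutable CpG has itself mutated,
the ancestral context is no longer recognizable, so exclusion removes most
but not all of a CpG-driven rate excess (about three quarters at a 6×
multiplier in the bundled simulation check).

## The synthetic-data generator

Because the original genome-scale inputs (annotation releases, genome
alignments, conservation tracks) are not redistributable at package scale,
every stage is validated against a bundled origination–fixation simulator
with known ground truth. It simulates substitutions, not populations — the
weak-mutation regime in which the r(S) theory lives: the rate of the Z→X
substitution is μ(Z→X)·r(S_X − S_Z), ancestors start at the stationary
distribution of that process (for symmetric μ, π_X ∝ e^(S_X), satisfying
detailed balance), and branches apply the matrix exponential of the rate
matrix.

Defaults are chosen once to emulate the primate study design and are not
tuning knobs:

* mutation: single transition/transversion ratio κ = 2, normalized so one Ks
  unit equals one expected neutral substitution per site;
* topology ((reference, sister), outgroup) with ksRef = ksSister = 0.03,
  ksInner = 0.01, ksOutgroup = 0.06 — approximately the human–macaque
  synonymous divergence with a marmoset-like outgroup;
* fitness per scored offset: 0 for Cn alleles and S for Nc alleles (S < 0
  means the consensus is favored); a fraction of sites may instead favor one
  uniformly chosen Nc allele with its own advantage (default 4Nes = +2), the
  minimal mechanism that reproduces site-specific negative selection;
* invariant GT/AG positions are hard-coded immutable, so every simulated
  record passes the canonical-dinucleotide filter by construction;
* neutral controls: 10 generated control columns per observed scored column
  and provenance, each with a phyloP-like score drawn from
  0.5·N(0, 0.3) + 0.5·N(0, 1.2) so that the |score| < 0.6 retention filter
  removes roughly half of them, emulating the funnel of the real filtering
  step (the retained and removed columns evolve identically here — the score
  is an annotation, not a mechanism);
* multispecies panel: a ladder of 12 species at Ks 0.05–4.0, a scaled-down
  stand-in for a 45-vertebrate panel. Species are evolved sequentially along
  the ladder, so two species share the evolutionary path up to the nearer
  distance — a caterpillar approximation of a real phylogeny that preserves
  the distance-prefix structure the conservation statistic consumes;
* one master seed drives a single RNG stream per generator call (the package
  performs no internal parallelism), making every ensemble byte-reproducible.

What the simulator does not emulate: indels and alignment error, splice-site
gain/loss, context-dependent mutation beyond the optional uniform CpG
multiplier, linked selection, and rate variation among sites. Passing tests
therefore demonstrate correctness of the inference machinery under the
model's own assumptions, not robustness to every artifact of real alignments.

## Multispecies conservation

For a column and a target nucleotide set, the conservation depth L is the
distance (Ks) of the most distant species x such that the target is observed
in every species at distance ≤ L(x); depth 0 columns (nearest species already
deviates) are included in averages, since they are informative about
non-conservation. Missing data terminates the conserved prefix, and all
species at a tied distance must match for that distance to count. The
contrast c = (obs − exp)/exp compares SS columns whose reference state
belongs to the queried class against neutral control columns matched by
reference nucleotide identity (exp is the composition-weighted mean of
per-nucleotide control depths). `c_nuc` targets the specific resident
nucleotide, `c_set` the whole class; on any fixed column set the set depth
dominates the nuc depth, so c_nuc > c_set can only arise through the
differing neutral expectations — which is exactly the signature of
site-specific preference for the resident allele. Confidence intervals are
percentile bootstrap over alignment columns (1,000 trials by default),
resampling observed and control columns jointly in each trial.

## Strength classes, stratification, drift load

SS strength is the fraction of scored offsets whose reference nucleotide is
consensus; ensembles are split at the tertiles of that fraction (weak /
middle / strong), with deterministic tie-breaking by site id. The same
machinery stratifies by any covariate. Genome-wide drift load is
nSS · meanNc · s, with s = S/(4Ne); outputs carry full precision and rounding
is left to reporting.

## Numerical and degenerate-input choices

* r(S) near 0 uses a 4-term series below |S| = 1e−5 to avoid cancellation;
  inversion brackets [−100, 100] and expands geometrically if needed.
* Clopper–Pearson uses the beta-quantile closed form; k = 0 and k = n map to
  exact 0/1 endpoints.
* Fisher tests on a table with a zero margin return p = 1 with a warning.
* A mutation matrix whose allele graph is not strongly connected is rejected
  (no unique stationary state); supplied matrices are renormalized to the
  one-substitution-per-Ks convention.
* Consensus derivation always takes the top nucleotide; the second is
  included at relative frequency ≥ 0.35 (configurable; the architecture
  forces invariant and no-consensus roles regardless of input), ties resolved
  alphabetically with a message.
* A constant stratification covariate yields a single stratum with a warning;
  missing covariates drop those sites with a warning.

## Problem sizes used in the checks

The bundled validation suite runs ensembles of 5×10^4 sites for parameter
recovery, 1.5×10^4 per site type for neutral nulls, 100 replicates for
interval calibration, 50 replicate panels (700 sites each) for the
conservation null, and 10^4 replicates for Clopper–Pearson coverage; the
acceptance script reproduces the same quantities from scratch at the same
sizes. These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping a full run in the minutes range on one CPU.

## Known limitations

Single-outgroup parsimony only (no probabilistic reconstruction); aligned
FASTA input (MAF is not parsed); no indel handling; minor spliceosome
(U12, GC–AG) sites are out of scope; the drift-load summary assumes a single
s per locus class rather than a distribution of fitness effects.
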