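---
title: "Methods: germplasm evaluation and SNP fingerprinting with germid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germplasm evaluation and SNP fingerprinting with germid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germid)
```

## The problem

A germplasm bank holds hundreds of accessions — catalogued individuals of a
species complex, here modelled on a tree collection of two diverged species
and their interspecific hybrids. Managing such a collection requires three
quantitative products: an assessment of how much genetic and phenotypic
diversity the collection holds, a description of its population structure,
and a cheap, unambiguous molecular identifier for every accession. `germid`
implements that pipeline over a diploid biallelic SNP panel: each genotype
is stored as an alternate-allele dosage in {0, 1, 2, missing}, and every
downstream statistic is a function of that matrix plus locus and sample
metadata.

## The synthetic panel: what it emulates and what it does not

Because real resequencing panels cannot ship with a package, `germid`
includes a generator (`simulate_panel()`) whose output has the statistical
structure the analysis assumes:

* **Population model.** Ancestral allele frequencies are uniform on
  `maf_range` (default [0.02, 0.5], deliberately straddling the 0.05
  screening cutoff). Each of `n_pops` (default 3) source populations drifts
  around the ancestral frequency under a Balding–Nichols beta model with
  parameter `divergence` (default F = 0.1, a typical between-species FST
  scale for congeneric trees). This is the minimal model that yields K = 3
  structure with realistic allele-frequency overlap.
* **Admixture.** A fraction `admixed_fraction` (default 1/3) of samples
  draws a symmetric Dirichlet ancestry vector and then draws each of its
  two allele copies from a population chosen by that vector — hybrids in a
  collection dominated by crosses are the motivating case. Unadmixed
  samples are labelled `pop1..popK`; admixed ones `admixed`, with the true
  simplex stored in the truth record.
* **Phenotypes.** A quantitative trait is a linear combination of planted
  causal dosages plus Gaussian noise scaled so the *realized* genetic
  variance fraction equals `heritability` exactly; categorical traits are
  coded integers drawn from stated class frequencies. At heritability 1 the
  trait is exactly genetic; at 0 it is pure noise.
* **QC annotations.** Site metrics are drawn comfortably inside the
  hard-filter acceptance region and a chosen fraction of sites is planted
  to violate exactly one criterion, so the cascade's confusion matrix is
  fully known.

Not emulated: linkage (loci are exchangeable given ancestry, so LD decay
with physical distance is flat under the generator — constructed
duplicated-locus blocks are used to test the decay machinery), coalescent
genealogies, depth-linked missingness (missingness is uniform), and
sequencing-read error processes. Tests passing on this generator therefore
demonstrate correctness of the computations and their calibration under the
stated model, not robustness to every artefact of real short-read data.

## Filter cascade

`site_filters()` applies, in order: (1) the six-metric hard filter with
strict printed inequalities (QD < 2.0, MQ < 40.0, FS > 60.0, SOR > 3.0,
MQRankSum < −12.5, ReadPosRankSum < −8.0; a missing metric is "not
evaluable" and passes that criterion, the standard hard-filter semantics);
(2) site screens — missing rate < 0.20, MAF > 0.05 (strict, so MAF exactly
0.05 is removed), Hardy–Weinberg exact p ≥ 1e−4, biallelic SNVs only;
(3) masking of genotypes with GQ < 30 to missing; (4) removal of sites
whose post-masking missing rate exceeds 0.01; (5) removal of sites whose
mean non-missing depth falls outside [3, 100]. Two points were genuinely
open and are fixed here as documented choices: the GQ masking runs *after*
the 20% missingness screen (the two missingness rules are separate stages),
and "average depth" is per-site across samples. MAF and the
Hardy–Weinberg test use non-missing genotypes only. The report records
newly-removed counts per stage and per-site reasons; the retained set is
order-invariant and re-audits clean, properties the test suite checks.

The Hardy–Weinberg test is the exact conditional test: given the allele
counts, the probability of each compatible heterozygote count is computed
by the recurrence P(h+2)/P(h) = 4·nAA(h)·naa(h) / ((h+1)(h+2)), and the
two-sided p sums all configurations no more probable than the observed one
(with a 1 + 1e−9 tie guard). The suite verifies it against an independent
log-factorial enumeration for every configuration up to n = 30.

## Diversity indices and trait statistics

Per locus, with allele frequencies p and q = 1 − p estimated from
non-missing genotypes: Na counts observed alleles; Ne = 1/(p² + q²);
Ho is the heterozygous-call fraction; He = 1 − p² − q²; PIC is Botstein's
codominant-marker form 1 − Σpᵢ² − Σᵢ<ⱼ 2pᵢ²pⱼ² (maximum 0.375 at p = 0.5
for a biallelic locus); H′ = −Σpᵢ ln pᵢ in nats; Nei's gene diversity
equals He per biallelic locus. Group reports average the per-locus indices
over loci *within* each group, using the group's own allele frequencies —
species-level diversity, not pooled-panel diversity. Groups of one sample
are skipped with a warning.

Trait summaries use the population (divide-by-n) standard deviation by
default (`sd_type = "sample"` switches), CV = SD/mean × 100 with CV defined
as 0 for constant traits, and Shannon H′ over class relative frequencies
with natural logs. Traits declared continuous are binned into 10
equal-width bins for H′ only; the binning choice is a convention, stated
here because measured growth traits have no canonical class structure.
Membership-function scores rescale each trait to (x − min)/(max − min),
reverse smaller-is-better traits, and average with the given weights, so
D ∈ [0, 1] with the boundary values attained at the trait-wise extremes.

## Structure, LD and the choice of K

Genotype PCA mean-imputes missing dosages per locus, centers columns
*without* scaling (loci keep frequency-proportional weight; standardization
is the documented alternative not taken), and uses the SVD. Component signs
are fixed by making each component's largest-magnitude loading positive, so
results are bit-reproducible. UPGMA clustering runs average-linkage
`hclust` on Euclidean distances of the imputed dosages; the tree is
ultrametric, exported as Newick via `ape`, with leaf-to-root height equal
to half the cophenetic distance.

LD uses the composite, phase-free convention: r² is the squared Pearson
correlation of dosage vectors over pairwise-complete samples, computed for
all pairs of the first `max_markers` (default 1000) position-ordered loci
on the chromosome carrying the most SNPs ("top" markers is read as genomic
order; the alternative — ranking by an informativeness score — is not what
a decay curve wants). Under the null, E[r²] ≈ 1/n, which the suite verifies
by simulation. `ld_decay()` bins pairs by physical distance and reports
per-bin means.

The number of clusters K is chosen by post-processing an external Bayesian
clustering run: for each interior K of a consecutive grid with replicate
log-likelihoods, ΔK = |L(K+1) − 2L(K) + L(K−1)| / sd(L(K)), where the
second difference is taken on replicate means. The definition is fixed by a
hand-computable example in the tests (ΔK = 45 for means −100, −50, −45,
−44 at unit sd). K values with zero replicate spread have undefined ΔK and
cannot win the argmax. The MCMC itself is out of scope by design; only the
selection rule is implemented.

One measurement protocol matters for the structure-recovery checks: the
generator's admixed samples are symmetric-Dirichlet mixtures of all three
populations, so they sit *between* the groups. The recovery criterion is
defined on unadmixed samples; accordingly PCA + k-means is evaluated on the
unadmixed samples' scores, and the UPGMA three-clade cut is taken on the
unadmixed subset. Cutting a full-panel tree at k = 3 would grade where the
hybrids fall, which is not the quantity of interest.

## Association scan

`glm_scan()` fits, per SNP, ordinary least squares of the trait on an
intercept plus additive dosage over complete cases, with two-sided p from
the t distribution on n − 2 degrees of freedom. Choices: additive 0/1/2
coding; complete-case analysis (no imputation inside the test); no
population-structure covariates (the model is intercept + genotype only —
on a structured panel this is anticonservative for structured traits, and
the QQ/λ diagnostics in `glance()` are provided to see it); no
multiple-testing correction, since reporting uses raw-p tiers p < 0.001 and
p < 0.0001 with a strict default threshold of 1e−3. SNPs monomorphic among
complete cases return NA statistics rather than disappearing. A p-value
that underflows to zero is reported as the smallest positive double so p
stays in (0, 1]. The suite validates the scan against `lm()` per SNP, a
10,000-draw permutation test, KS-uniformity of the null, and a power study
(single causal locus, h² = 0.3, n = 200: recovery at p < 1e−3 in well over
80% of replicates).

## Core markers and fingerprints

The core-set problem is set cover: find a small locus subset under which
every pair of accessions differs somewhere. "Most informative" is defined
as the number of currently-confounded pairs a candidate resolves, with ties
broken by higher PIC and then genomic position — PIC enters exactly where a
field protocol would list it alongside selected markers. A pair counts as
resolved only when both genotypes are non-missing and differ: a missing
call is a wildcard that can never discriminate, the conservative rule a
fingerprint must satisfy. After greedy growth, a pruning pass removes any
locus whose removal leaves the resolved-pair set unchanged, making the set
irredundant; byte-identical accessions terminate with an explicit
unresolved group instead of looping. Greedy set cover is not guaranteed
minimal, so `brute_force_min_set()` provides an exhaustive oracle (guarded
to ≤ 20 candidates × ≤ 12 samples); on 100 random small instances the suite
checks greedy resolves whenever the oracle does and never beats the proven
minimum.

Fingerprint codes concatenate genotype tokens (`0/0`, `0/1`, `1/1`, `./.`)
in chromosome-position order with a `|` separator — selection order never
leaks into the code. The QR payload is a canonical four-line text (version
tag, `id=`, `fp=`, `traits=` with `name:value` pairs), with reserved
characters percent-encoded so arbitrary ids survive; parsing and
re-encoding is byte-idempotent. Images are model-2 QR symbols in byte mode
at error-correction level M with mask pattern 0 (fixed for pixel-exact
reproducibility; the mask id is carried in the format word as usual, so the
choice is transparent to readers). The package includes its own encoder and
decoder: the decoder re-derives the module grid from the PNG, validates the
BCH format word, reverses masking, placement and block interleaving, and
requires the Reed-Solomon parity of every block to match exactly before
accepting the payload — `render_and_verify_qr()` only returns after this
round trip succeeds. The per-version error-correction table is audited
against the symbol geometry for all 40 versions at test time. Level-M byte
capacity tops out at 2331 bytes; a 13-marker code plus 34 coded traits sits
near 700 bytes (about version 22), comfortably inside.

## Numerical and degenerate-input conventions

Boundary semantics follow printed inequalities strictly throughout
(QD = 2.0 passes; MAF = 0.05 fails; p = 0.001 is not a hit). Ts/Tv with
zero transversions is undefined (NA), not an error. All-missing loci,
all-constant trait tables, singleton groups, empty candidate sets and
non-consecutive K grids raise informative errors or warnings as
appropriate. Every stochastic function takes an explicit seed and restores
the caller's RNG state; fixed seed means bit-identical output.

## Problem sizes used by the tests

The suite runs panels up to 200 samples × 1000 loci, 50-replicate power
studies, 500-replicate LD nulls, the exhaustive Hardy–Weinberg sweep to
n = 30, 100 random core-set instances against brute force, and a
200-accession QR export with per-image decode verification — sizes chosen
so the full suite completes in about half a minute while leaving each
statistical check enough resolution to fail loudly if a formula or
convention regresses.

## Limitations

The GLM scan deliberately omits structure correction; on structured panels
use the diagnostics before trusting tiered hits. The generator's lack of
linkage means LD-decay behaviour with distance is exercised only through
constructed block fixtures. Greedy + pruning yields irredundant, not
provably minimum, marker sets beyond oracle-checkable sizes. The QR
implementation targets this package's own symbols (clean, axis-aligned
images); it validates integrity exactly but is not a general-purpose
scanner for photographs.
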