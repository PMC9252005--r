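---
title: "Methods: simulating, imputing and evaluating multi-breed sequence panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, imputing and evaluating multi-breed sequence panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and of the design
decisions behind them: what is simulated and why, how the imputation
HMM is parameterised, which conventions the accuracy evaluation uses,
and what the desk-scale results do and do not say about real data.

## The study design being emulated

The package targets the common design of sequence-level imputation
studies in livestock: a few hundred sequenced animals from many breeds
form the reference pool; a target cluster of closely related animals
(here, the warmblood-like tier 1) is the population of interest;
accuracy is estimated by five-fold cross-validation inside the target
cluster, masking each validation fold down to the positions of a
commercial SNP array and imputing back to sequence level. Reference
panels are nested by genetic relationship — RP1 is the target cluster,
RP2 adds related breeds, RP3 everything — so that panel size and breed
composition can be separated: the RP2/RP3 scenarios always use the
same four-fifths of RP1 plus the extra animals, while the panel-size
sweep uses two, three or four fifths of RP1 alone, selected cyclically
after the validation fold.

## The synthetic cohort

`simulate_dataset()` draws, per site, an ancestral allele frequency
from Beta(0.5, 0.5) — a U-shaped site-frequency spectrum with many rare
variants, which is what makes the MAF-stratified accuracy analysis
informative — and, per breed, a Balding–Nichols frequency
$p_b \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, where $F$ is the
breed's divergence from the common ancestor. Haplotypes are recombinant
mosaics of a per-breed pool of 20 founder haplotypes: segment lengths
are exponential with mean $1/\text{recomb\_rate}$ Mb (default 1 cM/Mb)
and each copied allele flips with probability 0.002. The mosaic
structure is what creates linkage disequilibrium and shared
identity-by-descent segments, i.e. the signal a haplotype-copying
imputer exploits; the mutation rate keeps haplotypes from being exact
founder copies.

Two non-obvious choices:

* **Founder allele counts are stochastically rounded**, not drawn iid
  Bernoulli. A 20-haplotype founder pool drawn iid would add roughly
  $1/(2 \times 20) = 0.025$ of extra drift on top of $F$, so a nominal
  $F = 0.1$ breed pair would measure near 0.145 by the Hudson FST
  estimator. Rounding the pool's allele count to the Balding–Nichols
  frequency (floor plus a Bernoulli on the fraction) keeps the realised
  divergence calibrated to $F$: the test suite verifies $F = 0$ pairs
  measure $|F_{ST}| < 0.01$ and $F = 0.1$ pairs measure inside
  $[0.08, 0.12]$.
* **The planted recessive lethal is constructed, not rejection-sampled**:
  $\mathrm{round}(2Nq)$ distinct individuals are made heterozygous
  carriers, which guarantees zero alt homozygotes and an allele
  frequency within one allele of the target — the property downstream
  tests need — without a retry loop.

Default study conditions (the package's choice of a desk-scale cohort,
used throughout the test suite): two 10-Mb chromosomes, 20,000 sites,
120 samples — 65 in tier 1 ($F = 0.02$; the size of five 13-animal CV
folds), 30 in tier 2 ($F = 0.10$), 25 in tier 3 ($F = 0.30$, i.e.
strongly diverged). Marker panels default to 600 (medium) and 5,400
(high) sites, preserving the roughly 1:9 density ratio of the 60K and
670K equine arrays; panels are MAF-weighted samples of sites with
cohort MAF ≥ 0.05 (arrays target common variants) and avoid a 1-Mb
coverage gap on chromosome 1 that emulates array-free assembly
regions. The between-breed $F$ values are free parameters — the
emulated study reports no quantitative divergence — chosen once to
give clear tier separation without making cross-breed imputation
impossible.

All randomness flows from one seed through named substreams
(`positions`, `ancestral`, per-breed `founders_*`/`mosaic_*`, `panels`,
`impacts`, `lethal_site`), so regenerating one component never
perturbs the others and equal seeds give byte-identical VCF output.

## Relationship tiers

The emulated studies assign breeds to tiers by eye from an MDS plot.
`assign_relationship_groups()` replaces that with an explicit rule:
classical (Torgerson) MDS of the 1−IBS matrix over the medium-density
markers, a centroid of the target samples in the first two dimensions,
and two radii — tier 1 within $t_1$ (inclusive), tier 2 within $t_2$,
tier 3 beyond. Defaults are $t_1 = 1.1\times$ the largest
target-to-centroid distance and $t_2 = 3 t_1$; both are declared
parameters, not inferences, since the source design states neither a
dimensionality nor a threshold. Negative Torgerson eigenvalues (IBS
matrices need not be Euclidean) are truncated to zero-width dimensions
rather than raised as errors.

## The imputation model

`impute_panel()` implements a diploid Li–Stephens haplotype-copying
HMM as a transparent, self-contained stand-in for production imputers.
The state is an ordered pair of reference haplotypes. Per interval,
each copy independently switches with probability
$\theta = 1 - \exp(-4 N_e \Delta / K)$ ($\Delta$ in Morgans from a
constant-rate map, $K$ haplotypes, uniform destination including self);
a floor of $10^{-8}$ keeps zero-length intervals from freezing the
chain. Emission at a typed site with genotype $g$ against copied dose
$d = h_i + h_j$ is $(1-\varepsilon)^{2-|g-d|}\varepsilon^{|g-d|}$,
treating the genotype as an unordered allele-count observation;
untyped and missing sites emit 1. Posterior dosages are exact
forward–backward expectations; the test suite checks them against
exhaustive enumeration over all haplotype-pair paths to $10^{-8}$.

Parameter defaults: $N_e = 1000$ (the conventional setting for horse
panels), $\varepsilon = 10^{-3}$ fixed rather than estimated,
1 cM/Mb. DR2 uses the Browning-style variance ratio
$\mathrm{Var}(ds)/(\mathrm{Var}(ds) + \overline{\mathrm{postvar}})$,
clamped to $[0,1]$ and defined as 0 in the degenerate 0/0 case; exact
formulas in production imputers are version-dependent, so this is the
declared contract.

Deliberate simplifications, stated as such: targets are imputed
unphased through the diploid HMM (no pre-phasing stage); haplotypes are
copied uniformly (no frequency weighting or haplotype clustering); and
per-sample imputation is independent given the reference, so results
cannot depend on target processing order. A single stand-in model
cannot reproduce contrasts *between* production imputers, and does not
try to.

Computation: transitions factorise into rank-one corrections per copy,
so a full update is $O(K^2)$; the forward matrices are stored at typed
sites only, and posteriors at untyped sites are reconstructed from the
flanking messages through the same factorisation, which reduces the
per-site cost to three sparse gathers over the alt-carrying haplotypes.
This keeps the default study conditions (references up to 214
haplotypes over 20,000 sites) at a few seconds per sample without any
approximation; the factorised path is covered by the same enumeration
oracle as the dense one.

## Accuracy conventions

Per-variant accuracy $r$ is the Pearson correlation between true
genotypes and imputed dosages over pooled validation samples, while
the no-variation exclusions are evaluated per validation fold: a
variant is dropped (with a single reason code) if it is multiallelic,
was not imputed, or shows constant genotypes or constant dosages
within any one fold. MAF is computed from the RP1 animals' sequence
data only. "Mean accuracy" is the unweighted mean of included
per-variant $r$; MAF bins follow the $(x, y]$ convention (a variant at
exactly 0.2 belongs to the 0.1–0.2 bin); windows are half-open 1-Mb
intervals, and the marker-density regression is an OLS of window mean
$r$ on markers per Mb, omitting windows without included variants.
Whether published overall accuracies are variant means or fold-averaged
means is generally not stated; the variant-mean convention is declared
here and used everywhere.

In the two-step scenario, step one imputes medium→high density using
the two folds preceding the validation fold (masked to the high
panel), an optional DR2 ≥ 0.4 filter prunes the hand-off, and step two
imputes to sequence level using the two following folds. The hand-off
uses best-guess (rounded) genotypes because the HMM consumes hard
genotypes; dosage-aware emissions would be an extension, not the
contract.

The trend suite runs each scenario on a single validation fold with
the seed fixed, rather than the full five-fold rotation: the
comparisons of interest (reference size, density, MAF, breed
composition) are paired within fold and seed, which is both cheaper
and statistically tighter. `accuracy_per_variant()` itself accepts
pooled multi-fold input, and the full rotation is exercised on a
smaller cohort.

## Monte Carlo ANOVA

The proportion of variation in panel A explained by panel B is
estimated by repeatedly drawing a focal variant from A's polymorphic
sites and regressing its centered genotypes on B's sites within
±0.5 Mb, reporting the mean adjusted
$R^2 = 1 - (1-R^2)(n-1)/(n-p-1)$, floored at 0 and capped at 1, with
$p$ the regression rank. The cited methodology leaves the local-window
details open; window width (1 Mb), the predictor cap ($n-2$, screened
by strongest correlation when a window is denser), and the adjustment
are this module's declared decisions. Two properties anchor the
estimator: a panel explains itself and any superset of itself exactly
(the focal variant is its own predictor, $R^2 = 1$ regardless of
adjustment), and under independence the adjusted $R^2$ is near-unbiased
at zero, so a noise panel reports a small positive value (the flooring
bias) rather than the inflated raw $R^2$. Focal draws sample variants,
not random linear combinations, keeping the per-site "proportion
explained" semantics and the analytic null. When windows are much
denser than $n$, correlation screening reintroduces selection bias and
the null is no longer tight — a known limitation; the package's
analyses keep window predictor counts moderate relative to $n$.

## Missing homozygosity

Each biallelic HIGH-impact variant is tested one-sided for a deficit
of homozygotes of its minor allele: under HWE the homozygote count is
$\mathrm{Bin}(n, q^2)$, and $p = P(X \le k)$, which for the
absence case $k = 0$ is exactly $(1-q^2)^n$. Bonferroni multiplies by
the number of tested variants (each variant once, regardless of how
many genes it annotates to). The tested frequency $q$ is estimated
from the same cohort — including the carriers — which is the
convention of the emulated analysis; it is mildly circular and makes
the test conservative rather than anticonservative, since carriers can
only inflate $q$ when a true lethal is present. The one-sided
"absence or reduction" alternative is a declared choice (the source
analysis does not state sidedness); it reproduces the published
boundary values exactly, e.g. a minimal sample size of 1,299 at
$q = 0.1$ with 23,148 tests at $\alpha = 0.05$, and a minimal MAF of
0.2008 at $n = 317$, both recomputed by `scripts/acceptance.R`.

The calculators invert the $k = 0$ formula:
`minimal_sample_size()` takes the smallest integer $n$ with
$(1-q^2)^n \le \alpha/m$, verifying the boundary in both directions,
and `minimal_maf()` uses the closed form
$q^* = \sqrt{1 - (\alpha/m)^{1/n}}$.

## What passing tests do and do not show

The simulation reproduces the statistical structure the analyses
need — tiered divergence, a realistic SFS, LD from shared mosaic
segments, nested panels with coverage gaps — but not demographic
history (bottlenecks, migration, admixture), sex chromosomes, array
genotyping error, or sequencing/calling artefacts. Consequently the
desk-scale accuracies (≈0.82–0.96 depending on scenario) say nothing
quantitative about real cohorts, where published genome-wide values
are far lower; what carries over is the ordering of scenarios:
accuracy rises with reference-fold count, the high-density array beats
the medium one, rare variants impute worst, and strongly diverged
reference animals do not help. The same applies to the MC-ANOVA
proportions: the directional asymmetry (imputation invents some
variation absent from the sequence panel, yet holds more sequence
information than the raw array) is the reproducible finding, not any
particular percentage.

## Numerical notes

* Genotypes are integer 0/1/2 with `NA` for missing — masking is never
  representable as homozygous reference. Positions are 1-based
  throughout (the R/Bioconductor convention); BED input is converted on
  read.
* The forward matrices are renormalised at every typed site;
  forward–backward underflow raises an error rather than returning
  silent zeros.
* Pearson correlations are computed with a zero-variance guard; an
  undefined $r$ is excluded with a reason code and never enters an
  aggregate.
* Chromosome order is taken from first appearance in the input header
  and treated as opaque labels; no species-specific naming is assumed.
* `make_folds()` splits a seeded permutation into contiguous blocks
  whose sizes differ by at most one, so 65 samples at $k = 5$ always
  give the canonical five folds of 13.
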