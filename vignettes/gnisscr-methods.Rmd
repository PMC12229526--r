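---
title: "Density, space use and kinship from non-invasive genotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density, space use and kinship from non-invasive genotypes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gnisscr)
```

`gnisscr` implements the computation chain that turns replicated
microsatellite allele calls from field-collected faecal samples into
Bayesian spatial capture-recapture (SCR) density estimates, sex-specific
space-use summaries, and kinship screens. This vignette explains the
models, the tunable parameters, the synthetic-data generator that stands
in for field data, and the design decisions taken where the methodology
left genuine choices open.

## The observation chain

A genetic non-invasive sampling (gNIS) campaign collects faeces from
latrines along transects that cover a habitat patch over a handful of
visits. Each sample is genotyped in replicate at a panel of
microsatellite loci; successful samples are assigned to individuals;
the spatially referenced detections of those individuals feed an SCR
model. Samples that fail genotyping are not discarded: they are known
*detections of somebody*, and the model uses them through a thinned
point-count likelihood. Around this trunk sit three satellite analyses:
population-genetic summaries of the individual catalog, kernel-smoothed
sexual segregation indices, and pairwise kinship screening.

## Consensus genotyping and individual matching

Each sample is amplified `n_replicates = 4` times per locus (3 for the
sex-typing introns). An allele enters the consensus when it is seen in at
least `min_confirmations = 2` replicates; a locus is called heterozygous
when exactly two alleles qualify, homozygous when one qualifies and it is
seen a third time or unanimously, and missing otherwise. Three or more
qualifying alleles void the locus with a `multi_allele` flag. The
2-replicate confirmation threshold follows common practice in consensus
callers for faecal DNA; it is a parameter, not a constant.

Samples are clustered into individuals by single-linkage: two samples
link when their consensus genotypes disagree at no more than
`max_mismatch = 2` loci among loci typed in both, with at least
`min_loci_compared = 7` of the 11 loci comparable. The published rule
this implements is pairwise only; single linkage is our completion of it
to a partition, and the per-individual *diameter* (largest pairwise
mismatch inside a cluster) is reported so chained merges can be audited.
Samples with fewer than 7 typed loci are quarantined rather than
matched, because sparse genotypes are exactly the ones that produce
spurious merges. Borderline cross-individual pairs (1-2 mismatches, not
linked) are listed in the catalog, mirroring the wet-lab step of
re-amplifying near-matching genotypes, which has no computational
analogue.

Error rates are estimated by concordance against the consensus: at a
consensus-heterozygous locus each consensus allele missing from a
replicate is a dropout event (two opportunities per replicate), and any
replicate allele absent from the consensus is a false-allele event. This
is a deliberate simplification of maximum-likelihood error estimators:
it is unbiased up to a factor `1/(1+e)` (conditioning on a non-missing
call), which is negligible at the ~1% rates typical of faecal DNA, and
it needs no numerical optimisation. Loci with no heterozygous consensus
report dropout as missing, never as zero.

## The random-thinning SCR model

Space in each patch is discretized into flat-topped regular hexagons of
`cell_area = 10` m^2; the centroid lattice spacing is
`sqrt(2 * 10 / sqrt(3)) = 3.398` m. Hexagon centroids are both the
detector locations (polygon detectors) and the support of the activity
centres, which makes the likelihood of the discrete model exact and
testable against brute-force evaluation. `build_hex_grid()` warns when
the spacing is not below 1.5 times a supplied movement-scale guess: with
a female scale near 2.2 m that guideline is marginally violated by 10 m^2
cells, which is a property of the design being emulated, so it is a
warning rather than an error.

For augmented individuals `i = 1..M` with inclusion indicators
`z_i ~ Bernoulli(psi)`, activity centres follow the discretized
point-process prior `s_i ~ lambda(s) / sum(lambda)` with
`lambda(s) = exp(beta1 * alt + beta2 * alt^2)` over habitat cells
(altitude standardized over the mask). Encounters are Poisson with the
half-normal rate

```
lambda_ij = lambda0_{sex_i}(j) * exp(-||s_i - x_j||^2 / (2 * sigma_sex^2))
log lambda0_sex(j) = aF * [sex = F] + b * effort_j + c * effort_j^2
```

The baseline-rate predictor has **no intercept**, and the rate is defined
as exactly zero in cells with zero transect effort: unsurveyed polygons
cannot detect. Effort is the transect length in each hexagon,
z-scored over surveyed cells only.

Identity thinning: each detection is individually identified with
probability `theta`. Identified detections form the usual SCR histories
`y_ijk | z_i ~ Poisson(z_i * lambda_ij * theta)`; unidentified samples
enter as per-cell counts `c_jk ~ Poisson((1 - theta) * sum_i z_i *
lambda_ij)`. Because thinning a Poisson process yields two independent
Poisson processes, the identities of the unidentified detections can be
marginalized exactly — the sampler never needs to assign labels to failed
samples, avoiding label-switching machinery entirely. With `theta = 0`
the c-likelihood collapses to an unmarked point-count model, a reduction
the test suite checks analytically.

The two patches are strata of one joint model: each has its own `N`,
`psi`, `theta`, sex ratio and covariate coefficients, while the
movement scales `sigma_F`, `sigma_M` are shared across strata — with a
handful of spatial recaptures per patch, sigma is the parameter that
most needs borrowing strength, and home-range scale is the parameter
most plausibly common across nearby patches.

### Priors, updates and initialization

Priors are weakly informative and configurable: coefficients
`Normal(0, 3)`; `sigma ~ Uniform(0.1, 20)` m; `psi`, `theta`, `p_male ~
Uniform(0, 1)`. The sampler is Metropolis-within-Gibbs, written in C++:

* `z_i`: exact Gibbs from the full conditional (the c-term couples
  individuals through `Lambda_j`, handled by incremental rate updates);
* `s_i`: for included individuals, a uniform proposal over habitat cells
  within 2.2 lattice spacings, Hastings-corrected for unequal
  neighbourhood sizes at the mask edge; for excluded individuals, exact
  Gibbs from the intensity prior;
* latent sexes (augmented individuals and unsexed observed ones): Gibbs;
* continuous parameters: adaptive Gaussian random walks on transformed
  scales (log sigma, logit probabilities, with the corresponding
  Jacobians), with scales adapted toward 44% acceptance during burn-in
  only, so the post-burn-in chain is a fixed Markov kernel.

All randomness is drawn from R's RNG, so a fit is bit-reproducible given
`scr_config(seed = )`. Two presets exist: `"paper"` (M = 300, 3 chains
of 50,000 with 1,000 burn-in, the full-scale setting) and `"desk"`
(M = 150, 3 chains of 5,000 with 500 burn-in), the default used by the
test-suite and the analysis scripts; at desk scale the bundled two-patch
study converges with split-R-hat below 1.05 in about two minutes.

Chains start from data-informed values jittered per chain: a crude sigma
from the root-mean-square spread of within-individual detections, an
inclusion probability proportional to the observed count, and random
coefficient draws. Pure prior draws (e.g. sigma anywhere in 0.1-20 m)
would need far longer burn-in than the desk preset provides; jittered
data-informed starts keep chains overdispersed where it matters (each
chain gets an independent multiplicative jitter up to a factor 2) while
staying inside the basin the burn-in can absorb. This is an
initialization policy, not a change to the posterior.

Convergence is assessed with split-R-hat (each chain halved; the
implementation is cross-checked against the reference implementation in
`coda` in the test suite). `summarize_posterior()` refuses to summarize
chains whose worst split-R-hat exceeds 1.1 unless forced. Density is
reported as `D = N / A` per draw, where `A` is the habitat-mask area
(cell count times cell area). When a published density and abundance
imply a different denominator than the drawn patch outline — as happens
when masks are buffered or clipped upstream — the mask area is the
denominator this package stands behind, and it is printed alongside.

### The realized-sex question

Realized male/female counts are reported as the posterior of
`sum(z_i * [sex_i = M])` over the latent sexes, not as `p_male * N`.
The two differ in finite samples; the latent-sex sum is the quantity
that answers "how many males were in the patch", and the alternative is
one line of code on the stored draws.

## The synthetic-data generator

The generator is first-class, tested code: every downstream stage is
exercised on data whose truth is known. Its defaults are the study
conditions the package targets:

* two patches of 0.66 and 1.38 ha with 3 and 4 visits;
* inclusion probabilities 0.40/0.45 at M = 300, i.e. expected
  abundances near 120 and 135 (densities in the 90-180/ha range);
* sex ratio `p_male = 0.33`;
* half-normal scales `sigma_F = 2.18`, `sigma_M = 2.75` m;
* altitude effects `(-0.86, -1.30)` and `(0.24, -0.18)` on the two
  patches (standardized scale);
* effort coefficients `(0.39, -0.18)` with zero sex effect;
* identification probability `theta_id = 0.414`, matching an overall
  genotyping success near 41%;
* 10 autosomal loci plus X-linked Mc07 with 5-12 alleles per locus;
  truncated-geometric allele frequencies (ratio 0.5), which give
  expected heterozygosities of about 0.6-0.75 — inside the 0.38-0.85
  band of the emulated panel;
* per-replicate allelic dropout 0.92% and false alleles 0.02%;
* serpentine transects 15 m apart, so roughly a quarter of cells carry
  effort — this, with the rate model above, reproduces sample volumes of
  a few hundred per campaign.

Error model: each allele of a true heterozygote drops independently at
the dropout rate (one lost gives an apparent homozygote, both lost a
missing call; dropout is unobservable on true homozygotes and silences
the hemizygous male X entirely); with the false-allele rate, one
surviving allele is replaced by a uniformly chosen different allele of
the locus. Founders are drawn in Hardy-Weinberg proportions; pedigreed
offspring inherit Mendelianly, daughters receive the paternal X, and the
mtDNA haplotype (Hap1/Hap7 at 0.89/0.11) is maternal.

What the generator does **not** emulate: PCR chemistry (stutter, peak
heights), spatial correlation of genotyping failure (failure is
independent per detection, while in the field wet latrines fail
together), latrine re-use (detections are independent Poisson counts,
not clustered visits to shared latrines), and within-season demography
(the population is closed). Tests passing on synthetic data therefore
validate the estimators under the model's own assumptions — they do not
show robustness to these field realities.

Activity centres are simulated at cell resolution (centroid plus uniform
jitter within the hexagon), matching the discretized state space the
inference uses; simulation and inference share the model by design, so
parameter-recovery tests are calibration checks, not robustness checks.

## Segregation indices

Sexual segregation is summarized on the individual detection locations
with a negative-exponential kernel `w(d) = exp(-d / decay_length)`. The
smoothed composition at point `p` is `tau_pg = sum_q w(d_pq) [q in g]`;
from it come the spatial dissimilarity

```
D = sum_p w_p / (2 T I) * sum_g | pi_pg - P_g |,   I = sum_g P_g (1 - P_g)
```

and the exposure matrix `P*[m -> n] = sum_{p in m} (w_p / T_m) pi_pn`,
whose diagonal is isolation and whose rows sum to one. The decay length
is the number these indices are most sensitive to, and published values
rarely state it; the default is 2.5 m (the posterior movement scale of
the animals being emulated, and the natural "local environment" radius
here), and `segregation_sweep()` emits the whole sensitivity curve by
default rather than a single number. Printed index values from any one
study should be compared against the sweep, not against the default
point. Points are all detections of each individual; a one-point-per-
individual variant is a flag away (`individuals.csv` mean locations),
because averaging locations first answers a subtly different question
(segregation of home-range centres rather than of activity).

## Kinship screening

The screen has two layers. Hard exclusions implement the preprocessing a
full pedigree-reconstruction run consumes: candidate parents excluded by
allele-sharing failure at more than `tolerance` loci, maternity excluded
on mtDNA haplotype mismatch, and paternity of daughters checked at the
hemizygous X locus (a father transmits his single X allele to every
daughter). Soft evidence is the pairwise likelihood ratio over the four
canonical relationship categories via Cotterman coefficients: unrelated
(1,0,0), half-sib (.5,.5,0), full-sib (.25,.5,.25), parent-offspring
(0,1,0), with loci multiplying and the X locus excluded (diploid
formulas are invalid for hemizygous males). The per-locus pair
probabilities are proper distributions — the suite checks they sum to
one by enumeration — and the full-sib/unrelated LR on the canonical
both-heterozygous biallelic fixture equals 1.25 exactly.

This is a *screen*, not joint pedigree reconstruction: likelihoods are
per pair, so its flagged full-sib counts are not expected to equal the
output of a full-pedigree analysis of the same data, and no
mating-system comparison is attempted. The default reporting threshold
`LR >= 10` ("strong evidence" on the usual interpretive scale) yields a
false-positive rate near 0.4% per pair on unrelated synthetic
populations at the default panel — at ~7,000 pairs per campaign that is
a few dozen false flags, which is why the threshold, the mtDNA
exclusion, and the full ranked table are all surfaced. An optional
error term mixes each locus likelihood toward the unrelated value at a
supplied rate, damping LRs manufactured by allelic dropout; it is off by
default because the hard exclusions already tolerate mismatches.

## Numerical choices and degenerate inputs

* Detection ties: a sample equidistant from two centroids goes to the
  lower (column-major) cell index, deterministically.
* A boundary smaller than one hexagon yields a one-cell grid rather
  than an error; a polygon with zero area errors.
* Monomorphic loci: `He = 0`, `F_IS` undefined (returned missing);
  dropout rate with no heterozygous consensus loci is likewise missing.
* The half-normal kernel is set to exactly zero beyond 40 log-units
  (relative error < 5e-18, below accumulation error) so the sampler's
  inner loops skip dead exponentials; the R likelihood keeps the full
  expression and the two agree to 1e-10 in the tests.
* Incremental caches in the sampler (per-cell rate sums) are rebuilt
  from scratch every 250 iterations to bound floating-point drift.
* `theta` has a closed-form Beta full conditional under the uniform
  prior (thinning of a Poisson process); the sampler still uses the
  random-walk update for uniformity of treatment, and the closed form
  serves as a check.

## Problem sizes

The defaults used by the test suite and the analysis scripts are chosen
as desk-scale scientific settings: parameter-recovery experiments use 20
replicate campaigns of a 0.66 ha patch (about 660 cells) with 60
individuals at the desk preset; matching experiments use 100 catalogs of
150 samples from 60 individuals; enumeration checks run on instances of
at most 3 individuals, 4 cells and 2 occasions where brute force is
exact. The full-scale preset (`"paper"`) is available wherever a config
is accepted.

## Known limitations

* Activity centres live on the cell lattice; continuous-space refinement
  is out of scope (and would break the exact brute-force oracle).
* Distances are Euclidean; no least-cost or barrier-aware metrics.
* The detection function is half-normal only.
* The population is closed within a campaign; no open-population
  dynamics.
* Identification failure is a single per-stratum Bernoulli probability
  per detection; structured failure (per-visit, per-latrine, DNA-quality
  covariates) is not modelled.
* The kinship module stops at pairwise screening plus connected
  components; sibship partitioning and mating-system inference require
  joint pedigree tools.
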