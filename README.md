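# gnisscr

Population density, sex-specific space use and kinship for small mammals
surveyed by **genetic non-invasive sampling** (gNIS): faeces collected
along transects are genotyped in replicate at a microsatellite panel,
samples are clustered into individuals, and the spatially referenced
detections feed a Bayesian **spatial capture-recapture** (SCR) model in
which samples that *failed* genotyping still contribute through a
random-thinning likelihood. The package targets the dense, patchily
distributed populations typical of fossorial voles — patches of a
hectare or so, movement scales of 2-3 m, hundreds of samples, ~40%
genotyping success — but every rate, scale and threshold is a parameter.

It is written for field ecologists and biostatisticians who have
replicated allele-call tables and survey geometry and want the whole
chain — consensus calling, individual matching, detector-grid
construction, the SCR fit, segregation and kinship summaries — as
tested, scriptable R functions, plus a synthetic-data generator that
makes the entire chain checkable against known truth.

## The model

Space in each habitat patch is discretized into 10 m² hexagonal cells
whose centroids are both the detectors and the support of the latent
activity centres. For augmented individuals *i* = 1..*M* (strata = patches):

- inclusion: *z_i* ~ Bernoulli(ψ), population size *N* = Σ *z_i*
- activity centres: *s_i* ∝ λ(s), λ(s) = exp(β₁·alt + β₂·alt²)
- encounter rate: λ_ij = λ₀(sex_i, j) · exp(−‖s_i − x_j‖² / 2σ²_sex),
  log λ₀ = a_F·[F] + b·effort + c·effort² with **no intercept**; cells
  without transect effort have rate exactly 0
- identified detections: y_ijk | z_i ~ Poisson(z_i · λ_ij · θ)
- unidentified detections: c_jk ~ Poisson((1−θ) · Σ_i z_i λ_ij)

θ is the per-detection probability that a sample yields an identifiable
genotype; thinning a Poisson process gives two independent Poisson
streams, so unidentified identities are marginalized exactly. Movement
scales σ_F, σ_M are shared across strata; everything else is
stratum-specific. Inference is Metropolis-within-Gibbs in compiled code
(Gibbs for z, latent sexes and excluded-individual centres; Hastings-
corrected lattice proposals for active centres; adaptive random walks on
transformed scales for the continuous parameters), with split-R-hat
convergence checks.

Upstream, consensus genotypes require each allele in ≥2 of 4 PCR
replicates, and samples match into individuals when they disagree at ≤2
of ≥7 comparable loci (single linkage, with cluster diameters reported).
Downstream, male/female space use is summarized by kernel-smoothed
dissimilarity and exposure/isolation indices with a negative-exponential
distance decay, and all individual pairs are screened for kinship by
Cotterman-coefficient likelihood ratios with Mendelian, mtDNA and
X-linked hard exclusions.

## Worked example

Simulate a compact one-patch campaign with known truth, run genotyping
and matching, and fit the SCR model at the desk preset:

```r
library(gnisscr)

cfg  <- sim_config(M = 120, psi = 0.5, theta_id = 0.5)
set.seed(7)
land <- simulate_landscape(cfg, list(width = 60, height = 45, strata_id = "PatchA"))
land <- rasterize_effort(serpentine_transects(60, 45, 10), land)
pop  <- simulate_population(land, cfg)
sim  <- simulate_detections(pop, land, cfg)
gt   <- simulate_genotype_data(pop, cfg,
          samples = sim$samples[sim$samples$identified, c("sample_id", "individual")])

cat("true N:", pop$n_true, "| detections:", nrow(sim$samples),
    "| identified:", sum(sim$samples$identified), "\n")
#> true N: 66 | detections: 201 | identified: 91

cons    <- consensus_genotypes(gt$replicates)
catalog <- match_individuals(cons, samples = sim$samples)
cat("individuals matched:", nrow(catalog$individuals), "\n")
#> individuals matched: 46

fit  <- fit_scr(sim$dataset, scr_config("desk", M = 150, seed = 1))
post <- summarize_posterior(fit)
subset(as.data.frame(post),
       parameter %in% c("N", "D_per_ha", "sigma_F", "sigma_M", "theta"))
#>    parameter stratum    mean   lower   upper rhat
#> 1          N  PatchA  77.965  61.000 101.000 1.00
#> 4   D_per_ha  PatchA 274.524 214.789 355.634 1.00
#> 7      theta  PatchA   0.453   0.385   0.522 1.00
#> 13   sigma_F  shared   2.140   1.828   2.525 1.01
#> 14   sigma_M  shared   2.653   2.132   3.185 1.00
```

Of 66 animals actually present, 46 were individually identified from the
91 successful samples; the posterior for *N* (mean 78.0, 95% BCI
61-101) covers the truth, the thinning probability is recovered (0.45
vs a true 0.5), and so are both movement scales (true 2.18 and 2.75 m).
`D_per_ha` is abundance divided by the 0.27 ha habitat mask, per draw.

The numbered scripts under `analysis/` run the same chain as a
narrative: `01_simulate.R` writes the raw tables of a two-patch
campaign, `02_genotyping.R` builds the catalog (error rates, diversity,
GenePop export), `03_scr_fit.R` fits the multi-strata model and writes
the posterior and density surfaces, `04_segregation.R` and
`05_kinship.R` produce the space-use and relatedness tables, all under
`results/`.

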