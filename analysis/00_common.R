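# Shared setup for the analysis scripts: the synthetic two-patch study
# bundle all stages analyse. Everything is deterministic in STUDY_SEED,
# so each script can rebuild the bundle instead of passing binary
# intermediates around.

library(gnisscr)

STUDY_SEED <- 1
RESULTS <- "results"

dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

build_study <- function(seed = STUDY_SEED) simulate_study(seed = seed)

study_inputs <- function(study) {
  list(replicates = study$genotypes$replicates,
       sex_markers = study$genotypes$sex_markers,
       haplotypes = study$genotypes$haplotypes,
       samples = study$samples,
       grids = list(Site1 = study$Site1$grid, Site2 = study$Site2$grid),
       n_occasions = c(Site1 = 3, Site2 = 4))
}
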