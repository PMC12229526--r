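test_that("landscape cell count matches patch area and seeds reproduce", {
  cfg <- sim_config(seed = 11)
  land <- simulate_landscape(cfg, list(width = 110, height = 60,
                                       altitude = "flat"))
  # 0.66 ha of 10 m2 cells: count within 5% of 660 (boundary effects)
  expect_lt(abs(length(land$x) * 10 - 6600) / 6600, 0.05)
  expect_true(all(is.finite(land$altitude[land$habitat])))

  land2 <- simulate_landscape(cfg, list(width = 110, height = 60,
                                        altitude = "flat"))
  expect_identical(land, land2)

  smooth1 <- simulate_landscape(cfg, list(width = 40, height = 30))
  smooth2 <- simulate_landscape(cfg, list(width = 40, height = 30))
  expect_identical(smooth1, smooth2)

  expect_error(simulate_landscape(cfg, list(width = -5, height = 10)),
               "invalid-argument")
  expect_error(simulate_landscape(cfg, list(width = 5, height = 10,
                                            cell_area = 0)),
               "invalid-argument")
})

test_that("functional altitude surfaces are evaluated at cell centroids", {
  cfg <- sim_config(seed = 2)
  bump <- function(x, y) 5 * exp(-((x - 20)^2 + (y - 15)^2) / 50)
  land <- simulate_landscape(cfg, list(width = 40, height = 30,
                                       altitude = bump))
  expect_equal(land$altitude, bump(land$x, land$y))
})

test_that("activity centres follow the cell intensity", {
  # flat intensity: chi-square does not reject uniformity at alpha = 0.01
  cfg <- sim_config(seed = 5, M = 10000, psi = 1, beta_altitude = c(0, 0))
  land <- simulate_landscape(cfg, list(width = 32, height = 30,
                                       altitude = "flat"))
  pop <- simulate_population(land, cfg)
  counts <- tabulate(pop$individuals$cell, nbins = length(land$x))
  expect_gt(chisq.test(counts)$p.value, 0.01)

  # degenerate inclusion: psi = 1, M = 50 -> N_true = 50
  cfg2 <- sim_config(seed = 3, M = 50, psi = 1)
  pop2 <- simulate_population(land, cfg2)
  expect_equal(pop2$n_true, 50)

  # two-level landscape (raw covariate 0/1, beta1 = 1): closed-form
  # occupancy fraction e / (1 + e)
  cfg3 <- sim_config(seed = 9, M = 10000, psi = 1, beta_altitude = c(1, 0))
  land3 <- simulate_landscape(cfg3, list(
    width = 32, height = 30, standardize = FALSE,
    altitude = function(x, y) as.numeric(x > 16)))
  n_hi <- sum(land3$altitude_std == 1)
  n_lo <- sum(land3$altitude_std == 0)
  pop3 <- simulate_population(land3, cfg3)
  hi <- land3$altitude_std[pop3$individuals$cell] == 1
  # exact cell-count imbalance corrected: expected fraction is
  # n_hi*e / (n_hi*e + n_lo)
  expected <- n_hi * exp(1) / (n_hi * exp(1) + n_lo)
  expect_lt(abs(mean(hi) - expected), 0.02)
  expect_gt(expected, 0.65)   # near e/(1+e) = 0.731 for balanced counts

  land_flat0 <- land
  land_flat0$habitat[] <- FALSE
  expect_error(simulate_population(land_flat0, cfg), "invalid")
})

test_that("detection thinning behaves at its degenerate settings", {
  g <- uniform_effort_grid(25, 22)
  cfg <- sim_config(seed = 4, M = 30, psi = 1, theta_id = 1,
                    sigma = c(F = 2.5, M = 2.5))
  land <- simulate_landscape(cfg, list(width = 25, height = 22,
                                       altitude = "flat"))
  land$effort <- g$effort; land$effort_std <- g$effort_std
  pop <- simulate_population(land, cfg)
  sim <- simulate_detections(pop, land, cfg)
  expect_equal(sum(sim$dataset$c), 0)          # theta = 1: nothing thinned
  expect_gt(sum(sim$dataset$y), 0)

  # zero effort everywhere: encounter rate 0, empty dataset
  land0 <- land
  land0$effort[] <- 0; land0$effort_std[] <- 0
  sim0 <- simulate_detections(pop, land0, cfg)
  expect_equal(nrow(sim0$samples), 0)
  expect_equal(sum(sim0$dataset$y) + sum(sim0$dataset$c), 0)
})

test_that("identity thinning splits Poisson counts at rate theta", {
  # single individual at the centroid of a single-cell grid, lambda = 1,
  # one occasion, theta = 0.5: identified and unidentified means ~ 0.5
  g <- build_hex_grid(rect_boundary(2, 2), 10)   # degenerate: one cell
  expect_equal(length(g$x), 1)
  g$effort <- 1; g$effort_std <- 0
  g$altitude <- 0; g$altitude_std <- 0
  cfg <- sim_config(M = 1, psi = 1, theta_id = 0.5,
                    lambda0_coefs = c(0, 0, 0),
                    sigma = c(F = 2, M = 2), n_occasions = 1)
  pop <- structure(list(
    individuals = data.frame(id = 1L, x = g$x, y = g$y, cell = 1L,
                             z = 1L, sex = "F"),
    pedigree = NULL, strata_id = g$strata_id, n_true = 1L),
    class = "true_population")
  set.seed(42)
  nid <- nun <- numeric(10000)
  for (r in seq_len(10000)) {
    sim <- simulate_detections(pop, g, cfg)
    nid[r] <- sum(sim$samples$identified)
    nun[r] <- sum(!sim$samples$identified)
  }
  expect_lt(abs(mean(nid) - 0.5), 0.03)
  expect_lt(abs(mean(nun) - 0.5), 0.03)
  # the two streams together are the full Poisson(1)
  expect_lt(abs(mean(nid + nun) - 1), 0.04)
})

test_that("thinning conserves detection counts exactly", {
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, M = 60, psi = 0.8,
                      theta_id = runif(1, 0.2, 0.9))
    land <- simulate_landscape(cfg, list(width = 40, height = 30))
    land <- rasterize_effort(serpentine_transects(40, 30, 8), land)
    pop <- simulate_population(land, cfg)
    sim <- simulate_detections(pop, land, cfg)
    expect_identical(sum(sim$dataset$y) + sum(sim$dataset$c),
                     as.integer(nrow(sim$samples)))
    expect_identical(sim$truth$n_detections, nrow(sim$samples))
  }
})

test_that("mean identified counts converge to theta * total rate", {
  # one individual, small grid: E[sum y] = theta * K * sum_j lambda_ij
  g <- uniform_effort_grid(12, 10)
  cfg <- sim_config(M = 1, psi = 1, theta_id = 0.6,
                    lambda0_coefs = c(0, 0, 0),
                    sigma = c(F = 2.5, M = 2.5), n_occasions = 2)
  pop <- structure(list(
    individuals = data.frame(id = 1L, x = g$x[5], y = g$y[5], cell = 5L,
                             z = 1L, sex = "M"),
    pedigree = NULL, strata_id = g$strata_id, n_true = 1L),
    class = "true_population")
  d2 <- (g$x - g$x[5])^2 + (g$y - g$y[5])^2
  expected <- 0.6 * 2 * sum(exp(-d2 / (2 * 2.5^2)))
  set.seed(99)
  tot <- numeric(10000)
  for (r in seq_len(10000)) {
    sim <- simulate_detections(pop, g, cfg)
    tot[r] <- sum(sim$dataset$y)
  }
  expect_lt(abs(mean(tot) - expected) / expected, 0.05)
})

test_that("replicate genotypes reproduce the truth when error-free", {
  cfg <- sim_config(seed = 21, error_rates = list(dropout = 0,
                                                  false_allele = 0))
  fam <- simulate_families(3, 2, cfg)
  gt <- simulate_genotype_data(fam, cfg)
  for (s in unique(gt$replicates$sample_id)) {
    ind <- gt$truth$samples$individual[gt$truth$samples$sample_id == s]
    g <- gt$truth$genotypes[[ind]]
    reps <- gt$replicates[gt$replicates$sample_id == s, ]
    expect_true(all(reps$allele1 == g[reps$locus, 1] &
                    reps$allele2 == g[reps$locus, 2] |
                    reps$allele1 == g[reps$locus, 2] &
                    reps$allele2 == g[reps$locus, 1]))
  }
  # offspring share >= 1 allele per autosomal locus with each true parent
  ped <- fam$pedigree[!is.na(fam$pedigree$mother), ]
  for (o in ped$id) {
    go <- gt$truth$genotypes[[o]]
    for (par in unlist(ped[ped$id == o, c("mother", "father")])) {
      gp <- gt$truth$genotypes[[par]]
      for (l in setdiff(rownames(go), gt$truth$x_locus))
        expect_true(any(go[l, ] %in% gp[l, ]))
    }
  }
  # mtDNA is maternal
  for (o in ped$id)
    expect_identical(gt$truth$haplotypes[[o]],
                     gt$truth$haplotypes[[ped$mother[ped$id == o]]])
})

test_that("heterozygote dropout yields apparent homozygotes at the derived rate", {
  freqs <- list(L1 = c(a = 0.5, b = 0.5))
  cfg <- sim_config(seed = 31, allele_freqs = freqs, n_replicates = 10000,
                    error_rates = list(dropout = 0.5, false_allele = 0))
  pop <- structure(list(
    individuals = data.frame(id = "i1", sex = "F"), pedigree = NULL,
    strata_id = "x", n_true = 1), class = "true_population")
  # find a seed where the founder is heterozygous
  gt <- simulate_genotype_data(pop, cfg)
  tries <- 0
  while (gt$truth$genotypes[["i1"]]["L1", 1] ==
         gt$truth$genotypes[["i1"]]["L1", 2] && tries < 20) {
    cfg$seed <- cfg$seed + 1; tries <- tries + 1
    gt <- simulate_genotype_data(pop, cfg)
  }
  expect_true(gt$truth$genotypes[["i1"]]["L1", 1] !=
              gt$truth$genotypes[["i1"]]["L1", 2])
  reps <- gt$replicates
  hom <- !is.na(reps$allele1) & reps$allele1 == reps$allele2
  mis <- is.na(reps$allele1)
  # one of two alleles lost (not both): P = 2 * 0.5 * 0.5 = 0.5
  expect_lt(abs(mean(hom) - 0.5), 0.02)
  # both lost: P = 0.25
  expect_lt(abs(mean(mis) - 0.25), 0.02)
})

test_that("full-sib heterozygosity matches the transmission enumeration", {
  # enumeration oracle: parents both heterozygous a/b; each offspring
  # inherits one allele from each parent uniformly -> P(offspring het) =
  # 2/4; two independent offspring -> 1/4
  p_het_off <- 0
  for (ma in c("a", "b")) for (fa in c("a", "b"))
    p_het_off <- p_het_off + 0.25 * (ma != fa)
  p_both_het <- p_het_off^2
  expect_equal(p_both_het, 0.25)

  freqs <- list(L1 = c(a = 0.5, b = 0.5))
  both_het <- 0; n_cond <- 0
  set.seed(77)
  for (r in 1:2000) {
    cfg <- sim_config(allele_freqs = freqs,
                      error_rates = list(dropout = 0, false_allele = 0))
    fam <- simulate_families(1, 2, cfg)
    gt <- simulate_genotype_data(fam, cfg)
    gm <- gt$truth$genotypes[["F01_mother"]]["L1", ]
    gf <- gt$truth$genotypes[["F01_father"]]["L1", ]
    if (gm[1] == gm[2] || gf[1] == gf[2]) next
    n_cond <- n_cond + 1
    o1 <- gt$truth$genotypes[["F01_off1"]]["L1", ]
    o2 <- gt$truth$genotypes[["F01_off2"]]["L1", ]
    if (o1[1] != o1[2] && o2[1] != o2[2]) both_het <- both_het + 1
  }
  expect_gt(n_cond, 300)
  expect_lt(abs(both_het / n_cond - p_both_het), 0.06)
})
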