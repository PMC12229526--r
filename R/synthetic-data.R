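# Synthetic-data generator: landscapes, true populations, half-normal
# Poisson detections with random identity thinning, and error-prone
# replicated microsatellite genotypes. The defaults emulate the study
# system the package targets: two ~0.7-1.4 ha fen patches holding dense
# vole populations (~120-140 animals), a female-biased sex ratio, 10
# autosomal loci plus one X-linked locus with 5-12 alleles each, four PCR
# replicates per faecal sample with ~1% allelic dropout and ~0.02% false
# alleles, and roughly 41% of collected samples yielding an identifiable
# genotype.

#' Default microsatellite allele frequencies
#'
#' Ten autosomal loci and one X-linked locus (`Mc07`), with 5-12 alleles
#' per locus. Frequencies follow a truncated geometric profile (ratio 0.5)
#' which yields expected heterozygosities of about 0.6-0.75, matching the
#' diversity typical of the panel this generator emulates. Allele labels
#' are fragment lengths in base pairs.
#' @return named list of named numeric vectors summing to 1; the X-linked
#'   locus carries attribute `x_linked = "Mc07"` on the list.
#' @export
default_allele_freqs <- function() {
  n_alleles <- c(Mc18 = 5, Mc24 = 7, Mc30 = 12, Mc02 = 6, MSMM3 = 8,
                 Mar03 = 9, Mar16 = 7, Mar76 = 8, MAG25 = 5, Ma25 = 10,
                 Mc07 = 6)
  freqs <- lapply(seq_along(n_alleles), function(i) {
    k <- n_alleles[[i]]
    w <- 0.5^(seq_len(k) - 1)
    stats::setNames(w / sum(w), as.character(100 + 2 * (seq_len(k) - 1)))
  })
  names(freqs) <- names(n_alleles)
  attr(freqs, "x_linked") <- "Mc07"
  freqs
}

#' Simulation configuration
#'
#' Bundles every parameter of the generative model. Defaults are the study
#' conditions the generator emulates; see the methods vignette for the
#' provenance of each value.
#'
#' @param M augmented population size used when drawing the population.
#' @param psi inclusion probability; expected true abundance is `M * psi`.
#' @param p_male probability an individual is male (female-biased default).
#' @param beta_altitude length-2 vector: linear and quadratic coefficients
#'   of standardized altitude in the activity-centre intensity.
#' @param lambda0_coefs length-3 vector: female effect on the log baseline
#'   encounter rate, and linear and quadratic standardized-effort effects
#'   (the linear predictor has no intercept; zero-effort cells have rate 0).
#' @param sigma named length-2 vector `c(F = , M = )`: half-normal movement
#'   scales in metres.
#' @param theta_id per-detection probability that a sample yields an
#'   identifiable genotype (random thinning parameter).
#' @param n_occasions number of survey visits.
#' @param n_replicates PCR replicates per sample (sex markers use 3).
#' @param error_rates list with `dropout` (per-allele, per-replicate) and
#'   `false_allele` (per-call, per-replicate) rates.
#' @param allele_freqs per-locus allele frequencies, see
#'   [default_allele_freqs()].
#' @param haplotype_freqs mtDNA haplotype frequencies.
#' @param marker_fail per-replicate amplification failure rate of the sex
#'   introns.
#' @param seed optional integer seed; every `simulate_*` call that receives
#'   a config with a seed is bit-reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(M = 300, psi = 0.40, p_male = 0.33,
                       beta_altitude = c(-0.86, -1.30),
                       lambda0_coefs = c(sex_f = 0, effort_lin = 0.39,
                                         effort_quad = -0.18),
                       sigma = c(F = 2.18, M = 2.75),
                       theta_id = 0.414,
                       n_occasions = 3,
                       n_replicates = 4,
                       error_rates = list(dropout = 0.0092,
                                          false_allele = 0.0002),
                       allele_freqs = default_allele_freqs(),
                       haplotype_freqs = c(Hap1 = 0.893, Hap7 = 0.107),
                       marker_fail = 0.02,
                       seed = NULL) {
  stopifnot(length(beta_altitude) == 2, length(lambda0_coefs) == 3,
            length(sigma) == 2)
  if (psi < 0 || psi > 1 || p_male < 0 || p_male > 1 ||
      theta_id < 0 || theta_id > 1)
    stop("invalid-argument: psi, p_male and theta_id must lie in [0, 1]")
  if (any(sigma <= 0)) stop("invalid-argument: sigma must be positive")
  if (M < 1) stop("invalid-argument: M must be a positive integer")
  for (nm in names(allele_freqs)) {
    f <- allele_freqs[[nm]]
    if (abs(sum(f) - 1) > 1e-8 || any(f < 0))
      stop(sprintf("invalid-argument: allele frequencies at locus %s do not sum to 1", nm))
  }
  if (is.null(names(sigma))) names(sigma) <- c("F", "M")
  structure(list(
    M = as.integer(M), psi = psi, p_male = p_male,
    beta_altitude = beta_altitude,
    lambda0_coefs = lambda0_coefs,
    sigma = sigma, theta_id = theta_id,
    n_occasions = as.integer(n_occasions),
    n_replicates = as.integer(n_replicates),
    error_rates = error_rates,
    allele_freqs = allele_freqs,
    haplotype_freqs = haplotype_freqs / sum(haplotype_freqs),
    marker_fail = marker_fail,
    seed = seed
  ), class = "sim_config")
}

#' Simulate a habitat patch landscape
#'
#' Builds the hexagonal discretization of a rectangular patch and lays a
#' smooth (spatially autocorrelated) altitude surface over it.
#'
#' @param config a `sim_config` (supplies `seed`; cell geometry comes from
#'   `patch_spec`).
#' @param patch_spec list with `width` and `height` in metres, optional
#'   `cell_area` (default 10), optional `altitude`: `"smooth"` (default,
#'   sum of random Gaussian bumps), `"flat"`, or a `function(x, y)`
#'   evaluated at cell centroids; optional `strata_id`; optional
#'   `standardize` (default TRUE) controlling whether the intensity
#'   covariate is the z-scored or the raw altitude.
#' @return a `detector_grid` with altitude attached (also class
#'   `landscape`).
#' @export
simulate_landscape <- function(config, patch_spec) {
  if (is.null(patch_spec$width) || is.null(patch_spec$height) ||
      patch_spec$width <= 0 || patch_spec$height <= 0)
    stop("invalid-argument: patch_spec needs positive width and height")
  cell_area <- patch_spec$cell_area %||% 10
  if (cell_area <= 0) stop("invalid-argument: cell_area must be positive")
  with_seed(config$seed, {
    grid <- build_hex_grid(rect_boundary(patch_spec$width, patch_spec$height),
                           cell_area = cell_area,
                           strata_id = patch_spec$strata_id %||% "patch")
    alt_spec <- patch_spec$altitude %||% "smooth"
    if (is.function(alt_spec)) {
      alt <- alt_spec(grid$x, grid$y)
    } else if (identical(alt_spec, "flat")) {
      alt <- rep(0, length(grid$x))
    } else if (identical(alt_spec, "smooth")) {
      # sum of broad Gaussian bumps: a smooth, autocorrelated surface with
      # metre-scale relief, emulating the micro-topography of a fen patch
      n_bumps <- patch_spec$n_bumps %||% 6
      bx <- runif(n_bumps, 0, patch_spec$width)
      by <- runif(n_bumps, 0, patch_spec$height)
      amp <- runif(n_bumps, -1, 1)
      sc <- runif(n_bumps, 0.2, 0.5) * max(patch_spec$width, patch_spec$height)
      alt <- rep(0, length(grid$x))
      for (b in seq_len(n_bumps))
        alt <- alt + amp[b] * exp(-((grid$x - bx[b])^2 + (grid$y - by[b])^2) /
                                    (2 * sc[b]^2))
      alt <- 300 + 2 * alt   # ~2 m relief around a 300 m base elevation
    } else stop("invalid-argument: unknown altitude spec")
    if (any(!is.finite(alt[grid$habitat])))
      stop("invalid-data: non-finite altitude over habitat cells")
    grid$altitude <- alt
    # standardize = FALSE keeps the raw surface as the intensity covariate
    # (useful when the covariate is already on a meaningful scale)
    grid$altitude_std[grid$habitat] <- if (isFALSE(patch_spec$standardize))
      alt[grid$habitat] else zscore(alt[grid$habitat])
    class(grid) <- c("landscape", class(grid))
    grid
  })
}

# Uniform point in the flat-topped hexagon centred at (cx, cy): rejection
# sampling from the bounding box.
jitter_in_hex <- function(cx, cy, R) {
  apo <- sqrt(3) / 2 * R
  ang <- pi / 3 * (0:5) + pi / 6
  nx <- cos(ang); ny <- sin(ang)
  repeat {
    dx <- runif(1, -R, R); dy <- runif(1, -apo, apo)
    if (all(dx * nx + dy * ny <= apo)) return(c(cx + dx, cy + dy))
  }
}

# Per-cell activity-centre intensity on the habitat mask.
cell_intensity <- function(landscape, beta) {
  A <- landscape$altitude_std
  lam <- exp(beta[1] * A + beta[2] * A^2)
  lam[!landscape$habitat] <- 0
  lam
}

# Per-cell baseline encounter rate by sex ("F", "M"); exactly zero where
# effort is zero (no intercept in the linear predictor).
cell_lambda0 <- function(grid, coefs) {
  lp <- coefs[2] * grid$effort_std + coefs[3] * grid$effort_std^2
  out <- cbind(F = exp(coefs[1] + lp), M = exp(lp))
  out[grid$effort <= 0, ] <- 0
  out
}

#' Simulate a true population of activity centres
#'
#' Draws `M` augmented individuals: inclusion flags `z ~ Bernoulli(psi)`,
#' sexes `~ Bernoulli(p_male)`, and activity centres from the discrete cell
#' distribution with probability proportional to
#' `exp(beta1 * alt + beta2 * alt^2)` over habitat cells, placed at the
#' cell centroid plus a uniform jitter within the hexagon.
#'
#' @param landscape a `landscape`/`detector_grid` with altitude attached.
#' @param config a `sim_config`.
#' @return object of class `true_population`: list with `individuals`
#'   (data frame `id`, `x`, `y`, `cell`, `z`, `sex`), `pedigree` (NULL
#'   here; see [simulate_families()]), `strata_id`, `n_true`.
#' @export
simulate_population <- function(landscape, config) {
  stopifnot(inherits(landscape, "detector_grid"))
  if (!any(landscape$habitat)) stop("invalid-argument: landscape has no habitat cells")
  lam <- cell_intensity(landscape, config$beta_altitude)
  if (sum(lam) <= 0 || any(!is.finite(lam)))
    stop("invalid-state: all-zero or non-finite activity-centre intensity")
  with_seed(config$seed, {
    M <- config$M
    z <- rbinom(M, 1, config$psi)
    sex <- ifelse(runif(M) < config$p_male, "M", "F")
    cells <- sample.int(length(lam), M, replace = TRUE, prob = lam)
    xy <- t(vapply(cells, function(j)
      jitter_in_hex(landscape$x[j], landscape$y[j], landscape$hex_R),
      numeric(2)))
    structure(list(
      individuals = data.frame(id = seq_len(M), x = xy[, 1], y = xy[, 2],
                               cell = cells, z = z, sex = sex,
                               stringsAsFactors = FALSE),
      pedigree = NULL,
      strata_id = landscape$strata_id,
      n_true = sum(z)
    ), class = "true_population")
  })
}

#' Simulate detections with random identity thinning
#'
#' For every alive individual, cell and occasion, draws
#' `y* ~ Poisson(lambda_ij)` encounter counts under the half-normal model
#' with sex-specific movement scale and effort-dependent baseline rate.
#' Each detection is then independently labelled identified with
#' probability `theta_id`; identified detections aggregate into the
#' detection array `y[i, j, k]`, the rest into unidentified counts
#' `c[j, k]`. The full detection-to-individual mapping is retained as the
#' truth record.
#'
#' @param pop a `true_population`.
#' @param grid a `detector_grid` with effort attached (must share geometry
#'   with the landscape the population was drawn on).
#' @param config a `sim_config`.
#' @return object of class `scr_sim`: list with `dataset` (an
#'   `scr_dataset` of the identified detections plus unidentified counts),
#'   `samples` (one row per detection: `sample_id`, `individual`, `site`,
#'   `x`, `y`, `visit`, `cell`, `identified`), and `truth` (the population
#'   and realized totals).
#' @export
simulate_detections <- function(pop, grid, config) {
  stopifnot(inherits(pop, "true_population"), inherits(grid, "detector_grid"))
  if (!identical(pop$strata_id, grid$strata_id))
    stop("invalid-argument: population and grid come from different strata")
  with_seed(config$seed, {
    lam0 <- cell_lambda0(grid, config$lambda0_coefs)
    act <- pop$individuals[pop$individuals$z == 1, , drop = FALSE]
    K <- config$n_occasions
    rows <- list(); nr <- 0
    if (nrow(act) && any(lam0 > 0)) {
      surveyed <- which(grid$effort > 0)
      for (i in seq_len(nrow(act))) {
        sx <- act$sex[i]
        d2 <- (grid$x[surveyed] - act$x[i])^2 + (grid$y[surveyed] - act$y[i])^2
        rate <- lam0[surveyed, sx] * exp(-d2 / (2 * config$sigma[[sx]]^2))
        counts <- matrix(rpois(length(surveyed) * K, rep(rate, K)),
                         nrow = length(surveyed))
        hit <- which(counts > 0, arr.ind = TRUE)
        for (h in seq_len(nrow(hit))) {
          j <- surveyed[hit[h, 1]]; k <- hit[h, 2]
          for (rep_i in seq_len(counts[hit[h, 1], hit[h, 2]])) {
            xy <- jitter_in_hex(grid$x[j], grid$y[j], grid$hex_R)
            nr <- nr + 1
            rows[[nr]] <- data.frame(individual = act$id[i],
                                     x = xy[1], y = xy[2], visit = k, cell = j)
          }
        }
      }
    }
    samples <- if (nr) do.call(rbind, rows) else
      data.frame(individual = integer(0), x = numeric(0), y = numeric(0),
                 visit = integer(0), cell = integer(0))
    n_det <- nrow(samples)
    samples$identified <- if (n_det) runif(n_det) < config$theta_id else logical(0)
    samples$site <- rep(grid$strata_id, n_det)
    samples$sample_id <- sprintf("%s_S%04d", grid$strata_id, seq_len(n_det))
    samples <- samples[, c("sample_id", "individual", "site", "x", "y",
                           "visit", "cell", "identified")]

    idf <- samples[samples$identified, , drop = FALSE]
    sex_lookup <- setNames(pop$individuals$sex, pop$individuals$id)
    identified_df <- data.frame(individual = idf$individual, x = idf$x,
                                y = idf$y, visit = idf$visit)
    attr(identified_df, "sexes") <-
      unname(sex_lookup[as.character(sort(unique(idf$individual)))])
    dataset <- assign_detections(
      identified = identified_df,
      failed_samples = samples[!samples$identified, c("x", "y", "visit")],
      grid = grid, n_occasions = K)
    structure(list(dataset = dataset, samples = samples,
                   truth = list(population = pop, n_true = pop$n_true,
                                n_detections = n_det,
                                n_identified = sum(samples$identified))),
              class = "scr_sim")
  })
}

#' Simulate family groups with a known pedigree
#'
#' Builds `n_families` monogamous pairs of unrelated founders plus
#' `n_offspring` full-sib offspring per pair, for testing kinship
#' screening and Mendelian exclusion on data with known truth.
#'
#' @param n_families number of families.
#' @param n_offspring offspring per family.
#' @param config a `sim_config` (supplies `p_male` and `seed`).
#' @return a `true_population`-like list with `individuals` (`id`, `sex`,
#'   `family`, `role`) and `pedigree` (`id`, `mother`, `father`).
#' @export
simulate_families <- function(n_families, n_offspring, config = sim_config()) {
  with_seed(config$seed, {
    ids <- list(); ped <- list(); k <- 0
    for (f in seq_len(n_families)) {
      mo <- sprintf("F%02d_mother", f); fa <- sprintf("F%02d_father", f)
      ids[[length(ids) + 1]] <- data.frame(id = mo, sex = "F", family = f,
                                           role = "founder")
      ids[[length(ids) + 1]] <- data.frame(id = fa, sex = "M", family = f,
                                           role = "founder")
      ped[[length(ped) + 1]] <- data.frame(id = c(mo, fa),
                                           mother = NA_character_,
                                           father = NA_character_)
      for (o in seq_len(n_offspring)) {
        oid <- sprintf("F%02d_off%d", f, o)
        ids[[length(ids) + 1]] <- data.frame(
          id = oid, sex = ifelse(runif(1) < config$p_male, "M", "F"),
          family = f, role = "offspring")
        ped[[length(ped) + 1]] <- data.frame(id = oid, mother = mo, father = fa)
      }
    }
    structure(list(individuals = do.call(rbind, ids),
                   pedigree = do.call(rbind, ped),
                   strata_id = "families", n_true = NA),
              class = "true_population")
  })
}

# Draw true multilocus genotypes for a set of individuals, respecting an
# optional pedigree (founders first in pedigree order), Hardy-Weinberg
# founder genotypes, Mendelian autosomal inheritance, X-linked inheritance
# at the hemizygous-male locus, and maternal mtDNA haplotypes.
sim_true_genotypes <- function(individuals, pedigree, config) {
  freqs <- config$allele_freqs
  xloc <- attr(freqs, "x_linked") %||% "Mc07"
  loci <- names(freqs)
  n <- nrow(individuals)
  geno <- vector("list", n)
  names(geno) <- individuals$id
  hap <- setNames(rep(NA_character_, n), individuals$id)
  sex <- setNames(individuals$sex, individuals$id)

  draw_allele <- function(locus) sample(names(freqs[[locus]]), 1,
                                        prob = freqs[[locus]])
  parent_of <- function(id) {
    if (is.null(pedigree)) return(c(NA, NA))
    r <- pedigree[pedigree$id == id, , drop = FALSE]
    if (!nrow(r)) return(c(NA, NA))
    c(r$mother[1], r$father[1])
  }

  order_ids <- individuals$id
  if (!is.null(pedigree)) {
    founders <- pedigree$id[is.na(pedigree$mother)]
    order_ids <- c(intersect(order_ids, founders),
                   setdiff(order_ids, founders))
  }
  for (id in order_ids) {
    par <- parent_of(id)
    g <- matrix(NA_character_, nrow = length(loci), ncol = 2,
                dimnames = list(loci, NULL))
    if (is.na(par[1])) {        # founder
      for (l in loci) {
        if (l == xloc && sex[[id]] == "M") {
          a <- draw_allele(l); g[l, ] <- c(a, a)   # hemizygous, shown twice
        } else g[l, ] <- c(draw_allele(l), draw_allele(l))
      }
      hap[id] <- sample(names(config$haplotype_freqs), 1,
                        prob = config$haplotype_freqs)
    } else {
      gm <- geno[[par[1]]]; gf <- geno[[par[2]]]
      for (l in loci) {
        if (l == xloc) {
          mat <- gm[l, sample(1:2, 1)]
          if (sex[[id]] == "M") g[l, ] <- c(mat, mat)
          else g[l, ] <- sort(c(mat, gf[l, 1]))   # father transmits his X
        } else {
          g[l, ] <- sort(c(gm[l, sample(1:2, 1)], gf[l, sample(1:2, 1)]))
        }
      }
      hap[id] <- hap[[par[1]]]
    }
    geno[[id]] <- g
  }
  list(genotypes = geno, haplotypes = hap, x_locus = xloc)
}

# Apply the replicate error model to a true two-allele call. Heterozygote
# alleles drop independently (one lost -> apparent homozygote, both ->
# missing); with the false-allele rate one surviving allele is replaced by
# a uniformly chosen different allele at the locus.
corrupt_call <- function(alleles, locus, config, hemizygous = FALSE) {
  d <- config$error_rates$dropout
  fa <- config$error_rates$false_allele
  a <- alleles
  if (hemizygous || a[1] == a[2]) {
    if (hemizygous && runif(1) < d) return(c(NA, NA))
  } else {
    drop <- runif(2) < d
    if (all(drop)) return(c(NA, NA))
    if (drop[1]) a <- c(a[2], a[2])
    if (drop[2]) a <- c(a[1], a[1])
  }
  if (runif(1) < fa) {
    others <- setdiff(names(config$allele_freqs[[locus]]), a)
    if (length(others)) {
      slot <- sample(1:2, 1)
      a[slot] <- sample(others, 1)
    }
  }
  sort(a)
}

#' Simulate replicated genotype, sex-marker and haplotype tables
#'
#' Draws true genotypes for the population (founders in Hardy-Weinberg
#' proportions, Mendelian inheritance when a pedigree is present, X-linked
#' inheritance at the hemizygous-male locus, maternal mtDNA), then produces
#' `n_replicates` error-prone PCR calls per sample and locus, 3 replicate
#' sex-intron amplification results, and a haplotype label per sample.
#'
#' @param pop a `true_population` (or [simulate_families()] output).
#' @param config a `sim_config`.
#' @param samples optional data frame (`sample_id`, `individual`) listing
#'   which samples to genotype (e.g. the identified detections of a
#'   [simulate_detections()] run); default is one sample per individual.
#' @return list with `replicates` (long data frame `sample_id`, `locus`,
#'   `replicate`, `allele1`, `allele2`), `sex_markers` (`sample_id`,
#'   `replicate`, `dbx`, `dby`), `haplotypes` (`sample_id`, `haplotype`),
#'   and `truth` (true genotypes, haplotypes, x locus, sample-individual
#'   map).
#' @export
simulate_genotype_data <- function(pop, config, samples = NULL) {
  with_seed(config$seed, {
    inds <- pop$individuals
    if (is.null(samples))
      samples <- data.frame(sample_id = paste0("smp_", inds$id),
                            individual = inds$id, stringsAsFactors = FALSE)
    truth <- sim_true_genotypes(inds, pop$pedigree, config)
    loci <- names(config$allele_freqs)
    nrep <- config$n_replicates
    ns <- nrow(samples)
    total <- ns * length(loci) * nrep
    out_sample <- character(total); out_locus <- character(total)
    out_rep <- integer(total); out_a1 <- character(total); out_a2 <- character(total)
    r <- 0
    for (s in seq_len(ns)) {
      g <- truth$genotypes[[as.character(samples$individual[s])]]
      male <- truth$x_locus %in% loci &&
        inds$sex[match(samples$individual[s], inds$id)] == "M"
      for (l in loci) {
        hemi <- male && l == truth$x_locus
        for (rep_i in seq_len(nrep)) {
          call <- corrupt_call(g[l, ], l, config, hemizygous = hemi)
          r <- r + 1
          out_sample[r] <- samples$sample_id[s]; out_locus[r] <- l
          out_rep[r] <- rep_i; out_a1[r] <- call[1]; out_a2[r] <- call[2]
        }
      }
    }
    replicates <- data.frame(sample_id = out_sample, locus = out_locus,
                             replicate = out_rep, allele1 = out_a1,
                             allele2 = out_a2, stringsAsFactors = FALSE)
    sexes <- inds$sex[match(samples$individual, inds$id)]
    sm <- expand.grid(sample_id = samples$sample_id, replicate = 1:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sm <- sm[order(sm$sample_id, sm$replicate), ]
    smale <- sexes[match(sm$sample_id, samples$sample_id)] == "M"
    sm$dbx <- runif(nrow(sm)) > config$marker_fail
    sm$dby <- smale & (runif(nrow(sm)) > config$marker_fail)
    haplotypes <- data.frame(
      sample_id = samples$sample_id,
      haplotype = unname(truth$haplotypes[as.character(samples$individual)]),
      stringsAsFactors = FALSE)
    list(replicates = replicates, sex_markers = sm, haplotypes = haplotypes,
         truth = c(truth, list(samples = samples, sexes = sexes)))
  })
}

#' Simulate a complete two-patch study bundle
#'
#' End-to-end generator emulating the full observation chain on two
#' habitat patches: landscape, serpentine survey effort, true population,
#' thinned detections, and replicated genotypes for the identified
#' samples. Patch 1 defaults to 0.66 ha with 3 visits; patch 2 to 1.38 ha
#' with 4 visits.
#'
#' @param config_site1,config_site2 `sim_config` objects for the two
#'   patches (visit numbers and inclusion probabilities may differ).
#' @param patch1,patch2 patch specs passed to [simulate_landscape()].
#' @param transect_spacing serpentine pass spacing in metres.
#' @param seed integer seed controlling the whole bundle.
#' @return list with per-site `landscape`, `grid`, `population`, `sim`
#'   (the `scr_sim`), pooled `genotypes` tables and a `samples` table over
#'   both sites (identified and failed).
#' @export
simulate_study <- function(
    config_site1 = sim_config(psi = 0.40, n_occasions = 3),
    config_site2 = sim_config(psi = 0.45, n_occasions = 4,
                              beta_altitude = c(0.24, -0.18)),
    patch1 = list(width = 110, height = 60, strata_id = "Site1"),
    patch2 = list(width = 115, height = 120, strata_id = "Site2"),
    transect_spacing = 15, seed = 1) {
  with_seed(seed, {
    sites <- list(Site1 = list(cfg = config_site1, patch = patch1),
                  Site2 = list(cfg = config_site2, patch = patch2))
    out <- list(); all_samples <- list(); geno <- list()
    for (nm in names(sites)) {
      cfg <- sites[[nm]]$cfg
      cfg$seed <- NULL   # one seed governs the bundle
      patch <- sites[[nm]]$patch
      land <- simulate_landscape(cfg, patch)
      land <- rasterize_effort(
        serpentine_transects(patch$width, patch$height, transect_spacing), land)
      pop <- simulate_population(land, cfg)
      sim <- simulate_detections(pop, land, cfg)
      idf <- sim$samples[sim$samples$identified, , drop = FALSE]
      gt <- simulate_genotype_data(
        pop, cfg, samples = idf[, c("sample_id", "individual")])
      out[[nm]] <- list(landscape = land, grid = land, population = pop,
                        sim = sim, genotypes = gt, config = cfg)
      all_samples[[nm]] <- sim$samples
      geno[[nm]] <- gt
    }
    reps <- do.call(rbind, lapply(geno, function(g) g$replicates))
    sexm <- do.call(rbind, lapply(geno, function(g) g$sex_markers))
    haps <- do.call(rbind, lapply(geno, function(g) g$haplotypes))
    rownames(reps) <- rownames(sexm) <- rownames(haps) <- NULL
    samples <- do.call(rbind, all_samples); rownames(samples) <- NULL
    c(out, list(samples = samples,
                genotypes = list(replicates = reps, sex_markers = sexm,
                                 haplotypes = haps),
                seed = seed))
  })
}
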