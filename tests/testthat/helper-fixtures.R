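# Shared fixtures and small independent oracles used across test files.

# Build a consensus_genotypes()-shaped object directly from a list of
# per-sample genotypes: each genotype is a named list locus -> c(a1, a2)
# (NA for missing loci).
make_consensus <- function(genotypes, loci = NULL) {
  ids <- names(genotypes)
  if (is.null(loci))
    loci <- unique(unlist(lapply(genotypes, names)))
  a1 <- a2 <- matrix(NA_character_, length(ids), length(loci),
                     dimnames = list(ids, loci))
  for (s in seq_along(ids)) {
    g <- genotypes[[s]]
    for (l in names(g)) {
      pair <- sort(as.character(g[[l]]))
      if (!anyNA(pair)) {
        a1[s, l] <- pair[1]; a2[s, l] <- pair[2]
      }
    }
  }
  list(a1 = a1, a2 = a2,
       flags = matrix("ok", length(ids), length(loci)),
       sample_ids = ids, loci = loci,
       n_confirmed = rowSums(!is.na(a1)))
}

# Minimal individual_catalog for functions that only need genotypes/loci.
make_catalog <- function(genotypes_long, loci, sites = NULL, haps = NULL) {
  ids <- unique(genotypes_long$individual_id)
  structure(list(
    individuals = data.frame(
      individual_id = ids, sex = "U",
      site = if (is.null(sites)) NA_character_ else unname(sites[as.character(ids)]),
      n_samples = 1L, diameter = 0L,
      haplotype = if (is.null(haps)) NA_character_ else unname(haps[as.character(ids)])),
    membership = data.frame(sample_id = as.character(ids), individual_id = ids),
    genotypes = genotypes_long, detections = NULL,
    unassignable = character(0), loci = loci),
    class = "individual_catalog")
}

# A small rectangular grid with uniform positive effort (all cells
# surveyed at the mean effort level, standardized value 0).
uniform_effort_grid <- function(width, height, strata_id = "patch",
                                cell_area = 10) {
  g <- build_hex_grid(rect_boundary(width, height), cell_area,
                      strata_id = strata_id)
  g$effort <- rep(1, length(g$x))
  g$effort_std <- rep(0, length(g$x))
  g$altitude <- rep(0, length(g$x))
  g$altitude_std <- rep(0, length(g$x))
  g
}

# Independent naive evaluation of the joint log density, written term by
# term with scalar loops and hand-rolled Poisson/Bernoulli log-pmfs
# (no shared code with the package implementation).
naive_joint_log_density <- function(dataset, params, latents) {
  grid <- dataset$grid
  hab <- which(grid$habitat)
  pk <- params$strata[[1]]; lk <- latents$strata[[1]]
  M <- length(lk$z); K <- dataset$n_occasions
  n_obs <- dim(dataset$y)[1]
  lpois <- function(y, mu) {
    if (mu == 0) { if (y == 0) 0 else -Inf }
    else y * log(mu) - mu - lgamma(y + 1)
  }
  lam0_at <- function(j, sex) {
    if (grid$effort[hab[j]] == 0) return(0)
    e <- grid$effort_std[hab[j]]
    exp(pk$lambda0_coefs[1] * (sex == "F") +
          pk$lambda0_coefs[2] * e + pk$lambda0_coefs[3] * e^2)
  }
  lam_ij <- function(i, j) {
    sg <- params$sigma[[lk$sex[i]]]
    d2 <- (grid$x[hab[lk$s[i]]] - grid$x[hab[j]])^2 +
      (grid$y[hab[lk$s[i]]] - grid$y[hab[j]])^2
    lam0_at(j, lk$sex[i]) * exp(-d2 / (2 * sg^2))
  }
  ll <- 0
  for (i in 1:M) {
    if (lk$z[i] == 1) {
      for (j in seq_along(hab)) {
        rate <- lam_ij(i, j) * pk$theta
        for (k in 1:K) {
          yv <- if (i <= n_obs) dataset$y[i, hab[j], k] else 0
          ll <- ll + lpois(yv, rate)
        }
      }
    }
    ll <- ll + ifelse(lk$z[i] == 1, log(pk$psi), log(1 - pk$psi))
    ll <- ll + ifelse(lk$sex[i] == "M", log(pk$p_male), log(1 - pk$p_male))
  }
  for (j in seq_along(hab)) {
    Lam <- 0
    for (i in 1:M) if (lk$z[i] == 1) Lam <- Lam + lam_ij(i, j)
    for (k in 1:K)
      ll <- ll + lpois(dataset$c[hab[j], k], Lam * (1 - pk$theta))
  }
  intens <- numeric(length(hab))
  for (j in seq_along(hab)) {
    a <- grid$altitude_std[hab[j]]
    intens[j] <- exp(pk$beta[1] * a + pk$beta[2] * a^2)
  }
  for (i in 1:M) ll <- ll + log(intens[lk$s[i]] / sum(intens))
  ll
}

# Random tiny SCR instance for oracle sweeps: a grid of <= max_cells
# habitat cells, random detections, random latents and parameters.
random_tiny_instance <- function(seed, max_M = 3, max_cells = 4, max_K = 2) {
  set.seed(seed)
  # rectangle sized to yield few cells
  g <- build_hex_grid(rect_boundary(runif(1, 3, 8), runif(1, 3, 7)), 10)
  while (length(g$x) > max_cells)
    g <- build_hex_grid(rect_boundary(runif(1, 3, 8), runif(1, 3, 7)), 10)
  J <- length(g$x)
  g$effort <- ifelse(runif(J) < 0.8, runif(J, 0.5, 2), 0)
  if (all(g$effort == 0)) g$effort[1] <- 1
  g$effort_std[g$effort > 0] <- gnisscr:::zscore(g$effort[g$effort > 0])
  g$altitude <- runif(J, -1, 1)
  g$altitude_std <- g$altitude
  K <- sample(max_K, 1)
  M <- sample(2:max_M, 1)
  n_obs <- sample(0:(M - 1), 1)
  y <- array(0L, dim = c(n_obs, J, K))
  if (n_obs > 0) {
    y[] <- rpois(length(y), 0.4)
    y[, g$effort == 0, ] <- 0L   # zero-effort detectors cannot detect
  }
  cmat <- matrix(0L, J, K)
  cmat[g$effort > 0, ] <- rpois(sum(g$effort > 0) * K, 0.5)
  ds <- structure(list(strata_id = "t", y = y, c = cmat,
                       sexes = sample(c("F", "M"), n_obs, replace = TRUE),
                       individual_ids = seq_len(n_obs),
                       n_occasions = K, grid = g), class = "scr_dataset")
  params <- list(strata = list(list(
    beta = rnorm(2, 0, 0.5),
    lambda0_coefs = rnorm(3, 0, 0.4),
    psi = runif(1, 0.2, 0.8), theta = runif(1, 0.2, 0.8),
    p_male = runif(1, 0.2, 0.8))),
    sigma = c(F = runif(1, 1, 4), M = runif(1, 1, 4)))
  z <- c(rep(1L, n_obs), rbinom(M - n_obs, 1, 0.6))
  if (sum(cmat) > 0 && sum(z) == 0) z[1] <- 1L  # c > 0 needs an active source
  latents <- list(strata = list(list(
    z = z,
    s = sample(J, M, replace = TRUE),
    sex = sample(c("F", "M"), M, replace = TRUE))))
  if (n_obs > 0) latents$strata[[1]]$sex[seq_len(n_obs)] <- ds$sexes
  list(dataset = ds, params = params, latents = latents)
}
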