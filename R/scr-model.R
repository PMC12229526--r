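# Random-thinning SCR model: likelihood reference implementation,
# MCMC driver (compiled sampler), convergence diagnostics and posterior
# summaries.

#' Half-normal encounter rate
#'
#' `lambda = exp(log_lambda0) * exp(-d^2 / (2 sigma^2))`, defined as
#' exactly zero for detectors with zero sampling effort (the baseline-rate
#' linear predictor has no intercept; unsurveyed polygons cannot detect).
#'
#' @param distance Euclidean distance(s) in metres, >= 0.
#' @param sigma half-normal scale in metres, > 0.
#' @param log_lambda0 log baseline encounter rate (linear predictor value).
#' @param effort optional effort value(s); where `effort == 0` the rate is 0.
#' @export
encounter_rate <- function(distance, sigma, log_lambda0, effort = NULL) {
  if (any(sigma <= 0)) stop("invalid-argument: sigma must be positive")
  if (any(distance < 0)) stop("invalid-argument: negative distance")
  rate <- exp(log_lambda0) * exp(-distance^2 / (2 * sigma^2))
  if (!is.null(effort)) rate[effort == 0] <- 0
  rate
}

#' MCMC configuration presets
#'
#' `"paper"` is the full-scale setting (M = 300, 3 chains of 50,000
#' iterations with 1,000 burn-in); `"desk"` is the scaled-down default for
#' testing and desk work (M = 150, 3 chains of 5,000 with 500 burn-in).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ... overrides for `n_chains`, `n_iter`, `burnin`, `M`, `seed`.
#' @export
scr_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper")
    list(n_chains = 3L, n_iter = 50000L, burnin = 1000L, M = 300L, seed = 1L)
  else
    list(n_chains = 3L, n_iter = 5000L, burnin = 500L, M = 150L, seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg$preset <- preset
  cfg
}

# Internal: per-stratum quantities shared by the likelihood reference and
# the sampler prep. State space = habitat cells of the grid.
scr_geometry <- function(dataset) {
  grid <- dataset$grid
  hab <- which(grid$habitat)
  x <- grid$x[hab]; y <- grid$y[hab]
  D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  # map full-grid cell indices to habitat-cell indices
  full2hab <- rep(NA_integer_, length(grid$x))
  full2hab[hab] <- seq_along(hab)
  list(hab = hab, D2 = D2, full2hab = full2hab,
       alt = grid$altitude_std[hab], eff = grid$effort_std[hab],
       eff_pos = as.integer(grid$effort[hab] > 0),
       spacing = grid$spacing)
}

# lam0 per habitat cell and sex from a coefficient triple.
lam0_vectors <- function(geom, coefs) {
  lp <- coefs[2] * geom$eff + coefs[3] * geom$eff^2
  lam0M <- exp(lp); lam0F <- exp(lp + coefs[1])
  lam0M[geom$eff_pos == 0] <- 0
  lam0F[geom$eff_pos == 0] <- 0
  list(F = lam0F, M = lam0M)
}

#' Joint log-density of the random-thinning SCR model
#'
#' Reference implementation of the full joint density: Poisson terms for
#' the identified detection histories `y[i, j, k]` (thinned rate
#' `lambda_ij * theta`, all-zero histories for augmented individuals),
#' Poisson terms for the unidentified counts `c[j, k]` with rate
#' `(1 - theta) * sum_i z_i lambda_ij`, Bernoulli inclusion and sex terms,
#' the discretized activity-centre point process
#' `sum_i [log lambda(s_i) - log sum_cells lambda]`, and the priors
#' (Normal(0, 3) coefficients; sigma ~ Uniform(0.1, 20); psi, theta,
#' p_male ~ Uniform(0, 1)).
#'
#' @param datasets an `scr_dataset` or list of them (one per stratum).
#' @param params list with `strata` (per stratum: `beta` length-2,
#'   `lambda0_coefs` length-3, `psi`, `theta`, `p_male`) and shared
#'   `sigma` named `c(F=, M=)`.
#' @param latents list with `strata` (per stratum: `z` length M, `s`
#'   habitat-cell indices length M, `sex` "F"/"M" length M).
#' @param include_priors add the log-prior terms (default TRUE).
#' @return scalar log-density.
#' @export
joint_log_density <- function(datasets, params, latents,
                              include_priors = TRUE) {
  if (inherits(datasets, "scr_dataset")) datasets <- list(datasets)
  ll <- 0
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    pk <- params$strata[[k]]
    lk <- latents$strata[[k]]
    geom <- scr_geometry(ds)
    J <- length(geom$hab); K <- ds$n_occasions
    M <- length(lk$z)
    n_obs <- dim(ds$y)[1]
    if (M < n_obs) stop("invalid-argument: latents shorter than observed set")
    if (any(lk$s < 1 | lk$s > J)) stop("invalid-state: s outside habitat")
    lp_check <- pk$beta[1] * geom$alt + pk$beta[2] * geom$alt^2
    if (any(!is.finite(lp_check)))
      stop(paste0("invalid-state: non-finite intensity linear predictor; params: ",
                  paste(deparse(pk), collapse = "")))
    lam0 <- lam0_vectors(geom, pk$lambda0_coefs)
    sig <- params$sigma
    # per-individual encounter rate rows at habitat-cell detectors
    lam <- matrix(0, M, J)
    for (i in seq_len(M)) {
      sg <- sig[[lk$sex[i]]]
      lam[i, ] <- lam0[[lk$sex[i]]] * exp(-geom$D2[lk$s[i], ] / (2 * sg^2))
    }
    theta <- pk$theta
    ysum <- apply(ds$y, c(1, 2), sum)
    if (any(ysum[, is.na(geom$full2hab), drop = FALSE] > 0))
      stop("invalid-state: detections in non-habitat cell")
    # y-term computed occasion-explicitly to mirror the model statement;
    # augmented individuals carry all-zero histories
    for (i in seq_len(M)) {
      if (lk$z[i] == 0) next
      rate <- lam[i, ] * theta
      for (j in seq_len(J)) {
        fullj <- geom$hab[j]
        for (kk in seq_len(K)) {
          yv <- if (i <= n_obs) ds$y[i, fullj, kk] else 0
          ll <- ll + dpois(yv, rate[j], log = TRUE)
        }
      }
    }
    Lam <- colSums(lam * lk$z)
    for (j in seq_len(J)) {
      fullj <- geom$hab[j]
      for (kk in seq_len(K))
        ll <- ll + dpois(ds$c[fullj, kk], Lam[j] * (1 - theta), log = TRUE)
    }
    ll <- ll + sum(dbinom(lk$z, 1, pk$psi, log = TRUE))
    ll <- ll + sum(dbinom(as.integer(lk$sex == "M"), 1, pk$p_male, log = TRUE))
    lam_cell <- exp(pk$beta[1] * geom$alt + pk$beta[2] * geom$alt^2)
    ll <- ll + sum(log(lam_cell[lk$s])) - M * log(sum(lam_cell))
    if (include_priors) {
      ll <- ll + sum(dnorm(c(pk$beta, pk$lambda0_coefs), 0, 3, log = TRUE))
      ll <- ll + sum(dunif(c(pk$psi, pk$theta, pk$p_male), 0, 1, log = TRUE))
    }
  }
  if (include_priors)
    ll <- ll + sum(dunif(params$sigma, 0.1, 20, log = TRUE))
  if (is.nan(ll)) stop("invalid-state: NaN joint log-density")
  ll
}

# Collapsed-occasion log kernel matching the compiled sampler term for
# term (differs from joint_log_density only by data-dependent constants:
# factorials and the K factors inside the Poisson logs).
scr_log_kernel <- function(datasets, params, latents) {
  if (inherits(datasets, "scr_dataset")) datasets <- list(datasets)
  ll <- 0
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    pk <- params$strata[[k]]
    lk <- latents$strata[[k]]
    geom <- scr_geometry(ds)
    J <- length(geom$hab); K <- ds$n_occasions
    M <- length(lk$z)
    n_obs <- dim(ds$y)[1]
    lam0 <- lam0_vectors(geom, pk$lambda0_coefs)
    sig <- params$sigma
    lam <- matrix(0, M, J)
    for (i in seq_len(M)) {
      sg <- sig[[lk$sex[i]]]
      lam[i, ] <- lam0[[lk$sex[i]]] * exp(-geom$D2[lk$s[i], ] / (2 * sg^2))
    }
    Y <- apply(ds$y, c(1, 2), sum)
    Yhab <- matrix(0, n_obs, J)
    for (j in seq_len(ncol(Y))) {
      hj <- geom$full2hab[j]
      if (!is.na(hj)) Yhab[, hj] <- Yhab[, hj] + Y[, j]
    }
    Chab <- rep(0, J)
    csum <- rowSums(ds$c)
    for (j in seq_along(csum)) {
      hj <- geom$full2hab[j]
      if (!is.na(hj)) Chab[hj] <- Chab[hj] + csum[j]
    }
    theta <- pk$theta
    for (i in seq_len(n_obs)) {
      hit <- which(Yhab[i, ] > 0)
      ll <- ll + sum(Yhab[i, hit] * (log(K * theta) + log(lam[i, hit])))
    }
    Lam <- colSums(lam * lk$z)
    hit <- which(Chab > 0)
    ll <- ll + sum(Chab[hit] * (log(K * (1 - theta)) + log(Lam[hit])))
    ll <- ll - K * sum(Lam)
    n1 <- sum(lk$z); nm <- sum(lk$sex == "M")
    ll <- ll + n1 * log(pk$psi) + (M - n1) * log(1 - pk$psi)
    ll <- ll + nm * log(pk$p_male) + (M - nm) * log(1 - pk$p_male)
    lam_cell_log <- pk$beta[1] * geom$alt + pk$beta[2] * geom$alt^2
    lse <- max(lam_cell_log) + log(sum(exp(lam_cell_log - max(lam_cell_log))))
    ll <- ll + sum(lam_cell_log[lk$s] - lse)
    ll <- ll + sum(dnorm(c(pk$beta, pk$lambda0_coefs), 0, 3, log = TRUE))
  }
  ll + sum(dunif(params$sigma, 0.1, 20, log = TRUE))
}

# Neighbourhood lists for the discrete activity-centre proposal: habitat
# cells within `radius_mult` lattice spacings, excluding the cell itself.
# 0-based for the compiled sampler.
neighbour_lists <- function(D2, spacing, radius_mult = 2.2) {
  r2 <- (radius_mult * spacing)^2
  lapply(seq_len(nrow(D2)), function(j) {
    nb <- which(D2[j, ] <= r2 & seq_len(ncol(D2)) != j)
    as.integer(nb - 1L)
  })
}

# Crude movement-scale estimate from within-individual detection spread,
# used only to centre overdispersed chain initializations.
crude_sigma <- function(datasets) {
  d2s <- c()
  for (ds in datasets) {
    Y <- apply(ds$y, c(1, 2), sum)
    for (i in seq_len(nrow(Y))) {
      cells <- which(Y[i, ] > 0)
      if (length(cells) < 2) next
      xs <- rep(ds$grid$x[cells], Y[i, cells])
      ys <- rep(ds$grid$y[cells], Y[i, cells])
      d2s <- c(d2s, (xs - mean(xs))^2 + (ys - mean(ys))^2)
    }
  }
  if (length(d2s) && mean(d2s) > 0) sqrt(mean(d2s)) else
    datasets[[1]]$grid$spacing
}

#' Fit the multi-strata random-thinning SCR model by MCMC
#'
#' Metropolis-within-Gibbs with data augmentation: inclusion indicators
#' and latent sexes by Gibbs, activity centres by Hastings-corrected
#' neighbourhood proposals on the habitat lattice (prior Gibbs draws for
#' excluded individuals), continuous parameters by adaptive Gaussian
#' random walks on transformed scales (log sigma, logit probabilities),
#' adapted during burn-in only. The movement scales `sigma_F`, `sigma_M`
#' are shared across strata; every other parameter is stratum-specific.
#' Chains start from data-informed values jittered per chain (crude sigma
#' from within-individual detection spread, inclusion probability from the
#' observed count) so that starts are overdispersed but inside the zone
#' the desk-scale burn-in can absorb.
#'
#' @param datasets an `scr_dataset` or list of them (one per stratum).
#' @param config a list from [scr_config()].
#' @return object of class `scr_chains`: per-chain draw matrices (named
#'   columns: per stratum `beta1`, `beta2`, `lam0_sexF`, `lam0_eff`,
#'   `lam0_eff2`, `psi`, `theta`, `p_male`, `N`, `N_male`, `N_female`,
#'   plus shared `sigma_F`, `sigma_M`), activity-centre surface
#'   accumulators, areas, and the fit configuration.
#' @export
fit_scr <- function(datasets, config = scr_config()) {
  if (inherits(datasets, "scr_dataset")) datasets <- list(datasets)
  M <- as.integer(config$M)
  strata_data <- list()
  geoms <- list()
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    n_obs <- dim(ds$y)[1]
    if (M <= n_obs)
      stop(sprintf("invalid-argument: M = %d must exceed the %d observed individuals",
                   M, n_obs))
    geom <- scr_geometry(ds)
    geoms[[k]] <- geom
    Y <- apply(ds$y, c(1, 2), sum)
    spatial_recaps <- sum(vapply(seq_len(nrow(Y)), function(i)
      sum(Y[i, ] > 0) > 1, logical(1)))
    if (n_obs == 0 || spatial_recaps == 0)
      warning(sprintf("stratum %s has no spatial recaptures; sigma is weakly identified",
                      ds$strata_id))
    ycells <- lapply(seq_len(n_obs), function(i) {
      cells <- which(Y[i, ] > 0)
      as.integer(geom$full2hab[cells] - 1L)
    })
    ycounts <- lapply(seq_len(n_obs), function(i) {
      cells <- which(Y[i, ] > 0)
      as.numeric(Y[i, cells])
    })
    csum <- rowSums(ds$c)
    Chab <- rep(0, length(geom$hab))
    Chab[geom$full2hab[which(csum > 0)]] <- csum[csum > 0]
    if (any(Chab > 0 & geom$eff_pos == 0))
      stop("invalid-data: unidentified counts in zero-effort cells")
    strata_data[[k]] <- list(
      D2 = geom$D2, K = as.integer(ds$n_occasions), M = M,
      alt = geom$alt, eff = geom$eff, eff_pos = geom$eff_pos,
      ycells = ycells, ycounts = ycounts, C = Chab,
      nbr = neighbour_lists(geom$D2, geom$spacing))
  }

  sig0 <- crude_sigma(datasets)
  set.seed(as.integer(config$seed))
  chain_seeds <- sample.int(.Machine$integer.max %/% 2, config$n_chains)

  chains <- list(); surfaces <- list(); finals <- list()
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    init_strata <- list()
    for (k in seq_along(datasets)) {
      ds <- datasets[[k]]
      geom <- geoms[[k]]
      J <- length(geom$hab)
      n_obs <- dim(ds$y)[1]
      Y <- apply(ds$y, c(1, 2), sum)
      s_obs <- vapply(seq_len(n_obs), function(i) {
        cells <- which(Y[i, ] > 0)
        as.integer(geom$full2hab[cells[which.max(Y[i, cells])]] - 1L)
      }, integer(1))
      psi0 <- min(0.9, max(0.1, 1.6 * n_obs / M)) * exp(runif(1, -0.4, 0.4))
      psi0 <- min(0.95, max(0.05, psi0))
      ytot <- sum(ds$y); ctot <- sum(ds$c)
      th0 <- if (ytot + ctot > 0) (ytot + 0.5) / (ytot + ctot + 1) else 0.5
      th0 <- min(0.95, max(0.05, th0 * exp(runif(1, -0.3, 0.3))))
      sex_obs <- ds$sexes
      pm_obs <- if (n_obs) max(0.1, min(0.9, mean(sex_obs == "M"))) else 0.5
      pm0 <- min(0.9, max(0.1, pm_obs * exp(runif(1, -0.3, 0.3))))
      z0 <- c(rep(1L, n_obs), rbinom(M - n_obs, 1, psi0))
      s0 <- c(s_obs, sample.int(J, M - n_obs, replace = TRUE) - 1L)
      sex_known <- c(as.integer(sex_obs %in% c("F", "M")), rep(0L, M - n_obs))
      sex_obs_init <- integer(n_obs)
      sex_obs_init[sex_obs == "M"] <- 1L
      unk <- which(!sex_obs %in% c("F", "M"))
      if (length(unk)) sex_obs_init[unk] <- rbinom(length(unk), 1, pm0)
      sex0 <- c(sex_obs_init, rbinom(M - n_obs, 1, pm0))
      init_strata[[k]] <- list(
        z = z0, s = s0, sex = as.integer(sex0), sex_known = sex_known,
        beta1 = rnorm(1, 0, 0.5), beta2 = rnorm(1, 0, 0.5),
        aF = rnorm(1, 0, 0.3), bEff = rnorm(1, 0, 0.3),
        cEff = rnorm(1, 0, 0.3),
        psi = psi0, theta = th0, pmale = pm0)
    }
    init <- list(strata = init_strata,
                 sigmaF = min(15, max(0.15, sig0 * exp(runif(1, -0.7, 0.7)))),
                 sigmaM = min(15, max(0.15, sig0 * exp(runif(1, -0.7, 0.7)))))
    res <- scr_mcmc_chain(strata_data, init, as.integer(config$n_iter),
                          as.integer(config$burnin))
    cn <- c()
    for (k in seq_along(datasets))
      cn <- c(cn, paste0(datasets[[k]]$strata_id, ".",
                         c("beta1", "beta2", "lam0_sexF", "lam0_eff",
                           "lam0_eff2", "psi", "theta", "p_male",
                           "N", "N_male", "N_female")))
    cn <- c(cn, "sigma_F", "sigma_M")
    colnames(res$draws) <- cn
    chains[[ch]] <- res$draws
    surfaces[[ch]] <- res$surface
    finals[[ch]] <- list(strata = res$final_state, sigma = res$final_sigma,
                         log_kernel = res$final_log_kernel)
  }
  structure(list(
    draws = chains,
    surfaces = surfaces,
    finals = finals,
    strata_ids = vapply(datasets, function(d) d$strata_id, character(1)),
    areas_ha = vapply(datasets, function(d) grid_area_ha(d$grid), numeric(1)),
    grids = lapply(datasets, function(d) d$grid),
    geoms = geoms,
    M = M, config = config, chain_seeds = chain_seeds
  ), class = "scr_chains")
}

#' @export
print.scr_chains <- function(x, ...) {
  cat(sprintf("<scr_chains: %d chain(s) x %d stored draws, %d strata, M = %d>\n",
              length(x$draws), nrow(x$draws[[1]]), length(x$strata_ids), x$M))
  invisible(x)
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Split-R-hat: each chain is halved, and the ratio of pooled-to-within
#' variance is computed over the resulting 2C sequences. Values near 1
#' indicate the chains sample the same distribution.
#'
#' @param chains an `scr_chains` object or a list of draw matrices with
#'   identical named columns.
#' @return named vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  mats <- if (inherits(chains, "scr_chains")) chains$draws else chains
  if (length(mats) < 2) stop("invalid-argument: need at least 2 chains")
  n <- nrow(mats[[1]])
  if (n < 10) stop("invalid-argument: need at least 10 draws per chain")
  half <- n %/% 2
  seqs <- list()
  for (m in mats) {
    seqs[[length(seqs) + 1]] <- m[seq_len(half), , drop = FALSE]
    seqs[[length(seqs) + 1]] <- m[(n - half + 1):n, , drop = FALSE]
  }
  nn <- half
  means <- sapply(seqs, colMeans)
  vars <- sapply(seqs, function(s) apply(s, 2, var))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- nn * apply(means, 1, var)
  varplus <- (nn - 1) / nn * W + B / nn
  rhat <- sqrt(varplus / W)
  rhat[W == 0 & B == 0] <- 1
  names(rhat) <- colnames(mats[[1]])
  rhat
}

#' Summarize SCR posterior draws
#'
#' Pools post-burn-in draws across chains and reports posterior means and
#' equal-tailed 95% credible intervals for abundance N, realized males and
#' females, density D = N / habitat-mask area (individuals per hectare,
#' computed per draw), sex ratio, the shared movement scales and all
#' covariate coefficients, together with split-R-hat per parameter.
#'
#' @param chains an `scr_chains` object.
#' @param grids optional list of `detector_grid`s supplying mask areas
#'   (defaults to the grids stored at fit time).
#' @param force proceed even if some R-hat exceeds 1.1.
#' @return data frame with columns `parameter`, `stratum`, `mean`,
#'   `lower`, `upper`, `rhat`; class `scr_summary`.
#' @export
summarize_posterior <- function(chains, grids = NULL, force = FALSE) {
  stopifnot(inherits(chains, "scr_chains"))
  if (!length(chains$draws) || !nrow(chains$draws[[1]]))
    stop("invalid-argument: empty chains")
  rhat <- if (length(chains$draws) >= 2) gelman_rubin(chains) else
    setNames(rep(NA_real_, ncol(chains$draws[[1]])),
             colnames(chains$draws[[1]]))
  if (!force && any(rhat > 1.1, na.rm = TRUE))
    stop(sprintf("chains not converged (max R-hat %.3f); rerun longer or use force = TRUE",
                 max(rhat, na.rm = TRUE)))
  pooled <- do.call(rbind, chains$draws)
  areas <- if (is.null(grids)) chains$areas_ha else
    vapply(grids, grid_area_ha, numeric(1))
  rows <- list()
  addrow <- function(parameter, stratum, x, rh = NA_real_) {
    q <- quantile(x, c(0.025, 0.975), names = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = parameter, stratum = stratum, mean = mean(x),
      lower = q[1], upper = q[2], rhat = rh)
  }
  for (k in seq_along(chains$strata_ids)) {
    id <- chains$strata_ids[k]
    col <- function(p) pooled[, paste0(id, ".", p)]
    rh <- function(p) unname(rhat[paste0(id, ".", p)])
    addrow("N", id, col("N"), rh("N"))
    addrow("N_male", id, col("N_male"), rh("N_male"))
    addrow("N_female", id, col("N_female"), rh("N_female"))
    addrow("D_per_ha", id, col("N") / areas[k], rh("N"))
    addrow("sex_ratio", id, col("p_male"), rh("p_male"))
    addrow("psi", id, col("psi"), rh("psi"))
    addrow("theta", id, col("theta"), rh("theta"))
    addrow("lam0_sexF", id, col("lam0_sexF"), rh("lam0_sexF"))
    addrow("lam0_eff", id, col("lam0_eff"), rh("lam0_eff"))
    addrow("lam0_eff2", id, col("lam0_eff2"), rh("lam0_eff2"))
    addrow("beta_alt1", id, col("beta1"), rh("beta1"))
    addrow("beta_alt2", id, col("beta2"), rh("beta2"))
  }
  addrow("sigma_F", "shared", pooled[, "sigma_F"], unname(rhat["sigma_F"]))
  addrow("sigma_M", "shared", pooled[, "sigma_M"], unname(rhat["sigma_M"]))
  out <- do.call(rbind, rows)
  class(out) <- c("scr_summary", "data.frame")
  out
}

#' Posterior mean activity-centre density surface
#'
#' Per-cell posterior mean count of included activity centres (`z = 1`),
#' accumulated over all stored draws of all chains. Cell values sum to the
#' posterior mean of N; sex-stratified surfaces partition the total.
#'
#' @param chains an `scr_chains` object.
#' @param stratum stratum index or id.
#' @param sex `NULL` for all individuals, or `"F"`/`"M"`.
#' @return numeric vector over the stratum's habitat cells, with
#'   attributes `x`, `y` (centroids) and `cell_area`.
#' @export
density_surface <- function(chains, stratum = 1, sex = NULL) {
  stopifnot(inherits(chains, "scr_chains"))
  if (is.character(stratum)) stratum <- match(stratum, chains$strata_ids)
  tot <- 0; male <- 0; ndraws <- 0
  for (ch in seq_along(chains$surfaces)) {
    s <- chains$surfaces[[ch]][[stratum]]
    tot <- tot + s$total[, 1]
    male <- male + s$male[, 1]
    ndraws <- ndraws + s$n_draws
  }
  counts <- if (is.null(sex)) tot else if (sex == "M") male else tot - male
  out <- counts / ndraws
  geom <- chains$geoms[[stratum]]
  grid <- chains$grids[[stratum]]
  attr(out, "x") <- grid$x[geom$hab]
  attr(out, "y") <- grid$y[geom$hab]
  attr(out, "cell_area") <- grid$cell_area
  out
}
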