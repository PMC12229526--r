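test_that("encounter rate follows the half-normal closed forms", {
  expect_equal(encounter_rate(0, 2, log(0.7)), 0.7)
  expect_equal(encounter_rate(2, 2, log(1)), exp(-0.5))
  expect_equal(encounter_rate(3, 2, log(0.5)), 0.5 * exp(-9 / 8))
  expect_equal(round(encounter_rate(3, 2, log(0.5)), 5), 0.16233)
  expect_equal(encounter_rate(3, 2, log(0.5), effort = 0), 0)
  expect_error(encounter_rate(1, -1, 0), "sigma")
})

test_that("joint log density reduces to the Poisson pmf on one cell", {
  g <- build_hex_grid(rect_boundary(2, 2), 10)   # single cell
  g$effort <- 1; g$effort_std <- 0; g$altitude_std <- 0
  mk <- function(y0) {
    y <- array(0L, dim = c(1, 1, 1)); y[1, 1, 1] <- y0
    structure(list(strata_id = "t", y = y,
                   c = matrix(0L, 1, 1), sexes = "M",
                   individual_ids = 1L, n_occasions = 1L, grid = g),
              class = "scr_dataset")
  }
  # lambda * theta = 1 via lam0 = 1 (zero coefficients at std effort 0),
  # d = 0 and theta = 1; the c-term is then dpois(0, 0) = 0
  params <- list(strata = list(list(beta = c(0, 0),
                                    lambda0_coefs = c(0, 0, 0),
                                    psi = 1, theta = 1, p_male = 1)),
                 sigma = c(F = 2, M = 2))
  latents <- list(strata = list(list(z = 1L, s = 1L, sex = "M")))
  expect_equal(joint_log_density(mk(0L), params, latents,
                                 include_priors = FALSE), -1)
  expect_equal(joint_log_density(mk(2L), params, latents,
                                 include_priors = FALSE), -1 - log(2))
})

test_that("joint log density matches the naive term-by-term oracle", {
  for (seed in 1:40) {
    inst <- random_tiny_instance(seed)
    got <- joint_log_density(inst$dataset, inst$params, inst$latents,
                             include_priors = FALSE)
    want <- naive_joint_log_density(inst$dataset, inst$params, inst$latents)
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("with theta = 0 the c-likelihood is an unmarked point-count likelihood", {
  g <- build_hex_grid(rect_boundary(2, 2), 10)   # single cell
  g$effort <- 1; g$effort_std <- 0; g$altitude_std <- 0
  cvec <- matrix(c(3L, 1L), 1, 2)
  ds <- structure(list(strata_id = "t",
                       y = array(0L, dim = c(0, 1, 2)), c = cvec,
                       sexes = character(0), individual_ids = integer(0),
                       n_occasions = 2L, grid = g), class = "scr_dataset")
  params <- list(strata = list(list(beta = c(0, 0),
                                    lambda0_coefs = c(0, 0.3, 0),
                                    psi = 0.7, theta = 0, p_male = 0.4)),
                 sigma = c(F = 2, M = 3))
  latents <- list(strata = list(list(z = c(1L, 1L), s = c(1L, 1L),
                                     sex = c("F", "M"))))
  ll <- joint_log_density(ds, params, latents, include_priors = FALSE)
  # analytic: both individuals sit on the detector, so
  # Lambda = lam0_F + lam0_M, and the detection part is the unmarked
  # Poisson count likelihood; remaining terms are the z/sex Bernoullis
  lam <- exp(0.3 * 0) * (exp(0) + exp(0))
  manual <- dpois(3, lam, log = TRUE) + dpois(1, lam, log = TRUE) +
    2 * log(0.7) + log(1 - 0.4) + log(0.4)
  expect_equal(ll, manual, tolerance = 1e-12)
})

test_that("the compiled sampler computes the same posterior kernel as R", {
  cfg <- sim_config(seed = 14, M = 25, psi = 0.8,
                    sigma = c(F = 2.2, M = 2.8), theta_id = 0.5,
                    n_occasions = 2)
  land <- simulate_landscape(cfg, list(width = 25, height = 20,
                                       altitude = "smooth"))
  land <- rasterize_effort(serpentine_transects(25, 20, 6), land)
  pop <- simulate_population(land, cfg)
  sim <- simulate_detections(pop, land, cfg)
  fit <- fit_scr(sim$dataset, scr_config("desk", n_iter = 60, burnin = 20,
                                         M = 40, n_chains = 2, seed = 5))
  offset <- NULL
  for (ch in 1:2) {
    fs <- fit$finals[[ch]]
    lat <- list(strata = lapply(fs$strata, function(st)
      list(z = st$z, s = st$s + 1L, sex = ifelse(st$sex == 1, "M", "F"))))
    par <- list(strata = lapply(fs$strata, function(st)
      list(beta = c(st$beta1, st$beta2),
           lambda0_coefs = c(st$aF, st$bEff, st$cEff),
           psi = st$psi, theta = st$theta, p_male = st$pmale)),
      sigma = c(F = fs$sigma[1], M = fs$sigma[2]))
    expect_equal(fs$log_kernel,
                 gnisscr:::scr_log_kernel(sim$dataset, par, lat),
                 tolerance = 1e-8)
    # the collapsed kernel and the occasion-explicit joint density differ
    # only by data constants: their difference is state-independent
    jd <- joint_log_density(sim$dataset, par, lat)
    kd <- gnisscr:::scr_log_kernel(sim$dataset, par, lat)
    if (is.null(offset)) offset <- jd - kd else
      expect_equal(jd - kd, offset, tolerance = 1e-8)
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 3, M = 20, psi = 0.9, theta_id = 0.6,
                    sigma = c(F = 2.5, M = 2.5), n_occasions = 2)
  land <- simulate_landscape(cfg, list(width = 20, height = 18,
                                       altitude = "flat"))
  land$effort <- rep(1, length(land$x)); land$effort_std <- rep(0, length(land$x))
  pop <- simulate_population(land, cfg)
  sim <- simulate_detections(pop, land, cfg)
  cfgf <- scr_config("desk", n_iter = 150, burnin = 50, M = 30,
                     n_chains = 2, seed = 11)
  f1 <- fit_scr(sim$dataset, cfgf)
  f2 <- fit_scr(sim$dataset, cfgf)
  expect_identical(f1$draws, f2$draws)
})

test_that("theta is recovered when every detection is identified", {
  cfg <- sim_config(seed = 8, M = 40, psi = 1, theta_id = 1,
                    sigma = c(F = 2.5, M = 2.5), n_occasions = 3)
  land <- simulate_landscape(cfg, list(width = 40, height = 30,
                                       altitude = "flat"))
  land$effort <- rep(1, length(land$x)); land$effort_std <- rep(0, length(land$x))
  pop <- simulate_population(land, cfg)
  sim <- simulate_detections(pop, land, cfg)
  expect_equal(sum(sim$dataset$c), 0)
  fit <- fit_scr(sim$dataset, scr_config("desk", n_iter = 1500, burnin = 400,
                                         M = 80, seed = 2))
  pooled <- do.call(rbind, fit$draws)
  expect_gt(mean(pooled[, "patch.theta"]), 0.9)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(5)
  # halves agree exactly: between-sequence variance 0, R-hat <= 1
  half <- matrix(rnorm(500), ncol = 1)
  chain <- rbind(half, half)
  colnames(chain) <- "p"
  rh <- gelman_rubin(list(chain, chain, chain))
  expect_lte(rh[["p"]], 1 + 1e-6)

  shifted <- list(matrix(rnorm(1000, 0), ncol = 1, dimnames = list(NULL, "p")),
                  matrix(rnorm(1000, 10), ncol = 1, dimnames = list(NULL, "p")))
  expect_gt(gelman_rubin(shifted)[["p"]], 1.5)

  iid <- lapply(1:3, function(i)
    matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "p")))
  r <- gelman_rubin(iid)[["p"]]
  expect_gt(r, 0.99); expect_lt(r, 1.01)

  # agrees with the reference implementation in coda
  skip_if_not_installed("coda")
  chains2 <- lapply(1:3, function(i)
    matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "p")))
  split_mats <- unlist(lapply(chains2, function(m)
    list(m[1:1000, , drop = FALSE], m[1001:2000, , drop = FALSE])),
    recursive = FALSE)
  ml <- coda::mcmc.list(lapply(split_mats, coda::mcmc))
  ref <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1]
  expect_equal(gelman_rubin(chains2)[["p"]], ref, tolerance = 0.002)
  expect_error(gelman_rubin(list(iid[[1]])), "at least 2 chains")
})

test_that("posterior summaries follow quantile arithmetic", {
  mkchains <- function(Nvals) {
    m <- matrix(0, length(Nvals), 13)
    colnames(m) <- c(paste0("p1.", c("beta1", "beta2", "lam0_sexF",
                                     "lam0_eff", "lam0_eff2", "psi",
                                     "theta", "p_male", "N", "N_male",
                                     "N_female")),
                     "sigma_F", "sigma_M")
    m[, "p1.N"] <- Nvals
    m[, "p1.N_male"] <- 1; m[, "p1.N_female"] <- Nvals - 1
    m[, "p1.psi"] <- 0.5; m[, "p1.theta"] <- 0.5; m[, "p1.p_male"] <- 0.4
    m[, "sigma_F"] <- 2; m[, "sigma_M"] <- 2
    structure(list(draws = list(m), strata_ids = "p1", areas_ha = 1,
                   grids = NULL, geoms = NULL, M = 100,
                   config = list(), chain_seeds = 1),
              class = "scr_chains")
  }
  s <- summarize_posterior(mkchains(rep(100, 20)))
  n <- s[s$parameter == "D_per_ha", ]
  expect_equal(n$mean, 100); expect_equal(n$lower, 100)
  expect_equal(n$upper, 100)

  s3 <- summarize_posterior(mkchains(c(90, 100, 110)))
  n3 <- s3[s3$parameter == "N", ]
  expect_equal(n3$mean, 100)
  # type-7 empirical quantiles of {90, 100, 110}
  expect_equal(n3$lower, 90.5)
  expect_equal(n3$upper, 109.5)

  expect_error(summarize_posterior(
    structure(list(draws = list()), class = "scr_chains")), "empty")
})

test_that("density surfaces conserve N, partition by sex, and are flat without data", {
  g <- uniform_effort_grid(30, 28)
  ds <- structure(list(strata_id = "patch",
                       y = array(0L, dim = c(0, length(g$x), 2)),
                       c = matrix(0L, length(g$x), 2),
                       sexes = character(0), individual_ids = integer(0),
                       n_occasions = 2L, grid = g), class = "scr_dataset")
  expect_warning(
    fit <- fit_scr(ds, scr_config("desk", n_iter = 2500, burnin = 500,
                                  M = 50, seed = 4)),
    "recaptures")
  surf <- density_surface(fit)
  pooled <- do.call(rbind, fit$draws)
  expect_equal(sum(surf), mean(pooled[, "patch.N"]), tolerance = 1e-9)
  sm <- density_surface(fit, sex = "M")
  sf <- density_surface(fit, sex = "F")
  expect_equal(as.numeric(sm) + as.numeric(sf), as.numeric(surf),
               tolerance = 1e-12)
  # empty data: posterior activity centres keep the flat prior within
  # Monte-Carlo error
  expect_lt(sd(surf) / mean(surf), 0.2)
})

test_that("posterior N is insensitive to the augmentation bound", {
  cfg <- sim_config(seed = 19, M = 25, psi = 0.8, theta_id = 0.6,
                    sigma = c(F = 2.5, M = 2.5), n_occasions = 3)
  land <- simulate_landscape(cfg, list(width = 30, height = 25,
                                       altitude = "flat"))
  land$effort <- rep(1, length(land$x)); land$effort_std <- rep(0, length(land$x))
  pop <- simulate_population(land, cfg)
  sim <- simulate_detections(pop, land, cfg)
  fit_small <- fit_scr(sim$dataset, scr_config("desk", n_iter = 4000,
                                               burnin = 1000, M = 60, seed = 6))
  fit_big <- fit_scr(sim$dataset, scr_config("desk", n_iter = 4000,
                                             burnin = 1000, M = 100, seed = 7))
  thin <- seq(1, 3000, by = 15)
  n_small <- unlist(lapply(fit_small$draws, function(m) m[thin, "patch.N"]))
  n_big <- unlist(lapply(fit_big$draws, function(m) m[thin, "patch.N"]))
  expect_gt(suppressWarnings(ks.test(n_small, n_big)$p.value), 0.01)
})
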