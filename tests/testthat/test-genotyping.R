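test_that("consensus rule handles confirmation, false alleles and multi-allele loci", {
  # four identical heterozygous replicates -> that heterozygote
  reps <- data.frame(locus = "L1", replicate = 1:4,
                     allele1 = "100", allele2 = "104")
  cons <- build_consensus(reps)
  expect_equal(c(cons$allele1, cons$allele2), c("100", "104"))
  expect_equal(cons$flag, "ok")

  # A seen 4x, B once -> homozygote A, putative false allele flagged
  reps <- data.frame(locus = "L1", replicate = 1:4,
                     allele1 = c("100", "100", "100", "100"),
                     allele2 = c("100", "100", "100", "108"))
  cons <- build_consensus(reps)
  expect_equal(c(cons$allele1, cons$allele2), c("100", "100"))
  expect_equal(cons$flag, "putative_false_allele")

  # three alleles each confirmed twice -> locus voided, multi-allele flag
  reps <- data.frame(locus = "L1", replicate = 1:3,
                     allele1 = c("100", "100", "104"),
                     allele2 = c("104", "108", "108"))
  cons <- build_consensus(reps)
  expect_true(is.na(cons$allele1))
  expect_equal(cons$flag, "multi_allele")

  # homozygote seen twice only, with a discordant replicate: unconfirmed
  reps <- data.frame(locus = "L1", replicate = 1:3,
                     allele1 = c("100", "100", "104"),
                     allele2 = c("100", "100", "104"))
  cons <- build_consensus(reps)
  expect_true(is.na(cons$allele1))

  # unanimity rule: two concordant homozygote replicates are enough
  reps <- data.frame(locus = "L1", replicate = 1:2,
                     allele1 = "100", allele2 = "100")
  cons <- build_consensus(reps)
  expect_equal(c(cons$allele1, cons$allele2), c("100", "100"))

  expect_error(build_consensus(data.frame(locus = "Lx", replicate = 1,
                                          allele1 = "1", allele2 = "1"),
                               loci = "L1"),
               "unknown locus")
})

test_that("error rates are zero on concordant data and match hand counts", {
  reps <- data.frame(
    sample_id = "s1",
    locus = rep(c("L1", "L2"), each = 4),
    replicate = rep(1:4, 2),
    allele1 = c(rep("100", 4), rep("100", 4)),
    allele2 = c(rep("104", 4), rep("100", 4)))
  er <- estimate_error_rates(reps)
  expect_equal(er$dropout[er$locus == "L1"], 0)
  expect_equal(er$false_allele[er$locus == "L1"], 0)
  expect_true(is.na(er$dropout[er$locus == "L2"]))   # no het consensus

  # one novel-allele replicate among four at a consensus-het locus:
  # 1 false-allele event / 4 replicate opportunities
  reps2 <- data.frame(
    sample_id = "s1", locus = "L1", replicate = 1:4,
    allele1 = c("100", "100", "100", "100"),
    allele2 = c("104", "104", "104", "112"))
  er2 <- estimate_error_rates(reps2)
  expect_equal(er2$false_allele[1], 1 / 4)
  # that replicate also lacks consensus allele 104: 1 dropout event over
  # 2 * 4 allele opportunities
  expect_equal(er2$dropout[1], 1 / 8)
})

test_that("error-rate estimation recovers the simulated dropout rate", {
  cfg <- sim_config(seed = 404, n_replicates = 4,
                    error_rates = list(dropout = 0.10, false_allele = 0))
  pop <- structure(list(
    individuals = data.frame(id = sprintf("i%03d", 1:200),
                             sex = rep(c("F", "M"), 100)),
    pedigree = NULL, strata_id = "x", n_true = 200),
    class = "true_population")
  gt <- simulate_genotype_data(pop, cfg)
  er <- estimate_error_rates(gt$replicates)
  expect_lt(abs(attr(er, "dropout_mean") - 0.10), 0.03)
  expect_lt(attr(er, "fa_mean"), 0.01)
})

test_that("identical genotypes collapse and chains merge under single linkage", {
  g <- list(
    s1 = list(L1 = c("1", "2"), L2 = c("3", "3"), L3 = c("1", "1"),
              L4 = c("2", "2"), L5 = c("1", "2"), L6 = c("4", "5"),
              L7 = c("1", "1")),
    s2 = list(L1 = c("1", "2"), L2 = c("3", "3"), L3 = c("1", "1"),
              L4 = c("2", "2"), L5 = c("1", "2"), L6 = c("4", "5"),
              L7 = c("1", "1")))
  cat <- match_individuals(make_consensus(g), min_loci_compared = 7)
  expect_equal(nrow(cat$individuals), 1)

  # A~B mismatch 2, B~C mismatch 2, A~C mismatch 4: one individual
  base <- list(L1 = c("1", "1"), L2 = c("2", "2"), L3 = c("3", "3"),
               L4 = c("4", "4"), L5 = c("5", "5"), L6 = c("6", "6"),
               L7 = c("7", "7"), L8 = c("8", "8"))
  A <- base
  B <- base; B$L1 <- c("9", "9"); B$L2 <- c("9", "9")
  C <- base; C$L1 <- c("9", "9"); C$L2 <- c("9", "9")
  C$L3 <- c("9", "9"); C$L4 <- c("9", "9")
  # verify the fixture by brute-force pairwise mismatch counts
  mm <- function(a, b) sum(mapply(function(x, y) !all(sort(x) == sort(y)), a, b))
  expect_equal(mm(A, B), 2); expect_equal(mm(B, C), 2); expect_equal(mm(A, C), 4)
  cat3 <- match_individuals(make_consensus(list(sA = A, sB = B, sC = C)),
                            min_loci_compared = 7)
  expect_equal(nrow(cat3$individuals), 1)
  expect_equal(cat3$individuals$n_samples, 3)
  expect_equal(cat3$individuals$diameter, 4)   # chained merge is audited

  # a sample with too few loci is quarantined, not merged
  D <- list(L1 = c("1", "1"), L2 = c("2", "2"))
  cat4 <- match_individuals(make_consensus(list(sA = A, sD = D),
                                           loci = names(base)),
                            min_loci_compared = 7)
  expect_equal(cat4$unassignable, "sD")
  expect_equal(nrow(cat4$individuals), 1)
})

test_that("individual matching is permutation invariant", {
  set.seed(8)
  cfg <- sim_config(seed = 8, error_rates = list(dropout = 0.05,
                                                 false_allele = 0.001))
  pop <- structure(list(
    individuals = data.frame(id = sprintf("i%02d", 1:20),
                             sex = rep(c("F", "M"), 10)),
    pedigree = NULL, strata_id = "x", n_true = 20),
    class = "true_population")
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:50),
    individual = sprintf("i%02d", c(1:20, sample(1:20, 30, replace = TRUE))))
  gt <- simulate_genotype_data(pop, cfg, samples = samples)
  cons <- consensus_genotypes(gt$replicates)
  cat1 <- match_individuals(cons)
  perm <- sample(nrow(gt$replicates))
  cons2 <- consensus_genotypes(gt$replicates[perm, ])
  cat2 <- match_individuals(cons2)
  part1 <- split(cat1$membership$sample_id, cat1$membership$individual_id)
  part2 <- split(cat2$membership$sample_id, cat2$membership$individual_id)
  norm <- function(p) unname(lapply(p, sort)[order(vapply(p, min, ""))])
  expect_equal(norm(part1), norm(part2))
})

test_that("sex assignment follows the replicate thresholds", {
  m <- data.frame(dbx = c(TRUE, TRUE, TRUE), dby = c(TRUE, TRUE, TRUE))
  expect_equal(assign_sex(m), "M")
  f <- data.frame(dbx = c(TRUE, TRUE, TRUE), dby = c(FALSE, FALSE, FALSE))
  expect_equal(assign_sex(f), "F")
  u <- data.frame(dbx = c(TRUE, TRUE, TRUE), dby = c(TRUE, FALSE, FALSE))
  expect_equal(assign_sex(u), "U")   # single DBY amplification: ambiguous
  u2 <- data.frame(dbx = c(TRUE, FALSE, FALSE), dby = logical(3))
  expect_equal(assign_sex(u2), "U")
})

test_that("diversity statistics match hand-computed values and limits", {
  # fixture: 4 individuals at one locus: AB, AB, AA, BC
  # allele counts A=4, B=3, C=1 of 8; Ho = 3/4;
  # He = (8/7) * (1 - (0.5^2 + 0.375^2 + 0.125^2)) = 0.6785714
  gl <- data.frame(individual_id = 1:4, locus = "L1",
                   allele1 = c("A", "A", "A", "B"),
                   allele2 = c("B", "B", "A", "C"))
  cat <- make_catalog(gl, loci = "L1")
  st <- diversity_stats(cat, exclude_loci = character(0))
  expect_equal(st$Na, 3L)
  expect_equal(st$Ho, 0.75)
  expect_equal(st$He, (8 / 7) * (1 - (0.5^2 + 0.375^2 + 0.125^2)))
  expect_equal(st$Fis, 1 - 0.75 / st$He)

  # all-heterozygous biallelic locus, large n: Ho = 1, He -> 0.5, Fis -> -1
  n <- 400
  gl2 <- data.frame(individual_id = 1:n, locus = "L1",
                    allele1 = "A", allele2 = "B")
  st2 <- diversity_stats(make_catalog(gl2, "L1"), exclude_loci = character(0))
  expect_equal(st2$Ho, 1)
  expect_lt(abs(st2$He - 0.5), 0.001)
  expect_lt(abs(st2$Fis - (-1)), 0.01)

  # monomorphic locus: He = 0, Fis undefined
  gl3 <- data.frame(individual_id = 1:5, locus = "L1",
                    allele1 = "A", allele2 = "A")
  st3 <- diversity_stats(make_catalog(gl3, "L1"), exclude_loci = character(0))
  expect_equal(st3$He, 0)
  expect_true(is.na(st3$Fis))
})

test_that("catalog-level F_IS is near zero under Hardy-Weinberg", {
  freqs <- default_allele_freqs()
  loci <- setdiff(names(freqs), "Mc07")
  set.seed(606)
  fis <- numeric(100)
  for (r in 1:100) {
    rows <- list()
    for (l in loci) {
      p <- freqs[[l]]
      a1 <- sample(names(p), 60, TRUE, prob = p)
      a2 <- sample(names(p), 60, TRUE, prob = p)
      rows[[l]] <- data.frame(individual_id = 1:60, locus = l,
                              allele1 = pmin(a1, a2), allele2 = pmax(a1, a2))
    }
    cat <- make_catalog(do.call(rbind, rows), loci)
    fis[r] <- attr(diversity_stats(cat), "overall_Fis")
  }
  expect_lt(abs(mean(fis)), 0.02)
})

test_that("probability of identity matches its closed forms", {
  half <- list(L1 = c(a = 0.5, b = 0.5))
  pid <- probability_of_identity(half)
  expect_equal(pid$pid, 0.375)
  expect_equal(pid$pid_sib, 0.59375)

  mono <- probability_of_identity(list(L1 = c(a = 1)))
  expect_equal(mono$pid, 1)
  expect_equal(mono$pid_sib, 1)
  expect_equal(mono$exclusion_probability, 0)

  # biallelic p = q = 0.5 one-parent exclusion: only opposite-homozygote
  # configurations exclude: 2 * 0.25 * 0.25 = 0.125
  expect_equal(pid$exclusion_probability, 0.125)

  # PIDsib >= PID over random frequency vectors
  set.seed(12)
  for (r in 1:200) {
    k <- sample(2:10, 1)
    p <- runif(k); p <- p / sum(p)
    names(p) <- paste0("a", seq_len(k))
    res <- probability_of_identity(list(L = p))
    expect_gte(res$pid_sib, res$pid)
  }
  expect_error(probability_of_identity(list(L1 = numeric(0))),
               "invalid-argument")
})
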