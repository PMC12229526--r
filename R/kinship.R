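# Pairwise kinship screening: hard Mendelian / mtDNA / X-linked
# exclusions (the preprocessing a full pedigree-reconstruction run would
# consume) and pairwise relationship likelihood ratios over the four
# canonical relationship categories. This is a screen, not a joint
# pedigree reconstruction: likelihoods are computed per pair, so its
# full-sib counts are not expected to equal those of a full-pedigree
# analysis of the same data.

#' Canonical relationship models (Cotterman coefficients)
#'
#' IBD-sharing probabilities (k0, k1, k2) for unrelated (1,0,0), half-sib
#' (0.5,0.5,0), full-sib (0.25,0.5,0.25) and parent-offspring (0,1,0).
#' @return named list of length-3 numeric vectors.
#' @export
relationship_models <- function() {
  list(unrelated = c(k0 = 1, k1 = 0, k2 = 0),
       `half-sib` = c(k0 = 0.5, k1 = 0.5, k2 = 0),
       `full-sib` = c(k0 = 0.25, k1 = 0.5, k2 = 0.25),
       `parent-offspring` = c(k0 = 0, k1 = 1, k2 = 0))
}

# HWE genotype probability of an unordered pair (a, b).
hwe_prob <- function(a, b, p) {
  if (a == b) unname(p[a]^2) else unname(2 * p[a] * p[b])
}

# Transition probability T(G2 | G1) that genotype G2 arises when one of
# its alleles is IBD with a random allele of G1 and the other is drawn
# from the population.
ibd1_prob <- function(g1, g2, p) {
  share <- function(x) {           # P(G2 | IBD allele = x)
    if (g2[1] == g2[2]) {
      if (x == g2[1]) unname(p[g2[1]]) else 0
    } else {
      unname((x == g2[1]) * p[g2[2]] + (x == g2[2]) * p[g2[1]])
    }
  }
  0.5 * share(g1[1]) + 0.5 * share(g1[2])
}

# Pr(G1, G2 | k) at one locus.
pair_locus_prob <- function(g1, g2, p, k) {
  p1 <- hwe_prob(g1[1], g1[2], p)
  same <- all(sort(g1) == sort(g2))
  k[1] * p1 * hwe_prob(g2[1], g2[2], p) +
    k[2] * p1 * ibd1_prob(g1, g2, p) +
    k[3] * p1 * as.numeric(same)
}

#' Mendelian, mitochondrial and X-linked parent-offspring exclusion
#'
#' A candidate parent is autosomally excluded when parent and offspring
#' share no allele at more than `tolerance` loci. Maternity is
#' additionally excluded when mtDNA haplotypes differ. For a male
#' candidate and a female offspring, the X-linked locus acts like an
#' autosomal check on the father's single X allele (a father transmits it
#' to every daughter); it contributes to the mismatch count. The X locus
#' is skipped for male offspring (they carry no paternal X).
#'
#' @param parent list with `genotype` (data frame `locus`, `allele1`,
#'   `allele2`), `sex` ("F"/"M"/NA), optional `haplotype`.
#' @param offspring list with `genotype`, optional `haplotype`, optional
#'   `sex` (needed for the X-linked rule).
#' @param tolerance mismatching loci tolerated before exclusion
#'   (default 0; a small tolerance absorbs genotyping error).
#' @param x_locus name of the X-linked locus (skipped from the autosomal
#'   rule and used hemizygously), or NULL.
#' @return list with `excluded`, `n_mismatch_loci`, `mismatch_loci`,
#'   `maternity_excluded`, `paternity_x_mismatch`.
#' @export
mendelian_exclusion <- function(parent, offspring, tolerance = 0,
                                x_locus = "Mc07") {
  gp <- parent$genotype; go <- offspring$genotype
  loci <- intersect(gp$locus, go$locus)
  if (!length(loci)) stop("invalid-argument: no shared loci")
  parent_sex <- parent$sex %||% NA_character_
  if (is.na(parent_sex) && !is.null(x_locus) && x_locus %in% loci)
    warning("parent candidate sex unknown: X-linked rule skipped")
  mism <- character(0)
  x_mism <- FALSE
  for (l in loci) {
    a <- unlist(gp[gp$locus == l, c("allele1", "allele2")])
    b <- unlist(go[go$locus == l, c("allele1", "allele2")])
    if (anyNA(a) || anyNA(b)) next
    if (!is.null(x_locus) && l == x_locus) {
      if (is.na(parent_sex)) next
      if (parent_sex == "M") {
        off_sex <- offspring$sex %||% NA_character_
        if (!is.na(off_sex) && off_sex == "F") {
          # father's single X (recorded as a homozygous pair) must appear
          # in the daughter's X genotype
          if (!(a[1] %in% b)) { mism <- c(mism, l); x_mism <- TRUE }
        }
      } else {
        # mother passes one of her X alleles to any offspring
        if (!any(a %in% b)) mism <- c(mism, l)
      }
      next
    }
    if (!any(a %in% b)) mism <- c(mism, l)
  }
  maternity_excluded <- FALSE
  if (!is.na(parent_sex) && parent_sex == "F" &&
      !is.null(parent$haplotype) && !is.null(offspring$haplotype) &&
      !is.na(parent$haplotype) && !is.na(offspring$haplotype) &&
      parent$haplotype != offspring$haplotype)
    maternity_excluded <- TRUE
  list(excluded = length(mism) > tolerance || maternity_excluded,
       n_mismatch_loci = length(mism),
       mismatch_loci = mism,
       maternity_excluded = maternity_excluded,
       paternity_x_mismatch = x_mism)
}

#' Pairwise relationship likelihood ratios
#'
#' Per locus, `Pr(G1, G2 | model) = k0 P0 + k1 P1 + k2 P2` where P0 is the
#' product of HWE genotype probabilities, P1 the probability under one
#' shared IBD allele and P2 the probability the genotypes are identical
#' given two shared IBD alleles; loci multiply and missing loci are
#' skipped. The X-linked locus is excluded (diploid formulas are invalid
#' for hemizygous males). An optional error term mixes each locus
#' likelihood with the unrelated-model value at rate `error_rate`,
#' shrinking per-locus evidence that could be manufactured by genotyping
#' error.
#'
#' @param g1,g2 genotype data frames (`locus`, `allele1`, `allele2`).
#' @param allele_freqs named list of per-locus allele frequency vectors.
#' @param models list of Cotterman triples (default
#'   [relationship_models()]).
#' @param x_locus X-linked locus name excluded from the LR (default
#'   "Mc07").
#' @param error_rate optional per-locus error mixing rate (default 0).
#' @return list with `logL` (per model), `LR` (vs unrelated),
#'   `best_model`, `n_loci_used`.
#' @export
pair_relationship_LR <- function(g1, g2, allele_freqs,
                                 models = relationship_models(),
                                 x_locus = "Mc07", error_rate = 0) {
  loci <- intersect(intersect(g1$locus, g2$locus), names(allele_freqs))
  loci <- setdiff(loci, x_locus)
  logL <- setNames(rep(0, length(models)), names(models))
  n_used <- 0
  for (l in loci) {
    a <- as.character(unlist(g1[g1$locus == l, c("allele1", "allele2")]))
    b <- as.character(unlist(g2[g2$locus == l, c("allele1", "allele2")]))
    if (anyNA(a) || anyNA(b)) next
    p <- allele_freqs[[l]]
    for (al in c(a, b)) if (!al %in% names(p))
      stop(sprintf("invalid-data: allele %s at locus %s absent from frequency table",
                   al, l))
    n_used <- n_used + 1
    p0 <- pair_locus_prob(a, b, p, c(1, 0, 0))
    for (m in names(models)) {
      pm <- pair_locus_prob(a, b, p, models[[m]])
      if (error_rate > 0) pm <- (1 - error_rate) * pm + error_rate * p0
      logL[m] <- logL[m] + log(pm)
    }
  }
  if (n_used == 0) stop("invalid-argument: no comparable loci")
  lr <- exp(logL - logL["unrelated"])
  list(logL = logL, LR = lr, best_model = names(which.max(logL)),
       n_loci_used = n_used)
}

#' Screen an individual catalog for full-sibling pairs
#'
#' Computes relationship likelihood ratios for every unordered pair of
#' individuals and reports those whose best-supported model is full-sib
#' with `LR >= lr_threshold` against unrelatedness, annotated same-site or
#' cross-site. Pairs are also run through the hard exclusions
#' (mtDNA for sibship/maternity) when haplotypes are available.
#'
#' @param catalog an `individual_catalog`, or NULL if `genotypes` given.
#' @param allele_freqs named list of per-locus frequencies.
#' @param lr_threshold minimum LR(full-sib : unrelated) to report
#'   (default 10).
#' @param genotypes optional long genotype data frame (`individual_id`,
#'   `locus`, `allele1`, `allele2`) overriding the catalog's.
#' @param sites optional named vector individual -> site.
#' @param haplotypes optional named vector individual -> mtDNA label;
#'   differing haplotypes exclude full sibship regardless of LR.
#' @param x_locus X-linked locus excluded from LRs.
#' @param error_rate optional LR error mixing rate.
#' @return data frame sorted by decreasing LR: `id_a`, `id_b`, `lr_fullsib`,
#'   `best_model`, `same_site`, `cross_site`, `sib_excluded_mtdna`,
#'   `n_loci`; attribute `n_pairs_tested`. Only rows flagged full-sib are
#'   returned; the complete table is attached as attribute `all_pairs`.
#' @export
screen_catalog <- function(catalog = NULL, allele_freqs, lr_threshold = 10,
                           genotypes = NULL, sites = NULL, haplotypes = NULL,
                           x_locus = "Mc07", error_rate = 0) {
  if (is.null(genotypes)) {
    if (is.null(catalog)) stop("supply `catalog` or `genotypes`")
    genotypes <- catalog$genotypes
    if (is.null(sites))
      sites <- setNames(catalog$individuals$site,
                        catalog$individuals$individual_id)
    if (is.null(haplotypes))
      haplotypes <- setNames(catalog$individuals$haplotype,
                             catalog$individuals$individual_id)
  }
  ids <- unique(genotypes$individual_id)
  if (length(ids) < 2) stop("invalid-argument: need at least 2 individuals")
  glist <- split(genotypes[, c("locus", "allele1", "allele2")],
                 genotypes$individual_id)
  rows <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      a <- ids[i]; b <- ids[j]
      lr <- pair_relationship_LR(glist[[as.character(a)]],
                                 glist[[as.character(b)]],
                                 allele_freqs, x_locus = x_locus,
                                 error_rate = error_rate)
      sib_excl <- FALSE
      if (!is.null(haplotypes)) {
        ha <- haplotypes[as.character(a)]; hb <- haplotypes[as.character(b)]
        if (!is.na(ha) && !is.na(hb) && ha != hb) sib_excl <- TRUE
      }
      same_site <- NA
      if (!is.null(sites)) {
        sa <- sites[as.character(a)]; sb <- sites[as.character(b)]
        same_site <- !is.na(sa) && !is.na(sb) && sa == sb
      }
      best <- lr$best_model
      if (sib_excl && best == "full-sib") best <- "unrelated"
      rows[[length(rows) + 1]] <- data.frame(
        id_a = a, id_b = b,
        lr_fullsib = unname(lr$LR["full-sib"]),
        lr_halfsib = unname(lr$LR["half-sib"]),
        lr_po = unname(lr$LR["parent-offspring"]),
        best_model = best,
        same_site = same_site, cross_site = isTRUE(!same_site),
        sib_excluded_mtdna = sib_excl,
        n_loci = lr$n_loci_used, stringsAsFactors = FALSE)
    }
  }
  all_pairs <- do.call(rbind, rows)
  all_pairs <- all_pairs[order(-all_pairs$lr_fullsib), ]
  rownames(all_pairs) <- NULL
  hits <- all_pairs[all_pairs$best_model == "full-sib" &
                    all_pairs$lr_fullsib >= lr_threshold, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_pairs_tested") <- nrow(all_pairs)
  attr(hits, "all_pairs") <- all_pairs
  hits
}
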