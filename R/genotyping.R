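# Consensus genotyping and individual identification from replicated
# microsatellite calls, plus the population-genetic summaries used to
# characterize the resulting individual catalog.

# Consensus rule for one locus of one sample. `a1`, `a2` are character
# vectors of the replicate calls (NA = missing). An allele is confirmed if
# it appears in >= min_conf replicates; a locus is consensus-heterozygous
# when exactly two alleles are confirmed, consensus-homozygous when one is
# confirmed and either it appears in >= min_conf + 1 replicates or every
# non-missing replicate agrees with it; three or more confirmed alleles
# void the locus (multi-allele flag). Unconfirmed extra alleles are
# flagged as putative false alleles.
consensus_locus <- function(a1, a2, min_conf = 2) {
  ok <- !is.na(a1)
  if (!any(ok)) return(list(alleles = c(NA, NA), flag = "missing"))
  a1 <- a1[ok]; a2 <- a2[ok]
  n_rep <- length(a1)
  alleles <- unique(c(a1, a2))
  support <- vapply(alleles, function(a) sum(a1 == a | a2 == a), integer(1))
  confirmed <- alleles[support >= min_conf]
  extra <- length(alleles) > length(confirmed)
  if (length(confirmed) == 2)
    return(list(alleles = sort(confirmed),
                flag = if (extra) "putative_false_allele" else "ok"))
  if (length(confirmed) == 1) {
    a <- confirmed
    unanimous <- all(a1 == a & a2 == a)
    if (support[match(a, alleles)] >= min_conf + 1 || unanimous)
      return(list(alleles = c(a, a),
                  flag = if (extra) "putative_false_allele" else "ok"))
    return(list(alleles = c(NA, NA), flag = "unconfirmed"))
  }
  if (length(confirmed) >= 3)
    return(list(alleles = c(NA, NA), flag = "multi_allele"))
  list(alleles = c(NA, NA), flag = "unconfirmed")
}

#' Build the consensus genotype of one sample
#'
#' Applies the replicate-confirmation rule locus by locus: an allele must
#' be seen in at least `min_confirmations` replicates to enter the
#' consensus; a homozygote additionally needs a third confirmation or
#' unanimity among non-missing replicates; loci with three or more
#' confirmed alleles are voided and flagged.
#'
#' @param replicates data frame with columns `locus`, `replicate`,
#'   `allele1`, `allele2` for a single sample (NA = failed amplification).
#' @param min_confirmations replicates required to confirm an allele.
#' @param loci optional character vector fixing the locus panel; unknown
#'   loci in `replicates` raise an error.
#' @return data frame (`locus`, `allele1`, `allele2`, `flag`) with
#'   attribute `n_confirmed_loci`.
#' @export
build_consensus <- function(replicates, min_confirmations = 2, loci = NULL) {
  if (!nrow(replicates)) stop("invalid-argument: no replicates supplied")
  if (is.null(loci)) loci <- unique(replicates$locus)
  if (!all(replicates$locus %in% loci))
    stop(sprintf("invalid-argument: unknown locus '%s'",
                 setdiff(replicates$locus, loci)[1]))
  out <- data.frame(locus = loci, allele1 = NA_character_,
                    allele2 = NA_character_, flag = "missing",
                    stringsAsFactors = FALSE)
  for (i in seq_along(loci)) {
    r <- replicates[replicates$locus == loci[i], , drop = FALSE]
    if (!nrow(r)) next
    cl <- consensus_locus(as.character(r$allele1), as.character(r$allele2),
                          min_confirmations)
    out$allele1[i] <- cl$alleles[1]
    out$allele2[i] <- cl$alleles[2]
    out$flag[i] <- cl$flag
  }
  attr(out, "n_confirmed_loci") <- sum(!is.na(out$allele1))
  out
}

#' Consensus genotypes for many samples
#'
#' Vectorized driver over [build_consensus()]'s rule; returns one wide row
#' per sample with two columns per locus.
#'
#' @param replicates long data frame (`sample_id`, `locus`, `replicate`,
#'   `allele1`, `allele2`).
#' @param min_confirmations replicates required to confirm an allele.
#' @return list with `a1`, `a2` (sample x locus character matrices of the
#'   sorted consensus pairs), `flags` (same shape), `sample_ids`, `loci`,
#'   `n_confirmed` per sample.
#' @export
consensus_genotypes <- function(replicates, min_confirmations = 2) {
  sample_ids <- unique(replicates$sample_id)
  loci <- unique(replicates$locus)
  ns <- length(sample_ids); nl <- length(loci)
  a1 <- a2 <- flags <- matrix(NA_character_, ns, nl,
                              dimnames = list(sample_ids, loci))
  si <- match(replicates$sample_id, sample_ids)
  li <- match(replicates$locus, loci)
  key <- (si - 1L) * nl + li
  ord <- order(key)
  key <- key[ord]
  ra1 <- as.character(replicates$allele1)[ord]
  ra2 <- as.character(replicates$allele2)[ord]
  starts <- c(1L, which(diff(key) != 0) + 1L)
  ends <- c(starts[-1] - 1L, length(key))
  for (g in seq_along(starts)) {
    idx <- starts[g]:ends[g]
    k <- key[starts[g]]
    s <- (k - 1L) %/% nl + 1L; l <- (k - 1L) %% nl + 1L
    cl <- consensus_locus(ra1[idx], ra2[idx], min_confirmations)
    a1[s, l] <- cl$alleles[1]; a2[s, l] <- cl$alleles[2]
    flags[s, l] <- cl$flag
  }
  list(a1 = a1, a2 = a2, flags = flags, sample_ids = sample_ids,
       loci = loci, n_confirmed = rowSums(!is.na(a1)))
}

#' Estimate genotyping error rates from replicate concordance
#'
#' A concordance estimator against the consensus: at consensus-
#' heterozygous loci, each consensus allele absent from a replicate call
#' counts one dropout event out of two opportunities per replicate; at any
#' locus with a consensus, each replicate allele not in the consensus
#' counts one false-allele event out of one opportunity per replicate.
#' Rates are events over opportunities per locus, with overall mean and sd
#' across loci.
#'
#' @param replicates long replicate table (`sample_id`, `locus`,
#'   `replicate`, `allele1`, `allele2`).
#' @param consensus optional output of [consensus_genotypes()]; computed
#'   if missing.
#' @return object of class `error_rates`: data frame per locus
#'   (`locus`, `dropout`, `false_allele`, `n_dropout_opp`, `n_fa_opp`)
#'   with attributes `dropout_mean`, `dropout_sd`, `fa_mean`, `fa_sd`.
#'   Loci with no heterozygous consensus have `dropout = NA` (undefined,
#'   not zero).
#' @export
estimate_error_rates <- function(replicates, consensus = NULL) {
  if (is.null(consensus)) consensus <- consensus_genotypes(replicates)
  si <- match(replicates$sample_id, consensus$sample_ids)
  li <- match(replicates$locus, consensus$loci)
  c1 <- consensus$a1[cbind(si, li)]
  c2 <- consensus$a2[cbind(si, li)]
  r1 <- as.character(replicates$allele1)
  r2 <- as.character(replicates$allele2)
  has_cons <- !is.na(c1)
  has_call <- !is.na(r1)
  use <- has_cons & has_call
  het <- use & (c1 != c2)
  # dropout: consensus allele not present in the replicate call
  d_events <- (het & r1 != c1 & r2 != c1) + (het & r1 != c2 & r2 != c2)
  # false allele: replicate allele absent from the consensus pair
  fa_events <- (use & r1 != c1 & r1 != c2) + (use & r2 != c1 & r2 != c2)
  fa_events <- pmin(fa_events, 1L)   # the model perturbs at most one allele
  loci <- consensus$loci
  per_locus <- data.frame(locus = loci, dropout = NA_real_,
                          false_allele = NA_real_,
                          n_dropout_opp = 0L, n_fa_opp = 0L)
  for (i in seq_along(loci)) {
    sel <- li == i
    nd <- 2L * sum(het[sel])
    nf <- sum(use[sel])
    per_locus$n_dropout_opp[i] <- nd
    per_locus$n_fa_opp[i] <- nf
    if (nd > 0) per_locus$dropout[i] <- sum(d_events[sel]) / nd
    if (nf > 0) per_locus$false_allele[i] <- sum(fa_events[sel]) / nf
  }
  structure(per_locus, class = c("error_rates", "data.frame"),
            dropout_mean = mean(per_locus$dropout, na.rm = TRUE),
            dropout_sd = sd(per_locus$dropout, na.rm = TRUE),
            fa_mean = mean(per_locus$false_allele, na.rm = TRUE),
            fa_sd = sd(per_locus$false_allele, na.rm = TRUE))
}

#' Assign sex from replicated sex-intron amplification results
#'
#' Male if the Y intron amplifies in at least two replicates with the X
#' intron present; female if the X intron amplifies in at least two
#' replicates and the Y intron in none; unknown otherwise.
#'
#' @param sex_markers data frame with logical columns `dbx`, `dby` (one
#'   row per replicate) for a single sample.
#' @return `"M"`, `"F"` or `"U"`.
#' @export
assign_sex <- function(sex_markers) {
  if (!nrow(sex_markers)) return("U")
  ndbx <- sum(sex_markers$dbx)
  ndby <- sum(sex_markers$dby)
  if (ndby >= 2 && ndbx >= 1) return("M")
  if (ndbx >= 2 && ndby == 0) return("F")
  "U"
}

#' Cluster samples into individuals by genotype matching
#'
#' Two samples link when their consensus genotypes mismatch at no more
#' than `max_mismatch` loci among the loci non-missing in both, provided
#' at least `min_loci_compared` loci were comparable; clusters are the
#' connected components of this link graph (single linkage), so a chain of
#' pairwise matches merges even when its endpoints differ at more than
#' `max_mismatch` loci — the reported cluster diameter makes such chained
#' merges auditable. Samples with fewer than `min_loci_compared`
#' non-missing loci are quarantined, never merged.
#'
#' @param consensus output of [consensus_genotypes()].
#' @param max_mismatch maximum mismatching loci for a link (default 2).
#' @param min_loci_compared minimum comparable loci (default 7 of 11).
#' @param samples optional data frame (`sample_id`, `site`, `x`, `y`,
#'   `visit`) with sample metadata carried into the catalog.
#' @param sex_calls optional named vector of per-sample sex calls
#'   ("F"/"M"/"U").
#' @param haplotypes optional named vector of per-sample mtDNA labels.
#' @return object of class `individual_catalog`: list with `individuals`
#'   (`individual_id`, `sex`, `site`, `n_samples`, `diameter`,
#'   `haplotype`), `membership` (`sample_id` -> `individual_id`),
#'   `genotypes` (per-individual majority consensus, long format),
#'   `detections` (`individual`, `x`, `y`, `visit`, `site`),
#'   `unassignable` (quarantined sample ids), `borderline_pairs`
#'   (cross-individual pairs differing at 1..max_mismatch loci, the ones a
#'   lab would re-amplify), and `site_totals`.
#' @export
match_individuals <- function(consensus, max_mismatch = 2,
                              min_loci_compared = 7, samples = NULL,
                              sex_calls = NULL, haplotypes = NULL) {
  ns <- length(consensus$sample_ids)
  if (!ns) stop("invalid-argument: empty consensus set")
  nl <- length(consensus$loci)
  ok_sample <- consensus$n_confirmed >= min_loci_compared
  A1 <- consensus$a1; A2 <- consensus$a2
  idx <- which(ok_sample)
  n <- length(idx)
  mism <- matrix(0L, n, n)
  comp <- matrix(0L, n, n)
  for (l in seq_len(nl)) {
    x1 <- A1[idx, l]; x2 <- A2[idx, l]
    present <- !is.na(x1)
    both <- outer(present, present, "&")
    eq <- outer(x1, x1, "==") & outer(x2, x2, "==")
    eq[is.na(eq)] <- FALSE
    comp <- comp + both
    mism <- mism + (both & !eq)
  }
  link <- comp >= min_loci_compared & mism <= max_mismatch
  diag(link) <- TRUE
  # connected components by label propagation
  comp_id <- seq_len(n)
  repeat {
    new_id <- apply(link, 1, function(row) min(comp_id[row]))
    if (all(new_id == comp_id)) break
    comp_id <- new_id
  }
  # canonical numbering: order components by their smallest sample id
  key <- vapply(unique(comp_id),
                function(cid) min(consensus$sample_ids[idx[comp_id == cid]]),
                character(1))
  remap <- match(comp_id, unique(comp_id)[order(key)])

  sample_site <- sample_x <- sample_y <- sample_visit <- NULL
  if (!is.null(samples)) {
    m <- match(consensus$sample_ids, samples$sample_id)
    sample_site <- samples$site[m]
    sample_x <- samples$x[m]; sample_y <- samples$y[m]
    sample_visit <- samples$visit[m]
  }

  n_ind <- max(remap)
  individuals <- data.frame(individual_id = seq_len(n_ind),
                            sex = "U", site = NA_character_,
                            n_samples = 0L, diameter = 0L,
                            haplotype = NA_character_,
                            stringsAsFactors = FALSE)
  membership <- data.frame(sample_id = consensus$sample_ids[idx],
                           individual_id = remap, stringsAsFactors = FALSE)
  geno_rows <- list()
  for (ind in seq_len(n_ind)) {
    members <- idx[remap == ind]
    pos <- match(members, idx)
    individuals$n_samples[ind] <- length(members)
    individuals$diameter[ind] <- if (length(members) > 1)
      max(mism[pos, pos]) else 0L
    if (!is.null(sex_calls)) {
      sx <- sex_calls[consensus$sample_ids[members]]
      sx <- sx[!is.na(sx) & sx != "U"]
      individuals$sex[ind] <- if (length(unique(sx)) == 1) unique(sx) else "U"
    }
    if (!is.null(haplotypes)) {
      hp <- haplotypes[consensus$sample_ids[members]]
      hp <- hp[!is.na(hp)]
      individuals$haplotype[ind] <- if (length(unique(hp)) == 1)
        unique(hp) else NA_character_
    }
    if (!is.null(sample_site)) {
      st <- unique(sample_site[match(members, seq_len(ns))])
      individuals$site[ind] <- st[1]
    }
    # per-locus majority genotype; ties broken by sorted pair label
    for (l in seq_len(nl)) {
      pairs <- paste(A1[members, l], A2[members, l], sep = "/")
      pairs <- pairs[!is.na(A1[members, l])]
      if (!length(pairs)) { al <- c(NA_character_, NA_character_) }
      else {
        tab <- sort(table(pairs), decreasing = TRUE)
        best <- names(tab)[tab == max(tab)]
        al <- strsplit(sort(best)[1], "/", fixed = TRUE)[[1]]
      }
      geno_rows[[length(geno_rows) + 1]] <-
        data.frame(individual_id = ind, locus = consensus$loci[l],
                   allele1 = al[1], allele2 = al[2], stringsAsFactors = FALSE)
    }
  }
  genotypes <- do.call(rbind, geno_rows)

  detections <- NULL
  if (!is.null(sample_x)) {
    mrows <- match(membership$sample_id, consensus$sample_ids)
    detections <- data.frame(individual = membership$individual_id,
                             x = sample_x[mrows], y = sample_y[mrows],
                             visit = sample_visit[mrows],
                             site = sample_site[mrows],
                             stringsAsFactors = FALSE)
  }

  # borderline pairs across individuals (1..max_mismatch mismatches but
  # failed the link rule, or linked only through chains)
  bp <- which(mism >= 1 & mism <= max_mismatch &
              outer(remap, remap, "!=") & upper.tri(mism), arr.ind = TRUE)
  borderline <- if (nrow(bp)) data.frame(
    sample_a = consensus$sample_ids[idx[bp[, 1]]],
    sample_b = consensus$sample_ids[idx[bp[, 2]]],
    mismatches = mism[bp], comparable = comp[bp]) else
    data.frame(sample_a = character(0), sample_b = character(0),
               mismatches = integer(0), comparable = integer(0))

  site_totals <- NULL
  if (!is.null(sample_site)) {
    site_totals <- as.data.frame(table(site = individuals$site,
                                       sex = individuals$sex))
    names(site_totals)[3] <- "n_individuals"
  }
  structure(list(individuals = individuals, membership = membership,
                 genotypes = genotypes, detections = detections,
                 unassignable = consensus$sample_ids[!ok_sample],
                 borderline_pairs = borderline,
                 site_totals = site_totals,
                 loci = consensus$loci,
                 max_mismatch = max_mismatch,
                 min_loci_compared = min_loci_compared),
            class = "individual_catalog")
}

#' @export
print.individual_catalog <- function(x, ...) {
  cat(sprintf("<individual_catalog: %d individuals from %d samples (%d quarantined)>\n",
              nrow(x$individuals), nrow(x$membership), length(x$unassignable)))
  invisible(x)
}

#' Per-locus diversity statistics over an individual catalog
#'
#' Computed over unique individuals: allele count Na, observed
#' heterozygosity H_O, unbiased expected heterozygosity
#' `H_E = (2n/(2n-1)) (1 - sum p^2)`, per-locus `F_IS = 1 - H_O/H_E`, and
#' overall `F_IS = 1 - mean(H_O)/mean(H_E)` across loci. The X-linked
#' locus is excluded by default (hemizygous males violate the diploid
#' estimators).
#'
#' @param catalog an `individual_catalog`.
#' @param exclude_loci loci dropped from the table (default the X-linked
#'   `Mc07`).
#' @return data frame (`locus`, `n`, `Na`, `Ho`, `He`, `Fis`) with
#'   attribute `overall_Fis`. Monomorphic loci have `He = 0` and
#'   `Fis = NA`.
#' @export
diversity_stats <- function(catalog, exclude_loci = "Mc07") {
  g <- catalog$genotypes
  g <- g[!g$locus %in% exclude_loci & !is.na(g$allele1), , drop = FALSE]
  loci <- setdiff(catalog$loci, exclude_loci)
  out <- data.frame(locus = loci, n = 0L, Na = NA_integer_, Ho = NA_real_,
                    He = NA_real_, Fis = NA_real_)
  for (i in seq_along(loci)) {
    gl <- g[g$locus == loci[i], , drop = FALSE]
    n <- nrow(gl)
    out$n[i] <- n
    if (n < 2) next
    alleles <- c(gl$allele1, gl$allele2)
    p <- table(alleles) / (2 * n)
    out$Na[i] <- length(p)
    out$Ho[i] <- mean(gl$allele1 != gl$allele2)
    out$He[i] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    if (out$He[i] > 0) out$Fis[i] <- 1 - out$Ho[i] / out$He[i]
  }
  ok <- !is.na(out$He)
  attr(out, "overall_Fis") <-
    1 - mean(out$Ho[ok], na.rm = TRUE) / mean(out$He[ok], na.rm = TRUE)
  out
}

#' Probability of identity and exclusion power of a locus panel
#'
#' Per locus, the probability two unrelated individuals share a genotype
#' is `PID = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2`; for full sibs
#' `PIDsib = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4`.
#' Multi-locus values multiply across loci. The one-parent exclusion
#' probability of a locus is the chance a random unrelated candidate
#' shares no allele with a random offspring,
#' `Q = sum_i p_i^2 (1-p_i)^2 + sum_{i<j} 2 p_i p_j (1 - p_i - p_j)^2`,
#' combined as `1 - prod(1 - Q)`.
#'
#' @param allele_freqs list of per-locus frequency vectors (each summing
#'   to 1).
#' @return list with `pid`, `pid_sib`, `exclusion_probability` and the
#'   per-locus table.
#' @export
probability_of_identity <- function(allele_freqs) {
  if (!length(allele_freqs)) stop("invalid-argument: empty frequency set")
  per <- lapply(allele_freqs, function(p) {
    if (!length(p)) stop("invalid-argument: empty frequency vector")
    if (abs(sum(p) - 1) > 1e-8) stop("invalid-argument: frequencies must sum to 1")
    s2 <- sum(p^2); s4 <- sum(p^4)
    pid <- s4 + sum((2 * outer(p, p))[upper.tri(outer(p, p))]^2)
    pidsib <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
    q <- sum(p^2 * (1 - p)^2)
    if (length(p) > 1) {
      pr <- outer(p, p); tot <- outer(p, p, function(a, b) (1 - a - b)^2)
      q <- q + sum((2 * pr * tot)[upper.tri(pr)])
    }
    c(pid = pid, pid_sib = pidsib, q = q)
  })
  tab <- do.call(rbind, per)
  list(pid = prod(tab[, "pid"]),
       pid_sib = prod(tab[, "pid_sib"]),
       exclusion_probability = 1 - prod(1 - tab[, "q"]),
       per_locus = data.frame(locus = names(allele_freqs), tab,
                              row.names = NULL))
}
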