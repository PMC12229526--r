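#!/usr/bin/env Rscript
# Stage 2 — consensus genotypes from the PCR replicates, concordance
# error rates, sample-to-individual matching under the two-mismatch rule,
# sex assignment from the intron markers, and the diversity summary of
# the resulting catalog.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

study <- build_study()
reps <- study$genotypes$replicates

cons <- consensus_genotypes(reps)
err <- estimate_error_rates(reps, cons)
sex_calls <- vapply(split(study$genotypes$sex_markers,
                          study$genotypes$sex_markers$sample_id),
                    assign_sex, character(1))
hap <- setNames(study$genotypes$haplotypes$haplotype,
                study$genotypes$haplotypes$sample_id)
catalog <- match_individuals(cons, samples = study$samples,
                             sex_calls = sex_calls, haplotypes = hap)
stats <- diversity_stats(catalog)
pid <- probability_of_identity(catalog_allele_freqs(catalog)[
  setdiff(catalog$loci, "Mc07")])

dir.create(file.path(RESULTS, "genotyping"), showWarnings = FALSE)
write.csv(as.data.frame(err), file.path(RESULTS, "genotyping", "error_rates.csv"),
          row.names = FALSE)
write.csv(catalog$individuals, file.path(RESULTS, "genotyping", "individuals.csv"),
          row.names = FALSE)
write.csv(as.data.frame(stats), file.path(RESULTS, "genotyping", "locus_stats.csv"),
          row.names = FALSE)
write_genepop(catalog, file.path(RESULTS, "genotyping", "catalog.gen"))

cat(sprintf("dropout %.2f%% +/- %.2f%%, false alleles %.3f%%\n",
            100 * attr(err, "dropout_mean"), 100 * attr(err, "dropout_sd"),
            100 * attr(err, "fa_mean")))
cat(sprintf("%d individuals identified (%d quarantined samples)\n",
            nrow(catalog$individuals), length(catalog$unassignable)))
print(table(site = catalog$individuals$site, sex = catalog$individuals$sex))
cat(sprintf("Na %d-%d, He %.2f-%.2f, overall F_IS %.3f\n",
            min(stats$Na, na.rm = TRUE), max(stats$Na, na.rm = TRUE),
            min(stats$He, na.rm = TRUE), max(stats$He, na.rm = TRUE),
            attr(stats, "overall_Fis")))
cat(sprintf("panel PID %.2e, PIDsib %.2e, exclusion %.4f\n",
            pid$pid, pid$pid_sib, pid$exclusion_probability))
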