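#!/usr/bin/env Rscript

# Stage 2: genotyping-error model and quality control.
#
# Pushes the true genotypes through a multi-tubes replicate protocol with
# allelic dropout and miscoring, builds consensus genotypes under the
# 4-heterozygote / 7-homozygote rule, and screens the consensus data with
# per-locus diversity statistics, Hardy-Weinberg tests, and a null-allele
# screen.

library(costsweep)

tab <- read_genotypes("results/genotypes.csv", format = "csv")

reps <- make_replicates(tab, dropout_rate = 0.10, misscore_rate = 0.02,
                        n_reps = 8, seed = 11)
cons <- consensus_table(reps, tab)

concordant <- mean((cons$a1 == tab$a1 & cons$a2 == tab$a2), na.rm = TRUE)
missing <- mean(is.na(cons$a1))
write.csv(data.frame(statistic = c("consensus_concordance",
                                   "consensus_missing_rate"),
                     value = c(concordant, missing)),
          "results/qc_consensus.csv", row.names = FALSE)
log_stage(sprintf("qc: consensus concordance %.3f, missing %.3f",
                  concordant, missing))

# screen within one group: pooling diverged groups would read the Wahlund
# heterozygote deficit as null alleles
g <- names(which.max(table(cons$group_id)))
stats <- locus_stats(cons)
stats$hwe_p <- vapply(stats$locus, function(l) {
  tryCatch(hwe_test(cons, g, l, n_perm = 2000, seed = 12),
           error = function(e) NA_real_)
}, numeric(1))
nulls <- lapply(stats$locus, function(l)
  null_allele_screen(cons, l, group = g, n_boot = 500, seed = 13))
stats$null_r <- vapply(nulls, `[[`, numeric(1), "r")
stats$null_flagged <- vapply(nulls, `[[`, logical(1), "flagged")
write.csv(stats, "results/qc_locus_stats.csv", row.names = FALSE)

write_genotypes(cons, "results/genotypes_consensus.csv", format = "csv")
log_stage(sprintf("qc: %d loci screened, %d flagged for null alleles",
                  nrow(stats), sum(stats$null_flagged)))
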